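# Closed-form references and manufactured solutions used by the test suite
# and the acceptance checks. Every oracle is pure and evaluable without
# running the simulator.

#' Poiseuille velocity profile
#'
#' Fully developed laminar profile in a plane channel:
#' `u(y) = 6 * u_mean * (y/H) * (1 - y/H)` with `u_mean = Q / (H * W)`.
#' Integrates back to the flow rate: `integral(u dy) * W = Q`.
#'
#' @param Q volumetric flow rate (m^3 s^-1); `H` channel height (m);
#'   `W` out-of-plane depth (m); `y` cross-channel coordinate(s) in `[0, H]`.
#' @export
poiseuille_profile <- function(Q, H, W, y) {
  stopifnot(all(y >= 0 & y <= H))
  u_mean <- Q / (H * W)
  6 * u_mean * (y / H) * (1 - y / H)
}

#' Well-mixed Langmuir binding curve
#'
#' Closed form of the binding ODE at constant concentration `c`:
#' `b(t) = b_eq + (b0 - b_eq) * exp(-(kon*c + koff) * t)` with
#' `b_eq = bmax * kon * c / (kon*c + koff)`.
#'
#' @param t time(s) (s); `c` constant analyte concentration (mol m^-3).
#' @param params a [surface_kinetics_params()]; `b0` initial coverage.
#' @export
well_mixed_langmuir <- function(t, c, params, b0 = 0) {
  k <- params$kon * c + params$koff
  b_eq <- if (k > 0) params$bmax * params$kon * c / k else b0
  b_eq + (b0 - b_eq) * exp(-k * t)
}

#' Manufactured-solution transport case
#'
#' Returns a verification case for the convection-diffusion discretization:
#' an exact concentration field, the analytically prescribed divergence-free
#' velocity, and the closed-form source that makes the exact field solve the
#' transport equation. Spatial cases are steady (solved by one large
#' backward-Euler step from the exact field); the temporal case has a
#' spatially exact (linear) profile so the measured error is purely the
#' first-order time discretization.
#'
#' Regimes on the unit square (`L = H = 1` m):
#' \describe{
#'   \item{diffusion}{`D = 1`, recirculating velocity of magnitude 0.5:
#'     cell Peclet below 1 at every level, expected spatial order 2.}
#'   \item{advection}{`D = 1e-3`, velocity magnitude 1: cell Peclet well
#'     above 1 on the coarse levels, expected spatial order at least 1 from
#'     the PIS upwinding.}
#'   \item{temporal}{zero velocity, linear-in-space exact field decaying in
#'     time: expected temporal order 1 (backward Euler).}
#' }
#'
#' @param level mesh-density level: the grid has `4 * 2^level + 1` nodes per
#'   side.
#' @param regime one of `"diffusion"`, `"advection"`, `"temporal"`.
#' @return list with the `bs_geometry`, `D`, `vel_fn(x, y)`, exact
#'   `c_fn(x, y, t)`, source `S_fn(x, y, t)` and the regime label.
#' @export
mms_case <- function(level, regime = c("diffusion", "advection", "temporal")) {
  regime <- match.arg(regime)
  stopifnot(level >= 1, level <= 6)
  n <- 4L * 2L^level + 1L
  geom <- geometry_config(L = 1, H = 1, Ls = 1, Nx = n, Ny = n, Ns = n)
  if (regime == "temporal") {
    D <- 1
    vel_fn <- function(x, y) cbind(0 * x, 0 * y)
    c_fn <- function(x, y, t) (1 + x + 2 * y) * exp(-t)
    S_fn <- function(x, y, t) -(1 + x + 2 * y) * exp(-t)  # dc/dt, Laplacian = 0
  } else {
    D <- if (regime == "diffusion") 1 else 1e-3
    U <- if (regime == "diffusion") 0.5 else 1
    vel_fn <- function(x, y)
      cbind(U * sin(pi * x) * cos(pi * y), -U * cos(pi * x) * sin(pi * y))
    c_fn <- function(x, y, t) 1 + sin(pi * x) * sin(pi * y)
    # steady: S = u . grad(c) - D * Laplacian(c)
    S_fn <- function(x, y, t) {
      dcdx <- pi * cos(pi * x) * sin(pi * y)
      dcdy <- pi * sin(pi * x) * cos(pi * y)
      lap <- -2 * pi^2 * sin(pi * x) * sin(pi * y)
      uv <- vel_fn(x, y)
      uv[, 1] * dcdx + uv[, 2] * dcdy - D * lap
    }
  }
  list(geom = geom, D = D, vel_fn = vel_fn, c_fn = c_fn, S_fn = S_fn,
       regime = regime, level = level)
}

#' Solve a manufactured-solution case and return its L2 error
#'
#' Spatial regimes: all four sides carry Dirichlet data from the exact field
#' and the steady solution is obtained with one backward-Euler step of
#' `dt = 1e9` s from the exact field. Temporal regime: marches from the exact
#' initial field to `t = 0.5` with the given `dt`.
#'
#' @param case a [mms_case()]; `dt` time-step for the temporal regime.
#' @return list with the volume-weighted `l2_error`, the mesh spacing `h`
#'   and the node count.
#' @export
run_mms <- function(case, dt = 0.05) {
  mesh <- build_channel_mesh(case$geom)
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  bc_dir <- list(type = "dirichlet", value = case$c_fn)
  bc <- list(inlet = bc_dir, outlet = bc_dir, top = bc_dir, bottom = bc_dir)
  params <- transport_params(D = case$D, c0 = 0, S = case$S_fn)
  if (case$regime == "temporal") {
    st <- transport_stepper(mesh, NULL, params, dt, bc, vel_fn = case$vel_fn)
    cc <- case$c_fn(x, y, 0)
    t_end <- 0.5
    nsteps <- round(t_end / dt)
    for (s in seq_len(nsteps)) cc <- step_transport(st, cc, s * dt)
    err <- cc - case$c_fn(x, y, t_end)
  } else {
    dt_big <- 1e9
    st <- transport_stepper(mesh, NULL, params, dt_big, bc, vel_fn = case$vel_fn)
    cc <- step_transport(st, case$c_fn(x, y, 0), dt_big)
    err <- cc - case$c_fn(x, y, 0)
  }
  list(l2_error = sqrt(sum(mesh$cv_area * err^2) / sum(mesh$cv_area)),
       h = 1 / (case$geom$Nx - 1L), n = nrow(mesh$nodes))
}

#' Observed convergence order over a sequence of levels
#'
#' Least-squares slope of `log(error)` against `log(h)` (spatial regimes) or
#' `log(dt)` (temporal regime, fixed fine mesh with `dt` halved per level).
#'
#' @param levels integer vector of [mms_case()] levels (spatial) or the
#'   number of dt-halvings (temporal).
#' @param regime as in [mms_case()].
#' @return list with the fitted `order` and the per-level `errors`.
#' @export
mms_convergence <- function(levels = 1:4,
                            regime = c("diffusion", "advection", "temporal")) {
  regime <- match.arg(regime)
  if (regime == "temporal") {
    case <- mms_case(3, "temporal")
    dts <- 0.1 / 2^(seq_along(levels) - 1L)
    errs <- vapply(dts, function(dt) run_mms(case, dt)$l2_error, numeric(1))
    hs <- dts
  } else {
    res <- lapply(levels, function(l) run_mms(mms_case(l, regime)))
    errs <- vapply(res, `[[`, numeric(1), "l2_error")
    hs <- vapply(res, `[[`, numeric(1), "h")
  }
  list(order = as.numeric(-stats::coef(stats::lm(log(errs) ~ log(1 / hs)))[2]),
       errors = errs, h = hs)
}

#' Packaged validation-case configuration
#'
#' Reads the configuration shipped in `inst/extdata/validation_case.cfg`:
#' the micro-chamber DNA-hybridization binding experiment (flow rate
#' 7e-11 m^3/s, inlet concentration 2.5e-6 mol/m^3, chamber 1e-2 x 1e-3 m,
#' bmax 1.668e-8 mol/m^2, kon 75 m^3/(mol s), koff 1e-2 1/s, duration
#' 1e5 s). The whole bottom wall is taken as the reactive sensor strip
#' (sensor position is not specified by the source tables) and the diffusion
#' coefficient, absent from those tables, is set to 1e-10 m^2/s (typical for
#' short DNA strands); both assumptions are flagged in the file and the run
#' log.
#'
#' @return a `bs_config` (see [read_config()]).
#' @export
validation_fixture <- function() {
  read_config(system.file("extdata", "validation_case.cfg",
                          package = "biosensim", mustWork = TRUE))
}
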