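# Implicit coupled (u, v, p) CVFEM solver for 2D incompressible laminar flow.
# Continuity is closed with Karimian-Schneider momentum-interpolated
# integration-point velocities (pressure-aware "hat" velocities on the
# collocated grid); momentum convection uses the PIS streamline-upwind
# closure. Nonlinear terms are Picard-linearized: the mass flux and the KS
# cross-terms are frozen at the previous iterate, everything else is implicit.

#' Fluid properties
#' @param rho density (kg m^-3).
#' @param mu dynamic viscosity (Pa s).
#' @export
fluid_properties <- function(rho, mu) {
  if (!(rho > 0) || !(mu > 0)) stop("rho and mu must be positive")
  structure(list(rho = rho, mu = mu), class = "bs_fluid")
}

#' Karimian-Schneider coupling coefficient
#'
#' `beta = rho * |Vbar| / As + mu / L_ref^2`, with `Vbar` the element-mean
#' velocity, `As` the element area and `L_ref` the reference length (the
#' channel height by default). Strictly positive for any viscous fluid; the
#' two terms are the convective and diffusive weights of the PIS
#' momentum-interpolated velocity, which therefore sum to one after division
#' by `beta`.
#'
#' @param vbar_mag element-mean velocity magnitude (m s^-1).
#' @param area element area (m^2 per unit depth).
#' @param rho,mu fluid density and viscosity.
#' @param L_ref reference length (m).
#' @export
compute_beta <- function(vbar_mag, area, rho, mu, L_ref) {
  if (any(area <= 0)) stop("element area must be positive")
  rho * abs(vbar_mag) / area + mu / L_ref^2
}

#' Karimian-Schneider hat velocity at an integration point
#'
#' The continuity-equation velocity
#' `u_hat = u_BL - (1/beta) * (-rho*(u*dv/dy - v*du/dy) + dp/dx - dpdx_bar)`
#' (and the analogous `v_hat`), which reduces to the interpolated velocity
#' `u_BL` when the pressure-gradient deviation and cross-terms vanish.
#'
#' `dpdx_bar`, `dpdy_bar` are the smooth (nodal-interpolated) pressure
#' gradients at the point. On a collocated grid the stabilizing pressure term
#' must be the deviation of the local shape-function gradient from this
#' smooth gradient: the deviation is zero for any linear pressure field (so a
#' developed channel flow is not distorted) while a checkerboard pressure
#' mode, invisible to the nodal gradient, is fully damped. With the defaults
#' `dpdx_bar = dpdy_bar = 0` the literal raw-gradient form is evaluated.
#'
#' @param u_bl,v_bl bilinearly interpolated velocity at the point.
#' @param beta coupling coefficient (from [compute_beta()]).
#' @param rho density.
#' @param dudx,dudy,dvdx,dvdy velocity gradients at the point.
#' @param dpdx,dpdy shape-function pressure gradient at the point.
#' @param dpdx_bar,dpdy_bar smooth nodal-interpolated pressure gradient.
#' @param u,v convecting velocity at the point (defaults to `u_bl`, `v_bl`).
#' @return c(u_hat, v_hat)
#' @export
ks_hat_velocity <- function(u_bl, v_bl, beta, rho, dudx, dudy, dvdx, dvdy,
                            dpdx, dpdy, dpdx_bar = 0, dpdy_bar = 0,
                            u = u_bl, v = v_bl) {
  stopifnot(beta > 0)
  c(u_bl - (-rho * (u * dvdy - v * dudy) + dpdx - dpdx_bar) / beta,
    v_bl - (-rho * (v * dudx - u * dvdx) + dpdy - dpdy_bar) / beta)
}

#' PIS momentum integration-point velocity
#'
#' `u_j = w_up * u_up + w_bl * u_BL - (1/beta) * dP/dx` with
#' `w_up = (rho*|Vbar|/As)/beta`, `w_bl = (mu/L_ref^2)/beta`; the two
#' velocity weights sum to one.
#'
#' @param u_up upwind (PIS) velocity, `u_bl` interpolated velocity.
#' @param vbar_mag,area,rho,mu,L_ref as in [compute_beta()].
#' @param dpd pressure gradient component in the equation's direction.
#' @export
pis_momentum_velocity <- function(u_up, u_bl, vbar_mag, area, rho, mu, L_ref,
                                  dpd = 0) {
  beta <- compute_beta(vbar_mag, area, rho, mu, L_ref)
  w_up <- (rho * abs(vbar_mag) / area) / beta
  (w_up * u_up + (1 - w_up) * u_bl) - dpd / beta
}

# ---- geometry tables shared by flow and transport assembly -----------------

# Per-mesh precomputation: shape weights at the 4 ips (4x4, rows = ip),
# physical shape gradients Gx, Gy (nel x 4ip x 4node) and ip coordinates.
# Channel meshes are axis-aligned rectangles, so the Jacobian is diagonal.
element_tables <- function(mesh) {
  nel <- nrow(mesh$elem)
  Nw <- t(vapply(1:4, function(k) bilinear_shape(IP_REF[k, 1], IP_REF[k, 2]),
                 numeric(4)))
  Gr <- lapply(1:4, function(k) bilinear_grad_ref(IP_REF[k, 1], IP_REF[k, 2]))
  dx <- mesh$x[mesh$elem_ij[, 1] + 1L] - mesh$x[mesh$elem_ij[, 1]]
  dy <- mesh$y[mesh$elem_ij[, 2] + 1L] - mesh$y[mesh$elem_ij[, 2]]
  Gx <- array(0, dim = c(nel, 4L, 4L))
  Gy <- array(0, dim = c(nel, 4L, 4L))
  ipx <- matrix(0, nel, 4L); ipy <- matrix(0, nel, 4L)
  ex <- matrix(mesh$nodes[mesh$elem, 1], ncol = 4L)
  ey <- matrix(mesh$nodes[mesh$elem, 2], ncol = 4L)
  for (k in 1:4) {
    for (m in 1:4) {
      Gx[, k, m] <- Gr[[k]][1, m] * 2 / dx
      Gy[, k, m] <- Gr[[k]][2, m] * 2 / dy
    }
    ipx[, k] <- ex %*% Nw[k, ]
    ipy[, k] <- ey %*% Nw[k, ]
  }
  # nodal finite-difference gradient stencils (2 entries per node, central in
  # the interior, one-sided on the boundary) used for the smooth pressure
  # gradient in the KS closure
  fd <- function(coord, idx, stride, N) {
    n <- length(coord)
    cA <- integer(N); cB <- integer(N); wA <- numeric(N); wB <- numeric(N)
    all_id <- seq_len(N)
    lo <- idx == 1L; hi <- idx == n; mid <- !(lo | hi)
    h <- numeric(N)
    h[mid] <- coord[idx[mid] + 1L] - coord[idx[mid] - 1L]
    cA[mid] <- all_id[mid] - stride; cB[mid] <- all_id[mid] + stride
    h[lo] <- coord[2L] - coord[1L]
    cA[lo] <- all_id[lo]; cB[lo] <- all_id[lo] + stride
    h[hi] <- coord[n] - coord[n - 1L]
    cA[hi] <- all_id[hi] - stride; cB[hi] <- all_id[hi]
    wA <- -1 / h; wB <- 1 / h
    list(cA = cA, cB = cB, wA = wA, wB = wB)
  }
  N <- nrow(mesh$nodes)
  fdx <- fd(mesh$x, mesh$node_i, 1L, N)
  fdy <- fd(mesh$y, mesh$node_j, mesh$nx, N)
  list(Nw = Nw, Gx = Gx, Gy = Gy, ipx = ipx, ipy = ipy,
       dx = dx, dy = dy, area = dx * dy,
       dsx = mesh$ds[, , 1], dsy = mesh$ds[, , 2],
       fdx = fdx, fdy = fdy)
}

# nodal finite-difference gradient of a field (vectors length N)
nodal_gradient <- function(et, f) {
  list(dx = et$fdx$wA * f[et$fdx$cA] + et$fdx$wB * f[et$fdx$cB],
       dy = et$fdy$wA * f[et$fdy$cA] + et$fdy$wB * f[et$fdy$cB])
}

# Upwind matrices for all elements given ip velocities (nel x 4 each).
# Axis-aligned rectangles let element corners be reconstructed cheaply.
all_upwind_matrices <- function(mesh, et, uip, vip, u_ref) {
  nel <- nrow(mesh$elem)
  C <- array(0, dim = c(nel, 4L, 4L))
  corners0 <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  for (e in seq_len(nel)) {
    corners <- cbind(corners0[, 1] * et$dx[e] + mesh$nodes[mesh$elem[e, 1], 1],
                     corners0[, 2] * et$dy[e] + mesh$nodes[mesh$elem[e, 1], 2])
    C[e, , ] <- element_upwind_matrix(corners,
                                      cbind(uip[e, ], vip[e, ]),
                                      u_ref = u_ref)
  }
  C
}

# gradient of nodal field f at all ips: list(dx = nel x 4, dy = nel x 4)
ip_gradient <- function(mesh, et, f) {
  fe <- matrix(f[mesh$elem], ncol = 4L)
  gx <- matrix(0, nrow(fe), 4L); gy <- gx
  for (k in 1:4) {
    gx[, k] <- rowSums(fe * et$Gx[, k, ])
    gy[, k] <- rowSums(fe * et$Gy[, k, ])
  }
  list(dx = gx, dy = gy)
}

# nodal field at ips (nel x 4)
ip_values <- function(mesh, et, f) {
  fe <- matrix(f[mesh$elem], ncol = 4L)
  fe %*% t(et$Nw)
}

# ---- flow boundary conditions ----------------------------------------------

# inlet velocity profile vector over the ny inlet nodes
inlet_profile_values <- function(mesh, u0_mean, profile = c("uniform", "parabolic")) {
  profile <- match.arg(profile)
  y <- mesh$y; H <- mesh$geom$H
  if (profile == "uniform") rep(u0_mean, length(y))
  else 6 * u0_mean * (y / H) * (1 - y / H)
}

#' One implicit flow step
#'
#' Advances the coupled (u, v, p) system by one backward-Euler step of size
#' `dt` (use `dt = Inf` for a steady Picard solve). Momentum convection uses
#' the PIS upwind closure, continuity uses KS hat velocities; the nonlinear
#' mass flux and cross-terms are Picard-iterated until the relative velocity
#' change is below `tol`.
#'
#' @param mesh a `bs_mesh`.
#' @param state list with numeric vectors `u`, `v`, `p` (previous state).
#' @param props a [fluid_properties()] object.
#' @param u_in inlet velocity values at the inlet column nodes.
#' @param dt time-step (s); `Inf` drops the transient term.
#' @param L_ref KS reference length; defaults to the channel height.
#' @param tol Picard relative-change tolerance.
#' @param max_iter Picard iteration cap.
#' @param et precomputed [element tables] (internal; recomputed if NULL).
#' @return updated state list with `u`, `v`, `p`, Picard iteration count and
#'   residual.
#' @export
solve_flow_step <- function(mesh, state, props, u_in, dt = Inf,
                            L_ref = NULL, tol = 1e-6, max_iter = 30,
                            et = NULL) {
  if (!(dt > 0)) stop("dt must be positive")
  if (is.null(et)) et <- element_tables(mesh)
  if (is.null(L_ref)) L_ref <- mesh$geom$H
  N <- nrow(mesh$nodes)
  u <- state$u; v <- state$v; p <- state$p
  u_scale <- max(abs(u_in), 1e-300)
  res <- NA_real_
  for (it in seq_len(max_iter)) {
    sys <- assemble_flow(mesh, et, u, v, p, props, u_in, dt,
                         u_old = state$u, v_old = state$v,
                         L_ref = L_ref, u_scale = u_scale)
    sol <- Matrix::solve(sys$A, sys$b)
    u_new <- as.numeric(sol[1:N])
    v_new <- as.numeric(sol[N + 1:N])
    p_new <- as.numeric(sol[2 * N + 1:N])
    res <- max(abs(u_new - u), abs(v_new - v)) / u_scale
    u <- u_new; v <- v_new; p <- p_new
    if (res < tol) break
  }
  if (res >= tol)
    stop(sprintf("flow Picard iteration failed to converge: residual %.3e after %d iterations",
                 res, max_iter))
  list(u = u, v = v, p = p, iterations = it, residual = res)
}

# Assemble the 3N x 3N coupled system for one Picard iteration.
# Frozen at the previous iterate: mass flux (rho * hat-velocity . ds), the KS
# cross-terms, beta and the upwind matrices. Implicit: u_BL, viscous fluxes,
# pressure (both the momentum surface force and the KS/PIS pressure-gradient
# corrections).
assemble_flow <- function(mesh, et, u0, v0, p0, props, u_in, dt,
                          u_old, v_old, L_ref, u_scale) {
  N <- nrow(mesh$nodes); nel <- nrow(mesh$elem)
  rho <- props$rho; mu <- props$mu
  elem <- mesh$elem
  Nw <- et$Nw; dsx <- et$dsx; dsy <- et$dsy

  uip <- ip_values(mesh, et, u0); vip <- ip_values(mesh, et, v0)
  gu <- ip_gradient(mesh, et, u0); gv <- ip_gradient(mesh, et, v0)
  gp <- ip_gradient(mesh, et, p0)

  vbx <- rowMeans(matrix(u0[elem], ncol = 4L))
  vby <- rowMeans(matrix(v0[elem], ncol = 4L))
  vmag <- sqrt(vbx^2 + vby^2)
  beta <- compute_beta(vmag, et$area, rho, mu, L_ref)
  w_up <- (rho * vmag / et$area) / beta

  Cup <- all_upwind_matrices(mesh, et, uip, vip, u_ref = u_scale)

  # KS cross-terms (lagged) and frozen hat velocities / mass flux; the
  # pressure term is the deviation from the smooth nodal gradient
  gpn <- nodal_gradient(et, p0)
  gpbx <- ip_values(mesh, et, gpn$dx)
  gpby <- ip_values(mesh, et, gpn$dy)
  crx <- -rho * (uip * gv$dy - vip * gu$dy)
  cry <- -rho * (vip * gu$dx - uip * gv$dx)
  uhat0 <- uip - (crx + gp$dx - gpbx) / beta
  vhat0 <- vip - (cry + gp$dy - gpby) / beta
  mflux <- rho * (uhat0 * dsx + vhat0 * dsy)      # nel x 4

  iu <- function(n) n; iv <- function(n) N + n; ip_ <- function(n) 2L * N + n

  blocks <- 4L * 4L * 24L
  ri <- vector("list", blocks); ci <- vector("list", blocks); xi <- vector("list", blocks)
  nb <- 0L
  add <- function(r, c, x) {
    nb <<- nb + 1L
    ri[[nb]] <<- r; ci[[nb]] <<- c; xi[[nb]] <<- x
  }
  rhs <- numeric(3L * N)
  add_rhs <- function(r, x) {
    s <- rowsum(x, r)
    idx <- as.integer(rownames(s))
    rhs[idx] <<- rhs[idx] + as.numeric(s)
  }

  for (k in 1:4) {
    rp <- elem[, k]; rm <- elem[, NXT[k]]
    dkx <- dsx[, k]; dky <- dsy[, k]
    mk <- mflux[, k]
    for (m in 1:4) {
      cm <- elem[, m]
      # u-momentum: advection (PIS) + viscous on u_m; pressure + PIS dP on p_m
      au <- mk * (w_up * Cup[, k, m] + (1 - w_up) * Nw[k, m]) -
        mu * (et$Gx[, k, m] * dkx + et$Gy[, k, m] * dky)
      ap <- -(mk / beta) * et$Gx[, k, m] + Nw[k, m] * dkx
      add(iu(rp), iu(cm), au); add(iu(rm), iu(cm), -au)
      add(iu(rp), ip_(cm), ap); add(iu(rm), ip_(cm), -ap)
      # v-momentum
      av <- mk * (w_up * Cup[, k, m] + (1 - w_up) * Nw[k, m]) -
        mu * (et$Gx[, k, m] * dkx + et$Gy[, k, m] * dky)
      bp <- -(mk / beta) * et$Gy[, k, m] + Nw[k, m] * dky
      add(iv(rp), iv(cm), av); add(iv(rm), iv(cm), -av)
      add(iv(rp), ip_(cm), bp); add(iv(rm), ip_(cm), -bp)
      # continuity (volume flux of hat velocities)
      cu <- Nw[k, m] * dkx
      cv <- Nw[k, m] * dky
      cp <- -(et$Gx[, k, m] * dkx + et$Gy[, k, m] * dky) / beta
      add(ip_(rp), iu(cm), cu); add(ip_(rm), iu(cm), -cu)
      add(ip_(rp), iv(cm), cv); add(ip_(rm), iv(cm), -cv)
      add(ip_(rp), ip_(cm), cp); add(ip_(rm), ip_(cm), -cp)
      # smooth nodal pressure gradient interpolated to the ip (opposite sign)
      coefx <- Nw[k, m] * dkx / beta
      coefy <- Nw[k, m] * dky / beta
      for (blk in list(list(et$fdx$cA, et$fdx$wA, coefx),
                       list(et$fdx$cB, et$fdx$wB, coefx),
                       list(et$fdy$cA, et$fdy$wA, coefy),
                       list(et$fdy$cB, et$fdy$wB, coefy))) {
        cc <- blk[[1]][cm]; vv <- blk[[3]] * blk[[2]][cm]
        add(ip_(rp), ip_(cc), vv); add(ip_(rm), ip_(cc), -vv)
      }
    }
    # lagged cross-terms -> RHS of continuity
    rc <- (crx[, k] * dkx + cry[, k] * dky) / beta
    add_rhs(ip_(rp), rc); add_rhs(ip_(rm), -rc)
  }

  rows <- unlist(ri[seq_len(nb)]); cols <- unlist(ci[seq_len(nb)])
  vals <- unlist(xi[seq_len(nb)])

  # transient term (skipped for steady dt = Inf)
  if (is.finite(dt)) {
    dcoef <- rho * mesh$cv_area / dt
    rows <- c(rows, iu(1:N), iv(1:N))
    cols <- c(cols, iu(1:N), iv(1:N))
    vals <- c(vals, dcoef, dcoef)
    rhs[iu(1:N)] <- rhs[iu(1:N)] + dcoef * u_old
    rhs[iv(1:N)] <- rhs[iv(1:N)] + dcoef * v_old
  }

  # inlet boundary mass influx into the inlet-node control volumes
  tg <- mesh$tags
  jin <- mesh$node_j[tg$inlet]
  rhs[ip_(tg$inlet)] <- rhs[ip_(tg$inlet)] + u_in[jin] * mesh$wy[jin]

  # constraint rows: Dirichlet velocity, outlet zero-gradient u / v = 0 / p = 0
  noslip <- c(tg$wall, tg$sensor)
  dir_idx <- c(iu(tg$inlet), iv(tg$inlet), iu(noslip), iv(noslip),
               iv(tg$outlet), ip_(tg$outlet))
  dir_val <- c(u_in[jin], rep(0, length(tg$inlet)),
               rep(0, 2L * length(noslip)),
               rep(0, 2L * length(tg$outlet)))
  out_rows <- iu(tg$outlet)
  keep <- !(rows %in% c(dir_idx, out_rows))
  rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
  # zero-streamwise-gradient u at outlet: u(nx, j) - u(nx-1, j) = 0
  nb_out <- tg$outlet - 1L
  rows <- c(rows, out_rows, out_rows, dir_idx)
  cols <- c(cols, iu(tg$outlet), iu(nb_out), dir_idx)
  vals <- c(vals, rep(1, length(out_rows)), rep(-1, length(out_rows)),
            rep(1, length(dir_idx)))
  rhs[out_rows] <- 0
  rhs[dir_idx] <- dir_val

  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(3L * N, 3L * N))
  list(A = A, b = rhs)
}

# Hat velocities, volume fluxes and upwind matrices of a converged state
# (consumed by the transport stage and by the conservation audits).
flow_ip_state <- function(mesh, et, u, v, p, props, L_ref, u_scale) {
  rho <- props$rho; mu <- props$mu
  elem <- mesh$elem
  uip <- ip_values(mesh, et, u); vip <- ip_values(mesh, et, v)
  gu <- ip_gradient(mesh, et, u); gv <- ip_gradient(mesh, et, v)
  gp <- ip_gradient(mesh, et, p)
  vbx <- rowMeans(matrix(u[elem], ncol = 4L))
  vby <- rowMeans(matrix(v[elem], ncol = 4L))
  beta <- compute_beta(sqrt(vbx^2 + vby^2), et$area, rho, mu, L_ref)
  gpn <- nodal_gradient(et, p)
  gpbx <- ip_values(mesh, et, gpn$dx)
  gpby <- ip_values(mesh, et, gpn$dy)
  crx <- -rho * (uip * gv$dy - vip * gu$dy)
  cry <- -rho * (vip * gu$dx - uip * gv$dx)
  uhat <- uip - (crx + gp$dx - gpbx) / beta
  vhat <- vip - (cry + gp$dy - gpby) / beta
  qf <- uhat * et$dsx + vhat * et$dsy       # volume flux per face, nel x 4
  list(uhat = uhat, vhat = vhat, qf = qf)
}

# Net hat-velocity volume flux out of every node's control volume, plus the
# inlet boundary influx (negative out-flux) on inlet-node volumes.
continuity_residuals <- function(mesh, ips, u_in) {
  N <- nrow(mesh$nodes)
  r <- numeric(N)
  elem <- mesh$elem
  for (k in 1:4) {
    s <- rowsum(ips$qf[, k], elem[, k]); i <- as.integer(rownames(s))
    r[i] <- r[i] + as.numeric(s)
    s <- rowsum(ips$qf[, k], elem[, NXT[k]]); i <- as.integer(rownames(s))
    r[i] <- r[i] - as.numeric(s)
  }
  jin <- mesh$node_j[mesh$tags$inlet]
  r[mesh$tags$inlet] <- r[mesh$tags$inlet] - u_in[jin] * mesh$wy[jin]
  r
}

#' Volumetric flux through a cross-section
#'
#' Trapezoid-quadrature integral of `u` over the mesh column nearest `x_pos`
#' (per unit depth; multiply by the depth for m^3/s).
#' @param mesh a `bs_mesh`; `state` a flow state; `x_pos` position (m).
#' @export
cross_section_flux <- function(mesh, state, x_pos) {
  i <- which.min(abs(mesh$x - x_pos))
  cols <- which(mesh$node_i == i)
  sum(state$u[cols] * mesh$wy[mesh$node_j[cols]])
}

#' Steady flow field
#'
#' Solves the steady coupled system by Picard iteration (a backward-Euler
#' step with `dt = Inf`), then audits discrete continuity: the hat-velocity
#' flux imbalance of every interior control volume must be below
#' `mass_tol` times the inlet flux.
#'
#' @param mesh a `bs_mesh`.
#' @param props a [fluid_properties()].
#' @param Q volumetric flow rate (m^3 s^-1).
#' @param depth_W out-of-plane depth (m) converting `Q` to the mean inlet
#'   velocity `u0 = Q / (H * W)`.
#' @param inlet_profile `"uniform"` (default) or `"parabolic"`.
#' @param tol Picard relative tolerance; `max_iter` its cap.
#' @param mass_tol continuity audit threshold (relative to inlet flux).
#' @return a `bs_flow` object: nodal `u`, `v`, `p`, the integration-point
#'   state (`ips`: hat velocities and face volume fluxes), `u_in`, and the
#'   continuity audit.
#' @export
steady_flow <- function(mesh, props, Q, depth_W = 1,
                        inlet_profile = "uniform",
                        tol = 1e-9, max_iter = 50, mass_tol = 1e-8) {
  et <- element_tables(mesh)
  H <- mesh$geom$H
  u0_mean <- Q / (H * depth_W)
  u_in <- inlet_profile_values(mesh, u0_mean, inlet_profile)
  N <- nrow(mesh$nodes)
  state <- list(u = numeric(N), v = numeric(N), p = numeric(N))
  if (u0_mean == 0) {
    return(structure(list(u = state$u, v = state$v, p = state$p,
                          u_in = u_in, et = et,
                          ips = flow_ip_state(mesh, et, state$u, state$v,
                                              state$p, props, H, 1),
                          max_continuity_residual = 0, Q_in = 0,
                          iterations = 0L),
                     class = "bs_flow"))
  }
  st <- solve_flow_step(mesh, state, props, u_in, dt = Inf,
                        tol = tol, max_iter = max_iter, et = et)
  u_scale <- max(abs(u_in))
  ips <- flow_ip_state(mesh, et, st$u, st$v, st$p, props, H, u_scale)
  Q_in <- sum(u_in[mesh$node_j[mesh$tags$inlet]] *
                mesh$wy[mesh$node_j[mesh$tags$inlet]])
  resid <- continuity_residuals(mesh, ips, u_in)
  rmax <- max(abs(resid[mesh$tags$interior])) / abs(Q_in)
  if (rmax > mass_tol)
    stop(sprintf("steady flow failed the continuity audit: max CV imbalance %.3e x inlet flux",
                 rmax))
  structure(list(u = st$u, v = st$v, p = st$p, u_in = u_in, et = et,
                 ips = ips, max_continuity_residual = rmax,
                 Q_in = Q_in, iterations = st$iterations),
            class = "bs_flow")
}
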