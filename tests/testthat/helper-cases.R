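# Shared fixtures and memoized heavy runs (computed once per test session).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

unit_square_corners <- function() cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

small_channel_config <- function(...) {
  defaults <- list(L = 1e-2, H = 1e-3, Ls = 1e-2, Q = 7e-11, c0 = 2.5e-6,
                   D = 1e-10, bmax = 1.668e-8, kon = 75, koff = 1e-2,
                   Nx = 31, Ny = 9, Ns = 31, rho = 1000, mu = 1e-3,
                   dt = 10, t_end = 200)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# classical RK4 integration of the binding ODE: the high-accuracy independent
# oracle for the exponential surface update and the closed-form curve
rk4_langmuir <- function(t_end, c_conc, kin, b0 = 0, h = 0.25) {
  f <- function(b) kin$kon * c_conc * (kin$bmax - b) - kin$koff * b
  n <- ceiling(t_end / h); h <- t_end / n
  b <- b0
  for (i in seq_len(n)) {
    k1 <- f(b); k2 <- f(b + h / 2 * k1); k3 <- f(b + h / 2 * k2)
    k4 <- f(b + h * k3)
    b <- b + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  b
}

shoelace <- function(q) {
  n <- nrow(q)
  0.5 * abs(sum(q[, 1] * q[c(2:n, 1), 2] - q[c(2:n, 1), 1] * q[, 2]))
}

# ---- memoized acceptance-scale runs ---------------------------------------

acc_poiseuille_flow <- function() memo("poiseuille81x41", {
  g <- geometry_config(L = 1e-2, H = 1e-3, Ls = 1e-2, Nx = 81, Ny = 41, Ns = 81)
  mesh <- build_channel_mesh(g)
  props <- fluid_properties(rho = 1000, mu = 1e-3)
  list(mesh = mesh, flow = steady_flow(mesh, props, Q = 7e-11))
})

# criterion 2/3 scenario: validation kinetics with D and Q scaled up 1e3x
acc_wellmixed_run <- function() memo("wellmixed1e3", {
  cfg <- small_channel_config(Q = 7e-8, D = 1e-7, Nx = 41, Ny = 11, Ns = 41,
                              dt = 0.5, t_end = 900, c_init = 2.5e-6)
  run_binding_cycle(cfg)
})

acc_validation_run <- function() memo("validation1e5", {
  run_binding_cycle(validation_fixture(), record_every = 10L)
})

acc_mms_orders <- function() memo("mms_orders", {
  list(diffusion = mms_convergence(1:4, "diffusion"),
       advection = mms_convergence(1:4, "advection"),
       temporal = mms_convergence(1:4, "temporal"))
})
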