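test_that("KS coupling coefficient follows the stated grouping", {
  # stagnant limit
  expect_equal(compute_beta(0, 1e-8, rho = 1000, mu = 1e-3, L_ref = 1e-3),
               1e-3 / 1e-6)
  # arithmetic on the stated grouping: rho*|V|/As + mu/L^2
  expect_equal(compute_beta(1e-4, 1e-8, rho = 1000, mu = 1e-3, L_ref = 1e-3),
               1.0e7 + 1.0e3)
  # doubling the element area strictly decreases beta
  b1 <- compute_beta(1e-4, 1e-8, 1000, 1e-3, 1e-3)
  b2 <- compute_beta(1e-4, 2e-8, 1000, 1e-3, 1e-3)
  expect_lt(b2, b1)
  expect_error(compute_beta(1, 0, 1000, 1e-3, 1e-3), "positive")
})

test_that("KS hat velocity reduces to the interpolated velocity and sees pressure", {
  # uniform flow, no pressure gradient: all corrections vanish
  expect_equal(ks_hat_velocity(2, 1, beta = 50, rho = 1000,
                               0, 0, 0, 0, 0, 0), c(2, 1))
  # stagnant fluid driven down the pressure gradient
  expect_equal(ks_hat_velocity(0, 0, beta = 50, rho = 1000,
                               0, 0, 0, 0, dpdx = 10, dpdy = 0),
               c(-10 / 50, 0))
  # manufactured values: term-by-term hand evaluation
  u <- 1.5; v <- -0.5; dudx <- 2; dudy <- -1; dvdx <- 0.5; dvdy <- 3
  dpdx <- 7; dpdy <- -4; rho <- 2; beta <- 10
  ref_u <- u - (-rho * (u * dvdy - v * dudy) + dpdx) / beta
  ref_v <- v - (-rho * (v * dudx - u * dvdx) + dpdy) / beta
  expect_equal(ks_hat_velocity(u, v, beta, rho, dudx, dudy, dvdx, dvdy,
                               dpdx, dpdy), c(ref_u, ref_v))
  # the smooth-gradient deviation form cancels a linear pressure field
  expect_equal(ks_hat_velocity(u, v, beta, rho, 0, 0, 0, 0,
                               dpdx = 7, dpdy = -4,
                               dpdx_bar = 7, dpdy_bar = -4,
                               u = 0, v = 0), c(u, v))
})

test_that("PIS momentum velocity weights are convex", {
  # upwind equals interpolated: recovered exactly regardless of the split
  expect_equal(pis_momentum_velocity(3, 3, vbar_mag = 0.7, area = 1e-8,
                                     rho = 1000, mu = 1e-3, L_ref = 1e-3), 3)
  # stagnant flow: pure diffusion limit returns the interpolated value
  expect_equal(pis_momentum_velocity(99, 3, vbar_mag = 0, area = 1e-8,
                                     rho = 1000, mu = 1e-3, L_ref = 1e-3), 3)
  # equal convective/diffusive weights: arithmetic mean plus pressure term
  rho <- 1000; mu <- 1e-3; L <- 1e-3; As <- 1e-8
  vmag <- (mu / L^2) * As / rho    # makes rho*vmag/As = mu/L^2
  beta <- compute_beta(vmag, As, rho, mu, L)
  expect_equal(pis_momentum_velocity(1, 3, vmag, As, rho, mu, L, dpd = 5),
               (1 + 3) / 2 - 5 / beta)
})

test_that("steady channel flow recovers Poiseuille and conserves mass", {
  g <- geometry_config(L = 1e-2, H = 1e-3, Ls = 1e-2, Nx = 41, Ny = 21, Ns = 41)
  mesh <- build_channel_mesh(g)
  props <- fluid_properties(rho = 1000, mu = 1e-3)
  Q <- 7e-11
  flow <- steady_flow(mesh, props, Q)
  u_mean <- Q / g$H
  u_ref <- poiseuille_profile(Q, g$H, 1, mesh$y)
  i <- which.min(abs(mesh$x - 0.6 * g$L))
  u <- flow$u[mesh$node_i == i]
  expect_lt(max(abs(u - u_ref)) / max(u_ref), 0.01)
  # global balance: inlet flux = outlet flux to 0.1%
  expect_lt(abs(cross_section_flux(mesh, flow, g$L) - flow$Q_in) /
              abs(flow$Q_in), 1e-3)
  # interior continuity audit threshold held
  expect_lt(flow$max_continuity_residual, 1e-8)
  # symmetry about the mid-plane
  expect_lt(max(abs(u - rev(u))) / max(u), 1e-10)
  # zero inlet flow: identically zero field
  f0 <- steady_flow(mesh, props, Q = 0)
  expect_equal(max(abs(f0$u)), 0)
  expect_equal(max(abs(f0$v)), 0)
})

test_that("the converged field is a fixed point of a finite time step", {
  g <- geometry_config(L = 1e-2, H = 1e-3, Ls = 1e-2, Nx = 21, Ny = 11, Ns = 21)
  mesh <- build_channel_mesh(g)
  props <- fluid_properties(rho = 1000, mu = 1e-3)
  flow <- steady_flow(mesh, props, Q = 7e-11)
  st <- solve_flow_step(mesh, list(u = flow$u, v = flow$v, p = flow$p),
                        props, flow$u_in, dt = 100, tol = 1e-10)
  u_scale <- max(abs(flow$u_in))
  expect_lt(max(abs(st$u - flow$u)) / u_scale, 1e-8)
  expect_lt(max(abs(st$v - flow$v)) / u_scale, 1e-8)
})

test_that("the Stokes-regime field is invariant to the viscosity", {
  g <- geometry_config(L = 1e-2, H = 1e-3, Ls = 1e-2, Nx = 21, Ny = 11, Ns = 21)
  mesh <- build_channel_mesh(g)
  f1 <- steady_flow(mesh, fluid_properties(1000, 1e-3), Q = 7e-11)
  f2 <- steady_flow(mesh, fluid_properties(1000, 2e-3), Q = 7e-11)
  u_scale <- max(abs(f1$u))
  # away from the inlet development cells (where the pressure-stabilization
  # magnitude, which scales with 1/beta, leaves a mu-dependent imprint) the
  # converged field is viscosity-independent at fixed Q
  sel <- mesh$node_i == which.min(abs(mesh$x - 0.6e-2))
  expect_lt(max(abs(f1$u[sel] - f2$u[sel]),
                abs(f1$v[sel] - f2$v[sel])) / u_scale, 1e-4)
  # even including the development region the fields agree to about the
  # stabilization error level
  expect_lt(max(abs(f1$u - f2$u)) / u_scale, 0.02)
})

test_that("grid refinement converges to Poiseuille at second order", {
  errs <- vapply(c(6, 11, 21), function(ny) {
    g <- geometry_config(L = 1e-2, H = 1e-3, Ls = 1e-2,
                         Nx = 2 * ny - 1, Ny = ny, Ns = 2 * ny - 1)
    mesh <- build_channel_mesh(g)
    flow <- steady_flow(mesh, fluid_properties(1000, 1e-3), Q = 7e-11)
    u_ref <- poiseuille_profile(7e-11, 1e-3, 1, mesh$y)
    i <- which.min(abs(mesh$x - 0.6e-2))
    u <- flow$u[mesh$node_i == i]
    sqrt(mean((u - u_ref)^2)) / max(u_ref)
  }, numeric(1))
  h <- 1 / (c(6, 11, 21) - 1)
  order <- as.numeric(-coef(lm(log(errs) ~ log(1 / h)))[2])
  expect_gte(order, 1.8)
})
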