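test_that("diffusive flux follows Fick's law at the integration faces", {
  g <- geometry_config(L = 1, H = 1, Ls = 1, Nx = 4, Ny = 4, Ns = 4)
  m <- build_channel_mesh(g)
  # uniform field: zero flux
  f0 <- diffusive_flux(m, rep(4.2, nrow(m$nodes)), D = 3)
  expect_equal(max(abs(f0$fx)), 0)
  expect_equal(max(abs(f0$fn)), 0)
  # linear field c = x with D = 2: F = (-2, 0) exactly, everywhere
  f1 <- diffusive_flux(m, m$nodes[, 1], D = 2)
  expect_equal(as.numeric(f1$fx), rep(-2, length(f1$fx)))
  expect_lt(max(abs(f1$fy)), 1e-14)
})

test_that("equilibrium states are preserved exactly", {
  g <- geometry_config(L = 1, H = 1, Ls = 1, Nx = 5, Ny = 5, Ns = 5)
  m <- build_channel_mesh(g)
  bc <- list(inlet = list(type = "neumann0"), outlet = list(type = "neumann0"),
             top = list(type = "neumann0"), bottom = list(type = "neumann0"))
  params <- transport_params(D = 1, c0 = 1)
  st <- transport_stepper(m, NULL, params, dt = 0.1, bc,
                          vel_fn = function(x, y) cbind(0 * x, 0 * y))
  cc <- rep(0.7, nrow(m$nodes))
  for (s in 1:5) cc <- biosensim:::step_transport(st, cc, s * 0.1)
  expect_equal(cc, rep(0.7, nrow(m$nodes)), tolerance = 1e-13)
  # zero field stays zero with c0 = 0 and no sources
  st2 <- transport_stepper(m, NULL, transport_params(1, 0), dt = 0.1,
                           vel_fn = function(x, y) cbind(0 * x + 1, 0 * y))
  z <- numeric(nrow(m$nodes))
  expect_equal(biosensim:::step_transport(st2, z, 0.1), z)
})

test_that("a plug-flow front advects at the flow speed", {
  g <- geometry_config(L = 1, H = 1, Ls = 1, Nx = 51, Ny = 5, Ns = 51)
  m <- build_channel_mesh(g)
  params <- transport_params(D = 1e-6, c0 = 1)
  st <- transport_stepper(m, NULL, params, dt = 0.005,
                          vel_fn = function(x, y) cbind(0 * x + 1, 0 * y))
  cc <- numeric(nrow(m$nodes))
  nstep <- 80L                      # t = 0.4
  for (s in seq_len(nstep)) cc <- biosensim:::step_transport(st, cc, s * 0.005)
  mid <- cc[m$node_j == 3L]
  front <- approx(mid, m$x, xout = 0.5)$y
  expect_lt(abs(front - 0.4), 1 / 50)
  # boundedness of the upwind advection
  expect_gt(min(cc), -1e-12)
  expect_lt(max(cc), 1 + 1e-12)
})

test_that("manufactured sources match numerical differentiation of the exact field", {
  for (regime in c("diffusion", "advection", "temporal")) {
    case <- mms_case(2, regime)
    set.seed(3)
    x <- runif(20, 0.1, 0.9); y <- runif(20, 0.1, 0.9); t <- runif(1, 0, 1)
    h <- 1e-5
    dct <- (case$c_fn(x, y, t + h) - case$c_fn(x, y, t - h)) / (2 * h)
    dcx <- (case$c_fn(x + h, y, t) - case$c_fn(x - h, y, t)) / (2 * h)
    dcy <- (case$c_fn(x, y + h, t) - case$c_fn(x, y - h, t)) / (2 * h)
    lap <- (case$c_fn(x + h, y, t) - 2 * case$c_fn(x, y, t) +
              case$c_fn(x - h, y, t)) / h^2 +
      (case$c_fn(x, y + h, t) - 2 * case$c_fn(x, y, t) +
         case$c_fn(x, y - h, t)) / h^2
    uv <- case$vel_fn(x, y)
    S_num <- dct + uv[, 1] * dcx + uv[, 2] * dcy - case$D * lap
    expect_equal(case$S_fn(x, y, t), S_num, tolerance = 1e-5)
    # prescribed velocity is divergence-free
    dux <- (case$vel_fn(x + h, y)[, 1] - case$vel_fn(x - h, y)[, 1]) / (2 * h)
    dvy <- (case$vel_fn(x, y + h)[, 2] - case$vel_fn(x, y - h)[, 2]) / (2 * h)
    expect_lt(max(abs(dux + dvy)), 1e-6)
  }
})

test_that("sensor flux enters as a conservative boundary sink", {
  g <- geometry_config(L = 1e-2, H = 1e-3, Ls = 1e-2, Nx = 31, Ny = 9, Ns = 31)
  m <- build_channel_mesh(g)
  props <- fluid_properties(1000, 1e-3)
  Q <- 7e-9                        # keep the sink a modest fraction of Q*c0
  flow <- steady_flow(m, props, Q)
  c0 <- 2.5e-6
  params <- transport_params(D = 1e-9, c0 = c0)
  st <- transport_stepper(m, flow, params, dt = 1e9)
  sys <- list(A = st$Afull,
              b = biosensim:::transport_rhs(st, numeric(nrow(m$nodes)), 1e9),
              stepper = st)
  # zero rate: identical right-hand side
  b0 <- apply_sensor_flux(sys, m, numeric(31))$b
  expect_equal(b0, sys$b)
  # uniform rate r: total sink = r * Ls per unit depth
  r <- 0.3 * flow$Q_in * c0 / 1e-2
  sys_r <- apply_sensor_flux(sys, m, rep(r, 31))
  keep <- !(m$sensor_nodes %in% st$dir$nodes)
  expect_equal(sum(sys$b[m$sensor_nodes[keep]] - sys_r$b[m$sensor_nodes[keep]]),
               r * sum(m$sensor_face_len[keep]), tolerance = 1e-12)
  expect_error(apply_sensor_flux(sys, m, numeric(5)), "length")

  # steady state with the constant sink: inflow - outflow = sink to 0.1%
  cc <- solve_transport_step(sys_r)
  bal <- biosensim:::species_balance(st, flow, cc, cc, rep(r, 31), 0)
  sink <- r * sum(m$sensor_face_len[keep])
  expect_lt(abs(bal$inflow - bal$outflow - sink) / (flow$Q_in * c0), 1e-3)
})

test_that("time stepping is first-order accurate in dt", {
  case <- mms_case(3, "temporal")
  e1 <- run_mms(case, dt = 0.05)$l2_error
  e2 <- run_mms(case, dt = 0.025)$l2_error
  ratio <- e1 / e2
  expect_gt(ratio, 1.85)
  expect_lt(ratio, 2.15)
})

test_that("missing boundary assignments are configuration errors", {
  g <- geometry_config(L = 1, H = 1, Ls = 1, Nx = 4, Ny = 4, Ns = 4)
  m <- build_channel_mesh(g)
  bc <- list(inlet = list(type = "dirichlet", value = 1),
             outlet = list(type = "outflow"), top = list(type = "neumann0"))
  expect_error(
    transport_stepper(m, NULL, transport_params(1, 1), 0.1, bc,
                      vel_fn = function(x, y) cbind(0 * x, 0 * y)),
    "bottom")
})
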