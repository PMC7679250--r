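test_that("bilinear shape functions interpolate and partition unity", {
  expect_equal(bilinear_shape(0, 0), rep(0.25, 4))
  expect_equal(bilinear_shape(-1, -1), c(1, 0, 0, 0))
  # direct-formula oracle at an off-centre point
  xi <- 0.5; eta <- -0.5
  ref <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
           (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
  expect_equal(bilinear_shape(xi, eta), ref)
  set.seed(1)
  for (i in 1:20) {
    w <- bilinear_shape(runif(1, -1, 1), runif(1, -1, 1))
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("streamline upwind point finds the upstream edge crossing", {
  P <- unit_square_corners()
  ctr <- c(0.5, 0.5)
  # flow in +x: upstream ray crosses the left edge (local edge 4) midpoint
  sp <- streamline_upwind_point(P, ctr, 1, 0)
  expect_false(sp$fallback)
  expect_equal(sp$edge_id, 4L)
  expect_equal(sp$a_frac, sp$b_frac)
  expect_equal(sort(sp$donors), c(1L, 4L))
  # flow in -y: upstream ray crosses the top edge with equal fractions
  sp2 <- streamline_upwind_point(P, ctr, 0, -1)
  expect_equal(sp2$edge_id, 3L)
  expect_equal(sp2$a_frac, sp2$b_frac)
  # diagonal flow from the bottom-left corner: corner tie-break
  sp3 <- streamline_upwind_point(P, ctr, 1, 1)
  w <- sp3$weights
  expect_equal(sum(w), 1)
  expect_equal(w[1], 1)          # full weight on the corner node
  expect_true(min(sp3$a_frac, sp3$b_frac) == 0)
  # zero velocity: no upwind direction
  expect_true(streamline_upwind_point(P, ctr, 0, 0)$fallback)
})

test_that("upwind interpolation along the crossed edge is exact", {
  P <- unit_square_corners()
  sp <- streamline_upwind_point(P, c(0.5, 0.5), 1, 0)
  phi <- c(1, 2, 3, 4)
  # donors are nodes 4 and 1 with equal fractions: mean(phi4, phi1) = 2.5
  expect_equal(upwind_value(sp, phi), 2.5)
  # nodal collocation at a corner hit
  sp2 <- streamline_upwind_point(P, c(0.5, 0.5), 1, 1)
  expect_equal(upwind_value(sp2, phi), phi[1])
  expect_error(upwind_value(streamline_upwind_point(P, c(.5, .5), 0, 0), phi),
               "fallback")
})

test_that("element upwind matrix rows are convex and respect the flow", {
  P <- unit_square_corners()
  # uniform +x flow: each row has exactly two nonzeros, on the left-edge donors
  C <- element_upwind_matrix(P, cbind(rep(1, 4), rep(0, 4)))
  for (k in 1:4) {
    expect_equal(sum(C[k, ] > 0), 2L)
    expect_setequal(which(C[k, ] > 0), c(1L, 4L))
    expect_equal(sum(C[k, ]), 1)
  }
  # zero flow: fallback to bilinear weights at each integration point
  C0 <- element_upwind_matrix(P, matrix(0, 4, 2))
  for (k in 1:4)
    expect_equal(C0[k, ], bilinear_shape(biosensim:::IP_REF[k, 1],
                                         biosensim:::IP_REF[k, 2]))
  # property: any velocity field gives convex rows, and the upwind value is
  # bounded by the donor extremes
  set.seed(42)
  for (rep in 1:25) {
    vel <- matrix(rnorm(8), 4, 2)
    Cr <- element_upwind_matrix(P, vel)
    expect_equal(rowSums(Cr), rep(1, 4))
    expect_true(all(Cr >= -1e-14 & Cr <= 1 + 1e-14))
    phi <- rnorm(4)
    up <- Cr %*% phi
    expect_true(all(up >= min(phi) - 1e-12 & up <= max(phi) + 1e-12))
  }
})

test_that("global assembly honors Dirichlet rows and face antisymmetry", {
  # all-Dirichlet single element: identity system returns the boundary values
  sys <- assemble_global(4, integer(0), integer(0), numeric(0),
                         dirichlet_idx = 1:4, dirichlet_val = c(5, 6, 7, 8))
  expect_equal(as.numeric(Matrix::solve(sys$A, sys$b)), c(5, 6, 7, 8))
  expect_error(assemble_global(4, 1L, 1:2, 1), "mismatched")

  # pure-diffusion operator with no outflow: columns sum to zero (global
  # conservation) and a uniform field is in its null space
  g <- geometry_config(L = 1, H = 1, Ls = 1, Nx = 5, Ny = 5, Ns = 5)
  m <- build_channel_mesh(g)
  et <- biosensim:::element_tables(m)
  bc <- list(inlet = list(type = "neumann0"), outlet = list(type = "neumann0"),
             top = list(type = "neumann0"), bottom = list(type = "neumann0"))
  zero_vel <- matrix(0, nrow(m$elem), 4)
  op <- biosensim:::transport_flux_operator(m, et, zero_vel, zero_vel,
                                            D = 2, u_ref = 1, bc = bc)
  expect_lt(max(abs(Matrix::colSums(op$A))), 1e-14)
  expect_lt(max(abs(op$A %*% rep(3.7, nrow(m$nodes)))), 1e-14)
})

test_that("diffusion assembly is exact for globally linear fields", {
  g <- geometry_config(L = 1, H = 1, Ls = 1, Nx = 3, Ny = 3, Ns = 3)
  m <- build_channel_mesh(g)
  lin <- function(x, y, t) 2 + 3 * x - 1.5 * y
  bc_dir <- list(type = "dirichlet", value = lin)
  bc <- list(inlet = bc_dir, outlet = bc_dir, top = bc_dir, bottom = bc_dir)
  params <- transport_params(D = 1, c0 = 0)
  sys <- assemble_transport(m, NULL, numeric(nrow(m$nodes)), params,
                            dt = 1e12, bc = bc,
                            vel_fn = function(x, y) cbind(0 * x, 0 * y))
  sol <- solve_transport_step(sys)
  expect_equal(sol, lin(m$nodes[, 1], m$nodes[, 2], 0), tolerance = 1e-10)
})
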