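# CVFEM discretization kernel: bilinear shape functions on the reference
# square [-1,1]^2, integration points at the midpoints of the internal
# sub-control-surfaces, and the physical-influence-scheme (PIS) upwind
# operator built from the upstream intersection of the local streamline with
# the element boundary.

# reference coordinates of the 4 integration points (midpoint of each
# edge-midpoint-to-centroid face), local CCW node/edge numbering
IP_REF <- matrix(c(0, -0.5,
                   0.5, 0,
                   0, 0.5,
                   -0.5, 0), 4L, 2L, byrow = TRUE)
NXT <- c(2L, 3L, 4L, 1L)

#' Bilinear shape functions
#'
#' Standard bilinear interpolation weights on the reference square, node
#' order counter-clockwise from (-1,-1).
#'
#' @param xi,eta reference coordinates in `[-1, 1]`.
#' @return numeric(4) weights, each in `[0, 1]`, summing to 1.
#' @export
bilinear_shape <- function(xi, eta) {
  c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
    (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
}

# d/d(xi,eta) of the 4 shape functions: 2 x 4 matrix
bilinear_grad_ref <- function(xi, eta) {
  rbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
        c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))) / 4
}

# physical gradient operator (2 x 4) at reference point for element corners P
shape_grad_phys <- function(P, xi, eta) {
  Gr <- bilinear_grad_ref(xi, eta)
  J <- Gr %*% P                       # 2 x 2 Jacobian d(x,y)/d(xi,eta)
  solve(t(J), Gr)
}

#' PIS streamline upwind point
#'
#' Traces the streamline through an integration point upstream (against the
#' local velocity) to its first intersection with the element boundary, and
#' returns the crossed edge together with the split fractions used for the
#' linear donor-edge interpolation. When the velocity magnitude is below
#' `1e-12 * u_ref` there is no upwind direction and the caller falls back to
#' bilinear interpolation (`fallback = TRUE`).
#'
#' @param corners 4 x 2 element corner coordinates, counter-clockwise.
#' @param ip_xy integration-point coordinates (length 2).
#' @param u,v velocity components at the integration point.
#' @param u_ref reference velocity scale for the zero-velocity threshold.
#' @return a list of class `bs_upwind_split`: `edge_id`, `donors` (the two
#'   local node indices bounding the crossed edge), `a_frac`, `b_frac`
#'   (portions of the edge on either side of the intersection; the upwind
#'   value is `(a*phi[donor1] + b*phi[donor2])/(a+b)`), `weights` (length-4
#'   convex weights on the element nodes) and `fallback`.
#' @export
streamline_upwind_point <- function(corners, ip_xy, u, v, u_ref = 1) {
  stopifnot(all(is.finite(c(u, v))))
  speed <- sqrt(u * u + v * v)
  if (speed <= 1e-12 * u_ref) {
    return(structure(list(edge_id = NA_integer_, donors = NA_integer_,
                          a_frac = NA_real_, b_frac = NA_real_,
                          weights = NULL, fallback = TRUE),
                     class = "bs_upwind_split"))
  }
  best <- NULL
  for (k in 1:4) {
    A <- corners[k, ]; B <- corners[NXT[k], ]
    # ip - s*(u,v) = A + t*(B-A)  ->  [B-A, (u,v)] %*% c(t, s) = ip - A
    M <- cbind(B - A, c(u, v))
    det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    if (abs(det) < 1e-300) next
    rhs <- ip_xy - A
    t <- (rhs[1] * M[2, 2] - rhs[2] * M[1, 2]) / det
    s <- (M[1, 1] * rhs[2] - M[2, 1] * rhs[1]) / det
    if (s <= 1e-14 || t < -1e-12 || t > 1 + 1e-12) next
    if (is.null(best) || s < best$s) best <- list(k = k, t = t, s = s)
  }
  if (is.null(best)) {
    # ip on the boundary moving inward, or round-off: fall back
    return(structure(list(edge_id = NA_integer_, donors = NA_integer_,
                          a_frac = NA_real_, b_frac = NA_real_,
                          weights = NULL, fallback = TRUE),
                     class = "bs_upwind_split"))
  }
  k <- best$k; t <- min(max(best$t, 0), 1)
  A <- corners[k, ]; B <- corners[NXT[k], ]
  elen <- sqrt(sum((B - A)^2))
  # corner tie-break: full weight to the corner the ray (nearly) hits
  if (t < 1e-12) t <- 0
  if (t > 1 - 1e-12) t <- 1
  w <- numeric(4)
  w[k] <- 1 - t
  w[NXT[k]] <- t
  structure(list(edge_id = k, donors = c(k, NXT[k]),
                 a_frac = (1 - t) * elen, b_frac = t * elen,
                 weights = w, fallback = FALSE),
            class = "bs_upwind_split")
}

#' Upwind value from a streamline split
#'
#' Linear interpolation along the crossed edge:
#' `phi_up = (a * phi[donor1] + b * phi[donor2]) / (a + b)`;
#' equivalently the convex combination stored in `weights`. Always
#' lies between the two donor nodal values.
#'
#' @param split a `bs_upwind_split` from [streamline_upwind_point()].
#' @param phi numeric(4) nodal values on the element.
#' @export
upwind_value <- function(split, phi) {
  stopifnot(inherits(split, "bs_upwind_split"), length(phi) == 4L)
  if (isTRUE(split$fallback)) stop("no upwind direction: zero-velocity fallback")
  if (split$a_frac + split$b_frac <= 0) stop("degenerate edge: zero length")
  sum(split$weights * phi)
}

#' Element upwind coefficient matrix
#'
#' The 4 x 4 matrix `C` mapping element nodal values to the four
#' integration-point upwind values (`C %*% phi = phi_up`). Each row is a
#' convex combination of nodal values: two nonzero entries on the donor nodes
#' of the crossed edge, or the bilinear weights at the integration point for
#' the zero-velocity fallback.
#'
#' @param corners 4 x 2 element corner coordinates, counter-clockwise.
#' @param ip_vel 4 x 2 matrix of (u, v) at the four integration points.
#' @param u_ref reference velocity scale for the fallback threshold.
#' @export
element_upwind_matrix <- function(corners, ip_vel, u_ref = 1) {
  C <- matrix(0, 4L, 4L)
  for (k in 1:4) {
    xi <- IP_REF[k, 1]; eta <- IP_REF[k, 2]
    Nw <- bilinear_shape(xi, eta)
    ip_xy <- as.numeric(Nw %*% corners)
    sp <- streamline_upwind_point(corners, ip_xy, ip_vel[k, 1], ip_vel[k, 2],
                                  u_ref = u_ref)
    C[k, ] <- if (sp$fallback) Nw else sp$weights
  }
  C
}

#' Assemble a global sparse system from element contributions
#'
#' Scatter-adds triplet contributions into an `n x n` sparse matrix and
#' right-hand side, then replaces Dirichlet rows by identity rows carrying
#' the boundary values.
#'
#' @param n number of unknowns.
#' @param rows,cols,vals triplet vectors (equal length).
#' @param rhs right-hand side (length `n`; contributions already summed in).
#' @param dirichlet_idx,dirichlet_val indices and values of Dirichlet rows.
#' @return list with sparse matrix `A` (`dgCMatrix`) and vector `b`.
#' @export
assemble_global <- function(n, rows, cols, vals, rhs = numeric(n),
                            dirichlet_idx = integer(0),
                            dirichlet_val = numeric(0)) {
  if (length(rows) != length(cols) || length(cols) != length(vals))
    stop("assembly error: triplet vectors have mismatched lengths")
  if (length(rhs) != n) stop("assembly error: rhs length != n")
  if (length(dirichlet_idx)) {
    keep <- !(rows %in% dirichlet_idx)
    rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
    rows <- c(rows, dirichlet_idx)
    cols <- c(cols, dirichlet_idx)
    vals <- c(vals, rep(1, length(dirichlet_idx)))
    rhs[dirichlet_idx] <- dirichlet_val
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  list(A = A, b = rhs)
}

# Interpolate nodal field(s) to the 4 integration points of every element.
# f: vector length N (or matrix N x m). Returns nel x 4 (or list of).
ip_interpolate <- function(mesh, f) {
  Nw <- t(vapply(1:4, function(k) bilinear_shape(IP_REF[k, 1], IP_REF[k, 2]),
                 numeric(4)))   # 4 x 4: rows ip, cols node weights
  vals <- array(0, dim = c(nrow(mesh$elem), 4L))
  fe <- matrix(f[mesh$elem], ncol = 4L)   # nel x 4 nodal values
  for (k in 1:4) vals[, k] <- fe %*% Nw[k, ]
  vals
}
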