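# Structured quad mesh of the channel: nodes, elements, sub-control volumes,
# boundary tags. The dual control volume of a node is the union of the
# quadrants of its adjacent elements; internal integration faces run from the
# element edge midpoints to the element centroid.

#' Channel geometry configuration
#'
#' Describes the rectangular microchannel, the sensor strip on the bottom
#' wall, and the structured-mesh resolution. All lengths are metres.
#'
#' @param L channel length (m), streamwise.
#' @param H channel height (m), cross-channel.
#' @param Ls sensor strip length (m) along the bottom wall.
#' @param sensor_offset distance from the inlet to the sensor leading edge (m).
#' @param Nx,Ny node counts in x and y (each at least 3).
#' @param Ns node count on the sensor strip. Must match the contiguous run of
#'   bottom-wall nodes obtained by snapping the strip edges to the mesh (see
#'   [build_channel_mesh()]).
#' @param grading_ratio geometric ratio of successive cell heights in y,
#'   growing away from the sensor (bottom) wall; 1 gives a uniform mesh.
#' @return an object of class `bs_geometry`.
#' @export
geometry_config <- function(L, H, Ls, Nx, Ny, Ns,
                            sensor_offset = 0, grading_ratio = 1) {
  stopifnot(is.numeric(L), is.numeric(H), is.numeric(Ls))
  if (!(L > 0) || !(H > 0)) stop("channel dimensions L, H must be positive")
  if (!(Ls > 0) || Ls > L) stop("sensor length Ls must satisfy 0 < Ls <= L")
  if (sensor_offset < 0 || sensor_offset + Ls > L + 1e-12 * L)
    stop("sensor must lie within the channel: sensor_offset + Ls <= L")
  if (Nx < 3 || Ny < 3) stop("Nx and Ny must each be at least 3")
  if (Ns < 2 || Ns > Nx) stop("Ns must satisfy 2 <= Ns <= Nx")
  if (!(grading_ratio > 0)) stop("grading_ratio must be positive")
  structure(list(L = L, H = H, Ls = Ls, sensor_offset = sensor_offset,
                 Nx = as.integer(Nx), Ny = as.integer(Ny), Ns = as.integer(Ns),
                 grading_ratio = grading_ratio),
            class = "bs_geometry")
}

# y coordinates with one-sided geometric grading toward y = 0 (sensor wall).
graded_coords <- function(H, n, ratio) {
  if (abs(ratio - 1) < 1e-12) return(seq(0, H, length.out = n))
  d <- ratio^(0:(n - 2))            # relative cell sizes, growing away from wall
  cumsum(c(0, d)) / sum(d) * H
}

#' Build the structured channel mesh
#'
#' Tensor-product quadrilateral mesh of the channel with node numbering
#' row-major in (i = x fastest, j = y), 1-based. Populates per-element
#' sub-control-surface geometry and boundary tags. The sensor leading and
#' trailing edges are snapped to the nearest bottom-wall nodes (within half a
#' cell); the snapped run must contain exactly `Ns` nodes.
#'
#' @param geom a [geometry_config()] object.
#' @return an object of class `bs_mesh` with fields `x`, `y` (coordinate
#'   vectors), `nodes` (N x 2 matrix), `elem` (nel x 4, counter-clockwise),
#'   `ds` (nel x 4 x 2 signed face area components), `sub_areas` (nel x 4),
#'   `cv_area` (per-node dual volume, per unit depth), `tags` (disjoint node
#'   sets inlet/outlet/wall/sensor/interior), `sensor_nodes` (ordered run,
#'   including any inlet/outlet corner it touches) and `sensor_face_len`
#'   (boundary face length owned by each sensor node).
#' @export
build_channel_mesh <- function(geom) {
  stopifnot(inherits(geom, "bs_geometry"))
  nx <- geom$Nx; ny <- geom$Ny
  x <- seq(0, geom$L, length.out = nx)
  y <- graded_coords(geom$H, ny, geom$grading_ratio)
  nodes <- cbind(x = rep(x, times = ny), y = rep(y, each = nx))
  N <- nx * ny

  nid <- function(i, j) (j - 1L) * nx + i
  # elements: (nx-1)(ny-1) quads, CCW local order 1=(i,j) 2=(i+1,j) 3=(i+1,j+1) 4=(i,j+1)
  ei <- rep(seq_len(nx - 1L), times = ny - 1L)
  ej <- rep(seq_len(ny - 1L), each = nx - 1L)
  elem <- cbind(nid(ei, ej), nid(ei + 1L, ej), nid(ei + 1L, ej + 1L), nid(ei, ej + 1L))
  nel <- nrow(elem)

  ds <- array(0, dim = c(nel, 4L, 2L))
  sub_areas <- matrix(0, nel, 4L)
  for (e in seq_len(nel)) {
    g <- element_geometry(nodes[elem[e, ], , drop = FALSE], e)
    ds[e, , ] <- g$ds
    sub_areas[e, ] <- g$sub_areas
  }
  cv_area <- numeric(N)
  for (k in 1:4) {
    contrib <- tapply(sub_areas[, k], elem[, k], sum)
    idx <- as.integer(names(contrib))
    cv_area[idx] <- cv_area[idx] + as.numeric(contrib)
  }

  ii <- rep(seq_len(nx), times = ny)
  jj <- rep(seq_len(ny), each = nx)
  inlet <- which(ii == 1L)
  outlet <- which(ii == nx)

  # sensor run on the bottom wall, snapped to nearest nodes within half a cell
  xa <- geom$sensor_offset; xb <- geom$sensor_offset + geom$Ls
  i1 <- which.min(abs(x - xa)); i2 <- which.min(abs(x - xb))
  half <- function(i) {
    lo <- if (i > 1L) (x[i] - x[i - 1L]) / 2 else (x[2L] - x[1L]) / 2
    hi <- if (i < nx) (x[i + 1L] - x[i]) / 2 else (x[nx] - x[nx - 1L]) / 2
    max(lo, hi)
  }
  if (abs(x[i1] - xa) > half(i1) + 1e-12 * geom$L ||
      abs(x[i2] - xb) > half(i2) + 1e-12 * geom$L)
    stop("sensor edges cannot be snapped to mesh nodes within half a cell")
  run <- nid(i1:i2, 1L)
  if (length(run) != geom$Ns)
    stop(sprintf(paste0("Ns = %d inconsistent with mesh: snapped sensor run ",
                        "[%g, %g] m contains %d bottom-wall nodes"),
                 geom$Ns, x[i1], x[i2], length(run)))

  wall <- setdiff(which(jj == 1L | jj == ny), c(inlet, outlet))
  sensor <- setdiff(run, c(inlet, outlet))
  wall <- setdiff(wall, sensor)
  interior <- setdiff(seq_len(N), c(inlet, outlet, wall, sensor))

  # boundary segment lengths owned by each node along x (bottom/top) and y (sides)
  own_len <- function(v) {
    n <- length(v)
    c((v[2] - v[1]) / 2,
      if (n > 2) (v[3:n] - v[1:(n - 2)]) / 2 else NULL,
      (v[n] - v[n - 1]) / 2)
  }
  wx <- own_len(x); wy <- own_len(y)

  structure(list(
    geom = geom, nx = nx, ny = ny, x = x, y = y, nodes = nodes,
    elem = elem, elem_ij = cbind(ei, ej), ds = ds, sub_areas = sub_areas,
    cv_area = cv_area, node_i = ii, node_j = jj,
    tags = list(inlet = inlet, outlet = outlet, wall = wall,
                sensor = sensor, interior = interior),
    sensor_nodes = run, sensor_face_len = wx[i1:i2],
    wx = wx, wy = wy
  ), class = "bs_mesh")
}

# Geometry of one quad element's four sub-control volumes and internal faces.
# Face k runs from the midpoint of edge k (nodes k, k+1) to the centroid; its
# signed area vector ds = (dy, -dx) of the midpoint->centroid segment points
# out of sub-volume k into sub-volume k+1.
element_geometry <- function(P, elem_id = NA_integer_) {
  ce <- colMeans(P)
  nxt <- c(2L, 3L, 4L, 1L)
  mid <- (P + P[nxt, , drop = FALSE]) / 2
  d <- matrix(ce, 4L, 2L, byrow = TRUE) - mid
  ds <- cbind(d[, 2], -d[, 1])
  shoelace <- function(q) {
    n <- nrow(q)
    0.5 * sum(q[, 1] * q[c(2:n, 1), 2] - q[c(2:n, 1), 1] * q[, 2])
  }
  prv <- c(4L, 1L, 2L, 3L)
  sub_areas <- vapply(1:4, function(k) {
    shoelace(rbind(P[k, ], mid[k, ], ce, mid[prv[k], ]))
  }, numeric(1))
  if (any(sub_areas <= 0))
    stop(sprintf("degenerate element %s: non-positive sub-control volume",
                 as.character(elem_id)))
  list(ds = ds, sub_areas = sub_areas, centroid = ce, midpoints = mid)
}

#' Sub-control-surface area components
#'
#' For a whole mesh, returns the `nel x 4 x 2` array of signed area components
#' of the four internal integration faces of every element (already stored on
#' the mesh). For a single element, pass its 4 x 2 corner-coordinate matrix
#' (counter-clockwise) and get the face vectors and sub-volume areas.
#'
#' Face `k` connects the midpoint of edge `k` (between local nodes `k` and
#' `k+1`) to the element centroid; its signed area vector points out of
#' sub-volume `k` into sub-volume `k+1` (outward-normal convention for the
#' owning sub-volume).
#'
#' @param m a `bs_mesh`, or a 4 x 2 numeric matrix of element corners.
#' @return the `ds` array for a mesh; for a single element, a list with `ds`
#'   (4 x 2), `sub_areas` (4), `centroid` and edge `midpoints`.
#' @export
subcontrol_areas <- function(m) {
  if (inherits(m, "bs_mesh")) return(m$ds)
  stopifnot(is.matrix(m), nrow(m) == 4L, ncol(m) == 2L)
  element_geometry(m)
}

#' Sensor node indices
#'
#' The contiguous run of bottom-wall nodes under the sensor strip, ordered by
#' x. Includes the inlet/outlet corner nodes when the strip touches them (the
#' velocity and concentration Dirichlet conditions still take precedence
#' there; the surface-binding ODE is integrated on every run node).
#'
#' @param mesh a `bs_mesh`.
#' @return integer vector of node indices.
#' @export
locate_sensor_nodes <- function(mesh) {
  stopifnot(inherits(mesh, "bs_mesh"))
  mesh$sensor_nodes
}

#' @export
print.bs_mesh <- function(x, ...) {
  g <- x$geom
  cat(sprintf("CVFEM channel mesh: %d x %d nodes on [0, %g] x [0, %g] m\n",
              x$nx, x$ny, g$L, g$H))
  cat(sprintf("  elements: %d; sensor: %d nodes on [%g, %g] m (bottom wall)\n",
              nrow(x$elem), length(x$sensor_nodes),
              x$nodes[x$sensor_nodes[1], 1],
              x$nodes[x$sensor_nodes[length(x$sensor_nodes)], 1]))
  invisible(x)
}
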