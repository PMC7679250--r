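# Convection-diffusion of the analyte on the frozen flow field. Advective
# face values use the PIS upwind operator built from the KS hat velocities
# (the same fluxes that satisfy discrete continuity, so a uniform
# concentration is transported exactly); diffusive fluxes use bilinear
# shape-function gradients (Fick's law). Backward-Euler in time.

#' Transport parameters
#' @param D diffusion coefficient (m^2 s^-1).
#' @param c0 inlet concentration (mol m^-3).
#' @param S volumetric source/sink: 0 (default), a numeric vector per node,
#'   or a function `S(x, y, t)` (used by the manufactured-solution cases).
#' @export
transport_params <- function(D, c0, S = 0) {
  if (!(D > 0)) stop("diffusion coefficient D must be positive")
  if (c0 < 0) stop("inlet concentration c0 must be non-negative")
  structure(list(D = D, c0 = c0, S = S), class = "bs_transport_params")
}

# side node sets with inlet/outlet precedence at corners
side_nodes <- function(mesh) {
  i <- mesh$node_i; j <- mesh$node_j
  inlet <- which(i == 1L); outlet <- which(i == mesh$nx)
  list(inlet = inlet, outlet = outlet,
       bottom = setdiff(which(j == 1L), c(inlet, outlet)),
       top = setdiff(which(j == mesh$ny), c(inlet, outlet)))
}

# default channel boundary conditions for the concentration field
default_transport_bc <- function(c0) {
  list(inlet = list(type = "dirichlet", value = c0),
       outlet = list(type = "outflow"),
       top = list(type = "neumann0"),
       bottom = list(type = "neumann0"))
}

bc_value_at <- function(value, x, y, t) {
  if (is.function(value)) value(x, y, t) else rep(value, length(x))
}

#' Diffusive flux at the integration faces
#'
#' Fick's law `F = -D * grad(c)` evaluated from the bilinear shape-function
#' gradients at each element's four integration points, plus the signed
#' normal flux `F . ds` through each internal face (antisymmetric between the
#' two sub-volumes sharing a face by construction).
#'
#' @param mesh a `bs_mesh`; `c_field` nodal concentrations; `D` diffusivity.
#' @return list with `fx`, `fy` (nel x 4 flux components at the ips) and
#'   `fn` (nel x 4 signed normal flux through each face).
#' @export
diffusive_flux <- function(mesh, c_field, D) {
  et <- element_tables(mesh)
  g <- ip_gradient(mesh, et, c_field)
  fx <- -D * g$dx; fy <- -D * g$dy
  list(fx = fx, fy = fy, fn = fx * et$dsx + fy * et$dsy)
}

# Flux operator A (N x N): row i = net advective+diffusive out-flux of CV i,
# linear in nodal c; includes the outlet advective efflux diagonal.
# uhat, vhat: nel x 4 face velocities; u_out: outflow velocity per outlet node.
transport_flux_operator <- function(mesh, et, uhat, vhat, D, u_ref, bc,
                                    u_out = NULL) {
  N <- nrow(mesh$nodes); elem <- mesh$elem
  Cup <- all_upwind_matrices(mesh, et, uhat, vhat, u_ref = u_ref)
  qf <- uhat * et$dsx + vhat * et$dsy
  out_diag <- NULL
  ri <- vector("list", 64L); ci <- ri; xi <- ri; nb <- 0L
  for (k in 1:4) {
    rp <- elem[, k]; rm <- elem[, NXT[k]]
    dkx <- et$dsx[, k]; dky <- et$dsy[, k]
    for (m in 1:4) {
      cm <- elem[, m]
      coef <- qf[, k] * Cup[, k, m] -
        D * (et$Gx[, k, m] * dkx + et$Gy[, k, m] * dky)
      nb <- nb + 1L; ri[[nb]] <- rp; ci[[nb]] <- cm; xi[[nb]] <- coef
      nb <- nb + 1L; ri[[nb]] <- rm; ci[[nb]] <- cm; xi[[nb]] <- -coef
    }
  }
  rows <- unlist(ri[seq_len(nb)]); cols <- unlist(ci[seq_len(nb)])
  vals <- unlist(xi[seq_len(nb)])
  sides <- side_nodes(mesh)
  if (identical(bc$outlet$type, "outflow")) {
    if (is.null(u_out)) stop("outflow boundary needs outlet velocities")
    jj <- mesh$node_j[sides$outlet]
    out_diag <- u_out * mesh$wy[jj]
    rows <- c(rows, sides$outlet)
    cols <- c(cols, sides$outlet)
    vals <- c(vals, out_diag)
  }
  list(A = Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(N, N)),
       Cup = Cup, qf = qf, out_diag = out_diag)
}

# collect Dirichlet nodes and a value function over the bc spec
dirichlet_info <- function(mesh, bc) {
  sides <- side_nodes(mesh)
  nodes <- integer(0); specs <- list()
  for (s in names(sides)) {
    e <- bc[[s]]
    if (!is.null(e) && identical(e$type, "dirichlet")) {
      nodes <- c(nodes, sides[[s]])
      specs[[s]] <- list(nodes = sides[[s]], value = e$value)
    }
  }
  value_at <- function(t) {
    out <- numeric(length(nodes)); pos <- 0L
    for (sp in specs) {
      n <- length(sp$nodes)
      out[pos + seq_len(n)] <- bc_value_at(sp$value,
                                           mesh$nodes[sp$nodes, 1],
                                           mesh$nodes[sp$nodes, 2], t)
      pos <- pos + n
    }
    out
  }
  list(nodes = nodes, value_at = value_at)
}

#' Transport time stepper
#'
#' Builds (and factorizes once) the backward-Euler system
#' `(V/dt + A) c_new = V/dt c_old + sources + boundary data` for the frozen
#' flow field; the matrix is constant over the whole run, so each step is a
#' pair of sparse triangular solves.
#'
#' @param mesh a `bs_mesh`.
#' @param flow a `bs_flow` from [steady_flow()], or `NULL` when `vel_fn` is
#'   given (manufactured-solution mode).
#' @param params a [transport_params()].
#' @param dt time-step (s).
#' @param bc boundary-condition list with entries `inlet`, `outlet`, `top`,
#'   `bottom`, each `list(type = "dirichlet"|"neumann0"|"outflow",
#'   value = const | function(x, y, t))`; defaults to inlet Dirichlet `c0`,
#'   advective outflow at the outlet and impermeable walls. The sensor flux
#'   enters through [apply_sensor_flux()] / the `dbdt` argument of
#'   `step_transport()`.
#' @param vel_fn optional `function(x, y) -> cbind(u, v)` prescribing the
#'   face velocities analytically (replaces `flow`).
#' @return a `bs_transport_stepper` object.
#' @export
transport_stepper <- function(mesh, flow, params, dt, bc = NULL,
                              vel_fn = NULL) {
  if (!(dt > 0)) stop("dt must be positive")
  if (is.null(bc)) bc <- default_transport_bc(params$c0)
  for (s in c("inlet", "outlet", "top", "bottom"))
    if (is.null(bc[[s]]))
      stop(sprintf("missing boundary assignment for side '%s'", s))
  et <- if (!is.null(flow)) flow$et else element_tables(mesh)
  sides <- side_nodes(mesh)
  if (!is.null(vel_fn)) {
    uv <- vel_fn(as.numeric(et$ipx), as.numeric(et$ipy))
    uhat <- matrix(uv[, 1], nrow(mesh$elem), 4L)
    vhat <- matrix(uv[, 2], nrow(mesh$elem), 4L)
    u_ref <- max(sqrt(uhat^2 + vhat^2), 1e-300)
    u_out <- vel_fn(mesh$nodes[sides$outlet, 1], mesh$nodes[sides$outlet, 2])[, 1]
  } else {
    uhat <- flow$ips$uhat; vhat <- flow$ips$vhat
    u_ref <- max(abs(flow$u_in), 1e-300)
    u_out <- flow$u[sides$outlet]
  }
  op <- transport_flux_operator(mesh, et, uhat, vhat, params$D, u_ref, bc, u_out)
  A <- op$A
  dir <- dirichlet_info(mesh, bc)
  N <- nrow(mesh$nodes)
  Afull <- A + Matrix::Diagonal(N, mesh$cv_area / dt)
  # Dirichlet rows -> identity
  if (length(dir$nodes)) {
    Afull[dir$nodes, ] <- 0
    Afull <- Afull + Matrix::sparseMatrix(i = dir$nodes, j = dir$nodes,
                                          x = rep(1, length(dir$nodes)),
                                          dims = c(N, N))
  }
  structure(list(mesh = mesh, et = et, A = A, Afull = Afull,
                 lu = Matrix::lu(Afull), dir = dir, dt = dt, params = params,
                 bc = bc, sides = sides, u_out = u_out,
                 Cup = op$Cup, qf = op$qf, out_diag = op$out_diag,
                 sensor_rows = setdiff(mesh$sensor_nodes, dir$nodes)),
            class = "bs_transport_stepper")
}

#' Assemble one backward-Euler transport system
#'
#' One-shot assembly of the linear system for the next concentration field
#' (the batch interface behind [transport_stepper()]): Dirichlet rows are
#' identity rows, walls are impermeable, the outlet carries advective
#' outflow, and the optional volumetric source is integrated over each
#' control volume.
#'
#' @inheritParams transport_stepper
#' @param c_old nodal concentration at the previous time level.
#' @param t_new time at the new level (s), used for time-dependent boundary
#'   values and sources.
#' @return list with the sparse matrix `A`, right-hand side `b`, and the
#'   stepper internals (`stepper`).
#' @export
assemble_transport <- function(mesh, flow, c_old, params, dt, bc = NULL,
                               vel_fn = NULL, t_new = dt) {
  st <- transport_stepper(mesh, flow, params, dt, bc, vel_fn)
  list(A = st$Afull, b = transport_rhs(st, c_old, t_new), stepper = st)
}

# right-hand side at the new time level (no sensor flux; see apply_sensor_flux)
transport_rhs <- function(st, c_old, t_new) {
  mesh <- st$mesh
  b <- mesh$cv_area / st$dt * c_old
  S <- st$params$S
  if (is.function(S)) {
    b <- b + S(mesh$nodes[, 1], mesh$nodes[, 2], t_new) * mesh$cv_area
  } else if (length(S) > 1 || any(S != 0)) {
    b <- b + S * mesh$cv_area
  }
  b[st$dir$nodes] <- st$dir$value_at(t_new)
  b
}

#' Add the sensor uptake flux to an assembled system
#'
#' The surface-binding rate `db/dt` (mol m^-2 s^-1, one value per sensor
#' node) removes analyte from the fluid through the sensor boundary faces:
#' each sensor node's right-hand side is reduced by `db/dt` times the
#' boundary face length it owns (per unit depth). Equivalent to the
#' normal-gradient statement `dc/dn = -(1/D) db/dt` multiplied through by
#' `D`, but applied in flux (integral) form so that the species balance is
#' conservative. Nodes of the sensor run whose concentration is pinned by a
#' Dirichlet condition (an inlet/outlet corner) are skipped.
#'
#' @param system list with `b` (and anything else), as from
#'   [assemble_transport()] or built per-step by the driver.
#' @param mesh a `bs_mesh`.
#' @param db_dt numeric vector, one rate per sensor node (ordered by x).
#' @return the system with its right-hand side updated.
#' @export
apply_sensor_flux <- function(system, mesh, db_dt) {
  run <- mesh$sensor_nodes
  if (length(db_dt) != length(run))
    stop("db_dt length does not match the sensor node list")
  dirn <- if (!is.null(system$stepper)) system$stepper$dir$nodes else integer(0)
  keep <- !(run %in% dirn)
  idx <- run[keep]
  system$b[idx] <- system$b[idx] - db_dt[keep] * mesh$sensor_face_len[keep]
  system
}

#' Solve an assembled transport system
#' @param system list with `A` and `b`.
#' @return nodal concentration vector at the new time level.
#' @export
solve_transport_step <- function(system) {
  as.numeric(Matrix::solve(system$A, system$b))
}

# one efficient step using the cached factorization
step_transport <- function(st, c_old, t_new, dbdt = NULL) {
  b <- transport_rhs(st, c_old, t_new)
  if (!is.null(dbdt)) {
    keep <- !(st$mesh$sensor_nodes %in% st$dir$nodes)
    idx <- st$mesh$sensor_nodes[keep]
    b[idx] <- b[idx] - dbdt[keep] * st$mesh$sensor_face_len[keep]
  }
  as.numeric(Matrix::solve(st$lu, b))
}

# Global species bookkeeping for one step (per unit depth), built from the
# scheme's own discrete face fluxes: inflow = advective + diffusive flux
# through the faces separating the inlet-node control volumes from the rest
# of the domain, outflow = advective efflux at the outlet, accumulation and
# surface sink over the non-Dirichlet control volumes. For a conservative
# assembly the residual telescopes to solver round-off at every step.
species_balance <- function(st, flow, c_new, c_old, dbdt, t_new) {
  mesh <- st$mesh; et <- st$et
  D <- st$params$D
  col1 <- which(mesh$elem_ij[, 1] == 1L)
  face_flux <- function(k) {
    g <- mesh$elem[col1, , drop = FALSE]
    adv <- st$qf[col1, k] *
      rowSums(st$Cup[col1, k, , drop = FALSE][, 1, ] *
                matrix(c_new[g], ncol = 4L))
    dif <- -D * rowSums((et$Gx[col1, k, , drop = FALSE][, 1, ] * et$dsx[col1, k] +
                           et$Gy[col1, k, , drop = FALSE][, 1, ] * et$dsy[col1, k]) *
                          matrix(c_new[g], ncol = 4L))
    adv + dif
  }
  inflow <- sum(face_flux(1L)) - sum(face_flux(3L))
  outflow <- if (is.null(st$out_diag)) 0 else
    sum(st$out_diag * c_new[st$sides$outlet])
  free <- setdiff(seq_len(nrow(mesh$nodes)), st$dir$nodes)
  accum <- sum(mesh$cv_area[free] * (c_new[free] - c_old[free])) / st$dt
  keep <- !(mesh$sensor_nodes %in% st$dir$nodes)
  sink <- if (is.null(dbdt)) 0 else
    sum(dbdt[keep] * mesh$sensor_face_len[keep])
  list(inflow = inflow, outflow = outflow,
       accumulation = accum, surface_sink = sink,
       residual = inflow - outflow - accum - sink)
}
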