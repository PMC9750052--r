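#' Fluid properties
#'
#' @param rho Density (kg/m^3); default 1.06e3 (blood).
#' @param mu Dynamic viscosity (Pa s); default 3.5e-3 (blood).
#' @return Object of class `fluid_props`.
#' @export
fluid_props <- function(rho = 1.06e3, mu = 3.5e-3) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_props")
}

#' Stabilization parameters
#'
#' Controls of the equal-order Q1-Q1 stabilized formulation: the backflow
#' coefficient `beta` of the outlet energy-dissipation term, and the scales
#' of the element-wise SUPG/PSPG parameter
#' \deqn{\tau_K = \big[(c_t\,\rho/\Delta t)^2 + (c_a\,\rho |u|/h_K)^2 +
#'       (c_v\,\mu/h_K^2)^2\big]^{-1/2}}
#' with defaults `c_t = 2`, `c_a = 2`, `c_v = 12`.
#'
#' @param beta Backflow coefficient (dimensionless, >= 0); default 1.
#' @param c_t,c_a,c_v Transient, advective and viscous scales of `tau`.
#' @return Object of class `stab_params`.
#' @export
stabilization_params <- function(beta = 1, c_t = 2, c_a = 2, c_v = 12) {
  stopifnot(beta >= 0, c_t > 0, c_a > 0, c_v > 0)
  structure(list(beta = beta, c_t = c_t, c_a = c_a, c_v = c_v),
            class = "stab_params")
}

# conversion constants at the 0D <-> FEM unit bridge
.MMHG_PA <- 133.322
.ML_M3 <- 1e-6

# shape values / reference gradients at many local points (P x 3) at once
.shape_at <- function(xi) {
  r <- .hex_ref_nodes
  out <- matrix(NA_real_, nrow(xi), 8L)
  for (a in 1:8) {
    out[, a] <- (1 + r[a, 1] * xi[, 1]) * (1 + r[a, 2] * xi[, 2]) *
      (1 + r[a, 3] * xi[, 3]) / 8
  }
  out
}
.dshape_at <- function(xi) {
  r <- .hex_ref_nodes
  out <- array(NA_real_, dim = c(nrow(xi), 8L, 3L))
  for (a in 1:8) {
    out[, a, 1] <- r[a, 1] * (1 + r[a, 2] * xi[, 2]) * (1 + r[a, 3] * xi[, 3]) / 8
    out[, a, 2] <- r[a, 2] * (1 + r[a, 1] * xi[, 1]) * (1 + r[a, 3] * xi[, 3]) / 8
    out[, a, 3] <- r[a, 3] * (1 + r[a, 1] * xi[, 1]) * (1 + r[a, 2] * xi[, 2]) / 8
  }
  out
}

# Jacobians with a per-row dN array (P, 8, 3) and coords (P, 8, 3)
.jacobians_var <- function(coords, dN) {
  P <- dim(coords)[1]
  J <- array(0, dim = c(P, 3L, 3L))
  for (i in 1:3) for (j in 1:3) {
    J[, i, j] <- rowSums(coords[, , i] * dN[, , j])
  }
  a11 <- J[, 1, 1]; a12 <- J[, 1, 2]; a13 <- J[, 1, 3]
  a21 <- J[, 2, 1]; a22 <- J[, 2, 2]; a23 <- J[, 2, 3]
  a31 <- J[, 3, 1]; a32 <- J[, 3, 2]; a33 <- J[, 3, 3]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  inv <- array(0, dim = c(P, 3L, 3L))
  inv[, 1, 1] <- (a22 * a33 - a23 * a32) / det
  inv[, 1, 2] <- (a13 * a32 - a12 * a33) / det
  inv[, 1, 3] <- (a12 * a23 - a13 * a22) / det
  inv[, 2, 1] <- (a23 * a31 - a21 * a33) / det
  inv[, 2, 2] <- (a11 * a33 - a13 * a31) / det
  inv[, 2, 3] <- (a13 * a21 - a11 * a23) / det
  inv[, 3, 1] <- (a21 * a32 - a22 * a31) / det
  inv[, 3, 2] <- (a12 * a31 - a11 * a32) / det
  inv[, 3, 3] <- (a11 * a22 - a12 * a21) / det
  list(det = det, inv = inv)
}

#' Precompute the finite-element discretization of a tube mesh
#'
#' Builds everything the time stepper needs and that depends only on the
#' geometry: per-quadrature-point physical shape gradients and Jacobian
#' weights, assembly index vectors, boundary-face quadrature data (normals,
#' parent shape values and gradients) for the inlet, outlet and wall, the
#' Dirichlet node sets, and element sizes for the stabilization parameter.
#'
#' @param mesh An `fem_mesh` from [generate_tube_mesh()].
#' @param props A [fluid_props()].
#' @param stab A [stabilization_params()].
#' @return An object of class `fem_disc`.
#' @export
fem_discretization <- function(mesh, props = fluid_props(),
                               stab = stabilization_params()) {
  stopifnot(inherits(mesh, "fem_mesh"))
  N <- nrow(mesh$nodes)
  E <- nrow(mesh$hex)
  coords <- .element_coords(mesh)
  g <- 1 / sqrt(3)
  qp <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  nq <- nrow(qp)
  Nval <- matrix(NA_real_, nq, 8L)
  detJ <- vector("list", nq)
  G <- vector("list", nq)
  vol <- numeric(E)
  for (q in seq_len(nq)) {
    Nval[q, ] <- .hex_shape(qp[q, ])
    dN <- .hex_dshape(qp[q, ])
    Jq <- .elem_jacobians(coords, dN)
    detJ[[q]] <- Jq$det
    Gq <- array(0, dim = c(E, 8L, 3L))
    for (a in 1:8) for (k in 1:3) {
      Gq[, a, k] <- dN[a, 1] * Jq$inv[, 1, k] + dN[a, 2] * Jq$inv[, 2, k] +
        dN[a, 3] * Jq$inv[, 3, k]
    }
    G[[q]] <- Gq
    vol <- vol + Jq$det
  }
  h_K <- vol^(1 / 3)

  # global dof ids: node + N*(var-1), var = ux, uy, uz, p
  gdof <- matrix(NA_integer_, E, 32L)
  for (v in 1:4) gdof[, (v - 1) * 8 + 1:8] <- mesh$hex + N * (v - 1L)
  # Ke is (E, l_row, l_col); as.vector runs e, then l_row, then l_col, so the
  # row index must cycle fastest over locals
  ii <- matrix(gdof[, rep(1:32, times = 32)], E, 32L * 32L)
  jj <- matrix(gdof[, rep(1:32, each = 32)], E, 32L * 32L)

  # boundary quadrature: 2x2 Gauss on each tagged face
  fg <- as.matrix(expand.grid(c(-g, g), c(-g, g)))
  bil <- function(s, t) c((1 - s) * (1 - t), (1 + s) * (1 - t),
                          (1 + s) * (1 + t), (1 - s) * (1 + t)) / 4
  dbil <- function(s, t) {
    rbind(c(-(1 - t), (1 - t), (1 + t), -(1 + t)) / 4,
          c(-(1 - s), -(1 + s), (1 + s), (1 - s)) / 4)
  }
  bdata <- lapply(mesh$faces, function(fs) {
    F_ <- nrow(fs$nodes)
    xc <- array(NA_real_, dim = c(F_, 4L, 3L))
    for (a in 1:4) xc[, a, ] <- mesh$nodes[fs$nodes[, a], ]
    pe <- mesh$hex[fs$parent, , drop = FALSE]
    pc <- coords[fs$parent, , , drop = FALSE]
    per_qp <- lapply(seq_len(nrow(fg)), function(q) {
      s <- fg[q, 1]; t <- fg[q, 2]
      b <- bil(s, t)
      db <- dbil(s, t)
      # physical position and tangents
      pos <- matrix(0, F_, 3L)
      t1 <- matrix(0, F_, 3L)
      t2 <- matrix(0, F_, 3L)
      for (a in 1:4) {
        pos <- pos + b[a] * xc[, a, ]
        t1 <- t1 + db[1, a] * xc[, a, ]
        t2 <- t2 + db[2, a] * xc[, a, ]
      }
      ndA <- cbind(t1[, 2] * t2[, 3] - t1[, 3] * t2[, 2],
                   t1[, 3] * t2[, 1] - t1[, 1] * t2[, 3],
                   t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1])
      # embedded local coordinates inside the parent element
      xi <- matrix(0, F_, 3L)
      for (a in 1:4) xi <- xi + b[a] * fs$corner_local[, a, ]
      Nf <- .shape_at(xi)
      dNf <- .dshape_at(xi)
      Jf <- .jacobians_var(pc, dNf)
      Gf <- array(0, dim = c(F_, 8L, 3L))
      for (a in 1:8) for (k in 1:3) {
        Gf[, a, k] <- dNf[, a, 1] * Jf$inv[, 1, k] +
          dNf[, a, 2] * Jf$inv[, 2, k] + dNf[, a, 3] * Jf$inv[, 3, k]
      }
      Gn <- NULL
      if (!is.null(fs$neighbor)) {
        # same local coordinates evaluated in the one-layer-inward neighbor
        # (structured grid: the neighbor's matching face shares the layout),
        # giving the gradient one cell away from the wall for recovery
        pcn <- coords[fs$neighbor, , , drop = FALSE]
        Jn <- .jacobians_var(pcn, dNf)
        Gn <- array(0, dim = c(F_, 8L, 3L))
        for (a in 1:8) for (k in 1:3) {
          Gn[, a, k] <- dNf[, a, 1] * Jn$inv[, 1, k] +
            dNf[, a, 2] * Jn$inv[, 2, k] + dNf[, a, 3] * Jn$inv[, 3, k]
        }
      }
      list(pos = pos, ndA = ndA, N = Nf, G = Gf, G_nb = Gn)
    })
    out <- list(pnode = pe, parent = fs$parent, qp = per_qp,
                area = Reduce(`+`, lapply(per_qp, function(d)
                  sqrt(rowSums(d$ndA^2)))))
    if (!is.null(fs$neighbor)) {
      out$pnode_nb <- mesh$hex[fs$neighbor, , drop = FALSE]
    }
    out
  })

  # Dirichlet nodes: wall (no slip) and inlet (parabolic inflow)
  wall_nodes <- sort(unique(as.vector(mesh$faces$wall$nodes)))
  inlet_nodes <- sort(unique(as.vector(mesh$faces$inlet$nodes)))
  # dof groups per axial node layer: the extruded mesh couples adjacent
  # layers only, so the system is block tridiagonal in this grouping and is
  # solved by a dense block-Thomas sweep (much faster than generic sparse LU)
  Ns <- N / (mesh$nz + 1L)
  layers <- lapply(0:mesh$nz, function(k) {
    nodes_k <- k * Ns + seq_len(Ns)
    c(nodes_k, nodes_k + N, nodes_k + 2L * N, nodes_k + 3L * N)
  })
  structure(list(
    mesh = mesh, props = props, stab = stab,
    N = N, E = E, ndof = 4L * N,
    qp_shape = Nval, detJ = detJ, G = G, h_K = h_K,
    gdof = gdof, ii = as.vector(ii), jj = as.vector(jj),
    boundary = bdata, layers = layers,
    wall_nodes = wall_nodes, inlet_nodes = inlet_nodes
  ), class = "fem_disc")
}

#' Fresh (rest) flow state
#'
#' @param disc An `fem_disc`.
#' @return Object of class `fem_state`: zero velocity (N x 3, m/s), zero
#'   pressure (N, Pa), time 0.
#' @export
fem_flow_state <- function(disc) {
  structure(list(u = matrix(0, disc$N, 3L), p = numeric(disc$N), t = 0),
            class = "fem_state")
}

#' Parabolic inflow boundary data
#'
#' Nodal values of the parabolic (Poiseuille) inlet profile carrying the
#' prescribed flow rate: axial speed `2 Q / (pi R^2) (1 - r^2/R^2)`,
#' directed into the domain; the discrete boundary flux of the interpolated
#' profile recovers `Q_IN` up to interpolation error.
#'
#' @param Q_IN Inlet flow rate (ml/s).
#' @param mesh An `fem_mesh` (circular inlet).
#' @param disc Optional `fem_disc`; when supplied, the nodal profile is
#'   rescaled so that its discrete boundary flux equals `Q_IN` exactly
#'   (the nodal interpolant of the parabola otherwise carries the flow rate
#'   only up to interpolation error, below 1% at `h = R/8`).
#' @return Tibble with `node`, `x`, `y`, `ux`, `uy`, `uz` (m/s).
#' @export
inflow_profile <- function(Q_IN, mesh, disc = NULL) {
  R <- mesh$geometry$radius
  nodes <- sort(unique(as.vector(mesh$faces$inlet$nodes)))
  xy <- mesh$nodes[nodes, 1:2, drop = FALSE]
  r2 <- rowSums(xy^2)
  Q_si <- Q_IN * .ML_M3
  uz <- 2 * Q_si / (pi * R^2) * pmax(0, 1 - r2 / R^2)
  out <- tibble::tibble(node = nodes, x = xy[, 1], y = xy[, 2],
                        ux = 0, uy = 0, uz = uz)
  if (!is.null(disc) && Q_IN != 0) {
    st <- fem_flow_state(disc)
    st$u[out$node, 3] <- out$uz
    q_h <- boundary_flow(st, disc, "inlet")
    out$uz <- out$uz * (Q_IN / q_h)
  }
  out
}

#' One time step of the stabilized flow solver
#'
#' Advances the incompressible Navier-Stokes equations on the tube by one
#' implicit-Euler step with semi-implicit convection (advecting velocity
#' lagged to the previous step), Q1-Q1 elements with SUPG/PSPG
#' stabilization, the outlet backflow dissipation term
#' `beta (rho/2) |(u^n . n)_-| u^{n+1} . v`, the do-nothing outlet traction
#' `T n = -P_OUT n`, strong parabolic inflow carrying `Q_IN` and no-slip
#' walls. The linear system is solved by a sparse direct factorization.
#'
#' @param state An `fem_state` at time `t^n`.
#' @param disc An `fem_disc`.
#' @param Q_IN Inlet flow rate for the step (ml/s).
#' @param P_OUT Outlet mean pressure for the step (mmHg).
#' @param dt Step size (s). A very large `dt` turns the step into a steady
#'   solve (the transient term vanishes), which is how steady regimes are
#'   computed.
#' @return The advanced `fem_state`.
#' @export
fem_time_step <- function(state, disc, Q_IN, P_OUT, dt) {
  stopifnot(inherits(state, "fem_state"), inherits(disc, "fem_disc"), dt > 0)
  mesh <- disc$mesh
  rho <- disc$props$rho
  mu <- disc$props$mu
  stb <- disc$stab
  N <- disc$N
  E <- disc$E
  hex <- mesh$hex
  P_OUT_si <- P_OUT * .MMHG_PA

  a_node <- state$u                       # advecting velocity (lagged)
  An <- array(0, dim = c(E, 8L, 3L))
  for (a in 1:8) An[, a, ] <- a_node[hex[, a], ]

  Ke <- array(0, dim = c(E, 32L, 32L))
  rhs_e <- matrix(0, E, 32L)
  iu <- function(i, a) (i - 1L) * 8L + a  # local dof of velocity comp i
  ip <- function(a) 24L + a               # local dof of pressure

  for (q in 1:8) {
    detw <- disc$detJ[[q]]
    G <- disc$G[[q]]
    Nv <- disc$qp_shape[q, ]
    a_qp <- matrix(0, E, 3L)
    for (a in 1:8) a_qp <- a_qp + Nv[a] * An[, a, ]
    amag <- sqrt(rowSums(a_qp^2))
    tau <- 1 / sqrt((stb$c_t * rho / dt)^2 +
                      (stb$c_a * rho * amag / disc$h_K)^2 +
                      (stb$c_v * mu / disc$h_K^2)^2)
    adG <- matrix(0, E, 8L)               # a . grad(phi_b)
    for (k in 1:3) adG <- adG + a_qp[, k] * G[, , k]

    for (a in 1:8) {
      supg_a <- tau * rho * adG[, a]      # SUPG test weight (times rho below)
      for (b in 1:8) {
        gg <- G[, a, 1] * G[, b, 1] + G[, a, 2] * G[, b, 2] +
          G[, a, 3] * G[, b, 3]
        diag_term <- detw * ((rho / dt) * Nv[a] * Nv[b] +
                               rho * Nv[a] * adG[, b] + mu * gg +
                               supg_a * rho * (Nv[b] / dt + adG[, b]))
        for (i in 1:3) {
          Ke[, iu(i, a), iu(i, b)] <- Ke[, iu(i, a), iu(i, b)] + diag_term
          for (j in 1:3) {
            Ke[, iu(i, a), iu(j, b)] <- Ke[, iu(i, a), iu(j, b)] +
              detw * mu * G[, b, i] * G[, a, j]
          }
          # pressure gradient and SUPG pressure coupling
          Ke[, iu(i, a), ip(b)] <- Ke[, iu(i, a), ip(b)] +
            detw * (-Nv[b] * G[, a, i] + supg_a * G[, b, i])
          # continuity and PSPG velocity coupling
          Ke[, ip(a), iu(i, b)] <- Ke[, ip(a), iu(i, b)] +
            detw * (Nv[a] * G[, b, i] +
                      tau * rho * G[, a, i] * (Nv[b] / dt + adG[, b]))
        }
        Ke[, ip(a), ip(b)] <- Ke[, ip(a), ip(b)] + detw * tau * gg
      }
      # right-hand side: transient history (Galerkin + SUPG + PSPG)
      for (i in 1:3) {
        rhs_e[, iu(i, a)] <- rhs_e[, iu(i, a)] +
          detw * (rho / dt) * (Nv[a] + tau * rho * adG[, a]) * a_qp[, i]
      }
      gdotu <- G[, a, 1] * a_qp[, 1] + G[, a, 2] * a_qp[, 2] +
        G[, a, 3] * a_qp[, 3]
      rhs_e[, ip(a)] <- rhs_e[, ip(a)] + detw * tau * (rho / dt) * gdotu
    }
  }

  # ---- boundary terms on the outlets: do-nothing traction and backflow ----
  out <- disc$boundary$outlet
  F_ <- nrow(out$pnode)
  bf_i <- vector("list", length(out$qp))
  bf_j <- vector("list", length(out$qp))
  bf_x <- vector("list", length(out$qp))
  rhs_bi <- vector("list", length(out$qp))
  rhs_bx <- vector("list", length(out$qp))
  for (q in seq_along(out$qp)) {
    d <- out$qp[[q]]
    wA <- sqrt(rowSums(d$ndA^2))
    nhat <- d$ndA / wA
    # lagged normal velocity drives the backflow switch: the term is exactly
    # zero wherever u^n . n >= 0 and dissipative otherwise
    u_qp <- matrix(0, F_, 3L)
    for (a in 1:8) u_qp <- u_qp + d$N[, a] * a_node[out$pnode[, a], ]
    un <- rowSums(u_qp * nhat)
    bcoef <- stb$beta * (rho / 2) * pmax(-un, 0) * wA
    # traction RHS: (T n) . v with T n = -P_OUT n
    gi <- as.vector(vapply(1:3, function(i)
      as.vector(out$pnode) + N * (i - 1L), integer(F_ * 8L)))
    gv <- as.vector(vapply(1:3, function(i)
      as.vector(-P_OUT_si * d$N * d$ndA[, i]), numeric(F_ * 8L)))
    rhs_bi[[q]] <- gi
    rhs_bx[[q]] <- gv
    # backflow surface mass (block-diagonal over components)
    ia <- matrix(out$pnode[, rep(1:8, each = 8)], F_, 64L)
    jb <- matrix(out$pnode[, rep(1:8, times = 8)], F_, 64L)
    Nab <- matrix(0, F_, 64L)
    for (a in 1:8) for (b in 1:8) {
      Nab[, (a - 1L) * 8L + b] <- bcoef * d$N[, a] * d$N[, b]
    }
    bf_i[[q]] <- as.vector(vapply(1:3, function(i)
      as.vector(ia) + N * (i - 1L), integer(F_ * 64L)))
    bf_j[[q]] <- as.vector(vapply(1:3, function(i)
      as.vector(jb) + N * (i - 1L), integer(F_ * 64L)))
    bf_x[[q]] <- rep(as.vector(Nab), 3L)
  }

  # ---- global assembly (duplicate triplets are summed) ----
  ii <- c(disc$ii, unlist(bf_i))
  jj <- c(disc$jj, unlist(bf_j))
  xx <- c(as.vector(Ke), unlist(bf_x))
  rhs <- as.vector(Matrix::sparseMatrix(
    i = c(as.vector(disc$gdof), unlist(rhs_bi)),
    j = rep(1L, E * 32L + length(unlist(rhs_bi))),
    x = c(as.vector(rhs_e), unlist(rhs_bx)),
    dims = c(disc$ndof, 1L)))

  # ---- Dirichlet rows: inlet profile and no-slip wall ----
  prof <- inflow_profile(Q_IN, mesh, disc)
  dir_nodes <- c(rep(disc$wall_nodes, 3L) +
                   N * rep(0:2, each = length(disc$wall_nodes)),
                 rep(prof$node, 3L) + N * rep(0:2, each = nrow(prof)))
  dir_vals <- c(rep(0, 3L * length(disc$wall_nodes)),
                prof$ux, prof$uy, prof$uz)
  # wall wins where a node is both on the wall and on the inlet rim
  keep_first <- !duplicated(dir_nodes)
  dir_nodes <- dir_nodes[keep_first]
  dir_vals <- dir_vals[keep_first]

  is_dir <- logical(disc$ndof)
  is_dir[dir_nodes] <- TRUE
  drop <- is_dir[ii]
  A <- Matrix::sparseMatrix(i = ii[!drop], j = jj[!drop], x = xx[!drop],
                            dims = c(disc$ndof, disc$ndof)) +
    Matrix::sparseMatrix(i = dir_nodes, j = dir_nodes,
                         x = rep(1, length(dir_nodes)),
                         dims = c(disc$ndof, disc$ndof))
  rhs[is_dir] <- 0
  rhs[dir_nodes] <- dir_vals

  sol <- .solve_layered(A, rhs, disc$layers)
  if (any(!is.finite(sol))) {
    stop("non-finite finite-element solution (solver failure)", call. = FALSE)
  }
  structure(list(u = matrix(sol[seq_len(3L * N)], N, 3L),
                 p = sol[3L * N + seq_len(N)],
                 t = state$t + dt),
            class = "fem_state")
}

# direct solve of the layer-wise block-tridiagonal system by a dense block
# Thomas sweep: forward elimination with LAPACK LU per layer block, then back
# substitution. `layers` lists the dof indices of each axial node layer.
.solve_layered <- function(A, b, layers) {
  nl <- length(layers)
  Fs <- vector("list", nl)
  rh <- vector("list", nl)
  prev_S <- NULL
  prev_r <- NULL
  for (k in seq_len(nl)) {
    ik <- layers[[k]]
    D <- as.matrix(A[ik, ik])
    r <- b[ik]
    if (k > 1L) {
      E <- A[ik, layers[[k - 1L]]]
      D <- D - as.matrix(E %*% prev_S)
      r <- r - as.vector(E %*% prev_r)
    }
    if (k < nl) {
      Fk <- as.matrix(A[ik, layers[[k + 1L]]])
      SF <- solve(D, cbind(Fk, r))
      prev_S <- SF[, seq_len(ncol(Fk)), drop = FALSE]
      prev_r <- SF[, ncol(Fk) + 1L]
      Fs[[k]] <- prev_S
      rh[[k]] <- prev_r
    } else {
      rh[[k]] <- as.vector(solve(D, r))
    }
  }
  x <- numeric(length(b))
  x[layers[[nl]]] <- rh[[nl]]
  for (k in seq(nl - 1L, 1L)) {
    x[layers[[k]]] <- rh[[k]] - as.vector(Fs[[k]] %*% x[layers[[k + 1L]]])
  }
  x
}
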