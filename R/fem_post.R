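#' Boundary flow rate
#'
#' Surface integral of `u . n` over a tagged boundary, converted to ml/s.
#' Sign convention: the integral uses the outward normal, then inlet flow is
#' reported positive into the domain (sign flipped at the inlet) and outlet
#' flow positive out of the domain.
#'
#' @param state An `fem_state`.
#' @param disc An `fem_disc`.
#' @param tag `"inlet"`, `"outlet"` or `"wall"`.
#' @return Flow rate (ml/s).
#' @export
boundary_flow <- function(state, disc, tag) {
  bd <- disc$boundary[[tag]]
  if (is.null(bd)) stop("unknown boundary tag: ", tag, call. = FALSE)
  flux <- 0
  F_ <- nrow(bd$pnode)
  for (q in seq_along(bd$qp)) {
    d <- bd$qp[[q]]
    u_qp <- matrix(0, F_, 3L)
    for (a in 1:8) u_qp <- u_qp + d$N[, a] * state$u[bd$pnode[, a], ]
    flux <- flux + sum(rowSums(u_qp * d$ndA))
  }
  out <- flux / .ML_M3
  if (tag == "inlet") -out else out
}

#' Boundary mean normal traction
#'
#' Area average of the normal-normal component of the Cauchy stress
#' `T = -p I + mu (grad u + grad u^T)` over a tagged boundary, returned as a
#' positive pressure in mmHg (i.e. `-mean(T n . n) / 133.322`): at rest with
#' a uniform pressure field `p0` it returns `p0`.
#'
#' @inheritParams boundary_flow
#' @return Mean pressure (mmHg).
#' @export
boundary_mean_traction <- function(state, disc, tag) {
  bd <- disc$boundary[[tag]]
  if (is.null(bd)) stop("unknown boundary tag: ", tag, call. = FALSE)
  mu <- disc$props$mu
  F_ <- nrow(bd$pnode)
  tot <- 0
  area <- 0
  for (q in seq_along(bd$qp)) {
    d <- bd$qp[[q]]
    wA <- sqrt(rowSums(d$ndA^2))
    nhat <- d$ndA / wA
    p_qp <- numeric(F_)
    gradu <- array(0, dim = c(F_, 3L, 3L))   # gradu[f, i, k] = d u_i / d x_k
    for (a in 1:8) {
      p_qp <- p_qp + d$N[, a] * state$p[bd$pnode[, a]]
      for (i in 1:3) for (k in 1:3) {
        gradu[, i, k] <- gradu[, i, k] + d$G[, a, k] * state$u[bd$pnode[, a], i]
      }
    }
    # T n . n = -p + 2 mu n . D(u) n
    ndn <- numeric(F_)
    for (i in 1:3) for (k in 1:3) {
      ndn <- ndn + nhat[, i] * mu * (gradu[, i, k] + gradu[, k, i]) * nhat[, k]
    }
    tnn <- -p_qp + ndn
    tot <- tot + sum(tnn * wA)
    area <- area + sum(wA)
  }
  -(tot / area) / .MMHG_PA
}

#' Wall shear stress field
#'
#' Magnitude of the tangential component of the boundary traction
#' `T n - (n . T n) n` on the wall, evaluated per wall face (mean over the
#' face quadrature points). With `recover = TRUE` (default) the velocity
#' gradient at the wall is linearly extrapolated from the wall element and
#' its one-layer-inward neighbor (`1.5 g_wall - 0.5 g_inner`), which removes
#' the O(h) one-sided bias of the trilinear gradient (exact for a parabolic
#' profile); `recover = FALSE` evaluates the raw element gradient.
#'
#' @param state An `fem_state`.
#' @param disc An `fem_disc`.
#' @param recover Use two-layer gradient recovery (default `TRUE`).
#' @return Tibble with face centroid coordinates `x, y, z`, face `area`
#'   (m^2) and `wss` (Pa).
#' @export
wall_shear_stress <- function(state, disc, recover = TRUE) {
  bd <- disc$boundary$wall
  mu <- disc$props$mu
  F_ <- nrow(bd$pnode)
  wss_acc <- numeric(F_)
  w_acc <- numeric(F_)
  pos_acc <- matrix(0, F_, 3L)
  for (q in seq_along(bd$qp)) {
    d <- bd$qp[[q]]
    wA <- sqrt(rowSums(d$ndA^2))
    nhat <- d$ndA / wA
    p_qp <- numeric(F_)
    gradu <- array(0, dim = c(F_, 3L, 3L))
    for (a in 1:8) {
      p_qp <- p_qp + d$N[, a] * state$p[bd$pnode[, a]]
      for (i in 1:3) for (k in 1:3) {
        gradu[, i, k] <- gradu[, i, k] + d$G[, a, k] * state$u[bd$pnode[, a], i]
      }
    }
    if (recover && !is.null(d$G_nb)) {
      gradn <- array(0, dim = c(F_, 3L, 3L))
      for (a in 1:8) for (i in 1:3) for (k in 1:3) {
        gradn[, i, k] <- gradn[, i, k] +
          d$G_nb[, a, k] * state$u[bd$pnode_nb[, a], i]
      }
      gradu <- 1.5 * gradu - 0.5 * gradn
    }
    tn <- matrix(0, F_, 3L)                 # traction vector T n
    for (i in 1:3) {
      tn[, i] <- -p_qp * nhat[, i]
      for (k in 1:3) {
        tn[, i] <- tn[, i] + mu * (gradu[, i, k] + gradu[, k, i]) * nhat[, k]
      }
    }
    tnn <- rowSums(tn * nhat)
    tang <- tn - tnn * nhat
    wss_acc <- wss_acc + sqrt(rowSums(tang^2)) * wA
    w_acc <- w_acc + wA
    pos_acc <- pos_acc + d$pos * wA
  }
  tibble::tibble(x = pos_acc[, 1] / w_acc, y = pos_acc[, 2] / w_acc,
                 z = pos_acc[, 3] / w_acc, area = w_acc,
                 wss = wss_acc / w_acc)
}

#' Divergence diagnostics of a flow state
#'
#' Net divergence integral and relative L2 divergence norm of the discrete
#' velocity; both should be small (mass conservation holds up to the
#' stabilization tolerance in the Q1-Q1 formulation).
#'
#' @inheritParams wall_shear_stress
#' @return List with `net` (m^3/s, the signed integral of `div u`) and
#'   `l2_rel` (L2 norm of `div u` relative to the L2 norm of `|grad u|`).
#' @export
divergence_diagnostics <- function(state, disc) {
  mesh <- disc$mesh
  E <- disc$E
  net <- 0
  div2 <- 0
  grad2 <- 0
  for (q in 1:8) {
    detw <- disc$detJ[[q]]
    G <- disc$G[[q]]
    gradu <- array(0, dim = c(E, 3L, 3L))
    for (a in 1:8) {
      ua <- state$u[mesh$hex[, a], , drop = FALSE]
      for (i in 1:3) for (k in 1:3) {
        gradu[, i, k] <- gradu[, i, k] + G[, a, k] * ua[, i]
      }
    }
    div_qp <- gradu[, 1, 1] + gradu[, 2, 2] + gradu[, 3, 3]
    net <- net + sum(detw * div_qp)
    div2 <- div2 + sum(detw * div_qp^2)
    grad2 <- grad2 + sum(detw * rowSums(matrix(gradu^2, E)))
  }
  list(net = net, l2_rel = sqrt(div2) / max(sqrt(grad2), 1e-300))
}

#' Steady flow by pseudo-time stepping
#'
#' Drives [fem_time_step()] with constant interface data and a very large
#' step (the implicit-Euler transient term then vanishes), iterating a few
#' times so the lagged convection velocity and the stabilization parameter
#' settle; at the low Reynolds numbers of the tube fixtures two or three
#' iterations suffice.
#'
#' @param disc An `fem_disc`.
#' @param Q_IN Inlet flow rate (ml/s).
#' @param P_OUT Outlet mean pressure (mmHg).
#' @param n_iter Number of quasi-Newton (Picard) iterations; default 3.
#' @param dt_steady Pseudo step (s); default 1e6.
#' @return The steady `fem_state`.
#' @export
fem_steady_state <- function(disc, Q_IN, P_OUT, n_iter = 3, dt_steady = 1e6) {
  st <- fem_flow_state(disc)
  for (k in seq_len(n_iter)) {
    st <- fem_time_step(st, disc, Q_IN, P_OUT, dt_steady)
  }
  st
}

#' Finite-element tube as a distributed model
#'
#' Wraps the stabilized tube-flow solver into the distributed-model
#' contract used by the coupling drivers: `advance(t, dt, Q_IN, P_OUT)`
#' imposes the parabolic inflow carrying `Q_IN` (ml/s) and the do-nothing
#' outlet traction at `P_OUT` (mmHg), takes one implicit step, and returns
#' `P_IN` (inlet mean normal traction, as positive pressure, mmHg) and
#' `Q_OUT` (outlet flow, ml/s). Checkpoint/restore snapshot the discrete
#' state so the splitting-implicit loop can re-run a step. All unit
#' conversions (mmHg/ml <-> Pa/m^3) happen inside this adapter.
#'
#' @param geometry A [tube_geometry()].
#' @param props A [fluid_props()].
#' @param stab A [stabilization_params()].
#' @return An object of class `distributed_model` with an extra `$disc`
#'   field (the discretization, for post-processing).
#' @export
fem_tube_model <- function(geometry = tube_geometry(),
                           props = fluid_props(),
                           stab = stabilization_params()) {
  mesh <- generate_tube_mesh(geometry)
  disc <- fem_discretization(mesh, props, stab)
  env <- new.env(parent = emptyenv())
  env$state <- fem_flow_state(disc)
  structure(list(
    advance = function(t, dt, Q_IN, P_OUT) {
      env$state <- fem_time_step(env$state, disc, Q_IN, P_OUT, dt)
      list(P_IN = boundary_mean_traction(env$state, disc, "inlet"),
           Q_OUT = boundary_flow(env$state, disc, "outlet"))
    },
    checkpoint = function() env$state,
    restore = function(token) {
      env$state <- token
      invisible(NULL)
    },
    state = function() env$state,
    disc = disc,
    label = sprintf("fem_tube (R=%g m, L=%g m, h=%g m)",
                    geometry$radius, geometry$length, geometry$h)
  ), class = "distributed_model")
}

#' Export a flow state to legacy VTK
#'
#' Writes the mesh with point-data velocity and pressure as an ASCII legacy
#' VTK file readable by ParaView.
#'
#' @param state An `fem_state`.
#' @param disc An `fem_disc`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(state, disc, path) {
  mesh <- disc$mesh
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "pulmflow tube flow state",
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(mesh$nodes)), con)
  utils::write.table(format(mesh$nodes, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  E <- nrow(mesh$hex)
  writeLines(sprintf("CELLS %d %d", E, 9L * E), con)
  utils::write.table(cbind(8L, mesh$hex - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  writeLines(as.character(rep(12L, E)), con)
  writeLines(sprintf("POINT_DATA %d", nrow(mesh$nodes)), con)
  writeLines("VECTORS velocity double", con)
  utils::write.table(format(state$u, digits = 9), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(state$p, digits = 9), con)
  invisible(path)
}
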