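#' Idealized tube geometry for the distributed flow model
#'
#' A straight rigid circular tube, meshed with structured hexahedra; the
#' stand-in geometry for the distributed pulmonary-artery domain (the
#' default caliber is roughly that of the main pulmonary artery).
#'
#' @param radius Tube radius (m); default 0.012.
#' @param length Tube length (m); default 0.05.
#' @param h Target mesh size (m); must resolve the radius (`h < radius`).
#' @return An object of class `tube_geometry`.
#' @export
tube_geometry <- function(radius = 0.012, length = 0.05, h = radius / 8) {
  stopifnot(radius > 0, length > 0)
  if (h >= radius) {
    stop("mesh size h must be smaller than the tube radius", call. = FALSE)
  }
  structure(list(radius = radius, length = length, h = h),
            class = "tube_geometry")
}

# reference Q1 hex: nodes of [-1,1]^3 in the usual counter-clockwise
# bottom/top ordering
.hex_ref_nodes <- matrix(c(
  -1, -1, -1,   1, -1, -1,   1, 1, -1,   -1, 1, -1,
  -1, -1,  1,   1, -1,  1,   1, 1,  1,   -1, 1,  1
), ncol = 3, byrow = TRUE)

.hex_shape <- function(xi) {
  # values of the 8 trilinear shape functions at local point xi (length 3)
  r <- .hex_ref_nodes
  (1 + r[, 1] * xi[1]) * (1 + r[, 2] * xi[2]) * (1 + r[, 3] * xi[3]) / 8
}

.hex_dshape <- function(xi) {
  # 8 x 3 matrix of reference-coordinate gradients at xi
  r <- .hex_ref_nodes
  cbind(r[, 1] * (1 + r[, 2] * xi[2]) * (1 + r[, 3] * xi[3]),
        r[, 2] * (1 + r[, 1] * xi[1]) * (1 + r[, 3] * xi[3]),
        r[, 3] * (1 + r[, 1] * xi[1]) * (1 + r[, 2] * xi[2])) / 8
}

#' Structured hexahedral mesh of a circular tube
#'
#' Builds a structured Q1 hexahedral mesh of the tube from a butterfly
#' (O-grid) cross-section -- a central square block surrounded by a
#' structured ring whose outer nodes lie exactly on the circle -- extruded
#' along the axis. This layout avoids the degenerate corner cells of a
#' single-block square-to-disk map and gives every wall cell a clean radial
#' layering (used for wall-gradient recovery). Boundary faces are tagged
#' `inlet` (z = 0, outward normal -z), `outlet` (z = L) and `wall`, each
#' face carrying its parent element (and, for the wall, its one-layer-inward
#' neighbor); every boundary face carries exactly one tag.
#'
#' @param geometry A [tube_geometry()].
#' @return An object of class `fem_mesh`: `nodes` (N x 3), `hex` (E x 8
#'   node indices), `faces` (named list of face sets with node ids, parent
#'   elements and parent-local corner coordinates), `h`, `geometry`.
#' @export
generate_tube_mesh <- function(geometry) {
  stopifnot(inherits(geometry, "tube_geometry"))
  R <- geometry$radius
  L <- geometry$length
  h <- geometry$h
  m_c <- max(2L, as.integer(round(R / h)))       # core cells per side
  m_r <- max(2L, as.integer(round(R / (2 * h)))) # radial ring layers
  nz <- max(2L, as.integer(round(L / h)))

  sec <- .disk_section(m_c, m_r, R)
  Ns <- nrow(sec$pts)
  C <- nrow(sec$quad)

  zs <- seq(0, L, length.out = nz + 1L)
  nodes <- cbind(
    x = rep(sec$pts[, 1], nz + 1L),
    y = rep(sec$pts[, 2], nz + 1L),
    z = rep(zs, each = Ns)
  )

  # extrude: element (k, c) has index k*C + c; bottom face = section quad
  hex <- matrix(NA_integer_, nz * C, 8L)
  for (k in 0:(nz - 1L)) {
    rows <- k * C + seq_len(C)
    hex[rows, 1:4] <- sec$quad + k * Ns
    hex[rows, 5:8] <- sec$quad + (k + 1L) * Ns
  }

  # inlet (k = 0, winding reversed so the normal points in -z) and outlet
  inlet_nodes <- sec$quad[, c(1L, 4L, 3L, 2L)]
  inlet_parent <- seq_len(C)
  outlet_nodes <- sec$quad + nz * Ns
  outlet_parent <- (nz - 1L) * C + seq_len(C)

  # wall: CCW perimeter edges x axial layers, outward normal by construction
  W <- nrow(sec$wall_edges)
  kk <- rep(0:(nz - 1L), each = W)
  e1 <- rep(sec$wall_edges[, 1], nz)
  e2 <- rep(sec$wall_edges[, 2], nz)
  wall_nodes <- cbind(e1 + kk * Ns, e2 + kk * Ns,
                      e2 + (kk + 1L) * Ns, e1 + (kk + 1L) * Ns)
  wall_parent <- kk * C + rep(sec$wall_cell, nz)
  wall_neighbor <- kk * C + rep(sec$wall_cell_in, nz)

  face_set <- function(fnodes, parent, neighbor = NULL) {
    # local coordinates of the face corners inside the parent hex
    loc <- array(NA_real_, dim = c(nrow(fnodes), 4L, 3L))
    for (a in 1:4) {
      pe <- hex[parent, , drop = FALSE]
      idx <- integer(nrow(fnodes))
      for (b in 1:8) idx[pe[, b] == fnodes[, a]] <- b
      loc[, a, ] <- .hex_ref_nodes[idx, ]
    }
    list(nodes = fnodes, parent = parent, corner_local = loc,
         neighbor = neighbor)
  }

  structure(list(
    nodes = nodes,
    hex = hex,
    faces = list(
      inlet = face_set(inlet_nodes, inlet_parent),
      outlet = face_set(outlet_nodes, outlet_parent),
      wall = face_set(wall_nodes, wall_parent, wall_neighbor)
    ),
    h = h, m = m_c, nz = nz,
    geometry = geometry
  ), class = "fem_mesh")
}

# butterfly cross-section of the unit disk scaled to radius R:
# a central square block of side R (m_c x m_c cells) plus m_r structured
# ring layers whose outer nodes lie exactly on the circle.
.disk_section <- function(m_c, m_r, R) {
  a <- R / 2
  grid <- expand.grid(i = 0:m_c, j = 0:m_c)
  core_pts <- cbind(a * (2 * grid$i / m_c - 1), a * (2 * grid$j / m_c - 1))
  cid <- function(i, j) j * (m_c + 1L) + i + 1L

  cc <- expand.grid(i = 0:(m_c - 1L), j = 0:(m_c - 1L))
  core_quad <- cbind(cid(cc$i, cc$j), cid(cc$i + 1L, cc$j),
                     cid(cc$i + 1L, cc$j + 1L), cid(cc$i, cc$j + 1L))

  # CCW perimeter node ids of the core
  per <- c(cid(0:(m_c - 1L), 0L),
           cid(m_c, 0:(m_c - 1L)),
           cid(m_c:1L, m_c),
           cid(0L, m_c:1L))
  P <- length(per)                      # = 4 m_c
  q <- core_pts[per, , drop = FALSE]
  phi <- atan2(q[, 2], q[, 1])
  circ <- R * cbind(cos(phi), sin(phi))

  ncore <- nrow(core_pts)
  ring_pts <- NULL
  for (l in seq_len(m_r)) {
    w <- l / m_r
    ring_pts <- rbind(ring_pts, (1 - w) * q + w * circ)
  }
  pts <- rbind(core_pts, ring_pts)
  # node id of ring layer l (1..m_r) at perimeter position p (1..P)
  rid <- function(l, p) if (l == 0L) per[p] else ncore + (l - 1L) * P + p

  pnext <- c(2:P, 1L)
  ring_quad <- NULL
  wall_cell <- integer(0)
  wall_cell_in <- integer(0)
  for (l in 0:(m_r - 1L)) {
    # CCW in the section plane: inner point, outward, then tangentially on
    ring_quad <- rbind(ring_quad, cbind(rid(l, seq_len(P)), rid(l + 1L, seq_len(P)),
                                        rid(l + 1L, pnext), rid(l, pnext)))
  }
  quad <- rbind(core_quad, ring_quad)
  nring0 <- nrow(core_quad)
  wall_cell <- nring0 + (m_r - 1L) * P + seq_len(P)
  wall_cell_in <- nring0 + (m_r - 2L) * P + seq_len(P)
  wall_edges <- cbind(rid(m_r, seq_len(P)), rid(m_r, pnext))
  list(pts = pts, quad = quad, wall_edges = wall_edges,
       wall_cell = wall_cell, wall_cell_in = wall_cell_in)
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf(
    "<fem_mesh> tube R=%g m, L=%g m: %d nodes, %d hexahedra (h = %g m)\n",
    x$geometry$radius, x$geometry$length, nrow(x$nodes), nrow(x$hex), x$h))
  cat(sprintf("  boundary faces: inlet %d, outlet %d, wall %d\n",
              nrow(x$faces$inlet$nodes), nrow(x$faces$outlet$nodes),
              nrow(x$faces$wall$nodes)))
  invisible(x)
}

#' Discrete mesh volume
#'
#' Sum of the Jacobian-weighted quadrature over all cells; converges to the
#' analytic `pi R^2 L` under refinement (the inscribed-polygon boundary
#' makes it a slight underestimate).
#'
#' @param mesh An `fem_mesh`.
#' @return Volume (m^3).
#' @export
mesh_volume <- function(mesh) {
  g <- 1 / sqrt(3)
  qp <- as.matrix(expand.grid(c(-g, g), c(-g, g), c(-g, g)))
  vol <- 0
  coords <- .element_coords(mesh)
  for (q in seq_len(nrow(qp))) {
    dN <- .hex_dshape(qp[q, ])
    J <- .elem_jacobians(coords, dN)
    vol <- vol + sum(J$det)
  }
  vol
}

# element corner coordinates as an (E, 8, 3) array
.element_coords <- function(mesh) {
  E <- nrow(mesh$hex)
  arr <- array(NA_real_, dim = c(E, 8L, 3L))
  for (a in 1:8) arr[, a, ] <- mesh$nodes[mesh$hex[, a], ]
  arr
}

# vectorized 3x3 Jacobians: J[e, i, j] = sum_a coords[e, a, i] dN[a, j]
# returns det and inverse (as inv[e, j, k] with grad_phys = dN %*% inv)
.elem_jacobians <- function(coords, dN) {
  E <- dim(coords)[1]
  J <- array(0, dim = c(E, 3L, 3L))
  for (i in 1:3) J[, i, ] <- coords[, , i] %*% dN
  a11 <- J[, 1, 1]; a12 <- J[, 1, 2]; a13 <- J[, 1, 3]
  a21 <- J[, 2, 1]; a22 <- J[, 2, 2]; a23 <- J[, 2, 3]
  a31 <- J[, 3, 1]; a32 <- J[, 3, 2]; a33 <- J[, 3, 3]
  c11 <- a22 * a33 - a23 * a32
  c12 <- a13 * a32 - a12 * a33
  c13 <- a12 * a23 - a13 * a22
  c21 <- a23 * a31 - a21 * a33
  c22 <- a11 * a33 - a13 * a31
  c23 <- a13 * a21 - a11 * a23
  c31 <- a21 * a32 - a22 * a31
  c32 <- a12 * a31 - a11 * a32
  c33 <- a11 * a22 - a12 * a21
  det <- a11 * c11 + a12 * c21 + a13 * c31
  inv <- array(0, dim = c(E, 3L, 3L))
  inv[, 1, 1] <- c11 / det; inv[, 1, 2] <- c12 / det; inv[, 1, 3] <- c13 / det
  inv[, 2, 1] <- c21 / det; inv[, 2, 2] <- c22 / det; inv[, 2, 3] <- c23 / det
  inv[, 3, 1] <- c31 / det; inv[, 3, 2] <- c32 / det; inv[, 3, 3] <- c33 / det
  list(det = det, inv = inv)
}
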