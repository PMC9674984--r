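#' Parametric gas-vesicle capsule geometry
#'
#' A gas vesicle is modelled as a circular cylinder of diameter `D` closed by
#' two conical end caps. `L` is the total tip-to-tip length, matching how
#' particle lengths are measured end-to-end on cryo-EM images. The cone height
#' is `cone_height_ratio * D` per cap (default 0.5, i.e. a 45 degree
#' half-angle cone); the true cone angle of native vesicles is not known and
#' the ratio is kept as an explicit free parameter.
#'
#' @param D Cylinder diameter in nm (> 0).
#' @param L Total tip-to-tip length in nm; must exceed `2 * cone_height_ratio * D`
#'   by a non-negative cylinder length (equality gives a pure bicone).
#' @param cone_height_ratio Cone height per cap as a fraction of `D` (default 0.5).
#' @return An object of class `gv_geometry`: list with fields `D`, `L`, `h`
#'   (cone height), `Lc` (cylinder length), `cone_height_ratio`, and analytic
#'   `volume` (nm^3) and `area` (nm^2) of the closed surface.
#' @examples
#' geom <- gv_capsule(85, 500)
#' geom$volume
#' @export
gv_capsule <- function(D, L, cone_height_ratio = 0.5) {
  stopifnot(is.numeric(D), length(D) == 1, is.numeric(L), length(L) == 1,
            is.numeric(cone_height_ratio), length(cone_height_ratio) == 1)
  if (!is.finite(D) || D <= 0) stop("diameter D must be a positive length (nm)")
  if (!is.finite(L) || L <= 0) stop("total length L must be a positive length (nm)")
  if (cone_height_ratio <= 0) stop("cone_height_ratio must be positive")
  h <- cone_height_ratio * D
  Lc <- L - 2 * h
  if (Lc < -1e-9 * L) {
    stop("cones longer than the particle: need L >= 2 * cone_height_ratio * D (L = ",
         L, " nm, cones = ", 2 * h, " nm)")
  }
  Lc <- max(Lc, 0)
  R <- D / 2
  geom <- list(
    D = D, L = L, h = h, Lc = Lc, cone_height_ratio = cone_height_ratio,
    volume = pi * R^2 * Lc + (2 / 3) * pi * R^2 * h,
    # lateral cylinder area + two cone slant areas
    area = pi * D * Lc + 2 * pi * R * sqrt(R^2 + h^2)
  )
  class(geom) <- "gv_geometry"
  geom
}

#' @export
print.gv_geometry <- function(x, ...) {
  cat("<gv_geometry> capsule: D =", x$D, "nm, L =", x$L, "nm (cylinder",
      format(x$Lc), "nm + 2 cones of", format(x$h), "nm)\n")
  cat("  analytic volume", format(x$volume, digits = 6), "nm^3, area",
      format(x$area, digits = 6), "nm^2\n")
  invisible(x)
}

# Radius of the surface of revolution at axial station z (z = 0 at centroid).
capsule_radius_profile <- function(geom, z) {
  half <- geom$L / 2
  zc <- geom$Lc / 2
  r <- numeric(length(z))
  az <- abs(z)
  in_cyl <- az <= zc + 1e-12
  r[in_cyl] <- geom$D / 2
  in_cone <- !in_cyl
  r[in_cone] <- pmax(0, (half - az[in_cone]) / geom$h) * geom$D / 2
  r
}

#' Triangulate a capsule geometry into a closed shell mesh
#'
#' Builds a structured surface mesh: rings of nodes along the z axis
#' (axis = vesicle principal axis, centroid at the origin), triangulated band
#' by band, with each cone tip closed by a fan to a single apex vertex. The
#' structured layout gives reproducible node ordering and trivially
#' identifiable apex nodes.
#'
#' @param geom A `gv_geometry` from [gv_capsule()].
#' @param target_edge Target edge length in nm; must resolve the circumference
#'   with at least ~18 segments (`target_edge <= D/6`).
#' @return A `gv_mesh`: list with `nodes` (n x 3 matrix, nm), `tris`
#'   (m x 3 integer matrix, 1-based, outward oriented), `apex` (ids of the two
#'   tip nodes), `edge_target`, and the generating `geometry`.
#' @examples
#' mesh <- gv_mesh(gv_capsule(85, 500), target_edge = 8)
#' mesh_volume(mesh) / gv_capsule(85, 500)$volume
#' @export
gv_mesh <- function(geom, target_edge = 5) {
  stopifnot(inherits(geom, "gv_geometry"))
  if (!is.finite(target_edge) || target_edge <= 0) stop("target_edge must be positive (nm)")
  if (target_edge > geom$D / 6) {
    stop("target_edge too coarse: need target_edge <= D/6 = ", format(geom$D / 6),
         " nm to resolve the circumference")
  }
  R <- geom$D / 2
  ntheta <- max(18L, as.integer(ceiling(pi * geom$D / target_edge)))
  # axial stations: cone tip -> cone base -> cylinder -> cone base -> tip
  n_cone <- max(2L, as.integer(ceiling(geom$h / target_edge)))
  n_cyl <- max(1L, as.integer(ceiling(geom$Lc / target_edge)))
  half <- geom$L / 2
  zc <- geom$Lc / 2
  z_cone_top <- seq(half, zc, length.out = n_cone + 1L)    # tip .. cone base
  z_cyl <- seq(zc, -zc, length.out = n_cyl + 1L)
  z_cone_bot <- seq(-zc, -half, length.out = n_cone + 1L)
  # ring stations exclude the two tips (apex points, zero radius)
  z_rings <- c(z_cone_top[-1L], z_cyl[-1L], z_cone_bot[-1L])
  z_rings <- z_rings[-length(z_rings)]
  if (geom$Lc == 0) { # bicone: drop duplicated equator station
    z_rings <- unique(z_rings)
  }
  nring <- length(z_rings)
  theta <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  r_rings <- capsule_radius_profile(geom, z_rings)
  # nodes: apex top (1), rings, apex bottom (last)
  ring_nodes <- matrix(0, nring * ntheta, 3)
  for (i in seq_len(nring)) {
    idx <- (i - 1L) * ntheta + seq_len(ntheta)
    ring_nodes[idx, 1] <- r_rings[i] * cos(theta)
    ring_nodes[idx, 2] <- r_rings[i] * sin(theta)
    ring_nodes[idx, 3] <- z_rings[i]
  }
  nodes <- rbind(c(0, 0, half), ring_nodes, c(0, 0, -half))
  apex_top <- 1L
  apex_bot <- nrow(nodes)
  ring_id <- function(i, j) 1L + (i - 1L) * ntheta + ((j - 1L) %% ntheta) + 1L

  tris <- vector("list", nring + 1L)
  j <- seq_len(ntheta)
  # top fan: apex at +z; outward orientation = counter-clockwise seen from +z
  tris[[1L]] <- cbind(apex_top, ring_id(1L, j), ring_id(1L, j + 1L))
  if (nring > 1L) {
    for (i in seq_len(nring - 1L)) {
      a <- ring_id(i, j); b <- ring_id(i, j + 1L)
      c_ <- ring_id(i + 1L, j); d <- ring_id(i + 1L, j + 1L)
      # band between ring i (higher z) and ring i+1; split each quad along
      # alternating diagonals (checkerboard) so the pattern is achiral and
      # introduces no global bending-twist bias
      even <- (i + j) %% 2L == 0L
      tri_a <- rbind(cbind(a, c_, b)[!even, , drop = FALSE],
                     cbind(a, c_, d)[even, , drop = FALSE])
      tri_b <- rbind(cbind(b, c_, d)[!even, , drop = FALSE],
                     cbind(a, d, b)[even, , drop = FALSE])
      tris[[i + 1L]] <- rbind(tri_a, tri_b)
    }
  }
  tris[[nring + 1L]] <- cbind(apex_bot, ring_id(nring, j + 1L), ring_id(nring, j))
  tris <- do.call(rbind, tris)
  storage.mode(tris) <- "integer"
  dimnames(tris) <- NULL

  mesh <- structure(list(
    nodes = nodes, tris = tris, apex = c(apex_top, apex_bot),
    edge_target = target_edge, geometry = geom
  ), class = "gv_mesh")
  if (mesh_volume(mesh) <= 0) stop("internal error: mesh not outward oriented")
  mesh
}

#' @export
print.gv_mesh <- function(x, ...) {
  cat("<gv_mesh>", nrow(x$nodes), "nodes,", nrow(x$tris), "triangles,",
      "target edge", x$edge_target, "nm\n")
  cat("  signed volume", format(mesh_volume(x), digits = 6), "nm^3 (analytic ",
      format(x$geometry$volume, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Signed enclosed volume and total area of a triangle shell mesh
#'
#' Volume by the divergence theorem (sum of signed tetrahedra against the
#' origin); positive for outward-oriented closed surfaces. Area is the plain
#' sum of triangle areas.
#'
#' @param mesh A `gv_mesh` (or any list with `nodes` and `tris`).
#' @return Volume in nm^3 / area in nm^2.
#' @export
mesh_volume <- function(mesh) {
  check_closed(mesh)
  p <- mesh$nodes
  t1 <- mesh$tris[, 1]; t2 <- mesh$tris[, 2]; t3 <- mesh$tris[, 3]
  a <- p[t1, , drop = FALSE]; b <- p[t2, , drop = FALSE]; c_ <- p[t3, , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(a * cr) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) {
  p <- mesh$nodes
  e1 <- p[mesh$tris[, 2], , drop = FALSE] - p[mesh$tris[, 1], , drop = FALSE]
  e2 <- p[mesh$tris[, 3], , drop = FALSE] - p[mesh$tris[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# All (unordered) edges of the mesh as a 2-column matrix plus incidence counts.
mesh_edges <- function(mesh) {
  t_ <- mesh$tris
  e <- rbind(t_[, c(1, 2)], t_[, c(2, 3)], t_[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  list(edges = e, counts = tab)
}

check_closed <- function(mesh) {
  counts <- mesh_edges(mesh)$counts
  if (any(counts != 2L)) {
    stop("mesh is not a closed 2-manifold: ", sum(counts != 2L),
         " edges not shared by exactly two triangles")
  }
  invisible(TRUE)
}

#' Validate shell-mesh invariants
#'
#' Checks that the mesh is a closed orientable genus-0 surface (every edge in
#' exactly two triangles, Euler characteristic 2, positive signed volume) and
#' that cylindrical-section nodes sit on the nominal radius.
#'
#' @param mesh A `gv_mesh`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
mesh_check <- function(mesh) {
  check_closed(mesh)
  nv <- nrow(mesh$nodes); nf <- nrow(mesh$tris)
  ne <- length(mesh_edges(mesh)$counts)
  if (nv - ne + nf != 2L) stop("Euler characteristic is not 2 (not genus-0)")
  if (mesh_volume(mesh) <= 0) stop("signed volume not positive (orientation)")
  geom <- mesh$geometry
  if (!is.null(geom) && geom$Lc > 0) {
    zc <- geom$Lc / 2
    in_cyl <- abs(mesh$nodes[, 3]) < zc - 1e-9
    if (any(in_cyl)) {
      r <- sqrt(rowSums(mesh$nodes[in_cyl, 1:2, drop = FALSE]^2))
      if (max(abs(r - geom$D / 2)) > 0.01 * geom$D / 2) {
        stop("cylindrical-section node radius deviates by more than 1% of D/2")
      }
    }
  }
  invisible(TRUE)
}

# Per-node area-weighted outward normals (used for exports and diagnostics).
mesh_node_normals <- function(mesh) {
  p <- mesh$nodes
  e1 <- p[mesh$tris[, 2], , drop = FALSE] - p[mesh$tris[, 1], , drop = FALSE]
  e2 <- p[mesh$tris[, 3], , drop = FALSE] - p[mesh$tris[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- matrix(0, nrow(p), 3)
  for (k in 1:3) {
    idx <- mesh$tris[, k]
    for (c_ in 1:3) nrm[, c_] <- nrm[, c_] + tabulate_sum(idx, cr[, c_], nrow(p))
  }
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

# sum `val` into bins `idx` of length n (rowsum-based scatter-add)
tabulate_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
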