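#' Bind mesh and material into a shell finite-element model
#'
#' Precomputes what the assembly and time-integration kernels need for the
#' facet-shell discretization (6 degrees of freedom per node: three
#' translations and three rotations): the membrane and bending section
#' matrices in the material frame, lumped nodal masses, and the constrained
#' degrees of freedom. The apex (cone tip) nodes have their translations
#' pinned. Because two pinned points on the axis leave the rigid spin about
#' the axis (numerically almost) free, the static/eigen problems additionally
#' carry an xz mirror-symmetry condition on the theta = 0 meridian (the
#' antisymmetric dofs u_y, rot_x, rot_z are fixed there); for the
#' axisymmetric structure this removes the spin and the redundant sine
#' partner of each degenerate mode pair without changing any eigenvalue.
#' The explicit integrator uses only the apex pins.
#'
#' @param mesh A [gv_mesh()].
#' @param material A [gv_material()].
#' @param bc Boundary condition: `"cone_caps"` (default) pins the
#'   translations of every node of both conical end caps (the reading of
#'   "zero displacement at the vertices of the conical ends" that reproduces
#'   the reported threshold and resonance of the average stripped vesicle);
#'   `"apex"` pins only the two tip nodes plus a meridian symmetry condition
#'   to remove the spin.
#' @return A `gv_model` list.
#' @export
gv_model <- function(mesh, material = gv_material(),
                     bc = c("cone_caps", "apex")) {
  stopifnot(inherits(mesh, "gv_mesh"), inherits(material, "gv_material"))
  bc <- match.arg(bc)
  section <- gv_section(material)
  axis <- c(0, 0, 1)
  areas <- tri_areas(mesh)
  rho_t <- material$rho_internal * material$thickness
  nn <- nrow(mesh$nodes)
  nodal_area <- numeric(nn)
  for (k in 1:3) {
    nodal_area <- nodal_area + tabulate_sum(mesh$tris[, k], areas, nn)
  }
  mass <- rho_t * nodal_area / 3

  if (bc == "cone_caps") {
    zc <- mesh$geometry$Lc / 2
    pin_nodes <- which(abs(mesh$nodes[, 3]) > zc - 1e-9 * mesh$geometry$L)
    fixed <- as.vector(vapply(pin_nodes, function(a) 6L * (a - 1L) + 1:3,
                              integer(3)))
  } else {
    pin_nodes <- mesh$apex
    apex_tdofs <- as.vector(vapply(mesh$apex, function(a) 6L * (a - 1L) + 1:3,
                                   integer(3)))
    # pinning two on-axis points leaves the rigid spin (numerically almost)
    # free; an xz mirror-symmetry condition on the theta = 0 meridian removes
    # it and the redundant sine partner of each degenerate pair without
    # changing any eigenvalue of the axisymmetric structure
    meridian <- which(abs(mesh$nodes[, 2]) < 1e-9 * mesh$geometry$D &
                        mesh$nodes[, 1] > 0)
    sym_dofs <- as.vector(vapply(meridian, function(a)
      6L * (a - 1L) + c(2L, 4L, 6L), integer(3)))
    fixed <- c(apex_tdofs, sym_dofs)
  }
  fixed <- sort(unique(fixed))
  # translational constraints in 3-dof numbering for the explicit integrator
  fixed_tra <- sort(as.vector(vapply(pin_nodes, function(a)
    3L * (a - 1L) + 1:3, integer(3))))

  structure(list(
    mesh = mesh, material = material, section = section, axis = axis,
    mass = mass, bc = bc, fixed_dofs = fixed, fixed_translations = fixed_tra,
    pinned_nodes = pin_nodes, drill_rel = 1e-6,
    ndof = 6L * nn
  ), class = "gv_model")
}

#' @export
print.gv_model <- function(x, ...) {
  cat("<gv_model>", nrow(x$mesh$nodes), "nodes /", x$ndof, "dofs,",
      length(x$fixed_dofs), "constrained dofs\n")
  invisible(x)
}

tri_areas <- function(mesh) {
  p <- mesh$nodes
  e1 <- p[mesh$tris[, 2], , drop = FALSE] - p[mesh$tris[, 1], , drop = FALSE]
  e2 <- p[mesh$tris[, 3], , drop = FALSE] - p[mesh$tris[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Assemble the elastic stiffness operator
#'
#' Facet-shell stiffness: constant-strain membrane plus discrete-Kirchhoff
#' (DKT) plate bending in each element's plane, with a small drilling
#' penalty (`drill_rel` of the element bending scale) regularizing the
#' in-plane rotation. Unconstrained and symmetric; its null space contains
#' the six rigid-body motions.
#'
#' @param model A [gv_model()].
#' @return Sparse symmetric `Matrix`, `ndof x ndof` (6 dof/node).
#' @export
assemble_stiffness <- function(model) {
  tm <- cpp_shell_triplets(model$mesh$nodes, model$mesh$tris,
                           model$section$Cm, model$section$Db, model$axis,
                           model$drill_rel)
  K <- Matrix::sparseMatrix(i = tm$i, j = tm$j, x = tm$x,
                            dims = c(model$ndof, model$ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Assemble the lumped (diagonal) mass operator
#'
#' Each node carries one third of the `rho * t * area` of its adjacent
#' triangles on its translational dofs, and the physical rotary inertia of
#' the wall (`m t^2 / 12`) on its rotational dofs.
#'
#' @param model A [gv_model()].
#' @return Numeric vector of length `ndof` (internal units, 1e-15 kg).
#' @export
assemble_mass <- function(model) {
  t2 <- model$material$thickness^2
  as.vector(vapply(model$mass, function(mi) c(rep(mi, 3), rep(mi * t2 / 12, 3)),
                   numeric(6)))
}

#' Linear static membrane prestress under a net external overpressure
#'
#' Solves the constrained linear system for a uniform net external
#' overpressure and recovers per-element membrane stress resultants. For a
#' long cylinder under external overpressure p the mid-section resultants
#' approach the thin-shell values `N_circ = -p R`, `N_axial = -p R / 2`
#' (compression negative).
#'
#' @param model A [gv_model()].
#' @param net_pressure_kpa Net external overpressure in kPa (positive =
#'   compression).
#' @return A tibble with one row per element: local-frame resultants
#'   `N11,N22,N12` and material-frame `N_axial,N_circ,N_shear` (pN/nm),
#'   plus the nodal displacement field in attribute `"displacement"`.
#' @export
solve_prestress <- function(model, net_pressure_kpa = 1) {
  p <- net_pressure_kpa * KPA_TO_MPA
  if (p == 0) {
    m <- nrow(model$mesh$tris)
    out <- tibble::tibble(N11 = numeric(m), N22 = numeric(m), N12 = numeric(m),
                          N_axial = numeric(m), N_circ = numeric(m),
                          N_shear = numeric(m))
    attr(out, "displacement") <- numeric(model$ndof)
    return(out)
  }
  K <- assemble_stiffness(model)
  f <- cpp_pressure_load(model$mesh$nodes, model$mesh$tris, p)
  free <- setdiff(seq_len(model$ndof), model$fixed_dofs)
  Kff <- K[free, free]
  u <- numeric(model$ndof)
  sol <- tryCatch(
    Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE), f[free],
                  system = "A"),
    error = function(e) stop("prestress system singular (unconstrained modes?): ",
                             conditionMessage(e))
  )
  u[free] <- as.numeric(sol)
  N <- cpp_membrane_stress(model$mesh$nodes, model$mesh$tris, model$section$Cm,
                           model$section$Db, model$axis, u)
  out <- tibble::tibble(N11 = N[, 1], N22 = N[, 2], N12 = N[, 3],
                        N_axial = N[, 4], N_circ = N[, 5], N_shear = N[, 6])
  attr(out, "displacement") <- u
  attr(out, "net_pressure_kpa") <- net_pressure_kpa
  out
}

#' Geometric (initial-stress) stiffness from a membrane prestress field
#'
#' Standard initial-stress formulation on the membrane stress resultants:
#' `Kg[a,b] = A * (grad_a' N grad_b) I3` per element on the translational
#' dofs. Linear in the prestress; destabilizing under external compression.
#' Used together with [pressure_load_stiffness()] the buckling pencil is
#' invariant under rigid rotations.
#'
#' @param model A [gv_model()].
#' @param prestress Result of [solve_prestress()] (or any tibble with
#'   `N11,N22,N12` local-frame resultants).
#' @return Sparse symmetric `Matrix`, `ndof x ndof`.
#' @export
geometric_stiffness <- function(model, prestress) {
  Nloc <- as.matrix(prestress[, c("N11", "N22", "N12")])
  tg <- cpp_kg_triplets(model$mesh$nodes, model$mesh$tris, model$section$Cm,
                        model$section$Db, model$axis, Nloc)
  Kg <- Matrix::sparseMatrix(i = tg$i, j = tg$j, x = tg$x,
                             dims = c(model$ndof, model$ndof))
  Matrix::forceSymmetric((Kg + Matrix::t(Kg)) / 2)
}

#' Load stiffness of a uniform follower pressure
#'
#' A uniform pressure acting normal to the deforming surface contributes its
#' own tangent stiffness (the derivative of the consistent nodal forces with
#' respect to geometry). Over a closed surface this operator is symmetric.
#' Including it together with the full initial-stress geometric stiffness
#' keeps the buckling pencil invariant under rigid rotations and reproduces
#' the classical hydrostatic ring-buckling coefficient.
#'
#' @param model A [gv_model()].
#' @param pressure_kpa Pressure in kPa (positive external).
#' @return Sparse symmetric `Matrix`, `ndof x ndof`.
#' @export
pressure_load_stiffness <- function(model, pressure_kpa = 1) {
  tp <- cpp_pressure_stiffness_triplets(model$mesh$nodes, model$mesh$tris,
                                        pressure_kpa * KPA_TO_MPA)
  Kp <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = tp$x,
                             dims = c(model$ndof, model$ndof))
  Matrix::forceSymmetric((Kp + Matrix::t(Kp)) / 2)
}

#' Restrict an operator (or vector) to the unconstrained dofs
#'
#' @param model A [gv_model()].
#' @param A Sparse matrix (`ndof x ndof`) or vector (length `ndof`).
#' @return The restriction of `A` to free dofs.
#' @export
apply_bc <- function(model, A) {
  free <- setdiff(seq_len(model$ndof), model$fixed_dofs)
  if (is.matrix(A) || inherits(A, "Matrix")) A[free, free] else A[free]
}
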