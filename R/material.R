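# Internal unit system: length nm, time us, force pN, pressure MPa (= pN/nm^2),
# mass 1e-15 kg. In these units moduli in MPa and densities in 1e-15 kg/nm^3
# give wave speeds in nm/us and frequencies in MHz without further conversion.
GPA_TO_MPA <- 1e3
KPA_TO_MPA <- 1e-3
DENSITY_SI_TO_INTERNAL <- 1e-12 # kg/m^3 -> 1e-15 kg / nm^3

#' Orthotropic gas-vesicle wall material
#'
#' The GV wall is a thin protein shell whose rib-like architecture makes it
#' strongly anisotropic: the GvpA ribs wind around the cylinder as a
#' low-pitch helix, so the stiff continuum direction runs circumferentially
#' (along the ribs) and the compliant direction along the vesicle axis
#' (across the ribs). Defaults are the standard continuum parameters for
#' stripped (GvpC-free) Anabaena vesicles: wall thickness 2.4 nm, density
#' 1350 kg/m^3, moduli 3.92 GPa and 0.98 GPa for the stiff (circumferential)
#' and compliant (axial) directions, and a near-incompressible major Poisson
#' ratio of 0.499 assigned to the stiff direction. With these assignments the
#' model reproduces the reported buckling threshold and lowest resonance of
#' the average stripped Anabaena vesicle; assigning the stiff modulus axially
#' instead lowers both by far more than their measurement uncertainty (see
#' the methods vignette). The minor ratio follows from reciprocity,
#' `nu12 * E_circ = nu21 * E_axial`. The in-plane shear modulus is not an
#' independent measurement; by default it is estimated as
#' `G = sqrt(E_axial * E_circ) / (2 * (1 + sqrt(nu12 * nu21)))`.
#'
#' @param E_axial Young's modulus along the vesicle axis, GPa (compliant,
#'   across the ribs).
#' @param E_circ Young's modulus across the axis, GPa (stiff, along the
#'   circumferential ribs).
#' @param nu Major Poisson ratio (associated with the stiff direction),
#'   dimensionless.
#' @param thickness Shell thickness, nm.
#' @param density Wall density, kg/m^3.
#' @param shear Optional in-plane shear modulus, GPa; `NULL` uses the
#'   geometric-mean estimate above.
#' @return A `gv_material` list with the inputs plus derived `nu21`, `G`
#'   (GPa) and internal-unit copies used by the assembly routines.
#' @examples
#' mat <- gv_material()
#' mat$nu21
#' @export
gv_material <- function(E_axial = 0.98, E_circ = 3.92, nu = 0.499,
                        thickness = 2.4, density = 1350, shear = NULL) {
  if (!all(is.finite(c(E_axial, E_circ, nu, thickness, density)))) {
    stop("material parameters must be finite")
  }
  if (E_axial <= 0 || E_circ <= 0) stop("moduli must be positive (GPa)")
  if (thickness <= 0) stop("thickness must be positive (nm)")
  if (density <= 0) stop("density must be positive (kg/m^3)")
  # the major ratio accompanies the stiffer in-plane direction; the minor
  # follows from reciprocity nu12 E2 = nu21 E1 (1 = axial, 2 = circumferential)
  if (E_circ >= E_axial) {
    nu21 <- nu
    nu12 <- nu * E_axial / E_circ
  } else {
    nu12 <- nu
    nu21 <- nu * E_circ / E_axial
  }
  if (nu < 0 || nu >= 1 || nu12 * nu21 >= 1) {
    stop("orthotropic stability violated: need 0 <= nu < 1 and nu12 * nu21 < 1 ",
         "(nu = ", nu, ", nu12 = ", format(nu12), ", nu21 = ", format(nu21), ")")
  }
  if (is.null(shear)) {
    nu_eff <- sqrt(nu12 * nu21)
    shear <- sqrt(E_axial * E_circ) / (2 * (1 + nu_eff))
  }
  if (shear <= 0) stop("shear modulus must be positive (GPa)")
  structure(list(
    E_axial = E_axial, E_circ = E_circ, nu = nu, nu12 = nu12, nu21 = nu21,
    G = shear, thickness = thickness, density = density,
    rho_internal = density * DENSITY_SI_TO_INTERNAL
  ), class = "gv_material")
}

#' @export
print.gv_material <- function(x, ...) {
  cat("<gv_material> E_axial", x$E_axial, "GPa, E_circ", x$E_circ,
      "GPa, nu12", format(x$nu12, digits = 4), "/ nu21",
      format(x$nu21, digits = 4), ", G", format(x$G, digits = 4),
      "GPa, t", x$thickness, "nm, rho", x$density, "kg/m^3\n")
  invisible(x)
}

#' Plane-stress constitutive and shell section matrices
#'
#' Returns the reduced orthotropic plane-stress stiffness `Q` (material frame:
#' axis 1 = vesicle axis, axis 2 = circumferential) together with the membrane
#' section matrix `Cm = t * Q` (force/length) and the bending section matrix
#' `Db = t^3/12 * Q` (force * length) of the homogeneous single-layer wall.
#' There is no membrane-bending coupling.
#'
#' @param material A [gv_material()].
#' @return A `gv_section` list with `Q` (MPa), `Cm` (pN/nm), `Db` (pN nm),
#'   and `thickness` (nm).
#' @export
gv_section <- function(material) {
  stopifnot(inherits(material, "gv_material"))
  E1 <- material$E_axial * GPA_TO_MPA
  E2 <- material$E_circ * GPA_TO_MPA
  G <- material$G * GPA_TO_MPA
  n12 <- material$nu12
  n21 <- material$nu21
  den <- 1 - n12 * n21
  Q <- matrix(c(E1 / den,       n21 * E1 / den, 0,
                n12 * E2 / den, E2 / den,       0,
                0,              0,              G), 3, 3, byrow = TRUE)
  Q <- (Q + t(Q)) / 2 # reciprocity makes Q symmetric; enforce exactly
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("constitutive matrix not positive definite")
  t_ <- material$thickness
  structure(list(Q = Q, Cm = t_ * Q, Db = t_^3 / 12 * Q, thickness = t_),
            class = "gv_section")
}

# Dilatational (stiffest in-plane) wave speed, nm/us.
dilatational_speed <- function(material) {
  sec <- gv_section(material)
  sqrt(max(sec$Q[1, 1], sec$Q[2, 2]) / material$rho_internal)
}
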