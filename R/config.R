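#' Structured run configuration
#'
#' Central, validated container for every tunable of the pipeline. The
#' defaults are exactly the standard constants of the stripped-Anabaena
#' model: geometry 85 x 500 nm with cone height D/2; moduli 3.92/0.98 GPa
#' (stiff circumferential), Poisson 0.499, thickness 2.4 nm, density
#' 1350 kg/m^3; ambient 101 kPa; 11.4 MHz burst of 1 us with 2-cycle Hann
#' tapers; CFL safety 0.8 and bulk-viscosity coefficients 0.06/1.2; ramp
#' from 100 kPa in 20 kPa steps, bisection to 1 kPa, buckling factor 3.
#'
#' @param ... Overrides as `block$key = value` named lists, e.g.
#'   `geometry = list(D = 60)`. Unknown blocks or keys are rejected.
#' @return A validated `gv_config` (nested named list).
#' @examples
#' cfg <- gv_config(geometry = list(D = 60, L = 300))
#' cfg$geometry$D
#' @export
gv_config <- function(...) {
  defaults <- list(
    geometry = list(D = 85, L = 500, cone_height_ratio = 0.5, target_edge = 5),
    material = list(E_axial = 0.98, E_circ = 3.92, nu = 0.499,
                    thickness = 2.4, density = 1350, shear = NA),
    load = list(ambient_kpa = 101, frequency = 11.4, duration = 1,
                taper_cycles = 2),
    solver = list(safety = 0.8, b1 = 0.06, b2 = 1.2, buckling_factor = 3,
                  tol = 1, p_start = 100, coarse_step = 20, p_max = 2000,
                  dynamics_edge = 12),
    seed = NA_integer_
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(over)) {
    if (blk == "seed") { defaults$seed <- over$seed; next }
    badk <- setdiff(names(over[[blk]]), names(defaults[[blk]]))
    if (length(badk)) {
      stop("unknown key(s) in block '", blk, "': ", paste(badk, collapse = ", "))
    }
    defaults[[blk]][names(over[[blk]])] <- over[[blk]]
  }
  validate_config(defaults)
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  if (g$D <= 0 || g$L <= 0) stop("geometry: D and L must be positive")
  if (g$L < 2 * g$cone_height_ratio * g$D) {
    stop("geometry: cones longer than the particle (L < 2 * ratio * D)")
  }
  m <- cfg$material
  nu_major <- m$nu
  nu_minor <- nu_major * min(m$E_axial, m$E_circ) / max(m$E_axial, m$E_circ)
  if (m$E_axial <= 0 || m$E_circ <= 0) stop("material: moduli must be positive")
  if (nu_major < 0 || nu_major >= 1 || nu_major * nu_minor >= 1) {
    stop("material: orthotropic stability violated (need 0 <= nu < 1 and ",
         "nu12 * nu21 < 1; got nu = ", m$nu, ")")
  }
  if (m$thickness <= 0) stop("material: thickness must be positive")
  if (m$density <= 0) stop("material: density must be positive")
  l <- cfg$load
  if (l$frequency <= 0 || l$duration <= 0) stop("load: frequency and duration must be positive")
  s <- cfg$solver
  if (s$safety <= 0 || s$safety > 1) stop("solver: safety must be in (0, 1]")
  if (s$tol <= 0 || s$coarse_step <= 0) stop("solver: tol and coarse_step must be positive")
  structure(cfg, class = "gv_config")
}

#' Load a configuration from a YAML file
#'
#' @param path YAML file with any subset of the [gv_config()] blocks.
#' @return A validated `gv_config`.
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  raw <- yaml::read_yaml(path)
  do.call(gv_config, raw)
}

#' Build model objects from a configuration
#'
#' @param cfg A [gv_config()].
#' @param target_edge Optional mesh-resolution override (nm).
#' @return A [gv_model()].
#' @export
config_model <- function(cfg, target_edge = NULL) {
  stopifnot(inherits(cfg, "gv_config"))
  g <- cfg$geometry
  m <- cfg$material
  mesh <- gv_mesh(gv_capsule(g$D, g$L, g$cone_height_ratio),
                  target_edge = target_edge %||% g$target_edge)
  mat <- gv_material(E_axial = m$E_axial, E_circ = m$E_circ, nu = m$nu,
                     thickness = m$thickness, density = m$density,
                     shear = if (is.na(m$shear)) NULL else m$shear)
  gv_model(mesh, mat)
}

#' Write a reproducibility manifest next to an output file
#'
#' Records the configuration (and its hash), package version, seed and
#' runtime so a run can be reproduced exactly.
#'
#' @param cfg A [gv_config()].
#' @param out_path The output artifact the manifest describes.
#' @param runtime_s Elapsed seconds.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(cfg, out_path, runtime_s = NA_real_) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required to write manifests")
  }
  man <- list(
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    package_version = as.character(utils::packageVersion("gvbuckle")),
    seed = cfg$seed,
    runtime_s = runtime_s,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
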