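#' Threshold sweep over diameter or length
#'
#' Computes buckling thresholds over a grid of diameters (at fixed total
#' length) or lengths (at fixed diameter), holding material, boundary and
#' load settings identical across the sweep. The default method is the
#' linear buckling analysis; the explicit ramp-plus-bisection protocol is
#' available but dominates runtime.
#'
#' @param vary `"diameter"` or `"length"`.
#' @param fixed_value The fixed dimension (nm).
#' @param grid Grid of the varied dimension (nm, >= 2 increasing values;
#'   >= 5 for fitting). Defaults: diameters `c(60,70,85,100,120,140,170)`,
#'   lengths `c(300,350,400,450,500,600)`.
#' @param method `"lba"` or `"explicit"`.
#' @param material A [gv_material()].
#' @param target_edge Mesh resolution (nm). Default 5 for LBA, 12 for
#'   explicit.
#' @param ... Passed to [find_threshold()] for the explicit method.
#' @return A `gv_sweep` tibble: `value_nm`, `threshold_kPa`, `method`,
#'   `varied`, `fixed_nm`.
#' @examples
#' \donttest{
#' sw <- sweep_thresholds("diameter", 500, grid = c(70, 100, 170))
#' }
#' @export
sweep_thresholds <- function(vary = c("diameter", "length"), fixed_value,
                             grid = NULL, method = c("lba", "explicit"),
                             material = gv_material(), target_edge = NULL,
                             ...) {
  vary <- match.arg(vary)
  method <- match.arg(method)
  if (is.null(grid)) {
    grid <- if (vary == "diameter") c(60, 70, 85, 100, 120, 140, 170)
            else c(300, 350, 400, 450, 500, 600)
  }
  if (length(grid) < 2) stop("grid needs at least two points (>= 5 to fit)")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (vary == "diameter") {
    if (any(grid < 40 | grid > 250)) stop("diameter grid outside [40, 250] nm")
  } else {
    if (any(grid < 200 | grid > 1000)) stop("length grid outside [200, 1000] nm")
  }
  if (is.null(target_edge)) target_edge <- if (method == "lba") 5 else 12
  thr <- vapply(grid, function(g) {
    D <- if (vary == "diameter") g else fixed_value
    L <- if (vary == "diameter") fixed_value else g
    mesh <- gv_mesh(gv_capsule(D, L), target_edge = min(target_edge, D / 6))
    model <- gv_model(mesh, material)
    if (method == "lba") {
      linear_buckling(model, n_modes = 1)$pressure_kPa[1]
    } else {
      find_threshold(model, ...)$threshold_kpa
    }
  }, numeric(1))
  out <- tibble::tibble(value_nm = grid, threshold_kPa = thr, method = method,
                        varied = vary, fixed_nm = fixed_value)
  class(out) <- c("gv_sweep", class(out))
  out
}

#' Fit the power law P = A x^alpha + B to a threshold sweep
#'
#' Nonlinear least squares with multistart over alpha initializations
#' (-4, -3, -2, -1, 0); the best-residual fit is kept. The additive offset
#' `B` is retained in the model and reported, not constrained.
#'
#' @param sweep A `gv_sweep` (or any tibble with `value_nm`,
#'   `threshold_kPa`).
#' @return A `gv_scaling_fit` list: `A`, `alpha`, `B`, `residual` (norm),
#'   `fit` (the `nls` object), `data`.
#' @examples
#' d <- tibble::tibble(value_nm = c(60, 80, 100, 130, 170, 200),
#'                     threshold_kPa = 1e8 * c(60, 80, 100, 130, 170, 200)^-3)
#' fit_power_law(d)$alpha
#' @export
fit_power_law <- function(sweep) {
  x <- sweep$value_nm
  y <- sweep$threshold_kPa
  if (length(x) < 5) stop("need at least 5 grid points to fit P = A x^alpha + B")
  best <- NULL
  for (a0 in c(-4, -3, -2, -1, 0)) {
    A0 <- if (abs(a0) < 1e-9) diff(range(y)) + 1e-9 else
      (y[1] - min(y)) / (x[1]^a0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * x^alpha + B,
                        start = list(A = A0, alpha = a0, B = min(y)),
                        control = nls.control(maxiter = 500, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # degenerate (flat) data: the power term is unidentifiable; report the
    # constant branch A = 0, alpha = 0, B = mean
    if (stats::sd(y) < 1e-8 * (abs(mean(y)) + 1e-300)) {
      flat <- stats::lm(y ~ 1)
      return(structure(list(
        A = 0, alpha = 0, B = mean(y),
        residual = sqrt(sum(stats::resid(flat)^2)), fit = flat,
        data = tibble::tibble(value_nm = x, threshold_kPa = y)
      ), class = "gv_scaling_fit"))
    }
    stop("power-law fit did not converge from any start")
  }
  co <- coef(best$fit)
  structure(list(
    A = unname(co["A"]), alpha = unname(co["alpha"]), B = unname(co["B"]),
    residual = sqrt(best$rss), fit = best$fit,
    data = tibble::tibble(value_nm = x, threshold_kPa = y)
  ), class = "gv_scaling_fit")
}

#' @export
print.gv_scaling_fit <- function(x, ...) {
  cat("<gv_scaling_fit> P = A * x^alpha + B with A =",
      format(x$A, digits = 4), ", alpha =", format(x$alpha, digits = 4),
      ", B =", format(x$B, digits = 4), "kPa (residual norm",
      format(x$residual, digits = 3), ")\n")
  invisible(x)
}

#' Classical ring-buckling pressure of a long thin cylinder
#'
#' The long-cylinder limit of the stability problem for an isotropic
#' cylindrical shell under external pressure:
#' `P = 2 E t^3 / ((1 - nu^2) D^3)`, i.e. `3 E I / R^3` per unit length with
#' `I = t^3 / 12` and the plane-strain correction `1/(1 - nu^2)`. This is
#' the concrete closed-form instantiation of the inverse-cubic
#' diameter-threshold relation.
#'
#' @param E Young's modulus (GPa).
#' @param nu Poisson ratio.
#' @param t Wall thickness (nm).
#' @param D Cylinder diameter (nm).
#' @return Pressure in kPa.
#' @examples
#' ring_buckling_pressure(1, 0.499, 2.4, 85)
#' @export
ring_buckling_pressure <- function(E, nu, t, D) {
  if (E <= 0 || t <= 0 || D <= 0 || nu < 0 || nu >= 1) {
    stop("non-physical inputs to the ring-buckling formula")
  }
  # E [GPa] * t^3/D^3 -> GPa = 1e6 kPa
  2 * E * t^3 / ((1 - nu^2) * D^3) * 1e6
}
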