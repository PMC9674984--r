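#' Sample a synthetic gas-vesicle population
#'
#' Draws per-vesicle lengths and diameters from named distributions,
#' emulating the geometry spread of a stripped Anabaena preparation:
#' diameters roughly 60-100 nm with a high tail, lengths roughly 200-800 nm.
#' Defaults: diameter ~ lognormal with median 85 nm and 10% coefficient of
#' variation, truncated to [50, 120] nm; length ~ normal(500, 100) truncated
#' to [200, 900] nm; draws independent.
#'
#' @param n Number of vesicles.
#' @param seed Mandatory RNG seed (integer).
#' @param diameter_dist,length_dist Lists `list(family, ...)` with family
#'   `"lognormal"` (meanlog, sdlog) or `"normal"` (mean, sd), plus
#'   `lower`/`upper` truncation bounds (nm).
#' @return A `gv_population` tibble: `id`, `length_nm`, `diameter_nm`,
#'   `intact` (all `TRUE`), with the distribution spec and seed in
#'   attributes. Thresholds are attached by [assign_thresholds()].
#' @examples
#' pop <- sample_population(1000, seed = 1)
#' median(pop$diameter_nm)
#' @export
sample_population <- function(n, seed,
                              diameter_dist = list(family = "lognormal",
                                                   meanlog = log(85),
                                                   sdlog = sqrt(log(1 + 0.1^2)),
                                                   lower = 50, upper = 120),
                              length_dist = list(family = "normal",
                                                 mean = 500, sd = 100,
                                                 lower = 200, upper = 900)) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n >= 1)
  rng <- function(spec, size) {
    lower <- spec$lower %||% -Inf
    upper <- spec$upper %||% Inf
    draw <- switch(spec$family,
      lognormal = function(k) {
        # truncated sampling by inverse CDF
        plo <- stats::plnorm(lower, spec$meanlog, spec$sdlog)
        phi <- stats::plnorm(upper, spec$meanlog, spec$sdlog)
        stats::qlnorm(runif(k, plo, phi), spec$meanlog, spec$sdlog)
      },
      normal = function(k) {
        plo <- stats::pnorm(lower, spec$mean, spec$sd)
        phi <- stats::pnorm(upper, spec$mean, spec$sd)
        stats::qnorm(runif(k, plo, phi), spec$mean, spec$sd)
      },
      stop("unknown distribution family: ", spec$family)
    )
    x <- draw(size)
    if (any(!is.finite(x)) || any(x <= 0)) {
      stop("invalid distribution parameters (non-positive or non-finite draws)")
    }
    x
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- rng(diameter_dist, n)
  l <- rng(length_dist, n)
  out <- tibble::tibble(id = seq_len(n), length_nm = l, diameter_nm = d,
                        intact = TRUE)
  attr(out, "seed") <- seed
  attr(out, "diameter_dist") <- diameter_dist
  attr(out, "length_dist") <- length_dist
  class(out) <- c("gv_population", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Diameter-to-threshold surrogate from a fitted power law
#'
#' Maps geometry to buckling threshold through a calibrated scaling fit
#' `P = A D^alpha + B`. Length is ignored by construction: the threshold of
#' cylindrical vesicles is set by the diameter and is essentially
#' length-independent over the physiological range.
#'
#' @param diameter_nm Diameters (nm).
#' @param fit A [fit_power_law()] result (on a diameter sweep).
#' @param length_nm Ignored; accepted for interface symmetry.
#' @return Thresholds in kPa. If any diameter lies outside the fitted range
#'   a warning attribute `"extrapolated"` is attached.
#' @export
threshold_surrogate <- function(diameter_nm, fit, length_nm = NULL) {
  stopifnot(inherits(fit, "gv_scaling_fit"))
  out <- fit$A * diameter_nm^fit$alpha + fit$B
  rng <- range(fit$data$value_nm)
  extra <- diameter_nm < rng[1] | diameter_nm > rng[2]
  if (any(extra)) {
    warning(sum(extra), " diameter(s) outside the fitted range [",
            rng[1], ", ", rng[2], "] nm; surrogate extrapolated")
    attr(out, "extrapolated") <- which(extra)
  }
  out
}

#' Attach surrogate buckling thresholds and collapse pressures
#'
#' Hydrostatic collapse is an irreversible event distinct from elastic
#' acoustic buckling, but the two are empirically correlated. The collapse
#' pressure is modelled phenomenologically as
#' `collapse_ratio * buckling threshold`.
#'
#' @param pop A [sample_population()] tibble.
#' @param fit A diameter [fit_power_law()].
#' @param collapse_ratio Scalar ratio; see [calibrate_collapse_ratio()].
#' @return The population with `threshold_kPa` and `collapse_kPa` columns.
#' @export
assign_thresholds <- function(pop, fit, collapse_ratio) {
  pop$threshold_kPa <- suppressWarnings(
    threshold_surrogate(pop$diameter_nm, fit))
  pop$collapse_kPa <- collapse_ratio * pop$threshold_kPa
  attr(pop, "collapse_ratio") <- collapse_ratio
  pop
}

#' Calibrate the collapse-to-buckling pressure ratio
#'
#' Chooses the single scalar `collapse_ratio` so that hydrostatic selection
#' of the given population at `at_pressure` leaves the target fraction
#' intact (survivors are the vesicles whose collapse pressure exceeds the
#' applied pressure, i.e. the small-diameter/high-threshold tail).
#'
#' @param pop Population with `threshold_kPa` (see [assign_thresholds()]
#'   with any ratio, or a bare threshold column).
#' @param target_intact Intact fraction at the calibration pressure.
#'   Default 0.30.
#' @param at_pressure Calibration pressure (kPa). Default 200.
#' @return The calibrated scalar ratio.
#' @export
calibrate_collapse_ratio <- function(pop, target_intact = 0.30,
                                     at_pressure = 200) {
  thr <- pop$threshold_kPa
  if (is.null(thr)) stop("population carries no thresholds")
  # survivors: collapse_ratio * thr > at_pressure for the top target_intact
  q <- stats::quantile(thr, 1 - target_intact, names = FALSE, type = 7)
  at_pressure / q
}

#' Hydrostatic precollapse selection
#'
#' Marks as collapsed every vesicle whose collapse pressure is at or below
#' the applied hydrostatic pressure and summarizes the selection: because
#' collapse pressure falls with diameter, pressure treatment removes the
#' large-diameter tail while leaving the length distribution essentially
#' unchanged.
#'
#' @param pop Population with `collapse_kPa` (see [assign_thresholds()]).
#' @param applied_pressure_kpa Applied hydrostatic pressure (kPa).
#' @return List with `population` (the surviving-marked population) and
#'   `report`, a one-row tibble: applied pressure, intact fraction, pre/post
#'   diameter and length summaries, max surviving diameter.
#' @export
hydrostatic_select <- function(pop, applied_pressure_kpa) {
  if (is.null(pop$collapse_kPa)) stop("population carries no collapse pressures")
  alive <- pop$intact & pop$collapse_kPa > applied_pressure_kpa
  if (!any(alive)) warning("no vesicles survive ", applied_pressure_kpa, " kPa")
  newpop <- pop
  newpop$intact <- alive
  surv <- newpop[alive, ]
  qs <- function(x) if (length(x)) stats::quantile(x, c(0.25, 0.5, 0.75),
                                                  names = FALSE) else rep(NA_real_, 3)
  report <- tibble::tibble(
    applied_kPa = applied_pressure_kpa,
    intact_fraction = mean(alive[pop$intact]),
    pre_mean_d = mean(pop$diameter_nm[pop$intact]),
    post_mean_d = mean(surv$diameter_nm),
    pre_sd_d = sd(pop$diameter_nm[pop$intact]),
    post_sd_d = sd(surv$diameter_nm),
    pre_mean_l = mean(pop$length_nm[pop$intact]),
    post_mean_l = mean(surv$length_nm),
    max_survivor_d = if (nrow(surv)) max(surv$diameter_nm) else NA_real_,
    d_q25 = qs(surv$diameter_nm)[1], d_q50 = qs(surv$diameter_nm)[2],
    d_q75 = qs(surv$diameter_nm)[3]
  )
  list(population = newpop, report = report)
}

#' Intact fraction versus hydrostatic pressure (collapse curve)
#'
#' Optical-density proxy of the fraction of intact vesicles as the
#' hydrostatic pressure increases: a monotone non-increasing step curve.
#'
#' @param pop Population with `collapse_kPa`.
#' @param pressure_grid Pressures (kPa).
#' @return Tibble `pressure_kPa`, `intact_fraction`.
#' @export
collapse_curve <- function(pop, pressure_grid) {
  alive0 <- pop$intact
  frac <- vapply(pressure_grid, function(p)
    mean(pop$collapse_kPa[alive0] > p), numeric(1))
  tibble::tibble(pressure_kPa = pressure_grid, intact_fraction = frac)
}

#' Nonlinear-signal proxy versus peak acoustic pressure
#'
#' Each intact vesicle contributes to the nonlinear (buckling-generated)
#' signal once the peak pressure reaches its buckling threshold, weighted by
#' a scattering proxy (volume-proportional, `diameter^3`, by default). The
#' apparent onset is the first grid pressure whose normalized signal exceeds
#' the noise floor.
#'
#' @param pop Population with `threshold_kPa`.
#' @param peak_grid Peak pressures (kPa), increasing.
#' @param noise_floor Normalized detection floor (default 0.02).
#' @param weight `"d3"` (volume proxy, default), `"d2"`, or `"uniform"`.
#' @return A `gv_signal` tibble: `peak_kPa`, `signal` (normalized to the
#'   all-buckled response of the same population); attribute
#'   `"onset_kPa"` (NA if never above floor).
#' @export
xam_signal <- function(pop, peak_grid, noise_floor = 0.02,
                       weight = c("d3", "d2", "uniform")) {
  weight <- match.arg(weight)
  alive <- pop$intact
  if (!any(alive)) stop("empty (fully collapsed) population")
  d <- pop$diameter_nm[alive]
  thr <- pop$threshold_kPa[alive]
  w <- switch(weight, d3 = d^3, d2 = d^2, uniform = rep(1, length(d)))
  wtot <- sum(w)
  sig <- vapply(peak_grid, function(p) sum(w[thr <= p]) / wtot, numeric(1))
  out <- tibble::tibble(peak_kPa = peak_grid, signal = sig)
  above <- which(sig > noise_floor)
  attr(out, "onset_kPa") <- if (length(above)) peak_grid[min(above)] else NA_real_
  attr(out, "noise_floor") <- noise_floor
  class(out) <- c("gv_signal", class(out))
  out
}

#' Optical density to vesicle concentration
#'
#' For stripped Anabaena vesicles an OD at 500 nm of 1 corresponds to
#' 184 pM, or a gas-filled volume fraction of 0.04%.
#'
#' @param od Optical density at 500 nm (>= 0).
#' @return Tibble with `concentration_pM` and `volume_fraction_percent`.
#' @examples
#' od_to_concentration(1)
#' @export
od_to_concentration <- function(od) {
  if (any(od < 0)) stop("optical density must be non-negative")
  tibble::tibble(od500 = od, concentration_pM = 184 * od,
                 volume_fraction_percent = 0.04 * od)
}

#' Diameter consistency of a single vesicle
#'
#' Standard deviation of repeated diameter measurements along the
#' cylindrical segment, expressed as a percentage of their mean; scale
#' invariant.
#'
#' @param segment_diameters At least two diameter measurements (nm).
#' @return Percent (100 * SD / mean).
#' @examples
#' diameter_consistency(c(84, 85, 86))
#' @export
diameter_consistency <- function(segment_diameters) {
  if (length(segment_diameters) < 2) stop("need at least two measurements")
  100 * stats::sd(segment_diameters) / mean(segment_diameters)
}
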