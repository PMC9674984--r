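#' Classify a trajectory as buckled or not
#'
#' Below the buckling threshold the maximum percent volume change grows
#' linearly with the peak overpressure; the onset of buckling appears as an
#' abrupt departure from that line. A probe is classified as buckled when
#' its `dv_max` exceeds `factor` times the linear prediction
#' `slope * peak` calibrated from low-pressure probes.
#'
#' @param dv_max_percent Maximum percent volume change of the probe.
#' @param peak_kpa Peak overpressure of the probe (kPa).
#' @param linear_slope Calibrated linear response slope (percent per kPa).
#' @param factor Departure factor (default 3; results should be insensitive
#'   over 2-5).
#' @return Logical.
#' @export
is_buckled <- function(dv_max_percent, peak_kpa, linear_slope, factor = 3) {
  if (!is.finite(linear_slope) || linear_slope <= 0) {
    stop("linear slope not calibrated (need >= 3 low-pressure probes)")
  }
  !is.finite(dv_max_percent) | dv_max_percent > factor * linear_slope * peak_kpa
}

#' Locate the dynamic buckling threshold by ramp plus bisection
#'
#' Reproduces the search protocol used to bracket the threshold: simulate
#' bursts starting at `p_start` and increasing in steps of `coarse_step`
#' until the structure buckles, then repeatedly bisect the bracketing
#' interval, keeping the subinterval in which buckling commences, down to a
#' bracket of width `tol`. The linear volume-response slope is calibrated
#' from the first three (unbuckled) probes. The threshold is reported as the
#' upper bracket edge, the first pressure that buckles.
#'
#' @param model A [gv_model()] (or a `simulate_fn` for testing, see below).
#' @param p_start Ramp start (kPa). Default 100.
#' @param coarse_step Ramp increment (kPa). Default 20.
#' @param tol Bracket width (kPa). Default 1.
#' @param p_max Give up above this pressure (kPa). Default 2000.
#' @param factor Buckling detection factor, see [is_buckled()].
#' @param simulate_fn Function `peak_kpa -> dv_max_percent`; defaults to
#'   running [simulate_burst()] on `model` with `...` passed through. A
#'   synthetic predicate can be supplied for testing the search logic.
#' @param ... Passed to [simulate_burst()] (e.g. `duration`, `safety`).
#' @return A `gv_threshold` list: `threshold_kpa`, `bracket` (lo, hi),
#'   `n_simulations`, and `probes`, a tibble of (peak_kPa, dv_max_percent,
#'   buckled) for audit.
#' @export
find_threshold <- function(model, p_start = 100, coarse_step = 20, tol = 1,
                           p_max = 2000, factor = 3, simulate_fn = NULL, ...) {
  if (is.null(simulate_fn)) {
    stopifnot(inherits(model, "gv_model"))
    args <- list(...)
    simulate_fn <- function(peak, abort_hint = Inf) {
      dv_max(do.call(simulate_burst,
                     c(list(model = model, peak_kpa = peak,
                            abort_dv_percent = abort_hint), args)))
    }
  } else {
    fn <- simulate_fn
    simulate_fn <- function(peak, abort_hint = Inf) fn(peak)
  }
  probes <- tibble::tibble(peak_kPa = numeric(), dv_max_percent = numeric(),
                           buckled = logical())
  record <- function(p, dv, bk) {
    probes <<- dplyr::bind_rows(probes, tibble::tibble(
      peak_kPa = p, dv_max_percent = dv, buckled = bk))
  }

  # coarse ramp; the first three probes calibrate the linear slope
  slope <- NA_real_
  cal <- numeric(0)
  p <- p_start
  lo <- NA_real_
  hi <- NA_real_
  nsim <- 0L
  while (p <= p_max) {
    abort_hint <- if (is.finite(slope)) 2 * factor * slope * p else Inf
    dv <- simulate_fn(p, abort_hint)
    nsim <- nsim + 1L
    if (length(cal) < 3) {
      cal <- c(cal, dv / p)
      if (length(cal) == 3) {
        slope <- stats::median(cal)
        # re-classify the calibration probes
        bk <- is_buckled(probes$dv_max_percent, probes$peak_kPa, slope, factor)
        if (any(bk)) stop("buckling below the calibration range; lower p_start")
        probes$buckled <- bk
      }
      record(p, dv, FALSE)
      p <- p + coarse_step
      next
    }
    bk <- is_buckled(dv, p, slope, factor)
    record(p, dv, bk)
    if (bk) {
      lo <- p - coarse_step
      hi <- p
      break
    }
    p <- p + coarse_step
  }
  if (!is.finite(hi)) {
    stop("no threshold found below ", p_max,
         " kPa (no buckling in the probed range)")
  }
  # bisection to the requested bracket width
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    abort_hint <- 2 * factor * slope * mid
    dv <- simulate_fn(mid, abort_hint)
    nsim <- nsim + 1L
    bk <- is_buckled(dv, mid, slope, factor)
    record(mid, dv, bk)
    if (bk) hi <- mid else lo <- mid
  }
  # post-hoc monotonicity audit of the probe record
  ord <- order(probes$peak_kPa)
  bk <- probes$buckled[ord]
  if (is.unsorted(bk)) {
    stop("non-monotone buckling record: the departure criterion is not ",
         "monotone over the probed range")
  }
  structure(list(
    threshold_kpa = hi, bracket = c(lo = lo, hi = hi),
    n_simulations = nsim, linear_slope = slope, factor = factor,
    probes = probes
  ), class = "gv_threshold")
}

#' @export
print.gv_threshold <- function(x, ...) {
  cat("<gv_threshold>", x$threshold_kpa, "kPa (bracket [",
      x$bracket["lo"], ",", x$bracket["hi"], "],", x$n_simulations,
      "simulations)\n")
  invisible(x)
}
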