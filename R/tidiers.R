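# broom-style tidiers and ggplot2 autoplot methods for the result objects

#' @rdname gv_tidiers
#' @param x A result object.
#' @param ... Unused.
#' @export
tidy.gv_buckling <- function(x, ...) {
  tibble::tibble(mode = x$mode, pressure_kPa = x$pressure_kPa)
}

#' @rdname gv_tidiers
#' @export
glance.gv_buckling <- function(x, ...) {
  tibble::tibble(n_modes = nrow(x), threshold_kPa = x$pressure_kPa[1])
}

#' @rdname gv_tidiers
#' @export
tidy.gv_modal <- function(x, ...) {
  tibble::tibble(mode = x$mode, frequency_MHz = x$frequency_MHz)
}

#' @rdname gv_tidiers
#' @export
glance.gv_modal <- function(x, ...) {
  tibble::tibble(n_modes = nrow(x), f1_MHz = x$frequency_MHz[1])
}

#' Tidiers for gvbuckle result objects
#'
#' [generics::tidy()] returns the per-component table of a result (modes,
#' probes, fit terms); [generics::glance()] returns a one-row summary.
#'
#' @name gv_tidiers
#' @export
tidy.gv_scaling_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @rdname gv_tidiers
#' @export
glance.gv_scaling_fit <- function(x, ...) {
  tibble::tibble(A = x$A, alpha = x$alpha, B = x$B, residual_norm = x$residual,
                 n = nrow(x$data))
}

#' @rdname gv_tidiers
#' @export
tidy.gv_threshold <- function(x, ...) {
  x$probes
}

#' @rdname gv_tidiers
#' @export
glance.gv_threshold <- function(x, ...) {
  tibble::tibble(threshold_kPa = x$threshold_kpa,
                 bracket_lo = x$bracket["lo"], bracket_hi = x$bracket["hi"],
                 n_simulations = x$n_simulations,
                 linear_slope = x$linear_slope)
}

#' Plot methods for gvbuckle results
#'
#' `autoplot()` draws the standard figure for each result type: volume
#' change versus time for trajectories, threshold versus geometry (log-log)
#' for sweeps, and signal versus peak pressure for signal curves.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gv_autoplot
#' @export
autoplot.gv_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_us, y = .data$dv_percent)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "time (µs)", y = "volume change (%)",
                  title = sprintf("burst response, peak %g kPa",
                                  attr(object, "peak_kpa"))) +
    ggplot2::theme_minimal()
}

#' @rdname gv_autoplot
#' @export
autoplot.gv_sweep <- function(object, ...) {
  xl <- if (object$varied[1] == "diameter") "diameter (nm)" else "length (nm)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value_nm,
                                       y = .data$threshold_kPa)) +
    ggplot2::geom_point(color = "#d95f02") +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = xl, y = "threshold pressure (kPa)") +
    ggplot2::theme_minimal()
}

#' @rdname gv_autoplot
#' @export
autoplot.gv_signal <- function(object, ...) {
  onset <- attr(object, "onset_kPa")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$peak_kPa,
                                            y = .data$signal)) +
    ggplot2::geom_line(color = "#1b9e77") +
    ggplot2::labs(x = "peak acoustic pressure (kPa)",
                  y = "nonlinear signal (normalized)") +
    ggplot2::theme_minimal()
  if (is.finite(onset)) {
    p <- p + ggplot2::geom_vline(xintercept = onset, linetype = 2,
                                 color = "grey40")
  }
  p
}
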