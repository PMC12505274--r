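#' Plot a thermogram
#'
#' Heat flow (exo up) against temperature.
#'
#' @param object A `thermogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thermogram <- function(object, ...) {
  ggplot(object, aes(.data$temp_C, .data$heat_flow)) +
    geom_line() +
    labs(x = "Temperature (°C)", y = "Heat flow (mW/mg, exo up)") +
    theme_minimal()
}

#' Plot a modified Avrami fit
#'
#' Amorphous-fraction data with the fitted decay and the t10 marker.
#'
#' @param object An `avrami_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avrami_fit <- function(object, ...) {
  d <- mutate(object$data, fitted = object$fitted)
  ggplot(d, aes(.data$time_min, .data$f)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    geom_vline(xintercept = object$t10, linetype = "dashed") +
    labs(x = "Time (min)", y = "Amorphous fraction (%)",
         title = sprintf("t10 = %.2f min, n = %.2f", object$t10, object$n)) +
    theme_minimal()
}

#' Plot a powder-profile fit
#'
#' Observed pattern, fitted profile and residual offset below.
#'
#' @param object A `pxrd_profile_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pxrd_profile_fit <- function(object, ...) {
  d <- tibble(two_theta = object$pattern$two_theta,
              observed = object$pattern$intensity,
              fitted = object$fitted)
  offset <- -0.15 * diff(range(d$observed))
  ggplot(d, aes(.data$two_theta)) +
    geom_point(aes(y = .data$observed), size = 0.2, alpha = 0.4) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    geom_line(aes(y = .data$observed - .data$fitted + offset),
              colour = "grey40") +
    labs(x = "2θ (°)", y = "Intensity (counts)") +
    theme_minimal()
}

#' Plot an activation-energy profile
#'
#' Apparent activation energy against conversion with standard-error bars,
#' the diagnostic for multistep kinetics (a flat profile supports a
#' single-step interpretation).
#'
#' @param kas_tbl A [kas_regression()] table, optionally with a
#'   `condition` column.
#' @return A ggplot.
#' @export
plot_ea_profile <- function(kas_tbl) {
  p <- ggplot(kas_tbl, aes(.data$alpha, .data$Ea / 1000)) +
    ggplot2::geom_errorbar(aes(ymin = (.data$Ea - .data$se_Ea) / 1000,
                               ymax = (.data$Ea + .data$se_Ea) / 1000),
                           width = 0.002) +
    geom_point() +
    labs(x = expression(alpha), y = expression(E[a] ~ "(kJ/mol)")) +
    theme_minimal()
  if ("condition" %in% names(kas_tbl))
    p <- p + aes(colour = .data$condition)
  p
}
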