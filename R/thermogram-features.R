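#' Apparent heat capacity from a heat-flow trace
#'
#' Converts an exotherm-up heat-flow signal (mW/mg) on a ramp segment to
#' apparent specific heat capacity, \eqn{c_p = -60 \cdot HF / \beta}
#' (J/(g K)), using the per-row heating rate.
#'
#' @param tg A `thermogram`.
#' @return The thermogram with an added `cp_app` column.
#' @export
apparent_cp <- function(tg) {
  if (any(tg$rate_C_min == 0))
    abort("apparent cp is undefined on isothermal segments")
  mutate(tg, cp_app = -60 * .data$heat_flow / .data$rate_C_min)
}

#' Detect the glass transition
#'
#' Fits a logistic step on a linear baseline to the apparent heat capacity
#' inside a search window:
#' \eqn{c_p(T) = a + bT + \Delta c_p / (1 + e^{-(T - T_g)/w})}.
#' `Tg` is the half-height midpoint of the step between the extrapolated
#' baselines and `dCp` the step height. If the fitted step height is below
#' three times the residual noise, the transition is reported as not found
#' (a result, not an error).
#'
#' @param tg A `thermogram` (exo-up heat flow on a ramp).
#' @param search_window Temperature window `c(lo, hi)` containing a single
#'   sigmoidal step, degC.
#'
#' @return A one-row tibble with `Tg` (degC), `dCp` (J/(g K)), `width`
#'   (degC) and `found`. When no step is detected, `Tg` and `dCp` are `NA`
#'   and `found` is `FALSE`.
#' @export
detect_glass_transition <- function(tg, search_window) {
  win <- filter(apparent_cp(tg), .data$temp_C >= search_window[1],
                .data$temp_C <= search_window[2])
  if (nrow(win) < 20) abort("search window contains too few samples")
  x <- win$temp_C
  y <- win$cp_app
  lo_part <- y[x <= stats::quantile(x, 0.25)]
  hi_part <- y[x >= stats::quantile(x, 0.75)]
  d0 <- mean(hi_part) - mean(lo_part)
  par0 <- c(a = mean(lo_part), b = 0, d = d0, Tg = mean(range(x)), w = 0.5)
  model <- function(p) p[1] + p[2] * (x - mean(x)) + p[3] / (1 + exp(-(x - p[4]) / p[5]))
  fit <- minpack.lm::nls.lm(
    par = par0, fn = function(p) y - model(p),
    lower = c(-Inf, -Inf, -Inf, min(x), 1e-3),
    upper = c(Inf, Inf, Inf, max(x), diff(range(x))),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  resid_sd <- sd(fit$fvec)
  found <- is.finite(p[3]) && abs(p[3]) > 3 * resid_sd && abs(p[3]) > 1e-12
  if (!found)
    return(tibble(Tg = NA_real_, dCp = NA_real_, width = NA_real_,
                  found = FALSE))
  tibble(Tg = unname(p[4]), dCp = unname(p[3]), width = unname(p[5]),
         found = TRUE)
}

thermo_window <- function(tg, limits) {
  win <- filter(tg, .data$temp_C >= limits[1], .data$temp_C <= limits[2],
                .data$rate_C_min != 0)
  if (nrow(win) < 5)
    abort("integration limits select too few samples inside the trace")
  if (limits[1] < min(tg$temp_C) || limits[2] > max(tg$temp_C))
    abort("integration limits lie outside the recorded trace")
  win
}

# Linear baseline through short edge windows at the two limits.
edge_baseline <- function(time_min, signal, edge_frac = 0.02) {
  n <- length(signal)
  k <- max(3L, ceiling(edge_frac * n))
  t1 <- mean(time_min[seq_len(k)])
  t2 <- mean(time_min[seq(n - k + 1, n)])
  y1 <- mean(signal[seq_len(k)])
  y2 <- mean(signal[seq(n - k + 1, n)])
  y1 + (time_min - t1) * (y2 - y1) / (t2 - t1)
}

#' Integrate a thermal event
#'
#' Integrates the baseline-corrected heat flow between two temperature
#' limits and reports the event enthalpy in J/g, positive for both
#' exothermic and endothermic events; the event sign is attached as the
#' attribute `event` (`"exothermic"` or `"endothermic"`, exo-up
#' convention). The baseline is linear between short edge windows at the
#' limits.
#'
#' @param tg A `thermogram`.
#' @param limits Temperature limits `c(T_lo, T_hi)`, degC, inside the trace.
#' @param per_mass Is the signal already mass-normalized (mW/mg)? If
#'   `FALSE` the integral (signal in mW) is divided by the `mass_mg`
#'   attribute.
#' @param edge_frac Fraction of the window used for each baseline anchor.
#'
#' @return Enthalpy in J/g (a positive number with attribute `event`).
#' @export
integrate_peak <- function(tg, limits, per_mass = TRUE, edge_frac = 0.02) {
  win <- thermo_window(tg, limits)
  base <- edge_baseline(win$time_min, win$heat_flow, edge_frac)
  raw <- 60 * trapz_(win$time_min, win$heat_flow - base)
  if (!per_mass) {
    mass <- attr(tg, "mass_mg")
    if (is.null(mass)) abort("per_mass = FALSE requires a mass_mg attribute")
    raw <- raw / mass
  }
  structure(abs(raw),
            event = if (raw >= 0) "exothermic" else "endothermic")
}

#' Extrapolated onset temperature of an exotherm
#'
#' The standard DSC extrapolated onset: the intersection of the pre-peak
#' linear baseline with the tangent at the inflection point of the peak's
#' leading edge. The leading-edge derivative is taken from a smoothing
#' spline so the construction is stable under noise.
#'
#' @param tg A `thermogram`.
#' @param peak_region Temperature window `c(T_lo, T_hi)` containing a
#'   single exotherm (exo up), degC.
#' @param baseline_frac Leading fraction of the window used to fit the
#'   pre-peak baseline.
#'
#' @return Onset temperature in degC, or `NA` if no rising inflection is
#'   found (e.g. a baseline-only window).
#' @export
onset_temperature <- function(tg, peak_region, baseline_frac = 0.15) {
  win <- thermo_window(tg, peak_region)
  x <- win$temp_C
  y <- win$heat_flow
  nb <- max(5L, ceiling(baseline_frac * length(x)))
  bl <- lm(y[seq_len(nb)] ~ x[seq_len(nb)])
  a <- coef(bl)[1]
  b <- coef(bl)[2]
  corr <- y - (a + b * x)
  noise <- sd(residuals(bl))
  ipk <- which.max(corr)
  if (corr[ipk] < max(6 * noise, 1e-12)) return(NA_real_)
  lead <- seq_len(ipk)
  if (length(lead) < 10) return(NA_real_)
  sp <- stats::smooth.spline(x[lead], y[lead])
  d1 <- predict(sp, x[lead], deriv = 1)$y
  ii <- which.max(d1)
  slope <- d1[ii]
  if (!is.finite(slope) || slope <= max(b, 0)) return(NA_real_)
  x0 <- x[lead][ii]
  y0 <- predict(sp, x0)$y
  # tangent y0 + slope (T - x0) meets baseline a + b T
  unname((a - y0 + slope * x0) / (slope - b))
}

#' Conversion curve from an exotherm
#'
#' Partial-area construction: the conversion at temperature T is the
#' cumulative baseline-corrected exotherm area up to T divided by the total
#' area between the limits, so the endpoints are exactly 0 and 1.
#'
#' @inheritParams integrate_peak
#' @return A tibble of class `conversion_curve` with `temp_C` and `alpha`,
#'   plus attribute `heating_rate` (degC/min).
#' @export
conversion_curve <- function(tg, limits, edge_frac = 0.02) {
  win <- thermo_window(tg, limits)
  base <- edge_baseline(win$time_min, win$heat_flow, edge_frac)
  cum <- cumtrapz_(win$time_min, win$heat_flow - base)
  total <- cum[length(cum)]
  if (total <= 0) abort("total exotherm area is not positive inside the limits")
  out <- tibble(temp_C = win$temp_C, alpha = cum / total)
  class(out) <- c("conversion_curve", class(out))
  attr(out, "heating_rate") <- median(win$rate_C_min)
  out
}

#' Deconvolve overlapping melting endotherms
#'
#' Fits a sum of two split pseudo-Voigt peaks plus a linear baseline to the
#' endotherm region (endo taken positive internally) and reports per-peak
#' melting enthalpies, ordered by center temperature: the lower-melting
#' peak is form II, the higher form I. The polymorph-proportion proxy is
#' `ratio_II_I = dHf_II / dHf_I`.
#'
#' @param tg A `thermogram`.
#' @param limits Temperature window containing at most two endotherms, degC.
#' @param fix_mix Fixed Lorentzian fraction for the fitted profiles
#'   (default 0, split-Gaussian); `NULL` lets the mixing float.
#'
#' @return An object of class `melting_deconvolution`: list with `peaks`
#'   (centers, widths, areas in J/g), `dHf_II`, `dHf_I`, `ratio_II_I`
#'   (Inf when the form I area is zero), `converged`, `rss`.
#' @export
deconvolve_melting <- function(tg, limits, fix_mix = 0) {
  win <- thermo_window(tg, limits)
  beta <- median(win$rate_C_min)
  x <- win$temp_C
  y <- -win$heat_flow  # endo positive
  span <- diff(range(x))
  # crude doublet initialization: global max, then max of the far side
  i1 <- which.max(y)
  mask <- abs(x - x[i1]) > span / 8
  i2 <- if (any(mask)) which(mask)[which.max(y[mask])] else NA_integer_
  amp0 <- max(y) - min(y)
  init <- tibble(
    center = sort(c(x[i1], if (is.na(i2)) x[i1] + span / 4 else x[i2])),
    amplitude = c(amp0, amp0 / 2)[order(c(x[i1], if (is.na(i2)) x[i1] + span / 4 else x[i2]))],
    fwhm_left = span / 10, fwhm_right = span / 10
  )
  res <- fit_splitpv_sum(x, y, init, background_degree = 1, fix_mix = fix_mix)
  if (!res$converged)
    abort(sprintf("melting deconvolution did not converge (residual norm %.3g)",
                  res$residual_norm))
  pk <- arrange(res$peaks, .data$center)
  pk$dHf <- pk$area * 60 / beta  # (mW/mg)*degC -> J/g at beta degC/min
  dHf_II <- pk$dHf[1]
  dHf_I <- pk$dHf[2]
  structure(list(
    peaks = pk,
    dHf_II = dHf_II, dHf_I = dHf_I,
    ratio_II_I = if (dHf_I <= 1e-6 * max(dHf_II, 1)) Inf else dHf_II / dHf_I,
    converged = res$converged, rss = res$rss,
    fitted = tibble(temp_C = x, endo = y, fit = res$fitted)
  ), class = "melting_deconvolution")
}

#' @export
tidy.melting_deconvolution <- function(x, ...) {
  mutate(x$peaks, form = c("II", "I")[seq_len(nrow(x$peaks))])
}

#' @export
glance.melting_deconvolution <- function(x, ...) {
  tibble(dHf_II = x$dHf_II, dHf_I = x$dHf_I, ratio_II_I = x$ratio_II_I,
         rss = x$rss, converged = x$converged)
}

#' @export
print.melting_deconvolution <- function(x, ...) {
  cat(sprintf(
    "Melting doublet: dHf_II = %.2f J/g, dHf_I = %.2f J/g, II/I = %s\n",
    x$dHf_II, x$dHf_I,
    if (is.infinite(x$ratio_II_I)) "Inf" else sprintf("%.2f", x$ratio_II_I)))
  invisible(x)
}

#' Extract the full feature set of a thermogram
#'
#' Convenience wrapper combining [detect_glass_transition()],
#' [onset_temperature()], [integrate_peak()] and [deconvolve_melting()]
#' into the one-row summary used in condition comparisons.
#'
#' @param tg A `thermogram`.
#' @param tg_window,exo_limits,melt_limits Temperature windows for the
#'   glass transition, the cold-crystallization exotherm and the melting
#'   doublet, degC.
#' @param crystallized_threshold Minimum exotherm enthalpy (J/g) for the
#'   sample to count as crystallized.
#'
#' @return A one-row tibble: `Tg`, `dCp`, `T_onset`, `dHc`, `dHf_II`,
#'   `dHf_I`, `dHf`, `ratio_II_I`, `crystallized`.
#' @export
thermogram_features <- function(tg, tg_window = c(45, 75),
                                exo_limits = c(85, 138),
                                melt_limits = c(139, 158),
                                crystallized_threshold = 5) {
  gt <- detect_glass_transition(tg, tg_window)
  onset <- onset_temperature(tg, exo_limits)
  dHc <- as.numeric(integrate_peak(tg, exo_limits))
  melt <- deconvolve_melting(tg, melt_limits)
  tibble(
    Tg = gt$Tg, dCp = gt$dCp, T_onset = onset, dHc = dHc,
    dHf_II = melt$dHf_II, dHf_I = melt$dHf_I,
    dHf = melt$dHf_II + melt$dHf_I,
    ratio_II_I = melt$ratio_II_I,
    crystallized = dHc > crystallized_threshold
  )
}
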