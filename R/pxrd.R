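#' Simulate a powder X-ray diffraction pattern
#'
#' Sum of split pseudo-Voigt peaks on a smooth polynomial background,
#' sampled on a uniform 2theta grid, optionally with additive counting
#' noise.
#'
#' @param peaks A data frame with one row per peak and columns `center`,
#'   `amplitude`, `fwhm_left`, `fwhm_right`, `mix_left`, `mix_right`
#'   (missing mix columns default to 0).
#' @param background Polynomial coefficients (ascending powers of the
#'   grid-centered, half-span-scaled abscissa).
#' @param two_theta_range Range of 2theta, degrees.
#' @param step Grid step, degrees.
#' @param noise_sd Additive Gaussian noise sd, counts.
#' @param seed Optional integer seed for the noise.
#'
#' @return A tibble of class `pxrd_pattern` with `two_theta`, `intensity`.
#' @export
simulate_pxrd <- function(peaks, background = 0,
                          two_theta_range = c(2.5, 40), step = 0.01,
                          noise_sd = 0, seed = NULL) {
  peaks <- normalize_peaks(peaks)
  if (any(peaks$center <= two_theta_range[1] | peaks$center >= two_theta_range[2]))
    abort("all peak centers must lie inside the 2theta range")
  x <- seq(two_theta_range[1], two_theta_range[2], by = step)
  y <- eval_background(background, x, two_theta_range)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    y <- y + split_pseudo_voigt(x, p$center, p$amplitude, p$fwhm_left,
                                p$fwhm_right, p$mix_left, p$mix_right)
  }
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(y), 0, noise_sd))
  out <- tibble(two_theta = x, intensity = y)
  class(out) <- c("pxrd_pattern", class(out))
  out
}

normalize_peaks <- function(peaks) {
  peaks <- as_tibble(peaks)
  for (col in c("mix_left", "mix_right"))
    if (!col %in% names(peaks)) peaks[[col]] <- 0
  need <- c("center", "amplitude", "fwhm_left", "fwhm_right")
  if (!all(need %in% names(peaks)))
    abort(paste("peak table needs columns:", paste(need, collapse = ", ")))
  if (any(peaks$fwhm_left <= 0 | peaks$fwhm_right <= 0))
    abort("peak widths must be positive")
  peaks
}

# Scaled polynomial background: sum_j c_j * ((x - mid)/halfspan)^j
eval_background <- function(coefs, x, xrange = range(x)) {
  z <- (x - mean(xrange)) / (diff(xrange) / 2)
  drop(outer(z, seq_along(coefs) - 1, `^`) %*% coefs)
}

# Pack/unpack peak parameter tables for the optimizer.
pack_peaks <- function(peaks) {
  as.numeric(t(as.matrix(peaks[, c("center", "amplitude", "fwhm_left",
                                   "fwhm_right", "mix_left", "mix_right")])))
}
unpack_peaks <- function(par, npk) {
  m <- matrix(par[seq_len(6 * npk)], ncol = 6, byrow = TRUE)
  tibble(center = m[, 1], amplitude = m[, 2], fwhm_left = m[, 3],
         fwhm_right = m[, 4], mix_left = m[, 5], mix_right = m[, 6])
}

# Shared bounded least-squares engine for sums of split pseudo-Voigt peaks
# plus a polynomial background (used by fit_profile and deconvolve_melting).
fit_splitpv_sum <- function(x, y, init_peaks, background_degree = 3,
                            fix_mix = NULL, max_iter = 200) {
  init_peaks <- normalize_peaks(init_peaks)
  npk <- nrow(init_peaks)
  xrange <- range(x)
  span <- diff(xrange)
  if (!is.null(fix_mix)) {
    init_peaks$mix_left <- fix_mix
    init_peaks$mix_right <- fix_mix
  }
  model <- function(par) {
    pk <- unpack_peaks(par, npk)
    if (!is.null(fix_mix)) {
      pk$mix_left <- fix_mix
      pk$mix_right <- fix_mix
    }
    bg <- par[(6 * npk + 1):length(par)]
    yhat <- eval_background(bg, x, xrange)
    for (i in seq_len(npk))
      yhat <- yhat + split_pseudo_voigt(x, pk$center[i], pk$amplitude[i],
                                        pk$fwhm_left[i], pk$fwhm_right[i],
                                        pk$mix_left[i], pk$mix_right[i])
    yhat
  }
  bg0 <- c(min(y), rep(0, background_degree))
  par0 <- c(pack_peaks(init_peaks), bg0)
  lower <- c(rep(c(xrange[1], 0, span * 1e-4, span * 1e-4, 0, 0), npk),
             rep(-Inf, background_degree + 1))
  upper <- c(rep(c(xrange[2], Inf, span, span, 1, 1), npk),
             rep(Inf, background_degree + 1))
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(par) y - model(par),
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )
  pk <- unpack_peaks(fit$par, npk)
  if (!is.null(fix_mix)) {
    pk$mix_left <- fix_mix
    pk$mix_right <- fix_mix
  }
  pk$area <- purrr::pmap_dbl(
    pk, function(center, amplitude, fwhm_left, fwhm_right, mix_left,
                 mix_right, ...) {
      split_pv_area(amplitude, fwhm_left, fwhm_right, mix_left, mix_right)
    })
  resid_norm <- sqrt(mean(fit$fvec^2))
  list(
    peaks = pk,
    background = fit$par[(6 * npk + 1):length(fit$par)],
    converged = fit$info %in% 1:4 ||
      resid_norm < 1e-8 * (max(abs(y)) + 1e-300),
    info = fit$info,
    rss = sum(fit$fvec^2),
    residual_norm = sqrt(mean(fit$fvec^2)),
    fitted = model(fit$par)
  )
}

#' Fit split pseudo-Voigt peaks to a powder pattern
#'
#' Simultaneous bounded least-squares fit of a sum of split pseudo-Voigt
#' peaks and a polynomial background. Per-peak areas come from the analytic
#' half-Gaussian/half-Lorentzian side-area formula ([split_pv_area()]), not
#' from numerical integration of the fit.
#'
#' @param pattern A `pxrd_pattern` (or any data frame with `two_theta` and
#'   `intensity`).
#' @param initial_peaks Data frame of starting peak parameters (columns as
#'   in [simulate_pxrd()]; mix columns optional).
#' @param background_degree Degree of the polynomial background.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#'
#' @return An object of class `pxrd_profile_fit`: list with `peaks`
#'   (tibble of fitted parameters plus `area`), `background` (coefficients),
#'   `converged`, `rss`, `residual_norm` and `fitted`. Use [tidy()] for the
#'   peak table and [glance()] for fit diagnostics.
#' @export
fit_profile <- function(pattern, initial_peaks, background_degree = 3,
                        max_iter = 200) {
  stopifnot(all(c("two_theta", "intensity") %in% names(pattern)))
  init <- normalize_peaks(initial_peaks)
  if (any(init$center < min(pattern$two_theta) |
          init$center > max(pattern$two_theta)))
    abort("initial peak centers must lie inside the pattern range")
  res <- fit_splitpv_sum(pattern$two_theta, pattern$intensity, init,
                         background_degree, max_iter = max_iter)
  res$pattern <- pattern
  if (!res$converged)
    warn(sprintf("profile fit did not converge (info = %d, residual norm %.3g)",
                 res$info, res$residual_norm))
  structure(res, class = "pxrd_profile_fit")
}

#' @export
tidy.pxrd_profile_fit <- function(x, ...) arrange(x$peaks, .data$center)

#' @export
glance.pxrd_profile_fit <- function(x, ...) {
  tibble(rss = x$rss, residual_norm = x$residual_norm,
         converged = x$converged, n_peaks = nrow(x$peaks),
         nobs = nrow(x$pattern))
}

#' @export
print.pxrd_profile_fit <- function(x, ...) {
  cat(sprintf("Split pseudo-Voigt profile fit: %d peak(s), rss = %.4g, %s\n",
              nrow(x$peaks), x$rss,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' Normalize peak areas to a reference reflection
#'
#' Divides every fitted peak area by the area of the reference reflection
#' and scales by 1000, so the reference row is exactly 1000. Used to compare
#' polymorph proportions between samples on a common scale.
#'
#' @param peaks A `pxrd_profile_fit` or a data frame with columns `center`
#'   and `area` (optionally `form`).
#' @param reference_center 2theta of the reference peak, degrees.
#' @param tol Matching window around `reference_center`, degrees.
#' @param forms Optional character vector of form labels, one per peak (in
#'   ascending-center order).
#'
#' @return A tibble with `center`, `area`, `normalized_area` and `form`.
#' @export
normalized_area <- function(peaks, reference_center = 16.1, tol = 0.2,
                            forms = NULL) {
  if (inherits(peaks, "pxrd_profile_fit")) peaks <- tidy(peaks)
  peaks <- arrange(as_tibble(peaks), .data$center)
  if (!"form" %in% names(peaks)) peaks$form <- NA_character_
  if (!is.null(forms)) peaks$form <- forms
  hit <- which(abs(peaks$center - reference_center) <= tol)
  if (length(hit) == 0)
    abort(sprintf("no fitted peak within %.2f deg of the reference center %.2f",
                  tol, reference_center))
  if (length(hit) > 1) hit <- hit[which.min(abs(peaks$center[hit] - reference_center))]
  ref_area <- peaks$area[hit]
  if (ref_area <= 0) abort("reference peak has non-positive area")
  tibble(center = peaks$center, area = peaks$area,
         normalized_area = peaks$area / ref_area * 1000,
         form = peaks$form)
}
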