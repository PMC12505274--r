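#' Residual amorphous fraction from reversing heat capacity
#'
#' Converts a quasi-isothermal reversing heat-capacity trace to the
#' residual amorphous fraction in percent,
#' \deqn{f(t) = \frac{C_p(t) - C_p^{cryst}}{C_p^{amorph} - C_p^{cryst}}
#'   \times 100,}
#' with the amorphous and crystalline plateau heat capacities taken as the
#' means of the first and last `edge_count` samples. Values may leave
#' \[0, 100\] under noise and are deliberately not clipped (clipping would
#' bias the subsequent fit).
#'
#' @param trace A `modulated_trace` (columns `time_min`, `cp`).
#' @param edge_count Number of samples defining each plateau.
#'
#' @return A tibble with `time_min` and `f` (percent), plus attributes
#'   `cp_amorphous`, `cp_crystal` and `edge_count`.
#' @export
amorphous_fraction <- function(trace, edge_count = 100) {
  n <- nrow(trace)
  if (n < 2 * edge_count + 10)
    abort("trace too short for the requested plateau windows")
  head_i <- seq_len(edge_count)
  tail_i <- seq(n - edge_count + 1, n)
  cp_am <- mean(trace$cp[head_i])
  cp_cr <- mean(trace$cp[tail_i])
  spread <- sqrt((var(trace$cp[head_i]) + var(trace$cp[tail_i])) / edge_count)
  if (cp_am - cp_cr <= 3 * spread)
    abort("plateau means are equal within noise; trace is degenerate")
  out <- tibble(time_min = trace$time_min,
                f = (trace$cp - cp_cr) / (cp_am - cp_cr) * 100)
  attr(out, "cp_amorphous") <- cp_am
  attr(out, "cp_crystal") <- cp_cr
  attr(out, "edge_count") <- edge_count
  out
}

avrami_model <- function(t, t10, n) 100 * 0.9^((t / t10)^n)

#' Fit the modified Avrami model
#'
#' Least-squares fit of \eqn{f(t) = 100 \cdot 0.9^{(t/t_{10})^n}} to an
#' amorphous-fraction time series: `t10` is the time at 10 percent
#' crystallinity (the fitted curve passes through 90 percent at `t10` by
#' construction) and `n` the Avrami exponent. The optimizer is bounded
#' Levenberg-Marquardt with a multistart over n in 1..6 and `t10`
#' initialized at the observed 90 percent crossing. By default the plateau
#' windows used to define the endpoints (see [amorphous_fraction()]) are
#' excluded from the fit.
#'
#' @param f A tibble from [amorphous_fraction()] (columns `time_min`, `f`).
#' @param fit_window Optional time range `c(lo, hi)` in min; the default
#'   excludes the first and last `edge_count` samples recorded on `f`.
#' @param n_starts Avrami-exponent starting values for the multistart.
#'
#' @return An object of class `avrami_fit`: `t10` (min), `n`, `rss`,
#'   `converged`, `degenerate`, standard errors, and the fitted data. Use
#'   [tidy()]/[glance()] for tabular summaries.
#' @export
fit_modified_avrami <- function(f, fit_window = NULL, n_starts = 1:6) {
  edge <- attr(f, "edge_count") %||% 0L
  dat <- f
  if (is.null(fit_window)) {
    if (edge > 0 && nrow(f) > 2 * edge + 10)
      dat <- f[seq(edge + 1, nrow(f) - edge), ]
  } else {
    dat <- filter(f, .data$time_min >= fit_window[1],
                  .data$time_min <= fit_window[2])
  }
  tt <- dat$time_min
  ff <- dat$f
  degenerate <- min(ff) > 80 || max(ff) < 30
  t10_init <- if (any(ff <= 90) && any(ff > 90)) {
    approx(ff, tt, xout = 90, ties = mean)$y
  } else {
    median(tt)
  }
  if (!is.finite(t10_init) || t10_init <= 0) t10_init <- median(tt)
  best <- NULL
  for (n0 in n_starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(t10 = t10_init, n = n0),
      lower = c(1e-6, 0.5), upper = c(Inf, 10),
      fn = function(p) ff - avrami_model(tt, p[1], p[2]),
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || sum(fit$fvec^2) < best$rss0) {
      best <- list(fit = fit, rss0 = sum(fit$fvec^2))
    }
  }
  if (is.null(best)) abort("modified Avrami fit failed from every start")
  fit <- best$fit
  p <- fit$par
  rss <- sum(fit$fvec^2)
  dof <- length(tt) - 2
  se <- rep(NA_real_, 2)
  if (!degenerate && dof > 0 && rss > 0) {
    covm <- try(solve(fit$hessian) * rss / dof, silent = TRUE)
    if (!inherits(covm, "try-error") && all(diag(covm) >= 0))
      se <- sqrt(diag(covm))
  }
  structure(list(
    t10 = unname(p[1]), n = unname(p[2]),
    se_t10 = unname(se[1]), se_n = unname(se[2]),
    rss = rss,
    converged = (fit$info %in% 1:4) && !degenerate,
    degenerate = degenerate,
    data = dat,
    fitted = avrami_model(tt, p[1], p[2])
  ), class = "avrami_fit")
}

#' @export
tidy.avrami_fit <- function(x, ...) {
  tibble(term = c("t10", "n"),
         estimate = c(x$t10, x$n),
         std.error = c(x$se_t10, x$se_n))
}

#' @export
glance.avrami_fit <- function(x, ...) {
  tibble(t10 = x$t10, n = x$n, rss = x$rss, converged = x$converged,
         degenerate = x$degenerate, nobs = nrow(x$data))
}

#' @export
print.avrami_fit <- function(x, ...) {
  cat(sprintf("Modified Avrami fit: t10 = %.3g min, n = %.3g (rss %.3g, %s)\n",
              x$t10, x$n, x$rss,
              if (x$converged) "converged"
              else if (x$degenerate) "degenerate" else "NOT converged"))
  invisible(x)
}
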