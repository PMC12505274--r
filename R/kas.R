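#' Isoconversional temperature table
#'
#' For each requested conversion level, finds the temperature at which each
#' heating-rate curve reaches that conversion, by monotone piecewise-linear
#' inverse interpolation of alpha(T).
#'
#' @param curves A list of [conversion_curve()] objects (each carries its
#'   heating rate as an attribute).
#' @param alphas Conversion levels (dimensionless, strictly inside (0, 1)).
#'
#' @return A tibble of class `iso_temperature_table` with columns `alpha`,
#'   `rate_K_min` and `T_K`.
#' @export
extract_iso_temperatures <- function(curves, alphas) {
  if (any(alphas <= 0 | alphas >= 1)) abort("alphas must lie in (0, 1)")
  rows <- map(curves, function(cc) {
    rate <- attr(cc, "heating_rate")
    keep <- c(TRUE, diff(cc$alpha) > 0)
    aa <- cc$alpha[keep]
    TT <- cc$temp_C[keep]
    if (any(alphas < min(aa) | alphas > max(aa)))
      abort(sprintf("requested conversion outside the curve at %.3g K/min", rate))
    tibble(alpha = alphas,
           rate_K_min = rate,
           T_K = approx(aa, TT, xout = alphas, ties = "ordered")$y + 273.15)
  })
  out <- list_rbind(rows)
  class(out) <- c("iso_temperature_table", class(out))
  out
}

#' Kissinger-Akahira-Sunose regression
#'
#' At each conversion level, ordinary least squares of
#' \eqn{y = \ln(\beta / T_\alpha^2)} on \eqn{x = 1/T_\alpha} across heating
#' rates (beta in K/min, T in K). The apparent activation energy is
#' \eqn{E_a = -\mathrm{slope} \cdot R} with R = 8.314 J/(mol K); the
#' intercept estimates \eqn{\ln(A R /(E_a g(\alpha)))}.
#'
#' @param table An [extract_iso_temperatures()] table.
#' @param alphas Conversion levels to regress (default: all levels present).
#'
#' @return A tibble with one row per conversion: `alpha`, `Ea` (J/mol),
#'   `se_Ea`, `intercept`, `se_intercept`, `r2`, `n_rates`.
#' @export
kas_regression <- function(table, alphas = NULL) {
  alphas <- alphas %||% sort(unique(table$alpha))
  rows <- map(alphas, function(a) {
    d <- filter(table, abs(.data$alpha - a) < 1e-12)
    if (nrow(d) < 3) abort("KAS regression needs at least 3 heating rates")
    x <- 1 / d$T_K
    y <- log(d$rate_K_min / d$T_K^2)
    if (sd(x) < 1e-15) abort("degenerate isoconversional temperatures (collinear)")
    fit <- lm(y ~ x)
    sm <- summary(fit)
    tibble(alpha = a,
           Ea = -coef(fit)[["x"]] * R_GAS,
           se_Ea = sm$coefficients["x", "Std. Error"] * R_GAS,
           intercept = coef(fit)[["(Intercept)"]],
           se_intercept = sm$coefficients["(Intercept)", "Std. Error"],
           r2 = sm$r.squared,
           n_rates = nrow(d))
  })
  list_rbind(rows)
}

#' Apparent frequency factor from a KAS intercept
#'
#' Inverts the KAS intercept with the Avrami-Erofeev reaction model
#' \eqn{g(\alpha) = [-\ln(1-\alpha)]^{1/n}}:
#' \deqn{\ln A = \mathrm{intercept} + \ln(E_a \, g(\alpha) / R).}
#' With beta in K/min the result is in ln(1/min). The Avrami exponent is
#' conventionally taken from the isothermal fit of the matching annealing
#' condition.
#'
#' @param Ea Apparent activation energy, J/mol.
#' @param intercept KAS regression intercept (ln units).
#' @param alpha Conversion level in (0, 1).
#' @param n Avrami exponent.
#'
#' @return `lnA` in ln(1/min); vectorized over all arguments.
#'
#' @examples
#' frequency_factor(134.0e3, 54.2, 0.05, 4.7)  # ~63.3
#' @export
frequency_factor <- function(Ea, intercept, alpha, n) {
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must lie in (0, 1)")
  if (any(n <= 0)) abort("Avrami exponent must be positive")
  if (any(Ea <= 0)) abort("Ea must be positive")
  g <- (-log(1 - alpha))^(1 / n)
  intercept + log(Ea * g / R_GAS)
}

#' Add frequency factors to a KAS table
#'
#' @param kas_tbl Output of [kas_regression()].
#' @param n Avrami exponent used in the Avrami-Erofeev reaction model.
#' @return `kas_tbl` with columns `lnA` and `se_lnA` (the intercept
#'   standard error carries over unchanged because the added term has no
#'   regression uncertainty).
#' @export
add_frequency_factor <- function(kas_tbl, n) {
  mutate(kas_tbl,
         lnA = frequency_factor(.data$Ea, .data$intercept, .data$alpha, n),
         se_lnA = .data$se_intercept)
}

#' ANCOVA comparison of two regression groups
#'
#' Nested linear-model F-tests comparing straight-line fits between two
#' groups: the slope p-value tests the x-by-group interaction in the full
#' model, and the intercept p-value tests the group main effect in the
#' common-slope model. Used to compare KAS slopes (activation energies)
#' and intercepts between annealing conditions.
#'
#' @param data A data frame with the regression abscissa, ordinate and a
#'   two-level grouping variable.
#' @param x,y,group Column names (strings).
#'
#' @return A one-row tibble: `p_slope`, `p_intercept`, `df_slope`,
#'   `df_intercept`, `zero_residual`. With an (essentially) perfect fit the
#'   p-values are degenerate and reported as `NA` with
#'   `zero_residual = TRUE`.
#' @export
ancova_compare <- function(data, x = "x", y = "y", group = "group") {
  d <- tibble(x = data[[x]], y = data[[y]],
              group = factor(data[[group]]))
  if (nlevels(d$group) != 2) abort("ANCOVA comparison requires exactly 2 groups")
  if (any(table(d$group) < 3)) abort("each group needs at least 3 points")
  if (any(tapply(d$x, d$group, sd) < 1e-15)) abort("singular design: x constant within a group")
  full <- lm(y ~ x * group, data = d)
  add <- lm(y ~ x + group, data = d)
  common <- lm(y ~ x, data = d)
  tss <- sum((d$y - mean(d$y))^2)
  if (sum(residuals(full)^2) <= 1e-12 * max(tss, 1)) {
    return(tibble(p_slope = NA_real_, p_intercept = NA_real_,
                  df_slope = NA_integer_, df_intercept = NA_integer_,
                  zero_residual = TRUE))
  }
  a_slope <- anova(add, full)
  a_int <- anova(common, add)
  tibble(p_slope = a_slope$`Pr(>F)`[2],
         p_intercept = a_int$`Pr(>F)`[2],
         df_slope = full$df.residual,
         df_intercept = add$df.residual,
         zero_residual = FALSE)
}

#' KAS analysis of a set of thermograms
#'
#' End-to-end isoconversional analysis: builds conversion curves from each
#' thermogram's exotherm, extracts isoconversional temperatures, regresses
#' at every requested conversion and (optionally) attaches frequency
#' factors.
#'
#' @param thermograms List of `thermogram` objects at different heating
#'   rates.
#' @param exo_limits Temperature window of the exotherm, degC.
#' @param alphas Conversion grid (default 0.01-0.50 in steps of 0.01; the
#'   low-conversion range up to 0.10 is the one interpreted when kinetics
#'   are multistep).
#' @param n Optional Avrami exponent for [add_frequency_factor()].
#'
#' @return A [kas_regression()] tibble (with `lnA` when `n` is given).
#' @export
kas_analysis <- function(thermograms, exo_limits, alphas = seq(0.01, 0.50, 0.01),
                         n = NULL) {
  curves <- map(thermograms, conversion_curve, limits = exo_limits)
  tab <- extract_iso_temperatures(curves, alphas)
  out <- kas_regression(tab)
  if (!is.null(n)) out <- add_frequency_factor(out, n)
  out
}
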