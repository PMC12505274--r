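test_that("isoconversional temperatures match a bisection oracle", {
  kin <- std_kin()
  rates <- c(0.5, 1, 2)
  curves <- lapply(kas_thermograms(), conversion_curve, limits = EXO_LIMITS)
  tab <- extract_iso_temperatures(curves, c(0.05, 0.10))
  # oracle: solve  integral of k dT / beta = g(alpha) - u0  by bisection on
  # adaptive quadrature of the Arrhenius integral, independent of the
  # simulator's quadrature grid
  oracle_T <- function(beta, a) {
    u0 <- (-log(1 - 1e-8))^(1 / kin$n)
    target <- (-log(1 - a))^(1 / kin$n) - u0
    k <- function(Tc) exp(kin$lnA - kin$Ea / (8.314 * (Tc + 273.15)))
    f <- function(Tc) stats::integrate(k, 25, Tc, rel.tol = 1e-12)$value / beta - target
    stats::uniroot(f, c(60, 159), tol = 1e-8)$root + 273.15
  }
  for (a in c(0.05, 0.10)) for (i in seq_along(rates)) {
    got <- tab$T_K[tab$alpha == a & tab$rate_K_min == rates[i]]
    expect_lt(abs(got - oracle_T(rates[i], a)), 0.05)
  }
  # exact grid point inverts exactly
  cc <- curves[[2]]
  j <- which.min(abs(cc$alpha - 0.5))
  tab1 <- extract_iso_temperatures(list(cc), cc$alpha[j])
  expect_equal(tab1$T_K, cc$temp_C[j] + 273.15, tolerance = 1e-12)
  # conversion outside a curve's span errors naming the rate
  trimmed <- cc[cc$alpha <= 0.5, ]
  class(trimmed) <- class(cc)
  attr(trimmed, "heating_rate") <- attr(cc, "heating_rate")
  expect_error(extract_iso_temperatures(list(trimmed), 0.9), "1 K/min")
  expect_error(extract_iso_temperatures(list(cc), 1.2), "\\(0, 1\\)")
})

test_that("KAS regression is exact on a manufactured line", {
  # three points exactly on y = 10 - 16000 x  =>  Ea = 16000 * R = 133.0 kJ/mol
  Ts <- c(370, 380, 390)
  x <- 1 / Ts
  beta <- Ts^2 * exp(10 - 16000 * x)
  tab <- tibble::tibble(alpha = 0.05, rate_K_min = beta, T_K = Ts)
  class(tab) <- c("iso_temperature_table", class(tab))
  reg <- suppressWarnings(kas_regression(tab))  # summary.lm: perfect fit
  expect_equal(reg$Ea, 16000 * 8.314, tolerance = 1e-9)
  expect_equal(reg$Ea / 1000, 133.0, tolerance = 1e-3)
  expect_equal(reg$intercept, 10, tolerance = 1e-7)
  expect_lt(reg$se_Ea, 1e-4)
  expect_equal(reg$r2, 1)
  # degenerate: identical temperatures across rates
  bad <- tibble::tibble(alpha = 0.05, rate_K_min = c(0.5, 1, 2), T_K = 380)
  expect_error(kas_regression(bad), "collinear|degenerate")
  expect_error(kas_regression(tab[1:2, ]), "3 heating rates")
})

test_that("simulated thermograms round-trip Ea and lnA through KAS", {
  kas <- kas_analysis(kas_thermograms(), EXO_LIMITS,
                      alphas = seq(0.05, 0.10, 0.01), n = 4.7)
  expect_true(all(abs(kas$Ea - 134e3) / 134e3 < 0.02))
  expect_true(all(abs(kas$lnA - 39.6) / 39.6 < 0.05))
  # Ea(alpha) flat within its standard errors for single-step kinetics
  expect_true(all(abs(kas$Ea - mean(kas$Ea)) < 2 * kas$se_Ea))
})

test_that("frequency factor inverts the KAS intercept algebraically", {
  # lnA - intercept depends only on (Ea, alpha, n)
  d1 <- frequency_factor(120e3, 50, 0.05, 4.5) - 50
  d2 <- frequency_factor(120e3, 10, 0.05, 4.5) - 10
  expect_equal(d1, d2)
  # closed-form identity check at arbitrary values
  g <- (-log(1 - 0.07))^(1 / 3.8)
  expect_equal(frequency_factor(125e3, 48.1, 0.07, 3.8),
               48.1 + log(125e3 * g / 8.314))
  expect_error(frequency_factor(125e3, 48.1, 1.0, 3.8), "\\(0, 1\\)")
  expect_error(frequency_factor(-1, 48.1, 0.05, 3.8), "positive")
})

test_that("a two-process mixture shows Ea decreasing with conversion", {
  # superpose two exotherms with different activation energies; the
  # apparent isoconversional Ea then falls as the low-Ea process takes over
  # the faster sub-process carries the high Ea, so early conversion is
  # high-Ea-controlled and late conversion low-Ea-controlled
  th <- std_thermo()
  mix_tg <- function(rate) suppressWarnings({
    t1 <- simulate_nonisothermal_thermogram(
      avrami_kinetics(Ea = 150e3, lnA = 46, n = 4), ramp_program(rate), th,
      dt = 0.02)
    t2 <- simulate_nonisothermal_thermogram(
      avrami_kinetics(Ea = 100e3, lnA = 29.2, n = 4), ramp_program(rate), th,
      dt = 0.02)
    make_thermogram(t1$temp_C, 0.5 * t1$heat_flow + 0.5 * t2$heat_flow,
                    rate = rate)
  })
  tgs <- lapply(c(0.5, 1, 2), mix_tg)
  kas <- kas_analysis(tgs, EXO_LIMITS, alphas = c(0.2, 0.5, 0.8))
  expect_true(all(diff(kas$Ea) < 0))
})

test_that("ANCOVA distinguishes slope and intercept differences", {
  x <- rep(1:6, 2)
  g <- rep(c("a", "b"), each = 6)
  set.seed(11)
  # same slope, intercepts far apart
  y <- 2 * x + ifelse(g == "a", 0, 5) + rnorm(12, 0, 0.05)
  res <- ancova_compare(data.frame(x = x, y = y, group = g))
  expect_gt(res$p_slope, 0.05)
  expect_lt(res$p_intercept, 1e-4)
  # different slopes
  y2 <- ifelse(g == "a", 2, 3) * x + rnorm(12, 0, 0.05)
  res2 <- ancova_compare(data.frame(x = x, y = y2, group = g))
  expect_lt(res2$p_slope, 1e-4)
  # identical groups without noise: zero-residual degeneracy flagged
  y3 <- 2 * x + 1
  res3 <- ancova_compare(data.frame(x = x, y = y3, group = g))
  expect_true(res3$zero_residual)
  expect_true(is.na(res3$p_slope))
  expect_error(ancova_compare(data.frame(x = x, y = y, group = "a")),
               "2 groups")
})

test_that("ANCOVA p-values are calibrated under the null", {
  set.seed(2026)
  n_rep <- 1000
  x <- rep(1:5, 2)
  g <- rep(c("a", "b"), each = 5)
  rej <- matrix(FALSE, n_rep, 2)
  for (i in seq_len(n_rep)) {
    y <- 1 + 2 * x + rnorm(10, 0, 0.5)
    r <- ancova_compare(data.frame(x = x, y = y, group = g))
    rej[i, ] <- c(r$p_slope < 0.05, r$p_intercept < 0.05)
  }
  expect_gt(mean(rej[, 1]), 0.03); expect_lt(mean(rej[, 1]), 0.07)
  expect_gt(mean(rej[, 2]), 0.03); expect_lt(mean(rej[, 2]), 0.07)
})
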