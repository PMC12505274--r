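test_that("temperature programs are contiguous and evaluate piecewise", {
  prog <- temperature_program(25, tp_ramp(80, 10), tp_hold(1), tp_ramp(160, 2))
  expect_equal(prog$start_T[-1], prog$end_T[-nrow(prog)])
  expect_equal(program_duration(prog), 5.5 + 1 + 40)
  expect_equal(program_temperature(prog, c(0, 5.5, 6, 6.5, 46.5)),
               c(25, 80, 80, 80, 160))
  expect_error(program_temperature(prog, 100), "outside")
  expect_error(temperature_program(25, tp_ramp(80, 0)), "nonzero")
})

test_that("isothermal trace follows the modified Avrami decay exactly", {
  # direct arithmetic: Cp(40) = 1.5 + 0.5 * 0.9^((40/20)^3)
  tr <- simulate_isothermal_trace(t10 = 20, n = 3, cp_amorphous = 2.0,
                                  cp_crystal = 1.5, duration = 60, dt = 0.5)
  expect_equal(tr$cp[tr$time_min == 40], 1.5 + 0.5 * 0.9^8)
  expect_equal(tr$cp[1], 2.0)                      # 0.9^0 = 1 at t = 0
  expect_true(all(diff(tr$cp) <= 0))               # noise-free, non-increasing
  # amorphous fraction at t = t10 is 90% by construction of the model
  tr2 <- simulate_isothermal_trace(t10 = 22.6, n = 5.1, duration = 70, dt = 0.1)
  f226 <- (tr2$cp[abs(tr2$time_min - 22.6) < 1e-9] - 1.45) / (1.75 - 1.45) * 100
  expect_equal(f226, 90)
  expect_error(simulate_isothermal_trace(t10 = -1, n = 3), "positive")
  expect_error(simulate_isothermal_trace(t10 = 10, n = 3, duration = 5),
               "duration")
})

test_that("noise is seeded, reproducible, and absent when sd = 0", {
  a <- simulate_isothermal_trace(20, 4, duration = 60, noise_sd = 0.01, seed = 42)
  b <- simulate_isothermal_trace(20, 4, duration = 60, noise_sd = 0.01, seed = 42)
  c <- simulate_isothermal_trace(20, 4, duration = 60, noise_sd = 0.01, seed = 43)
  expect_identical(a$cp, b$cp)
  expect_gt(max(abs(a$cp - c$cp)), 0.001)
  # seeding does not disturb the caller's RNG stream
  set.seed(1); r1 <- rnorm(1)
  set.seed(1); invisible(simulate_isothermal_trace(20, 4, duration = 60,
                                                   noise_sd = 0.01, seed = 7))
  expect_identical(rnorm(1), r1)
})

test_that("conversion is monotone, bounded, and matches an ODE integrator", {
  skip_if_not_installed("deSolve")
  kin <- std_kin()
  prog <- ramp_program(1)
  conv <- conversion_profile(kin, prog, dt = 0.02)
  expect_true(all(diff(conv$alpha) >= 0))
  expect_true(all(conv$alpha >= 0 & conv$alpha <= 1))
  # independent route: adaptive lsoda on the rate law itself
  rate_fn <- function(t, y, parms) {
    # lsoda may internally step slightly past the final output time
    Tk <- program_temperature(prog, min(t, program_duration(prog))) + 273.15
    k <- exp(kin$lnA - kin$Ea / (8.314 * Tk))
    a <- min(max(y[1], 1e-12), 1 - 1e-12)
    list(k * kin$n * (1 - a) * (-log(1 - a))^((kin$n - 1) / kin$n))
  }
  times <- seq(0, program_duration(prog), by = 0.5)
  ode <- deSolve::lsoda(c(a = max(kin$alpha0, 1e-8)), times, rate_fn,
                        rtol = 1e-10, atol = 1e-12)
  closed <- approx(conv$time_min, conv$alpha, xout = times)$y
  expect_lt(max(abs(ode[, "a"] - closed)), 1e-3)
})

test_that("exotherm shifts up with heating rate and down with more nuclei", {
  peak_T <- function(tg) {
    win <- dplyr::filter(tg, temp_C > 85, temp_C < 138)
    win$temp_C[which.max(win$heat_flow)]
  }
  expect_gt(peak_T(std_thermogram(2)), peak_T(std_thermogram(1)))
  # 10x the preformed-nuclei seed lowers the exotherm onset
  kin_lo <- avrami_kinetics(alpha0 = 1e-5)
  kin_hi <- avrami_kinetics(alpha0 = 1e-4)
  tg_lo <- simulate_nonisothermal_thermogram(kin_lo, ramp_program(1), std_thermo())
  tg_hi <- simulate_nonisothermal_thermogram(kin_hi, ramp_program(1), std_thermo())
  expect_lt(onset_temperature(tg_hi, EXO_LIMITS),
            onset_temperature(tg_lo, EXO_LIMITS))
})

test_that("energy bookkeeping: event areas equal configured enthalpies", {
  th <- std_thermo()
  tg <- std_thermogram(1)
  dHc <- integrate_peak(tg, EXO_LIMITS)
  expect_equal(as.numeric(dHc), th$dHc, tolerance = 1e-3)
  expect_identical(attr(dHc, "event"), "exothermic")
  dHf <- integrate_peak(tg, MELT_LIMITS)
  expect_equal(as.numeric(dHf), th$dHf_I + th$dHf_II, tolerance = 1e-3)
  expect_identical(attr(dHf, "event"), "endothermic")
})

test_that("incomplete crystallization before melting raises the warning flag", {
  slow <- avrami_kinetics(Ea = 134e3, lnA = 37.5, n = 4.7)  # too sluggish
  expect_warning(
    tg <- simulate_nonisothermal_thermogram(slow, ramp_program(3), std_thermo()),
    "0.999")
  expect_true(attr(tg, "incomplete_crystallization"))
})

test_that("simulated powder peaks have exact closed-form areas and shapes", {
  # pure Gaussian: area = amplitude * FWHM * sqrt(pi / (4 ln 2))
  pk <- data.frame(center = 20, amplitude = 500, fwhm_left = 0.2,
                   fwhm_right = 0.2, mix_left = 0, mix_right = 0)
  pat <- simulate_pxrd(pk, background = 0, two_theta_range = c(15, 25),
                       step = 0.002)
  num <- sum(pat$intensity) * 0.002
  expect_equal(num, 500 * 0.2 * sqrt(pi / (4 * log(2))), tolerance = 5e-3)
  # Lorentzian wings dominate at +/- 5 FWHM
  g <- split_pseudo_voigt(21, 20, 500, 0.2, 0.2, 0, 0)
  l <- split_pseudo_voigt(21, 20, 500, 0.2, 0.2, 1, 1)
  expect_gt(l, g)
  # symmetric parameters give a symmetric peak with max at center
  x <- seq(18, 22, by = 0.01)
  y <- split_pseudo_voigt(x, 20, 500, 0.3, 0.3, 0.4, 0.4)
  expect_equal(y, rev(y))
  expect_equal(max(y), split_pseudo_voigt(20, 20, 500, 0.3, 0.3, 0.4, 0.4))
  expect_error(simulate_pxrd(transform(pk, center = 50)), "inside")
})

test_that("dissolution traces exercise the first-point correction", {
  d1 <- simulate_dissolution(first_point_bias = 1)
  expect_equal(d1$conc_ug_ml[1], 40)
  expect_equal(correct_concentration(d1)$conc_ug_ml, d1$conc_ug_ml)
  d2 <- simulate_dissolution(first_point_bias = 0.8)
  expect_equal(d2$conc_ug_ml[1], 32)
  expect_equal(correct_concentration(d2)$conc_ug_ml[1], 40)
  # bias is uniform so correction recovers the unbiased trace everywhere
  expect_equal(correct_concentration(d2)$conc_ug_ml, d1$conc_ug_ml)
  # unimodal with an interior maximum at peak_time
  expect_equal(d1$time_h[which.max(d1$conc_ug_ml)], 24, tolerance = 0.05)
  dm <- diff(d1$conc_ug_ml)
  expect_lt(sum(diff(sign(dm[dm != 0])) != 0), 2)
  # nominal above c_max: monotone decay branch
  d3 <- simulate_dissolution(c_max = 30, c_final = 15, nominal = 40)
  expect_true(all(diff(d3$conc_ug_ml) <= 0))
  expect_error(simulate_dissolution(c_max = 10, c_final = 20), "below")
})
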