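test_that("glass transition recovers the generated step and is equivariant", {
  tg <- std_thermogram(1)
  gt <- detect_glass_transition(tg, TG_WINDOW)
  expect_true(gt$found)
  expect_equal(gt$Tg, 58.4, tolerance = 0.1 / 58.4)
  expect_equal(gt$dCp * 471.68, 271.4, tolerance = 0.01)  # molar units
  # translation: shifting the trace +10 degC shifts Tg by exactly +10
  shifted <- make_thermogram(tg$temp_C + 10, tg$heat_flow)
  gt10 <- detect_glass_transition(shifted, TG_WINDOW + 10)
  expect_equal(gt10$Tg, gt$Tg + 10, tolerance = 1e-6)
  # flat trace: not-found result, not an error
  flat <- make_thermogram(seq(40, 80, by = 0.05), rep(-0.02, 801))
  expect_false(detect_glass_transition(flat, TG_WINDOW)$found)
})

test_that("peak integration is linear, signed, and mass-normalizing", {
  tg <- std_thermogram(1)
  expect_equal(as.numeric(integrate_peak(tg, EXO_LIMITS)), 95.3,
               tolerance = 5e-3)
  # zero signal integrates to zero
  zero <- make_thermogram(seq(90, 130, 0.05), rep(0, 801))
  expect_equal(as.numeric(integrate_peak(zero, c(95, 125))), 0)
  # doubling mass at fixed total heat halves the per-mass enthalpy
  raw <- make_thermogram(tg$temp_C, tg$heat_flow * 5, mass = 5)
  raw2 <- make_thermogram(tg$temp_C, tg$heat_flow * 5, mass = 10)
  expect_equal(as.numeric(integrate_peak(raw, EXO_LIMITS, per_mass = FALSE)),
               2 * as.numeric(integrate_peak(raw2, EXO_LIMITS, per_mass = FALSE)))
  expect_error(integrate_peak(tg, c(10, 120)), "outside")
})

test_that("extrapolated onset matches the printed value and translates", {
  tg <- std_thermogram(1)
  onset <- onset_temperature(tg, EXO_LIMITS)
  expect_equal(onset, 107.4, tolerance = 0.3 / 107.4)
  shifted <- make_thermogram(tg$temp_C + 5, tg$heat_flow)
  expect_equal(onset_temperature(shifted, EXO_LIMITS + 5), onset + 5,
               tolerance = 0.02 / 112)
  # onset rises with heating rate (kinetic shift)
  expect_gt(onset_temperature(std_thermogram(2), EXO_LIMITS), onset)
  # baseline-only region: not found
  flat <- make_thermogram(seq(85, 138, 0.05), rep(-0.02, 1061))
  expect_true(is.na(onset_temperature(flat, c(86, 137))))
})

test_that("conversion curves are exact partial-area constructions", {
  tg <- std_thermogram(1)
  cc <- conversion_curve(tg, EXO_LIMITS)
  expect_equal(cc$alpha[1], 0)
  expect_equal(cc$alpha[nrow(cc)], 1)
  expect_true(all(diff(cc$alpha) >= -1e-6))  # up to quadrature round-off
  # matches the generating kinetics (sup-norm over the event)
  truth <- conversion_profile(std_kin(), ramp_program(1), dt = 0.02)
  tr_a <- approx(truth$temp_C, truth$alpha, xout = cc$temp_C)$y
  expect_lt(max(abs(cc$alpha - tr_a)), 1e-3)
  # symmetric synthetic peak: alpha = 0.5 at the midpoint temperature
  x <- seq(100, 120, by = 0.01)
  sym <- make_thermogram(x, split_pseudo_voigt(x, 110, 1, 1.5, 1.5))
  ccs <- conversion_curve(sym, c(100, 120))
  expect_equal(approx(ccs$temp_C, ccs$alpha, xout = 110)$y, 0.5,
               tolerance = 1e-3)
  expect_error(conversion_curve(make_thermogram(x, -split_pseudo_voigt(x, 110, 1, 1.5, 1.5)),
                                c(100, 120)), "not positive")
})

test_that("melting deconvolution recovers the polymorph ratio", {
  tg <- std_thermogram(1)
  m <- deconvolve_melting(tg, MELT_LIMITS)
  expect_equal(m$ratio_II_I, 99.7 / 13.5, tolerance = 0.03)
  expect_lt(abs(m$peaks$center[1] - 145.9), 0.1)
  expect_lt(abs(m$peaks$center[2] - 149.9), 0.1)
  # area sum consistent with single-window integration
  expect_equal(m$dHf_II + m$dHf_I,
               as.numeric(integrate_peak(tg, MELT_LIMITS)), tolerance = 0.01)
  # swapped generation order yields identical output (ordered by center)
  th_sw <- std_thermo()
  swapped <- simulate_nonisothermal_thermogram(std_kin(), ramp_program(1),
                                               th_sw, dt = 0.02)
  m2 <- deconvolve_melting(swapped, MELT_LIMITS)
  expect_equal(m2$ratio_II_I, m$ratio_II_I, tolerance = 1e-6)
  # single peak: infinite-ratio flag
  x <- seq(139, 158, by = 0.01)
  single <- make_thermogram(x, -split_pseudo_voigt(x, 146, 2, 1.2, 1.8))
  ms <- deconvolve_melting(single, c(139, 158))
  expect_true(is.infinite(ms$ratio_II_I))
})

test_that("feature table bundles the full per-thermogram summary", {
  feat <- thermogram_features(std_thermogram(1))
  expect_s3_class(feat, "tbl_df")
  expect_true(feat$crystallized)
  expect_equal(feat$dHf, 113.2, tolerance = 1e-3)
  expect_equal(feat$ratio_II_I, feat$dHf_II / feat$dHf_I)
})
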