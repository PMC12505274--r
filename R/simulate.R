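#' Conversion along a temperature program
#'
#' Integrates the Avrami-Erofeev rate law
#' \eqn{d\alpha/dt = A e^{-E_a/RT} n (1-\alpha)[-\ln(1-\alpha)]^{(n-1)/n}}
#' along a temperature program. Substituting
#' \eqn{u = [-\ln(1-\alpha)]^{1/n}} reduces the rate law to \eqn{du/dt = k(T)},
#' so the conversion has the closed form
#' \eqn{\alpha(t) = 1 - \exp(-[u_0 + \int_0^t k(T(s))\,ds]^n)}; the integral
#' is evaluated by trapezoidal quadrature on the output grid. The seed
#' \eqn{u_0} comes from `max(alpha0, 1e-8)` because the rate vanishes at
#' exactly \eqn{\alpha = 0}.
#'
#' @param kin An [avrami_kinetics()] object.
#' @param program A [temperature_program()].
#' @param dt Output/quadrature time step, min.
#' @return A tibble with `time_min`, `temp_C`, `alpha`, `dalpha_dt` (1/min).
#' @export
conversion_profile <- function(kin, program, dt = 0.02) {
  if (dt <= 0) abort("dt must be positive")
  times <- seq(0, program_duration(program), by = dt)
  temp <- program_temperature(program, times)
  Tk <- temp + 273.15
  k <- exp(kin$lnA - kin$Ea / (R_GAS * Tk))
  u0 <- (-log(1 - max(kin$alpha0, 1e-8)))^(1 / kin$n)
  u <- u0 + cumtrapz_(times, k)
  alpha <- 1 - exp(-u^kin$n)
  alpha <- pmin(alpha, 1 - 1e-15)
  dalpha <- k * kin$n * (1 - alpha) * u^(kin$n - 1)
  tibble(time_min = times, temp_C = temp, alpha = alpha, dalpha_dt = dalpha)
}

#' Simulate a nonisothermal DSC thermogram
#'
#' Builds an exotherm-up heat-flow trace (mW/mg) along a temperature program
#' containing: the sensible-heat baseline \eqn{-c_p(T)\beta/60} with a
#' sigmoidal heat-capacity step of height `thermo$dCp` centered at
#' `thermo$Tg`; a cold-crystallization exotherm whose conversion follows
#' [conversion_profile()] and whose total area is `thermo$dHc` (J/g) when
#' crystallization completes; and two melting endotherms at `thermo$Tm_II`
#' and `thermo$Tm_I` with areas `dHf_II` and `dHf_I`, modeled as split
#' pseudo-Voigt peaks in temperature.
#'
#' If conversion has not reached 0.999 by just below `Tm_II`, the returned
#' thermogram carries the attribute `incomplete_crystallization = TRUE`
#' (melting areas then correspond to the crystallized fraction only).
#'
#' @param kin An [avrami_kinetics()] object.
#' @param program A [temperature_program()]; should span Tg through Tm_I.
#' @param thermo A [thermo_params()] object.
#' @param sample_mass Sample mass, mg (recorded; the signal is already
#'   mass-normalized).
#' @param dt Simulation time step, min.
#' @param tg_width Width of the Tg sigmoid, degC.
#' @param cp_glass Intercept and slope of the linear glassy baseline
#'   \eqn{c_p(T) = a + b (T - 25)}, J/(g K).
#' @param melt_shape List with `fwhm_left`, `fwhm_right` (degC) and `mix`
#'   for the endotherm profiles.
#' @param noise_sd Additive Gaussian noise standard deviation, mW/mg.
#' @param seed Optional integer seed for the noise.
#'
#' @return A tibble of class `thermogram` with columns `time_min`, `temp_C`,
#'   `heat_flow` (mW/mg, exo up), `rate_C_min`, and attributes `mass_mg`,
#'   `program`, `thermo`, `alpha_true` (noise-free conversion, for
#'   diagnostics) and `incomplete_crystallization`.
#'
#' @examples
#' tg <- simulate_nonisothermal_thermogram(
#'   avrami_kinetics(), temperature_program(25, tp_ramp(160, 1)),
#'   thermo_params())
#' @export
simulate_nonisothermal_thermogram <- function(kin, program, thermo,
                                              sample_mass = 5,
                                              dt = 0.02,
                                              tg_width = 1.5,
                                              cp_glass = c(1.20, 0.003),
                                              melt_shape = list(fwhm_left = 1.2,
                                                                fwhm_right = 1.8,
                                                                mix = 0),
                                              noise_sd = 0, seed = NULL) {
  lo <- min(program$start_T, program$end_T)
  hi <- max(program$start_T, program$end_T)
  if (lo > thermo$Tg || hi < thermo$Tm_I)
    abort("temperature program must cover Tg through Tm_I")
  conv <- conversion_profile(kin, program, dt = dt)
  times <- conv$time_min
  temp <- conv$temp_C
  idx <- findInterval(pmin(times, max(program$t_end) - 1e-12), program$t_start,
                      rightmost.closed = TRUE)
  beta <- program$rate[pmin(pmax(idx, 1L), nrow(program))]

  cp <- cp_glass[1] + cp_glass[2] * (temp - 25) +
    thermo$dCp / (1 + exp(-(temp - thermo$Tg) / (tg_width / 4)))
  hf <- -cp * beta / 60
  hf <- hf + thermo$dHc * conv$dalpha_dt / 60

  unit_area <- split_pv_area(1, melt_shape$fwhm_left, melt_shape$fwhm_right,
                             melt_shape$mix)
  for (melt in list(c(thermo$Tm_II, thermo$dHf_II),
                    c(thermo$Tm_I, thermo$dHf_I))) {
    hf <- hf - (melt[2] * beta / 60 / unit_area) *
      split_pseudo_voigt(temp, melt[1], 1,
                         melt_shape$fwhm_left, melt_shape$fwhm_right,
                         melt_shape$mix)
  }

  pre_melt <- temp <= thermo$Tm_II - 6 * melt_shape$fwhm_left
  incomplete <- !any(pre_melt) || max(conv$alpha[pre_melt]) < 0.999
  if (incomplete)
    warn("conversion did not reach 0.999 before the form II endotherm")

  if (noise_sd > 0)
    hf <- hf + with_seed(seed, rnorm(length(hf), 0, noise_sd))

  out <- tibble(time_min = times, temp_C = temp, heat_flow = hf,
                rate_C_min = beta)
  class(out) <- c("thermogram", class(out))
  attr(out, "mass_mg") <- sample_mass
  attr(out, "program") <- program
  attr(out, "thermo") <- thermo
  attr(out, "alpha_true") <- conv$alpha
  attr(out, "incomplete_crystallization") <- incomplete
  out
}

#' Simulate a quasi-isothermal reversing heat-capacity trace
#'
#' The reversing heat capacity decays from the amorphous plateau to the
#' crystalline plateau as the sample crystallizes isothermally, following
#' the modified Avrami form: the noise-free trace is
#' \deqn{C_p(t) = C_p^{cryst} + (C_p^{amorph} - C_p^{cryst}) \cdot
#'   0.9^{(t/t_{10})^n}}
#' so the amorphous fraction passes through 90 percent at `t10`.
#'
#' @param t10 Time at which 10 percent of the sample has crystallized, min.
#' @param n Avrami exponent.
#' @param cp_amorphous,cp_crystal Plateau heat capacities, J/(g K);
#'   `cp_amorphous > cp_crystal`.
#' @param duration Hold duration, min (must exceed `t10`).
#' @param dt Sampling interval, min.
#' @param hold_temp Hold temperature, degC (metadata).
#' @param noise_sd Additive Gaussian noise sd, J/(g K).
#' @param seed Optional integer seed for the noise.
#'
#' @return A tibble of class `modulated_trace` with `time_min`, `cp` and
#'   attribute `hold_temp_C`.
#' @export
simulate_isothermal_trace <- function(t10, n, cp_amorphous = 1.75,
                                      cp_crystal = 1.45,
                                      duration = 3 * t10, dt = 0.1,
                                      hold_temp = 100,
                                      noise_sd = 0, seed = NULL) {
  if (t10 <= 0 || dt <= 0) abort("t10 and dt must be positive")
  if (duration <= t10) abort("duration must exceed t10")
  if (cp_amorphous <= cp_crystal) abort("cp_amorphous must exceed cp_crystal")
  times <- seq(0, duration, by = dt)
  cp <- cp_crystal + (cp_amorphous - cp_crystal) * 0.9^((times / t10)^n)
  if (noise_sd > 0)
    cp <- cp + with_seed(seed, rnorm(length(cp), 0, noise_sd))
  out <- tibble(time_min = times, cp = cp)
  class(out) <- c("modulated_trace", class(out))
  attr(out, "hold_temp_C") <- hold_temp
  out
}

#' Simulate a dissolution/supersaturation trace
#'
#' Emulates the concentration-time course of an amorphous sample dissolving
#' into a medium pre-loaded at the nominal concentration: the true curve
#' starts at `nominal`, passes through a supersaturation maximum `c_max` at
#' `peak_time` (gamma-shaped pulse) and relaxes toward `c_final` as the
#' supersaturated drug precipitates. The measured trace is the true curve
#' scaled by `first_point_bias`, emulating a multiplicative probe
#' calibration offset, so the nominal-concentration correction is exercised
#' (the corrected first point equals `nominal` exactly).
#'
#' If `nominal >= c_max` no supersaturation pulse can start at `nominal`;
#' the trace then decays monotonically from `nominal` to `c_final` with
#' time constant `peak_time`.
#'
#' @param peak_time Time of the concentration maximum, h.
#' @param c_max Maximum concentration, ug/mL (`> c_final`).
#' @param c_final Late-time plateau concentration, ug/mL.
#' @param nominal Nominal (pre-loaded) concentration, ug/mL.
#' @param first_point_bias Multiplicative measurement bias (1 = unbiased).
#' @param duration Trace duration, h.
#' @param dt Sampling interval, h.
#' @param pulse_shape Shape exponent of the gamma pulse.
#' @param noise_sd Additive Gaussian noise sd, ug/mL.
#' @param seed Optional integer seed for the noise.
#'
#' @return A tibble of class `dissolution_trace` with `time_h`,
#'   `conc_ug_ml` and attribute `nominal`.
#' @export
simulate_dissolution <- function(peak_time = 24, c_max = 50, c_final = 16,
                                 nominal = 40, first_point_bias = 1,
                                 duration = 72, dt = 0.5, pulse_shape = 2,
                                 noise_sd = 0, seed = NULL) {
  if (c_final >= c_max) abort("c_final must be below c_max")
  if (peak_time <= 0 || peak_time >= duration)
    abort("peak_time must lie inside (0, duration)")
  if (first_point_bias <= 0) abort("first_point_bias must be positive")
  times <- seq(0, duration, by = dt)
  if (nominal < c_max && nominal > c_final) {
    # gamma pulse with an offset s chosen so the curve starts at `nominal`
    pulse <- function(t, s) {
      z <- (t + s) / (peak_time + s)
      z^pulse_shape * exp(pulse_shape * (1 - z))
    }
    f <- function(s) c_final + (c_max - c_final) * pulse(0, s) - nominal
    s <- stats::uniroot(f, c(0, 1e6 * peak_time), tol = 1e-10)$root
    true <- c_final + (c_max - c_final) * pulse(times, s)
  } else {
    true <- c_final + (nominal - c_final) * exp(-times / peak_time)
  }
  meas <- first_point_bias * true
  if (noise_sd > 0)
    meas <- meas + with_seed(seed, rnorm(length(meas), 0, noise_sd))
  out <- tibble(time_h = times, conc_ug_ml = meas)
  class(out) <- c("dissolution_trace", class(out))
  attr(out, "nominal") <- nominal
  out
}
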