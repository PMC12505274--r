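#' Entropy of fusion
#'
#' \eqn{\Delta S_f = \Delta H_f / T_m} with the melting point converted to
#' kelvin.
#'
#' @param dHf Enthalpy of fusion, kJ/mol.
#' @param Tm Melting temperature, degC.
#' @return Entropy of fusion, J/(mol K); vectorized.
#' @examples
#' entropy_of_fusion(54.4, 149.9)  # form I, ~128.6
#' @export
entropy_of_fusion <- function(dHf, Tm) {
  if (any(dHf <= 0)) abort("dHf must be positive")
  if (any(Tm <= -273.15)) abort("Tm must exceed absolute zero")
  dHf * 1000 / (Tm + 273.15)
}

#' Critical nucleus radius (classical nucleation theory)
#'
#' \deqn{r^* = \frac{2 \sigma T_m}{\Delta H_f (T_m - T)}}
#' The critical radius diverges as T approaches Tm and shrinks with
#' undercooling, which is why nucleation can proceed far below the glass
#' transition when a local mobility mode is still active.
#'
#' @param sigma Crystal/amorphous interfacial specific surface energy,
#'   J/m^2; either a constant or a function of T (K) returning J/m^2.
#' @param Tm Melting temperature, K.
#' @param dHf_vol Enthalpy of fusion per unit volume, J/m^3 (see
#'   [molar_to_volumetric_enthalpy()]).
#' @param T Temperature(s), K, strictly below `Tm`.
#' @return Critical radius r* in meters; vectorized over `T`.
#' @export
critical_radius <- function(sigma, Tm, dHf_vol, T) {
  if (any(T >= Tm)) abort("T must be strictly below Tm")
  if (Tm <= 0 || dHf_vol <= 0) abort("Tm and dHf_vol must be positive")
  s <- if (is.function(sigma)) sigma(T) else sigma
  if (any(s <= 0)) abort("sigma must be positive")
  2 * s * Tm / (dHf_vol * (Tm - T))
}

#' Convert molar to volumetric enthalpy of fusion
#'
#' @param dHf Molar enthalpy of fusion, kJ/mol.
#' @param molar_volume Molar volume of the crystal, cm^3/mol.
#' @return Enthalpy of fusion per unit volume, J/m^3.
#' @export
molar_to_volumetric_enthalpy <- function(dHf, molar_volume) {
  if (dHf <= 0 || molar_volume <= 0) abort("inputs must be positive")
  dHf * 1000 / (molar_volume * 1e-6)
}

#' Nominal-concentration correction of a dissolution trace
#'
#' Rescales an in-situ UV concentration trace so the first measured point
#' equals the nominal pre-loaded concentration:
#' \deqn{c_{corr}(t) = \frac{c_{nominal}}{c_{meas}(t_1)} c_{meas}(t).}
#' The correction is multiplicative, so ratios between any two timepoints
#' are preserved.
#'
#' @param trace A `dissolution_trace` (or data frame with `time_h` and
#'   `conc_ug_ml`).
#' @param nominal Nominal concentration, ug/mL; defaults to the trace's
#'   `nominal` attribute.
#' @return The trace with `conc_ug_ml` replaced by the corrected values and
#'   the raw measurements kept in `conc_raw`.
#' @export
correct_concentration <- function(trace, nominal = NULL) {
  nominal <- nominal %||% attr(trace, "nominal")
  if (is.null(nominal) || nominal <= 0) abort("a positive nominal concentration is required")
  first <- trace$conc_ug_ml[1]
  if (!is.finite(first) || first <= 0)
    abort("first measured concentration must be positive")
  out <- mutate(trace, conc_raw = .data$conc_ug_ml,
                conc_ug_ml = nominal / first * .data$conc_ug_ml)
  attr(out, "nominal") <- nominal
  out
}

#' Summary of solubility replicates
#'
#' @param replicates Equilibrium solubility replicates, ug/mL (at least 2).
#' @return A one-row tibble with `mean`, `sd`, `n`.
#' @export
solubility_summary <- function(replicates) {
  if (length(replicates) < 2) abort("at least two replicates are required")
  tibble(mean = mean(replicates), sd = sd(replicates),
         n = length(replicates))
}
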