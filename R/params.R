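#' Thermodynamic parameters of the glass/crystal pair
#'
#' Container for the calorimetric constants that define a simulated sample:
#' glass transition, heat-capacity step, the two melting points of the
#' monotropically related polymorph pair (form II melts lower than form I),
#' and the event enthalpies. Defaults are for amorphous terfenadine.
#'
#' @param Tg Glass-transition temperature, degC.
#' @param dCp Heat-capacity step at Tg, J/(g K) (specific; use
#'   `dCp_molar / molar_mass` to convert from molar units).
#' @param Tm_I,Tm_II Melting temperatures of forms I and II, degC
#'   (`Tm_II < Tm_I`).
#' @param dHf_I,dHf_II Enthalpies of fusion of forms I and II, J/g.
#' @param dHc Enthalpy of cold crystallization, J/g.
#'
#' @return A list of class `thermo_params`.
#' @export
thermo_params <- function(Tg = 58.4, dCp = 271.4 / 471.68,
                          Tm_I = 149.9, Tm_II = 145.9,
                          dHf_I = 13.5, dHf_II = 99.7,
                          dHc = 95.3) {
  if (!(Tm_II < Tm_I)) abort("monotropic pair requires Tm_II < Tm_I")
  if (!(Tg < Tm_II)) abort("Tg must lie below Tm_II")
  if (any(c(dCp, dHf_I, dHf_II, dHc) <= 0)) abort("enthalpies and dCp must be positive")
  structure(
    list(Tg = Tg, dCp = dCp, Tm_I = Tm_I, Tm_II = Tm_II,
         dHf_I = dHf_I, dHf_II = dHf_II, dHc = dHc),
    class = "thermo_params"
  )
}

#' Arrhenius/Avrami-Erofeev kinetic parameters
#'
#' Parameters of the effective cold-crystallization rate law
#' \deqn{d\alpha/dt = A e^{-E_a/RT} \, n (1-\alpha) [-\ln(1-\alpha)]^{(n-1)/n}}
#' used by the nonisothermal simulator. `alpha0` seeds the conversion and is
#' the simulator's handle for preformed crystal nuclei: a larger seed shifts
#' the exotherm to lower temperature, emulating the effect of sub-Tg
#' annealing.
#'
#' @param Ea Apparent activation energy, J/mol.
#' @param lnA Log apparent frequency factor, ln(1/min).
#' @param n Avrami exponent (0.5-10).
#' @param alpha0 Initial conversion seed, in \[0, 0.01).
#'
#' @return A list of class `avrami_kinetics`.
#' @export
avrami_kinetics <- function(Ea = 134e3, lnA = 39.6, n = 4.7, alpha0 = 1e-8) {
  if (Ea <= 0) abort("Ea must be positive")
  if (n < 0.5 || n > 10) abort("Avrami exponent must lie in [0.5, 10]")
  if (alpha0 < 0 || alpha0 >= 0.01) abort("alpha0 must lie in [0, 0.01)")
  structure(list(Ea = Ea, lnA = lnA, n = n, alpha0 = alpha0),
            class = "avrami_kinetics")
}
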