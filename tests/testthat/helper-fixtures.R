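# Shared fixtures, memoised so expensive simulations run once per session.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

std_thermo <- function() thermo_params()
std_kin <- function() avrami_kinetics()  # Ea 134 kJ/mol, lnA 39.6, n 4.7

ramp_program <- function(rate, start = 25, end = 160)
  temperature_program(start, tp_ramp(end, rate))

# Noise-free thermogram at a given heating rate under the default conditions.
std_thermogram <- function(rate = 1) {
  fixture(paste0("tg_rate_", rate),
          simulate_nonisothermal_thermogram(std_kin(), ramp_program(rate),
                                            std_thermo(), dt = 0.02))
}

kas_thermograms <- function() lapply(c(0.5, 1, 2), std_thermogram)

EXO_LIMITS <- c(85, 138)
MELT_LIMITS <- c(139, 158)
TG_WINDOW <- c(45, 75)

# Build a thermogram tibble from raw vectors (e.g. shifted/flat traces).
make_thermogram <- function(temp, heat_flow, rate = 1, mass = 5) {
  as_thermogram(data.frame(time_min = (temp - temp[1]) / rate,
                           temp_C = temp, heat_flow = heat_flow,
                           rate_C_min = rate), mass_mg = mass)
}
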