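#' Temperature programs
#'
#' A temperature program is an ordered sequence of contiguous segments, each
#' either a linear ramp (given a target temperature and a rate in degC/min)
#' or an isothermal hold (given a duration in min). Programs drive the
#' nonisothermal simulator and are stored alongside simulated thermograms.
#'
#' @param start_temp Starting temperature, degC.
#' @param ... Segments built with [tp_ramp()] or [tp_hold()].
#'
#' @return A tibble of class `temperature_program` with one row per segment
#'   and columns `kind`, `start_T`, `end_T`, `rate`, `duration`, `t_start`,
#'   `t_end` (times in min from the start of the program).
#'
#' @examples
#' prog <- temperature_program(25, tp_ramp(160, 1))
#' program_temperature(prog, c(0, 60, 135))
#' @export
temperature_program <- function(start_temp, ...) {
  segs <- list(...)
  if (length(segs) == 0) abort("a temperature program needs at least one segment")
  cur_T <- start_temp
  cur_t <- 0
  rows <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (identical(s$kind, "ramp")) {
      if (!is.finite(s$rate) || s$rate == 0) abort("ramp rate must be nonzero")
      if (s$to == cur_T) abort("ramp target equals segment start temperature")
      dur <- abs(s$to - cur_T) / abs(s$rate)
      rate <- sign(s$to - cur_T) * abs(s$rate)
      rows[[i]] <- tibble(
        kind = "ramp", start_T = cur_T, end_T = s$to,
        rate = rate, duration = dur,
        t_start = cur_t, t_end = cur_t + dur
      )
      cur_T <- s$to
      cur_t <- cur_t + dur
    } else {
      if (s$duration <= 0) abort("hold duration must be positive")
      rows[[i]] <- tibble(
        kind = "isothermal", start_T = cur_T, end_T = cur_T,
        rate = 0, duration = s$duration,
        t_start = cur_t, t_end = cur_t + s$duration
      )
      cur_t <- cur_t + s$duration
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("temperature_program", class(out))
  out
}

#' @rdname temperature_program
#' @param to Target temperature of a ramp, degC.
#' @param rate Heating (or cooling) rate magnitude, degC/min.
#' @export
tp_ramp <- function(to, rate) list(kind = "ramp", to = to, rate = rate)

#' @rdname temperature_program
#' @param duration Hold duration, min.
#' @export
tp_hold <- function(duration) list(kind = "isothermal", duration = duration)

#' Evaluate a temperature program
#'
#' @param program A [temperature_program()].
#' @param time_min Times (min) at which to evaluate; must lie within the
#'   program.
#' @return Temperatures in degC at `time_min`.
#' @export
program_temperature <- function(program, time_min) {
  t_end <- max(program$t_end)
  if (any(time_min < -1e-9 | time_min > t_end + 1e-9))
    abort("time outside the temperature program")
  idx <- findInterval(pmin(pmax(time_min, 0), t_end), program$t_start,
                      rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(program))
  program$start_T[idx] + program$rate[idx] * (time_min - program$t_start[idx])
}

#' @rdname program_temperature
#' @export
program_duration <- function(program) max(program$t_end)
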