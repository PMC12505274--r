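#' Read and write thermal traces
#'
#' Thermal traces travel as plain CSV with header columns `time_min`,
#' `temp_C` and one signal column (`heat_flow_mW_per_mg` for thermograms,
#' `cp_J_per_gK` for reversing-heat-capacity traces), plus an optional YAML
#' sidecar (`<path>.yaml`) carrying the temperature program and metadata.
#'
#' @param trace A `thermogram` or `modulated_trace`.
#' @param path Output CSV path.
#' @param sidecar Write the YAML sidecar?
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  if (inherits(trace, "thermogram")) {
    df <- data.frame(time_min = trace$time_min, temp_C = trace$temp_C,
                     heat_flow_mW_per_mg = trace$heat_flow,
                     rate_C_min = trace$rate_C_min)
    meta <- list(
      signal = "heat_flow_mW_per_mg",
      mass_mg = attr(trace, "mass_mg"),
      incomplete_crystallization = isTRUE(attr(trace, "incomplete_crystallization")),
      program = lapply(seq_len(nrow(attr(trace, "program") %||% tibble())),
                       function(i) as.list(attr(trace, "program")[i, ]))
    )
  } else if (inherits(trace, "modulated_trace")) {
    df <- data.frame(time_min = trace$time_min, cp_J_per_gK = trace$cp)
    meta <- list(signal = "cp_J_per_gK",
                 hold_temp_C = attr(trace, "hold_temp_C"))
  } else {
    abort("write_trace_csv handles thermogram and modulated_trace objects")
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("trace file not found: %s", path))
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if ("heat_flow_mW_per_mg" %in% names(df)) {
    out <- tibble(time_min = df$time_min, temp_C = df$temp_C,
                  heat_flow = df$heat_flow_mW_per_mg,
                  rate_C_min = df$rate_C_min %||% NA_real_)
    class(out) <- c("thermogram", class(out))
    attr(out, "mass_mg") <- meta$mass_mg
    attr(out, "incomplete_crystallization") <- isTRUE(meta$incomplete_crystallization)
  } else if ("cp_J_per_gK" %in% names(df)) {
    out <- tibble(time_min = df$time_min, cp = df$cp_J_per_gK)
    class(out) <- c("modulated_trace", class(out))
    attr(out, "hold_temp_C") <- meta$hold_temp_C
  } else {
    abort(sprintf("unrecognized trace columns in %s", path))
  }
  out
}

#' Read and write powder patterns
#'
#' Powder patterns travel as two-column whitespace-delimited XY files
#' (2theta in degrees, intensity in counts), the lingua franca of powder
#' diffraction software.
#'
#' @param pattern A `pxrd_pattern`.
#' @param path File path.
#' @return `path` (write) or a `pxrd_pattern` tibble (read).
#' @export
write_xy <- function(pattern, path) {
  utils::write.table(data.frame(pattern$two_theta, pattern$intensity),
                     path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_xy
#' @export
read_xy <- function(path) {
  if (!file.exists(path)) abort(sprintf("pattern file not found: %s", path))
  df <- utils::read.table(path, col.names = c("two_theta", "intensity"))
  out <- as_tibble(df)
  class(out) <- c("pxrd_pattern", class(out))
  out
}

#' Construct trace objects from plain data frames
#'
#' Validating constructors for data imported from instrument exports that
#' are already tabular.
#'
#' @param data A data frame with columns `time_min`, `temp_C`, `heat_flow`
#'   (mW/mg, exo up) and `rate_C_min` (for thermograms), or `time_min` and
#'   `cp` (J/(g K), for modulated traces).
#' @param mass_mg Sample mass, mg.
#' @param hold_temp_C Hold temperature of a modulated trace, degC.
#' @return A `thermogram` or `modulated_trace` tibble.
#' @export
as_thermogram <- function(data, mass_mg = NA_real_) {
  need <- c("time_min", "temp_C", "heat_flow", "rate_C_min")
  if (!all(need %in% names(data)))
    abort(paste("thermogram needs columns:", paste(need, collapse = ", ")))
  if (is.unsorted(data$time_min, strictly = TRUE))
    abort("time must be strictly increasing")
  out <- as_tibble(data[need])
  class(out) <- c("thermogram", class(out))
  attr(out, "mass_mg") <- mass_mg
  out
}

#' @rdname as_thermogram
#' @export
as_modulated_trace <- function(data, hold_temp_C = NA_real_) {
  if (!all(c("time_min", "cp") %in% names(data)))
    abort("modulated trace needs columns time_min, cp")
  if (is.unsorted(data$time_min, strictly = TRUE))
    abort("time must be strictly increasing")
  out <- as_tibble(data[c("time_min", "cp")])
  class(out) <- c("modulated_trace", class(out))
  attr(out, "hold_temp_C") <- hold_temp_C
  out
}
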