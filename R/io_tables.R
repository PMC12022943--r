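# CSV readers/writers for kinetic traces, titrations and spectra.

#' Read a kinetic trace
#'
#' Reads a two-column CSV (time in seconds, fluorescence intensity in a.u.)
#' into a kinetic-trace tibble. Optional `temperature` and `channel` columns or
#' reader arguments tag the trace for downstream Arrhenius analysis.
#'
#' @param path CSV path with columns `time`, `intensity` (extra columns kept).
#' @param temperature Temperature in kelvin attached to the trace (overrides a
#'   `temperature` column if given).
#' @param channel `"donor"` (rise) or `"acceptor"` (decay) label.
#' @return A tibble with columns `time`, `intensity` and attributes
#'   `temperature` and `channel`.
#' @export
read_trace <- function(path, temperature = NULL, channel = NULL) {
  if (!file.exists(path)) abort(sprintf("trace file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time", "intensity") %in% names(df))) {
    if (ncol(df) >= 2 && all(vapply(df[1:2], is.numeric, logical(1)))) {
      names(df)[1:2] <- c("time", "intensity")
    } else {
      abort("trace CSV must have numeric columns `time` and `intensity`")
    }
  }
  if (is.null(temperature) && "temperature" %in% names(df)) {
    temperature <- df$temperature[[1]]
  }
  if (is.null(channel) && "channel" %in% names(df)) channel <- df$channel[[1]]
  new_kinetic_trace(df[c("time", "intensity")],
                    temperature = temperature, channel = channel)
}

new_kinetic_trace <- function(df, temperature = NULL, channel = NULL) {
  validate_trace_times(df$time)
  out <- as_tibble(df)
  attr(out, "temperature") <- temperature
  attr(out, "channel") <- channel %||% "donor"
  out
}

validate_trace_times <- function(time) {
  if (length(time) > 1 && any(diff(time) <= 0)) {
    abort("trace times must be strictly increasing (duplicate or non-monotone timestamps)")
  }
  invisible(time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a kinetic trace as CSV
#'
#' @param trace Trace tibble (columns `time`, `intensity`; `temperature` and
#'   `channel` attributes are written as columns when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace[c("time", "intensity")])
  if (!is.null(attr(trace, "temperature"))) df$temperature <- attr(trace, "temperature")
  if (!is.null(attr(trace, "channel"))) df$channel <- attr(trace, "channel")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a fluorescence titration table
#'
#' Reads a CSV of lipid concentration (M) versus fluorescence intensity (a.u.),
#' one row per well; optional `replicate` and `condition` columns are kept.
#'
#' @param path CSV path with columns `lipid_conc`, `intensity`.
#' @return A titration tibble suitable for [fit_partition()].
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) abort(sprintf("titration file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("lipid_conc", "intensity") %in% names(df))) {
    abort("titration CSV must have columns `lipid_conc` and `intensity`")
  }
  if (any(df$lipid_conc < 0)) abort("lipid concentrations must be >= 0")
  as_tibble(df)
}

#' Read a spectrum
#'
#' Reads a two-column CSV (wavelength in nm, value) into a spectrum tibble.
#' Emission spectra are in arbitrary units; absorption spectra in molar
#' absorptivity (M^-1 cm^-1).
#'
#' @param path CSV path with columns `wavelength`, `value` (or two numeric
#'   columns in that order).
#' @return A tibble with strictly increasing `wavelength` and `value >= 0`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) abort(sprintf("spectrum file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("wavelength", "value") %in% names(df))) {
    if (ncol(df) >= 2) names(df)[1:2] <- c("wavelength", "value")
  }
  validate_spectrum(df[c("wavelength", "value")])
}

validate_spectrum <- function(df) {
  if (any(diff(df$wavelength) <= 0)) {
    abort("spectrum wavelengths must be strictly increasing")
  }
  if (any(df$value < 0)) abort("spectrum values must be >= 0")
  as_tibble(df)
}
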