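#' Pipeline configuration
#'
#' Bundles the handful of settings shared across pipeline stages: the bath
#' temperature used for Boltzmann inversion and tempering, the depth-histogram
#' bin width, the free-energy-surface grid resolution, the RNG seed recorded in
#' all reports, and named input/output paths.
#'
#' @param temperature Temperature in kelvin. Default 310.15 K (37 degC), the
#'   bath temperature of the simulations and exchange assays.
#' @param energy_units Reporting units flag, `"kJ/mol"` (default) or `"J/mol"`.
#'   All internal arithmetic is in kJ/mol.
#' @param bin_width_z Depth-histogram bin width in nm.
#' @param grid_resolution Points per collective-variable axis for FES grids
#'   (must be >= 16).
#' @param rng_seed Integer seed echoed into every report.
#' @param paths Named list of input/output locations.
#'
#' @return A list with class `memperm_config`.
#' @export
memperm_config <- function(temperature = 310.15,
                           energy_units = c("kJ/mol", "J/mol"),
                           bin_width_z = 0.05,
                           grid_resolution = 201L,
                           rng_seed = 1L,
                           paths = list()) {
  energy_units <- match.arg(energy_units)
  stopifnot_scalar_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(bin_width_z, "bin_width_z", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(grid_resolution, "grid_resolution", lower = 16)
  structure(
    list(
      temperature = temperature,
      energy_units = energy_units,
      bin_width_z = bin_width_z,
      grid_resolution = as.integer(grid_resolution),
      rng_seed = as.integer(rng_seed),
      paths = paths
    ),
    class = "memperm_config"
  )
}

#' Read a configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys match the arguments of
#'   [memperm_config()].
#' @return A `memperm_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- intersect(names(vals), names(formals(memperm_config)))
  do.call(memperm_config, vals[known])
}

#' @export
print.memperm_config <- function(x, ...) {
  cat("<memperm_config>\n")
  cat(sprintf("  temperature: %g K | units: %s | bin_width_z: %g nm | grid: %d | seed: %d\n",
              x$temperature, x$energy_units, x$bin_width_z,
              x$grid_resolution, x$rng_seed))
  invisible(x)
}

#' Machine-readable report for a pipeline result
#'
#' Converts a fitted or derived object into a plain list (config echo, seed,
#' and the object's own summaries) suitable for `jsonlite::write_json()`.
#'
#' @param x A memperm result object.
#' @param config A [memperm_config()] echoed into the report.
#' @param ... Passed on to methods.
#' @return A named list.
#' @export
as_report <- function(x, config = memperm_config(), ...) {
  UseMethod("as_report")
}

#' @export
as_report.default <- function(x, config = memperm_config(), ...) {
  list(
    config = unclass(config)[c("temperature", "energy_units", "bin_width_z",
                               "grid_resolution", "rng_seed")],
    seed = config$rng_seed,
    result = if (is.data.frame(x)) as.data.frame(x) else unclass(x)
  )
}

#' Write a report as JSON
#'
#' @param x A memperm result object.
#' @param path Output path.
#' @param config Configuration echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, config = memperm_config()) {
  jsonlite::write_json(as_report(x, config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}
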