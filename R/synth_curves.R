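# Seeded generators for titration curves, exchange traces and Arrhenius series.
# Noise is multiplicative lognormal (fluorescence is positive); noiseless
# outputs satisfy the forward models exactly.

#' Simple-partition forward model
#'
#' Expected fluorescence intensity at lipid concentration `lipid_conc` for a
#' solute partitioning between water (intensity `I_W`) and membrane (`I_M`)
#' with partition coefficient `K_P`:
#' `I = (I_W + I_M * K_P * V_L * L) / (1 + K_P * V_L * L)`.
#'
#' @param lipid_conc Lipid concentration(s), M.
#' @param K_P Dimensionless partition coefficient (>= 0).
#' @param I_W,I_M Intensities with all solute in water / in the membrane (a.u.).
#' @param molar_volume Lipid molar volume, dm^3/mol (default 0.8).
#' @return Expected intensities, same length as `lipid_conc`.
#' @export
partition_model <- function(lipid_conc, K_P, I_W, I_M, molar_volume = 0.8) {
  x <- K_P * molar_volume * lipid_conc
  (I_W + I_M * x) / (1 + x)
}

#' Generate a synthetic partition titration
#'
#' Draws intensity-vs-lipid-concentration curves from the simple-partition
#' model, optionally with multiplicative lognormal noise of coefficient of
#' variation `noise_cv`.
#'
#' @inheritParams partition_model
#' @param lipid_concs Lipid concentrations, M.
#' @param noise_cv Relative standard deviation of the multiplicative noise
#'   (0 = noiseless).
#' @param replicates Number of replicate curves.
#' @param seed Integer seed (NULL leaves the RNG state alone).
#' @return A tibble with columns `lipid_conc`, `intensity`, `replicate`.
#' @export
gen_partition_curve <- function(K_P, I_W = 100, I_M = 1000,
                                molar_volume = 0.8,
                                lipid_concs = 10^seq(-8, -4, length.out = 10),
                                noise_cv = 0, replicates = 1, seed = NULL) {
  stopifnot_scalar_number(K_P, "K_P", lower = 0)
  stopifnot_scalar_number(noise_cv, "noise_cv", lower = 0)
  if (any(lipid_concs < 0)) abort("lipid concentrations must be >= 0")
  mu <- partition_model(lipid_concs, K_P, I_W, I_M, molar_volume)
  with_seed(seed, {
    purrr::map_dfr(seq_len(replicates), function(r) {
      tibble(lipid_conc = lipid_concs,
             intensity = mu * lognormal_noise(length(mu), noise_cv),
             replicate = r)
    })
  })
}

#' Generate a synthetic exchange trace
#'
#' Multi-exponential FRET exchange trace. For the donor channel the intensity
#' rises towards `plateau`: `I(t) = plateau - sum a_i exp(-k_i t)`; for the
#' acceptor channel it decays towards `baseline`:
#' `I(t) = baseline + sum a_i exp(-k_i t)`.
#'
#' @param components Data frame (or list coercible to one) with columns
#'   `amplitude` (a.u., >= 0) and `rate` (s^-1, > 0).
#' @param time Time grid in seconds (strictly increasing).
#' @param plateau Long-time donor intensity (a.u.).
#' @param baseline Long-time acceptor intensity (a.u.).
#' @param channel `"donor"` (rise) or `"acceptor"` (decay).
#' @param temperature Temperature tag in kelvin.
#' @param noise_cv Multiplicative lognormal noise CV (0 = noiseless).
#' @param seed Integer seed.
#' @return A kinetic-trace tibble (`time`, `intensity`) with `temperature` and
#'   `channel` attributes.
#' @export
gen_exchange_trace <- function(components,
                               time = seq(0, 28800, length.out = 600),
                               plateau = 1, baseline = 0,
                               channel = c("donor", "acceptor"),
                               temperature = 310.15,
                               noise_cv = 0, seed = NULL) {
  channel <- match.arg(channel)
  components <- as_tibble(components)
  if (any(components$amplitude < 0)) abort("amplitudes must be >= 0")
  if (any(components$rate <= 0)) abort("rates must be > 0")
  validate_trace_times(time)
  decay <- rowSums(vapply(seq_len(nrow(components)), function(i) {
    components$amplitude[i] * exp(-components$rate[i] * time)
  }, numeric(length(time))))
  mu <- if (channel == "donor") plateau - decay else baseline + decay
  intensity <- with_seed(seed, mu * lognormal_noise(length(mu), noise_cv))
  new_kinetic_trace(tibble(time = time, intensity = intensity),
                    temperature = temperature, channel = channel)
}

#' Generate an Arrhenius-distributed rate series
#'
#' Rate constants `k = A * exp(-Ea / (R T))` on a temperature grid, optionally
#' with multiplicative lognormal noise.
#'
#' @param A Pre-exponential factor, s^-1.
#' @param Ea Activation energy, kJ/mol (>= 0).
#' @param temps Temperatures in kelvin. Default 288.15-310.15 K (15-37 degC).
#' @param noise_cv Multiplicative lognormal noise CV.
#' @param seed Integer seed.
#' @return A tibble with columns `temperature` (K) and `k` (s^-1).
#' @export
gen_arrhenius_series <- function(A, Ea,
                                 temps = c(288.15, 298.15, 304.15, 310.15),
                                 noise_cv = 0, seed = NULL) {
  stopifnot_scalar_number(A, "A", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(Ea, "Ea", lower = 0)
  if (any(temps <= 0)) abort("temperatures must be > 0 K")
  k <- A * exp(-Ea / (gas_constant_kj() * temps))
  k <- with_seed(seed, k * lognormal_noise(length(k), noise_cv))
  tibble(temperature = temps, k = k)
}
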