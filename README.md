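# memperm

Quantitative analysis of passive membrane transport of large amphiphilic
solutes, built around the assays and simulation post-processing used to study
how conformational isomers of a ~1 kDa photosensitizer bind to, exchange
between, and cross phospholipid bilayers.

Large molecules are usually assumed not to cross membranes passively, yet
amphiphilic solutes with an asymmetric polar-group arrangement can bind
liposomes orders of magnitude more strongly than their octanol/water partition
predicts, and exchange between vesicles at rates that track desorption rather
than translocation. Testing that picture needs four quantitative pieces, which
this package implements end to end, plus seeded synthetic generators for every
input so the whole pipeline is testable without a fluorimeter or an MD engine:

1. **Liposome partition fitting.** Fluorescence titrations against large
   unilamellar vesicles follow the simple-partition hyperbola

   `I([L]) = (I_W + I_M · K_P · V̄_L · [L]) / (1 + K_P · V̄_L · [L])`

   where `I_W`/`I_M` are the all-water/all-membrane intensities, `V̄_L` the
   lipid molar volume (0.8 dm³/mol) and `K_P` the dimensionless partition
   coefficient. `fit_partition()` estimates `(K_P, I_W, I_M)` by
   Levenberg–Marquardt least squares with `K_P` parametrized on the log10
   scale; `compare_logKP()` applies the Welch two-tailed unequal-variance
   t-test to replicate `log10 K_P` estimates.

2. **FRET exchange kinetics.** Donor-rise / acceptor-decay traces are fitted
   with `I(t) = offset ± Σ aᵢ·exp(−kᵢt)` (`fit_exponentials()`); a
   biexponential is kept only when it at least halves the χ² of the
   monoexponential (`select_model()`); the exchange rate constant is the
   amplitude-weighted mean `k = Σ aᵢkᵢ / Σ aᵢ` (`weighted_rate()`); and
   `fit_arrhenius()` regresses `ln k` on `1/T` to give the activation energy
   `E_a = −slope·R` and pre-exponential `A = exp(intercept)`.
   `overlap_integral()`/`forster_radius()` compute the spectral overlap `J`
   and the Förster radius `R₀ = (8.79·10⁻⁵ κ² n⁻⁴ Φ_D J)^{1/6}`.

3. **Bilayer trajectory descriptors.** From coordinate trajectories:
   the transverse collective variables CV1 (macrocycle-N centre of mass to
   bilayer centre) and CV2 (opposite-sulfur-pair centre of mass), the tilt θ
   of the CV1→CV2 vector from the bilayer normal, depth histograms
   Boltzmann-inverted to partial free-energy profiles (−RT ln d(z)),
   geometric hydrogen bonds (donor–acceptor < 0.35 nm, angle at the donor
   < 30°), distance-resolved acyl-chain order parameters −S_CD, and
   instantaneous dipole moments from partial charges.

4. **Metadynamics post-processing.** `read_hills()` parses PLUMED-dialect
   HILLS files; `reconstruct_fes()` sums the Gaussian bias on a periodic
   normalized CV grid and converts it to free energy
   (`F = −γ/(γ−1)·V` for well-tempered deposition);
   `average_symmetrize()` averages replicates and enforces leaflet
   (point-inversion) symmetry; `rescale_cvs()` maps normalized CVs to nm via
   the mean z-box; `mfep_string()` extracts the minimum free-energy path with
   the zero-temperature string method; `project_1d()` and `barriers()` give
   the 1D profile and the desorption/translocation barriers.

Everything is tidyverse-native: data frames in, tibbles out, fitted objects
with `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(memperm)

# --- partition: noisy synthetic titration generated at K_P = 1.5e6 ----------
titr <- gen_partition_curve(K_P = 1.5e6, I_W = 100, I_M = 1000,
                            noise_cv = 0.03, seed = 42)
fit <- fit_partition(titr, molar_volume = 0.8)
fit
#> <partition_fit>
#>   log10 K_P = 6.163 (se 0.039) | K_P = 1.45e+06
#>   I_W = 102.1, I_M = 1024 | V_L = 0.8 dm^3/mol | n = 10 | ||resid|| = 58.3 (4 iter)
```

The fitted `log10 K_P = 6.16 ± 0.04` recovers the generating coefficient
(`log10 1.5e6 = 6.18`) within its standard error from a 3%-noise curve;
`I_W` and `I_M` return the two fluorescence asymptotes.

```r
# --- exchange: two-component donor-rise trace, 1% noise ---------------------
mix <- tibble::tibble(amplitude = c(0.7, 0.3), rate = c(2.0e-4, 3.33e-5))
trace <- gen_exchange_trace(mix, noise_cv = 0.01, seed = 1)
fit_exchange(trace)
#> <exchange_fit> 1 component(s), donor channel
#>  amplitude         rate
#>  0.8561549 0.0001534126
#>   offset = 0.8774 | chi2 = 0.06352 | k_weighted = 0.0001534 s^-1
```

Here the χ²-halving rule retains the monoexponential description and its rate
(1.53·10⁻⁴ s⁻¹) sits next to the generating mixture's amplitude-weighted mean
(1.50·10⁻⁴ s⁻¹) — the weighted average is what makes mono- and biexponential
readings of the same trace agree.

```r
# --- Arrhenius analysis over 15-37 degC -------------------------------------
fit_arrhenius(gen_arrhenius_series(A = 2.6e17, Ea = 125))
#> <arrhenius_fit> Ea = 125 kJ/mol (se 3.4e-14) | A = 2.6e+17 s^-1 | 4 temperatures
```

For the metadynamics side, `analytic_fes()` + `gen_hills_from_fes()` run a
tempered Metropolis walker on a prescribed surface and the
reconstruct → symmetrize → rescale → `mfep_string()` → `project_1d()` →
`barriers()` chain recovers its minima and barriers; see the methods vignette
(`vignettes/membrane-permeation-analysis.Rmd`) for the full toy pipeline.

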