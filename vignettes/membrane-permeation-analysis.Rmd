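---
title: "Methods: membrane partition, exchange kinetics, and permeation free-energy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane partition, exchange kinetics, and permeation free-energy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memperm)
```

`memperm` analyses passive membrane transport of large amphiphilic solutes
along two experimental axes (equilibrium partition to liposomes, inter-vesicle
exchange kinetics read out by FRET) and two simulation axes (per-frame bilayer
descriptors, metadynamics free-energy post-processing). This vignette explains
the models, the defaults and why they were chosen, what the synthetic
generators do and do not emulate, and the numerical decisions a maintainer
would want written down.

## Partition to liposomes

At solute concentrations low enough to exclude self-aggregation and membrane
saturation, the fluorescence of a solute titrated with lipid vesicles follows
the simple-partition hyperbola

$$I([L]) = \frac{I_W + I_M\,K_P\,\bar V_L\,[L]}{1 + K_P\,\bar V_L\,[L]},$$

with asymptotes $I_W$ (all solute aqueous) and $I_M$ (all membrane-bound) and
half-transition at $[L] = 1/(K_P \bar V_L)$. This hyperbolic form is the one
consistent with those asymptotes and with half-partition behaviour, and it is
what `fit_partition()` fits; the choice is stated prominently because the
partition equation is sometimes written in volume-fraction variants that
differ only in how $\bar V_L [L]$ is grouped.

Decisions and defaults:

* **Molar volume** $\bar V_L = 0.8$ dm³/mol, appropriate for both POPC and
  POPE; always explicit in the fit object.
* **Weighting.** Fits use untransformed intensities with uniform weights —
  no weighting scheme is implied by the assay description, and replicate
  curves can simply be pooled row-wise.
* **Parametrization.** $K_P$ is fitted as $\log_{10} K_P$, which enforces
  $K_P \ge 0$ and returns the standard error of the log-scale estimate
  directly. All averaging and hypothesis testing is done on
  $\log_{10} K_P$, the quantity that is approximately normal across
  replicates; `compare_logKP()` is a Welch two-sample, two-tailed
  unequal-variance t-test on those log-scale estimates.
* **Initialization.** $I_W$ from the lowest-concentration intensities, $I_M$
  from the highest, $K_P$ from the concentration nearest the mid-intensity.
  With these starts the Levenberg–Marquardt fit converges in a handful of
  iterations on well-formed curves.
* **Degenerate inputs.** All-equal intensities and titrations with fewer than
  four distinct concentrations are rejected rather than fitted.

The non-goal worth stating: solute aggregation in the aqueous phase bends the
titration sigmoidal and depresses the apparent $K_P$. The model does not
describe that regime; it surfaces only through a poor residual norm.

## Exchange kinetics and Arrhenius analysis

Inter-vesicle exchange is followed as a donor-fluorescence rise (or acceptor
decay) after mixing labelled donor vesicles with blank acceptor vesicles.
`fit_exponentials()` fits

$$I(t) = \mathrm{offset} \pm \sum_i a_i e^{-k_i t},$$

with amplitudes and rates on the log scale (positivity without box
constraints) and three starting points per model order to avoid local minima;
components are reported in decreasing-rate order, and a flag is raised when a
fitted rate approaches the resolution limits of the time grid.

* **Model selection.** The biexponential is retained iff
  $\chi^2_2 \le \tfrac12 \chi^2_1$ (`select_model()`). The boundary is
  *inclusive* at exactly one half: "to half or less" reads as $\le$, and the
  convention is documented here because a strict inequality would silently
  change the boundary case.
* **Weighted rate.** The exchange rate constant of a multiexponential fit is
  the amplitude-weighted arithmetic mean $k = \sum a_i k_i / \sum a_i$ — the
  standard reduction of a multiexponential to a single effective rate. It is
  scale-invariant in the amplitudes and bounded by the component rates.
* **Arrhenius analysis.** `fit_arrhenius()` regresses $\ln k$ on $1/T$
  (log-scale rates are the normally distributed quantity), with
  $E_a = -\mathrm{slope}\cdot R$ in kJ/mol and $A = e^{\mathrm{intercept}}$;
  $R = 8.314$ J mol⁻¹ K⁻¹ throughout, temperatures in kelvin
  (°C + 273.15). At least three temperatures are required; with noiseless
  input the generate–fit round trip is exact to numerical precision, which is
  how the recovery tests are framed. Single-channel traces are assumed; when
  donor and acceptor channels are measured separately, each is fitted on its
  own and the weighted rates compared.

## Förster radius

`overlap_integral()` evaluates
$J = \int F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4 d\lambda \big/ \int F_D(\lambda) d\lambda$
by trapezoid on the donor grid (acceptor interpolated linearly onto it), in
M⁻¹ cm⁻¹ nm⁴; donor normalization is built in, so emission spectra may be in
any arbitrary units. `forster_radius()` applies
$R_0 = (8.79\times10^{-5}\,\kappa^2 n^{-4}\Phi_D J)^{1/6}$ Å, reported in nm.
Defaults: $\kappa^2 = 2/3$ (isotropic dynamic averaging — an assumption, not a
measurement) and $n = 1.326$ (methanol, the medium in which the reference
spectra were taken). Disjoint spectra give $J = 0$ with a warning rather than
an error, so pipelines can treat "no overlap" as a measured zero.

## Trajectory descriptors

A `traj_bundle` carries frames in nm, per-frame box dimensions, and a
topology table (names, residues, partial charges). PDB/DCD inputs (ångström)
are converted on read; GRO files are parsed natively (nm).

* **CV1 / CV2 / tilt.** CV1 is the signed transverse distance from the
  macrocycle-N centre of mass to the bilayer centre of mass; CV2 the same for
  the two diametrically opposite S atoms; θ the angle of the CV1→CV2 vector
  from the +z box normal, reported unfolded on [0°, 180°] — the acute/obtuse
  distinction carries physical meaning (substituents pointing to water versus
  to the bilayer centre), so no folding to [0°, 90°] is applied. The bilayer
  centre of mass uses all lipid atoms (robust to leaflet asymmetry;
  configurable through the selection arguments). For a symmetric isomer whose
  two S pairs are inequivalent frame-to-frame, the caller chooses which pair
  defines CV2 via `s_atoms` — the package takes no position.
* **Depth free energy.** The transverse location is binned (default 0.05 nm)
  into a relative-frequency density integrating to one, then Boltzmann
  inverted, $\Delta G(z) = -RT\ln d(z)$, min-shifted to zero with empty bins
  masked. At 310.15 K a Gaussian depth of sd 0.1 nm implies
  $\Delta G(\mu + \sigma) = RT/2 \approx 1.29$ kJ/mol, the closed form used in
  the tests. At least 500 samples are required — below that the histogram is
  mostly noise.
* **Hydrogen bonds.** Geometric criteria, donor–acceptor distance < 0.35 nm
  and hydrogen–donor–acceptor angle < 30°. The angle is read as the angle *at
  the donor* between D→H and D→A (configurable to the D–H–A reading at the
  hydrogen, since the phrase is ambiguous in common usage). Counting is exact
  pairwise — no cell lists and no periodic images; the intended inputs are
  local solute–solvent geometries well inside the box. Counts are verified
  against an O(N²) brute-force scan in the tests.
* **Order parameters.** $S_{CD} = \langle 3\cos^2\theta_{CH} - 1\rangle/2$
  per chain carbon, reported as $-S_{CD}$, resolved into radial shells by the
  minimum lateral (xy, minimum-image) distance between each lipid's
  phosphorus and any solute atom. Default shell edges 0.6 and 1.0 nm — the
  distances at which local perturbation is strong and at which it becomes
  negligible.
* **Dipole moments.** $\mu = \sum q_i (r_i - \bar r)$ in e·nm, converted at
  48.03 D per e·nm, with orientation reported against the best-fit
  macrocycle-plane normal. The centroid reference makes the value
  origin-independent for net-neutral selections; net-charged selections warn
  and use the documented centroid convention.

## Metadynamics post-processing

Hills are Gaussian bias records $(t, c_1, c_2, \sigma_1, \sigma_2, h, \gamma)$
in normalized CV coordinates on $[-0.5, 0.5]^2$. The HILLS reader is
header-driven (`#! FIELDS ...`) with a fixed-order fallback and treats the
bias-factor column as optional (default γ = 30), because the exact column
layout of these text files varies between producing setups.

* **Reconstruction.** $V(s) = \sum_i h_i \exp(-\sum_d \mathrm{wrap}(s_d -
  c_{id})^2 / 2\sigma_{id}^2)$ with periodic wrapping, evaluated separably in
  blocks of hills (two matrix products per block), so $5\times10^4$ hills on a
  201² grid take seconds. The free-energy estimate is
  $F = -\tfrac{\gamma}{\gamma-1}V$, min-shifted to zero. For
  transition-tempered deposition the prefactor is exact only once tempering
  is active; the untempered estimate $F = -V$ is available
  (`estimator = "negative_bias"`) for the pre-threshold regime. A warning is
  raised when the grid spacing exceeds σ/2.
* **Averaging and symmetry.** Replicate surfaces are each min-shifted to zero
  before pointwise averaging — how replicates were aligned is otherwise
  undefined, and a common zero at the minimum is the convention adopted here.
  Symmetrization is point inversion through the origin,
  $F \leftarrow [F(cv_1, cv_2) + F(-cv_1, -cv_2)]/2$: exchanging leaflets
  flips the signs of *both* CVs together, so a mirror in one coordinate alone
  would be the wrong symmetry. The pointwise standard error across replicates
  is carried alongside the mean.
* **Rescaling.** Normalized CVs are multiplied by the mean z-box dimension;
  a unit flag makes double application an error.
* **String method.** Zero-temperature: interior nodes move along the
  bilinear-interpolated $-\nabla F$ (central-difference gradient grids), then
  the string is reparametrized to equal arclength; convergence when the
  maximum per-iteration node displacement drops below `tol` (default 1e-4
  axis units). The step is 0.1 grid spacings with the gradient normalized by
  its maximum over nodes, which makes the step size surface-scale-free.
  Defaults: 100 nodes, 5000 iterations, endpoints at the deposition basins
  (0, 0) and (0.48, 0.48) (scaled to nm when the surface is). Non-convergence
  is an error carrying the last path for inspection.
* **Projection and barriers.** The path is projected onto CV1; nodes sharing
  a CV1 bin (default bin = grid spacing) keep the *minimum* F — the explicit
  tie-break — and the profile is min-shifted. The desorption barrier is the
  mean bulk-plateau F above the global minimum; the translocation barrier is
  the interpolated profile height at CV1 = 0 above the global minimum,
  evaluated there regardless of whether the centre is a local maximum.

## What the synthetic generators emulate

The generators produce inputs with exactly the statistical structure the
analyses assume:

* `gen_partition_curve()` — the partition hyperbola with multiplicative
  lognormal noise. The noise is multiplicative because fluorescence is
  strictly positive and detector/gain noise scales with signal; `noise_cv = 0`
  reproduces the forward model exactly.
* `gen_exchange_trace()` — mono/multi-exponential donor-rise or
  acceptor-decay traces; the default grid (600 points over 8 h) matches the
  slow-exchange assay geometry.
* `gen_arrhenius_series()` — Arrhenius rates over 15–37 °C with optional
  lognormal noise.
* `gen_toy_trajectory()` — a rigid solute proxy: four "N" sites in a ring
  plus an opposite "S" pair 0.51 nm from the ring centre (the fixed rigid
  geometry that also bounds $|CV1 - CV2|$), placed at Gaussian-sampled depth
  (default 1.41 ± 0.07 nm) and tilt (31 ± 4°); mirrored lipid leaflets so
  the all-lipid centre of mass sits exactly at the box midplane (delta plants
  are then recovered *exactly*); C–H bonds planted at prescribed
  $-S_{CD}$ per carbon as a function of lateral distance; waters planted at
  hydrogen-bond-true and decoy geometries; charges realising a prescribed
  dipole along the ring normal.
* `gen_hills_from_fes()` — a 2D Metropolis walker on an analytic surface
  (`analytic_fes()`: double-well, single-well, flat, valley, membrane-like),
  depositing a hill every `stride` moves. Heights stay at $h_0$ until the
  local bias exceeds the threshold and are then tempered well-tempered style,
  $h = h_0 e^{-(V - V_{thr})/((\gamma-1)k_BT)}$, mirroring
  transition-tempered deposition once a transition path exists. Deposition
  defaults are the production values: $h_0 = 0.015$ kJ/mol, σ = 0.02
  (normalized), γ = 30, threshold 10 kJ/mol, walker bath 310.15 K. Overdamped
  Metropolis dynamics is the cheapest sampler that populates CV space with
  the right stationary weights — the real system's dynamics are irrelevant to
  testing the reconstruction arithmetic. The analytic surfaces couple the
  diagonal coordinate $(cv_1+cv_2)/2$ to a stiff transverse mode whose
  stiffness (default 200 kJ/mol over the period) confines $|cv_1 - cv_2|$ to
  about the 0.05 normalized units the rigid solute geometry allows in a
  ~10 nm box.

What they deliberately do **not** emulate: real solute geometry or charges,
lipid force-field detail, aggregation kinetics, photobleaching, stopped-flow
dead time, or the μs-scale sampling of production simulations. Passing tests
therefore demonstrate that the *estimators* are correct on data obeying their
assumptions — they do not certify instrument-specific artefact handling, and
the production MD averages themselves are not reproducible at desk scale.

## Problem sizes and tolerances used in the checks

The test suite runs the pipeline at sizes chosen to make sampling error small
relative to the tolerances while staying desk-scale: 200 replicate titrations
at 3% noise for parameter-recovery medians; 200 seeded exchange traces for the
weighted-rate median; 10⁵ samples for histogram closed forms; 10⁴ orientations
for order-parameter averages; 5×10⁴–10⁵ hills on a 201² grid for the
metadynamics recovery (barriers checked within 15%, the minimum location
within 0.1 nm). The well-tempered ripple left on a flat surface after 2×10⁴
hills is bounded by kT in the tests — the expected magnitude of the residual
roughness of a converged tempered bias.

## Known limitations

* The H-bond and CV machinery assumes the solute does not span the periodic
  boundary along z; only lateral minimum-image corrections are applied (shell
  assignment), matching the intended toy and single-solute use.
* The well-tempered prefactor $\gamma/(\gamma-1)$ is an approximation for
  transition-tempered runs before tempering activates; both estimators are
  exposed, and the toy-pipeline recovery quantifies the residual error.
* `fit_exponentials()` supports one or two components — the model-selection
  rule it implements is defined for exactly that comparison.
* GRO output carries the format's native 3-decimal (pm) precision;
  coordinate round trips are exact to that precision, not to machine
  precision (HILLS and CSV round trips are).
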