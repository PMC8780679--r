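---
title: "Estimating membrane permeability from umbrella sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating membrane permeability from umbrella sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memperm)
```

## The model

`memperm` computes passive membrane permeability coefficients with the
inhomogeneous solubility–diffusion (ISD) model. The solute's position
along the bilayer normal, z (nm, zero at the hydrophobic core, negative
on the outer/extracellular side), is treated as a slow coordinate with a
free-energy profile ΔG(z) (kJ/mol) and a local diffusion coefficient
D(z) (nm²/ps). Steady-state flux across the slab gives

$$R(z) = \frac{e^{\beta \Delta G(z)}}{D(z)}, \qquad
  R_\mathrm{eff} = \int_{z_1}^{z_2} R(z)\,dz, \qquad
  P = \frac{1}{R_\mathrm{eff}},$$

with $\beta = 1/(R_\mathrm{gas} T)$. Because ΔG is molar, the "Boltzmann
constant times temperature" is the molar gas constant times temperature:
$R_\mathrm{gas} = 0.008314462618$ kJ/mol/K. P in nm/ps converts to cm/s
by the factor $10^5$ (1 nm/ps = $10^{-7}$ cm / $10^{-12}$ s); log P is
always the base-10 logarithm of P in cm/s, rounded only at report time.

The ISD model assumes Markovian, overdamped dynamics of z with local
equilibrium at each depth — adequate for small neutral solutes on the
microsecond scales of interest, but blind to memory effects, solute
reorientation kinetics and charged-species chemistry, all of which are
out of scope here.

## Free-energy estimation (WHAM)

Umbrella sampling restrains the solute near successive depths
$c_i$ with harmonic biases $w_i(z) = \tfrac{k}{2}(z - c_i)^2$. Window
histograms on a shared grid are combined by the Weighted Histogram
Analysis Method, iterating

$$\rho(z_b) = \frac{\sum_i n_i(z_b)}{\sum_i N_i f_i e^{-\beta w_i(z_b)}},
  \qquad
  f_i^{-1} = \sum_b \rho(z_b)\, e^{-\beta w_i(z_b)}\,\Delta z$$

to self-consistency; $\Delta G(z_b) = -RT\ln\rho(z_b)$. Numerical
choices, each visible in the output headers:

* **Bin width 0.02 nm**, about an eighth of the restrained thermal width
  $\sqrt{RT/k} \approx 0.16$ nm at the defaults, so the histograms are
  well resolved without starving bins.
* **Convergence**: iteration stops when the largest change in the window
  free energies $-RT\ln f_i$ falls below **1e-7 kJ/mol** (cap $10^5$
  sweeps). The WHAM equations fix $\rho$ and $f$ only up to a joint
  scale, and direct iteration drifts along that gauge direction; the
  implementation renormalises $\rho$ to unit integral each sweep, which
  pins the gauge and leaves the physically meaningful free-energy
  differences untouched. Non-convergence raises a warning and flags the
  profile rather than failing silently.
* **Empty bins are masked**, never interpolated: downstream stages
  refuse to integrate across masked bins instead of inventing free
  energies.
* **Referencing**: profiles are zeroed on the declared bulk region,
  |z| ≥ 2.0 nm by default (the solute is inserted about 2 nm from the
  head groups, so beyond that is bulk water). Referencing happens before
  smoothing; the two operations commute only approximately at truncated
  ends, and the chosen order keeps the bulk anchor defined on the raw
  estimate.
* **Smoothing**: centred moving average spanning 0.05 nm (0.5 Å),
  truncated — not padded — at the profile ends.

### Leaflet assembly

For a bilayer whose two leaflets share one composition, sampling one
leaflet suffices: the PMF on z ∈ [−2.2, 0] is mirror-duplicated,
ΔG(+z) := ΔG(−z) (`symmetrize_cancer`), and the window-wise D estimates
are mirrored the same way. For an asymmetric bilayer the two leaflets
are sampled independently; each half-profile is referenced to its own
bulk flank and the halves are concatenated with the inner half shifted
additively so the profile is continuous at z = 0. How the two
independent half-profiles should meet at the core is genuinely open —
they carry independent statistical errors — so the applied shift is
reported as `core_mismatch`, a useful convergence diagnostic in itself.

Windows restrained near the core spill samples past z = 0, so
one-leaflet histograms extend to z = +0.5 nm (keeping the lost-sample
fraction far below 1%) and the profile is cut at the core after
unbiasing.

### Uncertainty and convergence

Per-bin standard errors come from block averaging: each window is split
into 5 contiguous blocks, WHAM is solved per block, and the spread
across blocks gives the error (`pmf_block_stderr`). Convergence is
checked by re-estimating the PMF from cumulative 50/75/100% slices of
every window and reporting the largest change between successive
estimates (`check_convergence`, default threshold 1 kJ/mol).

## Position-dependent diffusivity

For a harmonically restrained coordinate the local diffusion coefficient
follows from the fluctuation statistics of the window itself:

$$D = \frac{\mathrm{var}(z)^2}{\int_0^\infty C_{zz}(t)\,dt},$$

where $C_{zz}$ is the autocovariance of z about its mean. Conventions
and choices:

* The ACF uses the **biased 1/n normalisation**, and var(z) is defined
  with the same normalisation, so $C_{zz}(0) = \mathrm{var}(z)$ exactly
  and the estimator is internally consistent. The FFT implementation is
  cross-checked in the tests against a literal double loop.
* The infinite upper limit is truncated at the **first non-positive ACF
  value** (configurable to the full tabulated range). For an
  exponentially decaying ACF with noise floor this is the usual
  bias/variance compromise: integrating further mostly accumulates
  noise. The maximum tabulated lag is 50 ps, far beyond the relaxation
  time $\tau_c = RT/(kD) \approx 0.64$ ps at the defaults.
* Each estimate is anchored at the window's **sample-mean position**,
  not its bias centre: on a tilted local PMF the window samples where
  its mean sits, and that is where the fluctuations were measured.
* Window estimates are linearly interpolated onto the PMF grid with
  constant extrapolation beyond the outermost window means — the
  simplest scheme that adds no structure the data do not contain.

On Ornstein–Uhlenbeck ground truth the estimator is exact in the
continuum limit (var = RT/k, ∫C = var·τ_c, var²/∫C = D); at the default
desk-scale trace length (16 000 saved samples) its relative error has a
median near 6%, and the test suite verifies both a 10% recovery bound
and that the error shrinks with trace length across seeds.

## The synthetic generator

The package replaces a molecular-dynamics engine with 1-D overdamped
Langevin dynamics: the analysis consumes only z time series, so any
generator with the correct stationary law and local mobility exercises
it fully. The Euler–Maruyama update of the Itô SDE

$$dz = \left[-\beta D(z)\left(\Delta G'(z) + k(z - c)\right) + D'(z)\right]dt
       + \sqrt{2D(z)\,dt}\,\xi$$

includes the spurious drift $D'(z)$, without which the stationary
density acquires a factor $1/D(z)$ and is no longer Boltzmann — the test
suite demonstrates exactly this failure mode with an exponential D(z).
Defaults: dt = 0.01 ps (safely inside the stability guard
$dt\,D\beta k < 0.1$), $2\times10^5$ steps per window, first 20%
discarded as equilibration, samples saved every 10 steps, reflecting
boundaries at the support edges (mimicking bulk water turnaround), and
per-window seeds `base_seed + window_index` for reproducible independent
streams. The window layout mirrors the umbrella protocol it stands in
for: 22 centres spaced 0.2 nm, k = 100 kJ/mol/nm², 310 K. Forces are
tabulated on a 0.001 nm grid and interpolated linearly inside the
compiled integrator; the interpolation error is orders of magnitude
below sampling noise.

What the generator does *not* emulate: force-field realism, solute
orientation, lateral heterogeneity, slow lipid relaxation (every window
starts at its bias centre; there is no pulling history), and
non-Markovian friction. Passing recovery tests therefore validates the
*analysis machinery* — unbiasing, assembly, estimators, quadrature and
units — not the physical accuracy of any particular force field.

Preset landscapes: `flat`; `gaussian_barrier` (height, width σ);
`square_barrier` (logistic shoulders of scale `steepness`, so the
gradient exists); `membrane_like` (central barrier 12 kJ/mol, interface
wells −4 kJ/mol near |z| = 1.3 nm, and a core mobility dip
D(0) = 0.02 nm²/ps against a bulk 0.04 nm²/ps). Bulk D = 0.04 nm²/ps is
a typical small-molecule aqueous diffusivity (4 × 10⁻⁶ cm²/s); barrier
and well magnitudes sit in the range typical of drug-like solutes in
phospholipid bilayers.

## Permeability integration

The resistivity integrand is evaluated on the WHAM grid and integrated
with the trapezoidal rule; at 0.02 nm resolution this matches adaptive
quadrature to better than 1% for barriers up to ~20 kJ/mol (verified in
the tests against `stats::integrate` and against the closed forms
P = D/L and the sharp-barrier limit). The integration bounds default to
the full sampled span [−2.2, 2.2] nm and are recorded in the output;
bulk flanks contribute only $L_\mathrm{bulk}/D_\mathrm{bulk}$, which is
negligible whenever a barrier dominates. The smoothed PMF feeds the
integrand by default (matching how smoothed profiles are usually
reported); `run_config(use_smoothed_pmf = FALSE)` switches to the raw
estimate.

## Structural metrics

The toy-bilayer module provides the standard sanity checks run on
equilibrated bilayers:

* **Density profiles**: mass-weighted z histograms over slabs of volume
  $L_x L_y \Delta z$, in kg/m³; by construction the profile integrates
  back to the total mass exactly.
* **Area per lipid**: lipid sites are the centroids of a triad of
  head-group atoms projected on the membrane plane; periodicity is
  handled by 3×3 image replication, each image's Voronoi cell is
  obtained by clipping the box rectangle against perpendicular
  bisectors (nearest sites first, stopping once no farther site can cut
  the cell), and in-box cell areas accrue to the owning lipid. The cells
  partition the box, so areas sum to $L_x L_y$ to machine precision — a
  property the tests assert on 100 random configurations, alongside a
  pixel-rasterisation oracle.
* **Order parameters**: $S_{CD} = -\tfrac12\langle 3\cos^2\theta - 1\rangle$
  per carbon, averaged over lipids and snapshots, with the analytic
  endpoints (−1 along the normal, +0.5 in-plane, 0 at the magic angle)
  and azimuthal invariance tested exactly.

The convention throughout: negative z is the outer (extracellular)
leaflet; in the asymmetric "normal" composition all PS sits in the inner
leaflet (outer 36 PC / 0 PS, inner 12 PC / 24 PS per 36-lipid leaflet),
while the "cancer" composition distributes PS symmetrically (24 PC /
12 PS per leaflet).

## Problem sizes and limitations

The validation suite runs at desk scale: $2\times10^5$ steps per window
(1.6 ns of 0.01 ps steps, 16 000 saved samples), 22 windows full-span or
11 per leaflet. At these sizes WHAM recovers a 10 kJ/mol Gaussian
barrier with RMS error ≈ 0.17 kJ/mol, single-window D estimates carry
~5–10% error, and end-to-end log P is recovered to within 0.1–0.3 log
units of the closed-form truth. Known limitations:

* Accumulated stitching noise across many windows tilts remote regions
  of the profile relative to one another (a random walk in the window
  free energies); with 22 windows the two bulk flanks can disagree by
  ±0.2 kJ/mol. Anchoring on both flanks at once averages this out.
* The Euler–Maruyama stationary density carries an $O(dt)$ bias
  (variance inflation $\approx \beta k D\,dt/2$, under 1% at the
  defaults); the stationarity test uses a reduced dt so the chi-square
  comparison is not confounded by discretisation.
* The first-zero ACF truncation leaves a small positive bias and a
  heavy-tailed error distribution in D; averaging over windows in the
  profile largely washes this out.
* No MBAR, no autocorrelation-corrected effective sample sizes inside
  WHAM, no memory-kernel diffusivity corrections, and no flux-based
  permeability estimators — all deliberately out of scope.
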