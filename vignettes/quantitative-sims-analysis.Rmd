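---
title: "Methods: quantitative ToF-SIMS depth profiling and 3D ion-image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative ToF-SIMS depth profiling and 3D ion-image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simsquant)
```

simsquant turns three kinds of raw ToF-SIMS output — per-cycle ion counts,
per-spot intensity tables, and stacked 2D ion images — into calibrated
quantities for a chlorinated additive in a polymer matrix. This vignette
explains the models behind each stage, the conventions and tunable
parameters, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## 1. Depth scaling and RSF calibration

### Model

Sputter depth profiling yields counts $I_i$ for cycles $i = 1..n$ and a
single crater depth $D$ measured afterwards by profilometry. Only $D$ is
known, so depths are assigned under the standard single-matrix assumption
of a constant sputter rate: cycle $i$ sits at its midpoint depth
$z_i = (i - \tfrac12)\,D/n$, with constant increment $\Delta z = D/n$.
This is exact for a homogeneous matrix and degrades gracefully for layered
ones; no crater-shape or rate-transient correction is attempted.

The relative sensitivity factor converts counts to atomic density. For an
implant standard of known areal dose $\varphi$ (atoms/cm²), conservation
of the implanted amount fixes the RSF:

$$\mathrm{RSF} = \frac{\varphi}{\Delta z_{\mathrm{cm}} \sum_i \max(I_i - B,\, 0)}$$

with $B$ the mean background count level over user-chosen trailing cycles.
Because the RSF is *defined* by this identity, converting the same profile
back through `quantify_profile()` and integrating recovers $\varphi$ to
floating-point accuracy — the dose-conservation invariant the test suite
asserts. Recovery of an independently known true RSF is limited only by
discretisation of the implant shape onto the cycle grid (below 0.1 % for
a Gaussian resolved by $\sigma/\Delta z \gtrsim 5$).

### Conventions

* **Background subtraction truncates at zero.** Concentrations are
  physical quantities; cycles where counts dip below the background
  estimate report zero, not negative, density.
* **Detection limit.** The background converts to a density as
  $\mathrm{LOD} = \mathrm{RSF}\,(B + k\,\mathrm{SD}(B))$ with $k = 3$ by
  default (`lod_sigma`); setting $k = 0$ gives the mean-only convention.
  Published LODs in this field rarely state their formula, so both are
  exposed rather than guessed at.
* **Isotopes.** A calibration is keyed by its species label; the common
  practice of assuming equal RSFs for ³⁵Cl⁻ and ³⁷Cl⁻ is left to the user
  (relabel or duplicate the calibration), not hard-coded.
* **Background window sanity check.** If the chosen background cycles
  contain the profile maximum, the calibration proceeds but warns: the
  background is then almost certainly contaminated by the implant peak.

## 2. Density to weight percent

With $n_{\mathrm{Cl}}$ chlorine atoms per analyte molecule, molar mass
$M$, and matrix density $\rho$,

$$\mathrm{wt\%} = 100\,\frac{c_{\mathrm{Cl}}}{n_{\mathrm{Cl}}}\,
\frac{M}{N_A\,\rho}.$$

Defaults — permethrin C₂₁H₂₀Cl₂O₃ ($M = 391.29$ g/mol, $n_{\mathrm{Cl}} =
2$) in HDPE ($\rho = 0.95$ g/cm³) — reproduce the 1.5×10¹⁸ atoms/cm³ ↔
0.051 wt% pairing and are the package's choice of plausible constants, not
asserted literature values; all are overridable through `matrix_model()`.
The dilute approximation (mixture density ≈ matrix density) is kept even
at percent-level loadings, consistent with using a single matrix-specific
RSF; at 2 wt% the density error is below 1 %, well under the RSF's own
matrix uncertainty.

## 3. Surface ratio statistics

Per-spot loadings are analyte/reference intensity ratios, which cancel
spot-to-spot instrumental variation. Summaries per (sample, condition)
follow the conventions of the printed tables this module mirrors:

* sample SD with the $n-1$ denominator, RSD $= 100\,s/\bar x$;
* **z-based 95 % CI**, $\bar x \pm 1.96\,s/\sqrt n$. This choice is
  deliberate: recomputing published intervals from their printed
  (mean, sd, n) reproduces them exactly under $z = 1.96$, while Student's
  $t$ (2.093 at $n = 20$) does not. The z-interval is mildly
  anti-conservative at $n = 20$; it is kept for comparability with the
  tables the package is designed to reproduce.
* median of an even-sized sample is the midpoint of the two central order
  statistics; full precision is kept internally and rounding happens only
  in display code.

Percent change versus a baseline condition is
$100(\bar x_c - \bar x_0)/\bar x_0$. No hypothesis tests are computed —
the design this mirrors reports overlapping CIs, not p-values — and no
outlier rejection is applied.

## 4. 3D intensity distribution

For a cube of integer intensities the histogram $N_x$ is exact, and the
*contribution function* $N_x x$ apportions the total signal
$\sum_x N_x x$ — proportional to total chlorine — across intensity
classes. Its normalised cumulative sum is fitted with the 3-parameter
log-logistic $y = a\,/\,(1 + (x/x_0)^{-b})$:

* the fit uses unweighted Levenberg–Marquardt least squares
  (minpack.lm) over integer levels $x \ge 1$ ($x = 0$ carries no
  intensity and the power law is undefined there);
* initialisation is deterministic — $a = 1$, $x_0$ at the empirical
  contribution median, $b = 2$ — so identical inputs give identical fits;
* $R^2 = 1 - SS_{res}/SS_{tot}$ is reported on the fitted points;
  non-convergence is an error, never a silent fallback.

Quantiles of the fitted curve solve in closed form,
$x(q) = x_0\,(1/q - 1)^{-1/b}$, after normalising by the fitted asymptote
$a$ so that $q$ is a true fraction (an unnormalised variant solving
$y(x) = q$ directly is available; with $a \ne 1$ the two differ slightly,
and both conventions appear in practice). Threshold fractions — "how much
of the Cl sits at $I \ge 50$?" — are computed on the **empirical**
histogram, not the fit: the fitted tail of a log-logistic is heavier than
typical measured tails, and empirical sums are exact where the data exist.
The fitted curve is for interpolation and compact description; the
histogram is for statements about the data.

Mode and median of the intensity distribution resolve ties to the
smallest qualifying level, for determinism.

## 5. Domain segmentation

Voxels at or above a threshold (default 50, the convention for
"high-concentration domain" in the measurements this package targets) are
grouped by **26-connectivity** — faces, edges and corners. Diffuse,
elongated domains sampled on an anisotropic grid fragment badly under
6-connectivity (voxels touching diagonally across a level boundary would
separate), so 26 is the default and 6 is available by argument. Components
are found by building the neighbour graph over above-threshold voxels
(vectorised neighbour matching, 13 forward offsets) and taking its
connected components with igraph; a hand-written flood fill serves as the
independent oracle in the tests.

All morphology is computed in physical units: lateral positions from the
pixel size, axial positions from the per-level depths, so a voxel is
typically ~0.2 µm × 0.2 µm × 0.16 µm. Per domain: centroid; eigenvectors
of the coordinate covariance give the principal axes; extents are
max–min projections onto those axes (centre-to-centre, so a single voxel
has zero extent); the orientation is the unit major-axis eigenvector with
its largest-magnitude component made positive (principal axes are
sign-ambiguous). Volume fraction uses voxel counts over the cube volume;
intensity fraction uses the domain's share of total cube intensity — the
two deliberately separate "how much space" from "how much chlorine",
which are different questions with different answers. The near-surface
report flags domains with any voxel shallower than a depth limit
(default 0.5 µm).

## 6. What the synthetic generators emulate

The generators produce data with the statistical structure the analysis
assumes, so every stage closes a parameter-recovery loop. Their defaults
are the study conditions the package is validated under, chosen once:

* **Implant profiles** (`gen_implant_profile()`): Gaussian implant of
  dose 5×10¹⁵ atoms/cm² at peak depth 200 nm, straggle 50 nm — a
  realistic shape for a ~140 keV implant into a polymer — on a flat count
  background, with optional Poisson counting noise; true RSF default
  2.2×10¹⁶ atoms/cm³ per count. Not emulated: sputter-rate transients,
  crater-edge effects, knock-in broadening.
* **Intensity cubes** (`gen_cube()`): 256 × 256 pixels over 50 µm,
  13 levels to 1.89 µm (851,968 voxels). The matrix background is
  lognormal, parameterised from its continuous **median 12 and mean
  15.04** ($\mu = \ln 12$, $\sigma^2 = 2\ln(15.04/12)$), rounded to
  integers and clipped to 0–125. Median+mean are used because the three
  published location statistics (mode 9, median 12, mean 15.04) are
  mutually inconsistent with an exact lognormal — the implied mode is
  ≈7.6 — and median+mean is the better-determined pair; the generator
  targets those two and lets the mode fall where it falls (≈8 after
  discretisation). Planted domains are non-overlapping ellipsoids with
  major semi-axes 1.5–10 µm and aspect 0.08–0.2, jittered about a common
  in-plane direction (emulating flow-oriented, micrometres-long
  inclusions), with uniform integer intensities on [50, 125].
* **Ground-truth identifiability.** When domains are planted, background
  draws are clipped just below the domain intensity floor (49 by
  default). A lognormal with median 12/mean 15.04 alone places ≈1.8 % of
  voxels at or above 50; without clipping, a "2 % planted" cube would
  contain ≈3.8 % above-threshold voxels and *no* generator parameter
  would correspond to what segmentation measures. Clipping makes the
  planted fraction the exact ground truth for validation. The cost is a
  slightly truncated background tail in planted cubes only; pure
  background cubes (`target_domain_volume_fraction = 0`) keep the full
  lognormal tail, and the tests check that tail mass against the
  closed-form lognormal.
* **Wash/regeneration series** (`gen_wash_series()`): single-compartment
  first-order blooming. Washing removes a fraction $\eta$ of the surface
  amount; incubation recovers toward a plateau $p\,m_0$ as
  $m(t) = m_w + \max(p\,m_0 - m_w, 0)(1 - e^{-kt})$. The recovery term
  is one-sided because blooming only adds material — with $\eta = 0$ all
  condition means equal the initial amount. Defaults ($m_0 = 5$,
  $\eta = 0.8$, $p = 0.75$, $k = 1$/day, lognormal location noise at
  35 % RSD, 20 locations/condition) reproduce the qualitative pattern the
  module is tested against: a large wash drop, substantial recovery by
  day 4, day 10 ≈ day 4, and between-location RSDs of a few tens of
  percent. A diffusion PDE through the fiber cross-section is
  deliberately out of scope; the observable pattern constrains only this
  level of kinetic detail.
* **Surface maps** (`gen_surface_map()`): soft-edged circular deposits of
  fixed total mass on a weak lognormal background. The covered-area
  target sets the deposit count; because mass per deposit is fixed,
  larger deposit radii spread the material thinner and the map RSD falls
  — the concentrated-fresh versus diffuse-regenerated contrast.

**What passing tests do and do not show.** The generators draw iid voxel
intensities (no lateral correlation in the matrix phase), use hard
ellipsoids (measured domains have diffuse boundaries), flat backgrounds,
and no detector saturation, topography, or charging artefacts. Recovery
on this synthetic data validates the *bookkeeping and estimators* —
conservation, segmentation, fitting, statistics — not the instrument
physics, and says nothing about matrix effects on real RSFs.

## 7. Problem sizes and numerical notes

The test suite and acceptance script run the cube analyses at the full
measurement scale (851,968 voxels; a few seconds each in plain R), with
brute-force oracle comparisons confined to cubes of ≤ 8×8×4. Domain
placement retries up to 2000 proposals and shrinks candidate ellipsoids
toward the remaining voxel budget, targeting the requested volume
fraction within 0.1 % of cube volume; infeasible requests error rather
than silently under-fill. All generators are bit-reproducible given
(spec, seed); the pipeline stages are deterministic, write through a
staging directory (a failed stage leaves no partial bundle), and log
every parameter and convention in force so that no silent defaults exist.

## 8. Known limitations

* Uniform sputter rate: layered or mixed matrices bias the depth axis.
* A single matrix-specific RSF; no matrix-effect or saturation model.
* The z-based CI is anti-conservative at small n (kept for table
  comparability; see §3).
* Log-logistic fit quality is reported, not tested against alternatives
  (the empirical route exists precisely so conclusions need not lean on
  the fit).
* The imzML instrument format is not read natively; the plain-text
  `.icube` container is the interchange format.
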