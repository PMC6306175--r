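# simsquant

Quantitative analysis of time-of-flight secondary ion mass spectrometry
(ToF-SIMS) measurements of chlorinated additives in polymer matrices —
developed around the problem of measuring permethrin insecticide on and
inside the high-density polyethylene (HDPE) fibers of long-lasting
insecticidal nets. ToF-SIMS sees only the top 1–2 monolayers per sputter
cycle, which makes it the right tool for asking how much insecticide is
*bioavailable at the fiber surface*, how it is distributed laterally and
with depth, and how the surface reservoir regenerates ("blooms") after
washing — questions total-content assays cannot answer.

The package is aimed at surface-analysis and vector-control-product
scientists who have per-cycle ion counts, per-spot intensity tables, or
3D ion-image stacks and need calibrated, reproducible numbers out of them.

## What it computes

**RSF calibration and depth profiling.** An ion-implanted standard of known
areal dose φ (atoms/cm²) calibrates the relative sensitivity factor
converting counts to atomic density. With a constant per-cycle depth
increment Δz (from the profilometer-measured crater depth D, Δz = D/n):

    RSF = φ / (Δz_cm · Σᵢ max(Iᵢ − B, 0))        [atoms/cm³ per count]

where B is the mean background count level estimated from trailing cycles.
The detection limit is `RSF · (B + 3·SD(B))`, and any test profile converts
to concentration via `cᵢ = RSF · max(Iᵢ − B, 0)` at depths `(i − ½)Δz`
(`compute_rsf()`, `quantify_profile()`).

**Stoichiometric conversion.** Chlorine atomic density ↔ analyte weight
percent under the dilute approximation, with defaults for permethrin
(C₂₁H₂₀Cl₂O₃, 391.29 g/mol, 2 Cl per molecule) in HDPE (0.95 g/cm³):
`wt% = 100 · (c_Cl/2) · M / N_A / ρ` (`cl_density_to_wtpct()`). The Cl
detection limit of 1.5×10¹⁸ atoms/cm³ converts to 0.051 wt% permethrin.

**Surface statistics.** Per-location ³⁵Cl⁻/C₄H₃⁻ intensity ratios,
summarised per (sample, condition) by median, mean, sample SD, RSD and the
z-based 95 % CI `mean ± 1.96·SD/√n`, plus percent change of each condition
mean against the sample's baseline (`wash_report()`).

**3D distribution analysis.** For an intensity cube with N_x voxels at
level x, the contribution function `N_x·x` gives each intensity class's
share of the total chlorine; its normalised cumulative sum is fitted by the
3-parameter log-logistic

    y = a / (1 + (x/x₀)^(−b))

whose quantiles solve in closed form `x(q) = x₀(1/q − 1)^(−1/b)`
(`fit_logistic()`, `solve_quantile()`). Threshold statements ("what
fraction of the Cl sits at I ≥ 50?") are computed on the empirical
histogram (`fraction_above()`). High-intensity domains are segmented as
26-connected components above a threshold, with centroids, principal-axis
extents and orientations in physical micrometres (anisotropic voxels
handled via the pixel size and per-level depths), per-domain volume and
intensity fractions, and a near-surface connectivity report
(`segment_domains()`, `surface_connectivity()`).

**Synthetic data.** Generators for every input: Gaussian implant profiles
with Poisson noise (`gen_implant_profile()`), intensity cubes with a
discretised-lognormal matrix background and planted oriented ellipsoidal
domains (`gen_cube()`), first-order wash/regeneration series
(`gen_wash_series()`), and patchy surface deposit maps
(`gen_surface_map()`). Each generator closes a parameter-recovery loop
with its analysis counterpart, which is how the package is tested without
instrument data.

## Worked example

```r
library(simsquant)

# calibrate from a synthetic implant standard (5e15 atoms/cm^2)
dp  <- gen_implant_profile(dose = 5e15, peak_depth = 200, sigma = 50,
                           n_cycles = 100, crater_depth = 1000,
                           background = 5, rsf_true = 2.2e16,
                           noise = "poisson", seed = 42)
cal <- compute_rsf(dp, dose = 5e15, background_cycles = 90:100)
cal
#> <rsf_calibration> 35Cl- in HDPE
#>   dose       5e+15 atoms/cm^2
#>   RSF        2.194e+16 atoms/cm^3 per count
#>   background 5.091 +/- 2.023 counts
#>   LOD        2.448e+17 atoms/cm^3 (mean + 3 sd)
```

The recovered RSF (2.194×10¹⁶) sits within 0.3 % of the generator's true
2.2×10¹⁶ atoms/cm³ per count; the detection limit reflects the low
synthetic background (`lod_wtpct(cal)` → 0.0084 wt%).

```r
# a 256 x 256 x 13 cube with 2% of voxels in high-intensity domains
cube <- gen_cube(cube_spec(target_domain_volume_fraction = 0.02, seed = 7))
h    <- intensity_histogram(cube)
distribution_stats(h)
#> <distribution_stats> mode 8, median 12, mean 16.13

fit <- fit_logistic(contribution_cdf(h))
fit
#> <logistic_fit> y = 0.9921 / (1 + (x/20.062)^-2.1274), R^2 = 0.9980
solve_quantile(fit, 0.5)   # intensity below which half the Cl resides
#> [1] 20.06
fraction_above(h, 50)      # empirical share of Cl in bright regions
#> [1] 0.103

seg <- segment_domains(cube, threshold = 50)
seg
#> <domain_segmentation> 7 domain(s) at intensity >= 50 (26-connectivity)
#>   total volume fraction 0.01902, total intensity fraction 0.1029
#>   largest domain: 6450 voxels, 14.7 x 2.42 x 1.64 um
surface_connectivity(seg, 0.5)
#> <surface_connectivity> 3 of 7 domain(s) reach depth < 0.5 um
```

Here segmentation recovers 1.90 vol% of the planted 2 % domain volume (the
placement tolerance, not a segmentation error), the domains are strongly
oriented and micrometres long, and — although they occupy ~2 % of the
volume — they carry ~10 % of the chlorine; the other 90 % is dissolved
throughout the matrix. That contrast between a dilute dissolved phase and
sparse concentrated domains is the signature of a monolithic
sustained-release device.

End-to-end runs (calibrate → quantify → surface stats → cube analysis)
are driven by a single YAML config through `run_pipeline()`, which writes
CSV/JSON reports, a parameter log and an input-checksum manifest; a thin
command-line wrapper is installed at `inst/cli/simsquant`.

## File formats

- **Depth profiles / spot tables** — comma- or tab-delimited text with a
  header; one species column per profile, one row per sputter cycle
  (columns `sample_id, condition, location_id, analyte_intensity,
  reference_intensity` for spot tables).
- **Ion cubes (`.icube`)** — single text file: line 1 the magic `#ICUBE 1`,
  line 2 a JSON object with `species_label`, `pixel_size` (µm),
  `level_depths` (µm) and `dim` (rows, cols, levels), then one
  whitespace-separated line of row-major integers per sputter level.
  Integer rasters and metadata round-trip losslessly.

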