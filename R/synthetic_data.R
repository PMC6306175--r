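#' Synthetic implant-standard depth profile
#'
#' Emulates the depth profile of an ion-implanted calibration standard: a
#' Gaussian concentration-depth profile of known areal dose, converted to
#' per-cycle counts through a known true sensitivity factor, plus a flat
#' count background and optional Poisson counting noise. With zero noise
#' and zero background, [compute_rsf()] on the output recovers `rsf_true`
#' up to discretisation of the Gaussian onto the cycle grid.
#'
#' @param dose Implanted areal dose in atoms/cm^2.
#' @param peak_depth Depth of the implant peak in nm.
#' @param sigma Gaussian straggle (standard deviation) in nm.
#' @param n_cycles Number of sputter cycles.
#' @param crater_depth Total crater depth in nm; the peak must lie well
#'   inside it (`peak_depth + 3 * sigma < crater_depth`).
#' @param background Constant background count level (default 0).
#' @param rsf_true True sensitivity factor in atoms/cm^3 per count.
#' @param noise `"none"` (default) or `"poisson"`.
#' @param seed Optional integer seed (sets the RNG when noise is used).
#' @return A [depth_profile].
#' @export
gen_implant_profile <- function(dose, peak_depth, sigma, n_cycles,
                                crater_depth, background = 0,
                                rsf_true = 2.2e16,
                                noise = c("none", "poisson"),
                                seed = NULL) {
  noise <- match.arg(noise)
  if (dose < 0) stopf("'dose' must be >= 0")
  if (peak_depth + 3 * sigma >= crater_depth)
    stopf("implant peak truncated by crater: need peak_depth + 3*sigma < crater_depth")
  if (!is.null(seed)) set.seed(seed)
  z <- ((seq_len(n_cycles) - 0.5) / n_cycles) * crater_depth   # nm
  # concentration atoms/cm^3: areal dose x per-depth density (1/nm -> 1/cm)
  conc <- dose * stats::dnorm(z, mean = peak_depth, sd = sigma) * 1e7
  counts <- conc / rsf_true + background
  if (noise == "poisson") counts <- stats::rpois(n_cycles, counts)
  depth_profile(counts, crater_depth, species_label = "35Cl-",
                sputter_params = sprintf(
                  "synthetic implant: dose %.3g, peak %g nm, sigma %g nm",
                  dose, peak_depth, sigma))
}

# ---------------------------------------------------------------------------
# Intensity cubes

#' Specification for a synthetic ion cube
#'
#' Describes the two-population intensity model the cube generator draws
#' from: a matrix background whose intensities follow a lognormal law
#' discretised to integers (parameterised by its continuous median and
#' mean: `mu = log(median)`, `sigma^2 = 2 * log(mean / median)`), plus an
#' optional sparse population of oriented high-intensity ellipsoidal
#' domains emulating phase-separated analyte-rich regions.
#'
#' Defaults reproduce the measurement geometry this analysis was designed
#' around: a 256 x 256 scan of a 50 um field at 13 sputter levels reaching
#' 1.89 um, background median 12 and mean 15.04, intensities clipped to
#' 0-125.
#'
#' @param shape `c(rows, cols, levels)`.
#' @param pixel_size Lateral pixel size in um.
#' @param level_spacing Depth increment between sputter levels in um; level
#'   depths are `0, level_spacing, ..., (levels - 1) * level_spacing`.
#' @param bg_median,bg_mean Median and mean of the continuous lognormal
#'   background law (`bg_mean > bg_median` required for a positive
#'   variance).
#' @param x_max Clip ceiling for intensities (default 125).
#' @param target_domain_volume_fraction Fraction of voxels to cover with
#'   planted domains (0 for a pure background cube; at most 0.5).
#' @param domain_intensity_range Integer range for domain voxel
#'   intensities, default `c(50, 125)`.
#' @param domain_major_um Range of the major *semi*-axis length in um for
#'   auto-placed ellipsoids.
#' @param domain_aspect Range of minor/major semi-axis ratios.
#' @param domain_orientation Mean in-plane orientation (unit 3-vector) of
#'   the major axes; placed domains jitter around it.
#' @param orientation_jitter_deg Standard deviation (degrees) of the
#'   in-plane jitter applied to each domain's orientation.
#' @param seed Integer seed; generation is reproducible given the spec.
#' @return An object of class `cube_spec`.
#' @seealso [gen_cube()]
#' @export
cube_spec <- function(shape = c(256, 256, 13),
                      pixel_size = 50 / 256,
                      level_spacing = 1.89 / 12,
                      bg_median = 12, bg_mean = 15.04, x_max = 125,
                      target_domain_volume_fraction = 0,
                      domain_intensity_range = c(50, 125),
                      domain_major_um = c(1.5, 10),
                      domain_aspect = c(0.08, 0.2),
                      domain_orientation = c(1, 0, 0),
                      orientation_jitter_deg = 10,
                      seed = 1L) {
  if (length(shape) != 3L || any(shape < 1))
    stopf("'shape' must be c(rows, cols, levels), all >= 1")
  if (bg_mean <= bg_median)
    stopf("'bg_mean' must exceed 'bg_median' for a lognormal law")
  f <- target_domain_volume_fraction
  if (!is_number(f) || f < 0 || f > 0.5)
    stopf("'target_domain_volume_fraction' must lie in [0, 0.5]")
  if (domain_intensity_range[1L] > domain_intensity_range[2L] ||
      domain_intensity_range[2L] > x_max)
    stopf("'domain_intensity_range' must be increasing and within x_max")
  u <- domain_orientation / sqrt(sum(domain_orientation^2))
  structure(
    list(shape = as.integer(shape), pixel_size = pixel_size,
         level_spacing = level_spacing, bg_median = bg_median,
         bg_mean = bg_mean, x_max = as.integer(x_max),
         target_domain_volume_fraction = f,
         domain_intensity_range = as.integer(domain_intensity_range),
         domain_major_um = domain_major_um, domain_aspect = domain_aspect,
         domain_orientation = u,
         orientation_jitter_deg = orientation_jitter_deg,
         seed = as.integer(seed)),
    class = "cube_spec")
}

lognormal_params <- function(median, mean) {
  list(mu = log(median), sigma = sqrt(2 * log(mean / median)))
}

# Rasterise one ellipsoid onto the voxel grid; returns linear indices.
# centre in um, semi_axes c(a, b, c) um (a along 'u'), u unit major axis.
ellipsoid_voxels <- function(centre, semi_axes, u, shape, pixel_size,
                             level_depths) {
  # orthonormal frame around u (deterministic)
  helper <- if (abs(u[3L]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- pracma_cross(u, helper); v <- v / sqrt(sum(v^2))
  w <- pracma_cross(u, v)
  rmax <- max(semi_axes)
  cols <- which(abs((seq_len(shape[2L]) - 0.5) * pixel_size - centre[1L]) <= rmax)
  rows <- which(abs((seq_len(shape[1L]) - 0.5) * pixel_size - centre[2L]) <= rmax)
  levs <- which(abs(level_depths - centre[3L]) <= rmax)
  if (!length(cols) || !length(rows) || !length(levs)) return(integer(0))
  g <- expand.grid(r = rows, c = cols, l = levs)
  dx <- (g$c - 0.5) * pixel_size - centre[1L]
  dy <- (g$r - 0.5) * pixel_size - centre[2L]
  dz <- level_depths[g$l] - centre[3L]
  pu <- dx * u[1L] + dy * u[2L] + dz * u[3L]
  pv <- dx * v[1L] + dy * v[2L] + dz * v[3L]
  pw <- dx * w[1L] + dy * w[2L] + dz * w[3L]
  inside <- (pu / semi_axes[1L])^2 + (pv / semi_axes[2L])^2 +
    (pw / semi_axes[3L])^2 <= 1
  if (!any(inside)) return(integer(0))
  g <- g[inside, , drop = FALSE]
  g$r + (g$c - 1L) * shape[1L] + (g$l - 1L) * shape[1L] * shape[2L]
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Generate a synthetic ion cube
#'
#' Draws background intensities from the spec's discretised lognormal and,
#' if a positive domain volume fraction is requested, plants non-overlapping
#' oriented ellipsoidal domains until that fraction of voxels is covered
#' (within a small placement tolerance). Domain voxels receive uniform
#' integer intensities from `domain_intensity_range`.
#'
#' When domains are planted, background draws are clipped just below the
#' domain intensity floor so that "voxels at or above the domain floor" is
#' exactly the planted ground truth; this makes the generator usable as a
#' segmentation validation standard with an identifiable answer. A pure
#' background cube (`target_domain_volume_fraction = 0`) keeps the full
#' lognormal upper tail.
#'
#' @param spec A [cube_spec].
#' @return An [ion_cube]. The attribute `"planted"` carries the generated
#'   ground truth: a list with `volume_fraction`, `voxel_count`, and a
#'   per-domain data frame (`centre`, `semi_axes`, `orientation`).
#' @export
gen_cube <- function(spec) {
  stopifnot(inherits(spec, "cube_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  n <- prod(d)
  lp <- lognormal_params(spec$bg_median, spec$bg_mean)
  bg <- round(stats::rlnorm(n, lp$mu, lp$sigma))
  bg <- pmin(pmax(bg, 0), spec$x_max)
  level_depths <- (seq_len(d[3L]) - 1L) * spec$level_spacing

  planted <- list(volume_fraction = 0, voxel_count = 0L,
                  domains = data.frame())
  if (spec$target_domain_volume_fraction > 0) {
    floor_int <- spec$domain_intensity_range[1L]
    bg <- pmin(bg, floor_int - 1L)   # ground truth identifiability
    target <- round(spec$target_domain_volume_fraction * n)
    tol <- max(1L, round(0.001 * n))
    occupied <- rep(FALSE, n)
    placed <- 0L
    doms <- list()
    tries <- 0L
    max_tries <- 2000L
    extent <- c(d[2L] * spec$pixel_size, d[1L] * spec$pixel_size,
                max(level_depths))
    while (placed < target - tol && tries < max_tries) {
      tries <- tries + 1L
      a <- stats::runif(1, spec$domain_major_um[1L], spec$domain_major_um[2L])
      asp <- stats::runif(2, spec$domain_aspect[1L], spec$domain_aspect[2L])
      semi <- c(a, a * asp)
      # shrink toward the remaining budget so the last domains can fit
      vox_vol <- spec$pixel_size^2 * spec$level_spacing
      est <- 4 / 3 * pi * prod(semi) / vox_vol
      remaining <- target - placed
      if (est > remaining) semi <- semi * (remaining / est)^(1 / 3)
      # jittered in-plane orientation around the spec direction
      ang <- atan2(spec$domain_orientation[2L], spec$domain_orientation[1L]) +
        stats::rnorm(1, 0, spec$orientation_jitter_deg * pi / 180)
      u <- c(cos(ang), sin(ang), 0)
      centre <- c(stats::runif(1, 0, extent[1L]),
                  stats::runif(1, 0, extent[2L]),
                  stats::runif(1, 0.15 * extent[3L], 0.95 * extent[3L]))
      vox <- ellipsoid_voxels(centre, semi, u, d, spec$pixel_size,
                              level_depths)
      if (length(vox) < 8L) next
      if (any(occupied[vox])) next
      if (placed + length(vox) > target + tol) next
      occupied[vox] <- TRUE
      placed <- placed + length(vox)
      doms[[length(doms) + 1L]] <- data.frame(
        centre_x_um = centre[1L], centre_y_um = centre[2L],
        centre_z_um = centre[3L], semi_a_um = semi[1L],
        semi_b_um = semi[2L], semi_c_um = semi[3L],
        orient_x = u[1L], orient_y = u[2L], orient_z = u[3L],
        voxel_count = length(vox))
    }
    if (placed < target - tol)
      stopf("could not place %.3g%% domain volume without overlap after %d proposals (reached %.3g%%)",
            100 * spec$target_domain_volume_fraction, max_tries,
            100 * placed / n)
    vox_all <- which(occupied)
    bg[vox_all] <- sample(
      spec$domain_intensity_range[1L]:spec$domain_intensity_range[2L],
      length(vox_all), replace = TRUE)
    planted <- list(volume_fraction = placed / n, voxel_count = placed,
                    domains = do.call(rbind, c(doms, make.row.names = FALSE)))
  }
  cube <- ion_cube(array(as.integer(bg), dim = d),
                   pixel_size = spec$pixel_size,
                   level_depths = level_depths,
                   species_label = "35Cl- (synthetic)")
  attr(cube, "planted") <- planted
  cube
}

# ---------------------------------------------------------------------------
# Wash / regeneration series

#' Specification of a wash/regeneration (blooming) series
#'
#' Single-compartment first-order kinetics for additive blooming: washing
#' removes a fraction of the surface amount; during incubation the surface
#' recovers from the subsurface reservoir toward a plateau,
#' `m(t) = m_washed + (plateau - m_washed) * (1 - exp(-transfer_rate * t))`.
#' Per-location measurements scatter around the condition mean with
#' multiplicative lognormal noise of the stated relative standard
#' deviation.
#'
#' Defaults emulate the observed pattern: a large drop after washing,
#' substantial recovery by 4 days that is essentially complete (day 10 ~
#' day 4), and between-location RSDs of a few tens of percent.
#'
#' @param initial_surface_amount Mean initial surface ratio (arbitrary
#'   units; ratios are dimensionless).
#' @param wash_efficiency Fraction of the surface amount removed by a wash.
#' @param plateau_fraction_of_initial Recovery plateau as a fraction of the
#'   initial amount.
#' @param transfer_rate First-order surface-recovery rate in 1/day.
#' @param noise_rsd Relative standard deviation of per-location noise, in
#'   percent.
#' @param n_locations Locations measured per condition.
#' @param seed Integer seed.
#' @return An object of class `bloom_spec`.
#' @export
bloom_spec <- function(initial_surface_amount = 5.0,
                       wash_efficiency = 0.8,
                       plateau_fraction_of_initial = 0.75,
                       transfer_rate = 1.0,
                       noise_rsd = 35,
                       n_locations = 20L,
                       seed = 1L) {
  if (wash_efficiency < 0 || wash_efficiency > 1)
    stopf("'wash_efficiency' must lie in [0, 1]")
  if (plateau_fraction_of_initial < 0 || plateau_fraction_of_initial > 1)
    stopf("'plateau_fraction_of_initial' must lie in [0, 1]")
  if (transfer_rate < 0) stopf("'transfer_rate' must be >= 0")
  if (noise_rsd < 0) stopf("'noise_rsd' must be >= 0")
  structure(
    list(initial_surface_amount = initial_surface_amount,
         wash_efficiency = wash_efficiency,
         plateau_fraction_of_initial = plateau_fraction_of_initial,
         transfer_rate = transfer_rate, noise_rsd = noise_rsd,
         n_locations = as.integer(n_locations), seed = as.integer(seed)),
    class = "bloom_spec")
}

#' Condition means implied by a bloom specification
#'
#' @param spec A [bloom_spec].
#' @param days Incubation times in days for the incubated conditions
#'   (default `c(4, 10)`).
#' @return Named numeric vector of the noise-free condition means.
#' @export
bloom_means <- function(spec, days = c(4, 10)) {
  stopifnot(inherits(spec, "bloom_spec"))
  m0 <- spec$initial_surface_amount
  washed <- m0 * (1 - spec$wash_efficiency)
  plateau <- m0 * spec$plateau_fraction_of_initial
  # blooming only adds material: no decay toward a plateau below the
  # current surface amount
  inc <- washed + max(plateau - washed, 0) *
    (1 - exp(-spec$transfer_rate * days))
  stats::setNames(c(m0, washed, inc),
                  c("initial", "washed",
                    sprintf("incubated_%dd", as.integer(days))))
}

#' Generate a synthetic wash/regeneration spot table
#'
#' @param spec A [bloom_spec].
#' @param sample_id Sample label for the generated records.
#' @return A [spot_table] with conditions `initial`, `washed`,
#'   `incubated_4d`, `incubated_10d`, `n_locations` records each; the
#'   reference intensity is 1, so ratios equal the analyte intensities.
#' @export
gen_wash_series <- function(spec, sample_id = "S1") {
  stopifnot(inherits(spec, "bloom_spec"))
  set.seed(spec$seed)
  means <- bloom_means(spec)
  r <- spec$noise_rsd / 100
  sig2 <- log(1 + r^2)                     # lognormal with unit mean
  n <- spec$n_locations
  recs <- lapply(names(means), function(cond) {
    noise <- stats::rlnorm(n, -sig2 / 2, sqrt(sig2))
    data.frame(sample_id = sample_id, condition = cond,
               location_id = seq_len(n),
               analyte_intensity = means[[cond]] * noise,
               reference_intensity = 1)
  })
  spot_table(do.call(rbind, recs))
}

# ---------------------------------------------------------------------------
# Patchy surface maps

#' Generate a patchy synthetic surface map
#'
#' Emulates the discontinuous, pooled appearance of an additive bloomed
#' onto a surface: soft-edged circular deposits of fixed total mass are
#' scattered on a weak lognormal background. `patch_density` sets the
#' target fraction of the field covered by deposits; `patch_scale` sets
#' the deposit radius in pixels. Because each deposit carries the same
#' mass, larger `patch_scale` spreads the material thinner, so the map's
#' intensity RSD falls as the deposit scale grows (diffuse regenerated
#' deposits versus concentrated fresh ones).
#'
#' @param shape `c(rows, cols)` of the map.
#' @param patch_density Target covered-area fraction in \[0, 0.5\]
#'   (0 gives a uniform low-intensity map).
#' @param patch_scale Deposit radius in pixels.
#' @param seed Integer seed.
#' @param patch_mass Total counts deposited per patch.
#' @param bg_median,bg_mean Background lognormal parameters.
#' @return A single-level [ion_cube]. The attribute `"patch_amplitude"`
#'   records the central intensity of one deposit.
#' @export
gen_surface_map <- function(shape = c(256, 256), patch_density = 0.1,
                            patch_scale = 6, seed = 1L,
                            patch_mass = 2000,
                            bg_median = 2, bg_mean = 2.2) {
  if (length(shape) != 2L || any(shape < 1))
    stopf("'shape' must be c(rows, cols)")
  if (patch_density < 0 || patch_density > 0.5)
    stopf("'patch_density' must lie in [0, 0.5]")
  if (patch_scale <= 0) stopf("'patch_scale' must be positive")
  set.seed(seed)
  n <- prod(shape)
  lp <- lognormal_params(bg_median, bg_mean)
  field <- matrix(pmax(round(stats::rlnorm(n, lp$mu, lp$sigma)), 0),
                  nrow = shape[1L])
  amp <- patch_mass / (pi * patch_scale^2)
  # a deposit covers pi * (1.1 r)^2 at or above half its central amplitude
  # (the cosine edge rolls through 0.5 at 1.1 r)
  n_patches <- round(patch_density * n / (pi * (1.1 * patch_scale)^2))
  if (n_patches > 0) {
    cx <- stats::runif(n_patches, 1, shape[2L])
    cy <- stats::runif(n_patches, 1, shape[1L])
    rows <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    cols <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
    deposit <- matrix(0, shape[1L], shape[2L])
    for (k in seq_len(n_patches)) {
      d2 <- (rows - cy[k])^2 + (cols - cx[k])^2
      # soft-edged disk: full amplitude inside r, cosine rolloff to 1.2 r
      r <- patch_scale
      wgt <- ifelse(d2 <= r^2, 1,
                    ifelse(d2 <= (1.2 * r)^2,
                           0.5 * (1 + cos(pi * (sqrt(d2) - r) / (0.2 * r))),
                           0))
      deposit <- deposit + amp * wgt
    }
    field <- field + round(deposit)
  }
  cube <- ion_cube(array(as.integer(field), dim = c(shape, 1L)),
                   pixel_size = 50 / 256, level_depths = 0.001,
                   species_label = "35Cl- (synthetic surface)")
  attr(cube, "patch_amplitude") <- amp
  cube
}
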