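test_that("generators are bit-reproducible given spec and seed", {
  s <- cube_spec(shape = c(24, 24, 6), target_domain_volume_fraction = 0.02,
                 seed = 77)
  expect_identical(gen_cube(s)$intensities, gen_cube(s)$intensities)

  b <- bloom_spec(seed = 13)
  expect_identical(gen_wash_series(b)$analyte_intensity,
                   gen_wash_series(b)$analyte_intensity)

  p1 <- gen_implant_profile(5e15, 200, 50, 60, 600, background = 5,
                            noise = "poisson", seed = 4)
  p2 <- gen_implant_profile(5e15, 200, 50, 60, 600, background = 5,
                            noise = "poisson", seed = 4)
  expect_identical(p1$counts, p2$counts)

  m1 <- gen_surface_map(c(48, 48), 0.1, 4, seed = 8)
  m2 <- gen_surface_map(c(48, 48), 0.1, 4, seed = 8)
  expect_identical(m1$intensities, m2$intensities)
})

test_that("noise-free implant profiles close the calibration loop", {
  dp <- gen_implant_profile(dose = 5e15, peak_depth = 200, sigma = 50,
                            n_cycles = 100, crater_depth = 1000,
                            background = 0, rsf_true = 2.2e16)
  cal <- compute_rsf(dp, dose = 5e15, background_cycles = 95:100)
  expect_lt(abs(cal$rsf - 2.2e16) / 2.2e16, 1e-3)

  expect_error(gen_implant_profile(5e15, 400, 80, 50, 500),
               "truncated")

  flat <- gen_implant_profile(dose = 0, peak_depth = 100, sigma = 20,
                              n_cycles = 40, crater_depth = 400,
                              background = 12)
  expect_equal(unique(flat$counts), 12)
})

test_that("Poisson-noise implant calibrations are unbiased", {
  recovered <- vapply(1:10, function(s) {
    dp <- gen_implant_profile(dose = 5e15, peak_depth = 200, sigma = 50,
                              n_cycles = 60, crater_depth = 600,
                              background = 10, rsf_true = 2.2e16,
                              noise = "poisson", seed = s)
    cal <- compute_rsf(dp, dose = 5e15, background_cycles = 55:60)
    # recovered dose under the true sensitivity factor
    dz_cm <- (600 / 60) * 1e-7
    2.2e16 * sum(pmax(dp$counts - cal$background_mean, 0)) * dz_cm
  }, numeric(1))
  se <- stats::sd(recovered) / sqrt(length(recovered))
  expect_lt(abs(mean(recovered) - 5e15), 3 * se + 1e-12 * 5e15)
})

test_that("background-only cubes reproduce the lognormal tail mass", {
  s <- cube_spec(shape = c(96, 96, 13), seed = 55)
  h <- intensity_histogram(gen_cube(s))
  frac <- sum(h$counts[h$intensities >= 50]) / h$total_voxels
  mu <- log(12); sig <- sqrt(2 * log(15.04 / 12))
  expected <- stats::plnorm(49.5, mu, sig, lower.tail = FALSE)
  mc_sd <- sqrt(expected * (1 - expected) / h$total_voxels)
  expect_lt(abs(frac - expected), 5 * mc_sd)
})

test_that("measurement-scale background cubes hit the target mean intensity", {
  s <- cube_spec(seed = 56)     # 256 x 256 x 13 defaults
  ds <- distribution_stats(intensity_histogram(gen_cube(s)))
  expect_lt(abs(ds$mean - 15.04), 0.1)
  expect_equal(ds$median, 12)
})

test_that("planted domains are recovered exactly by thresholding", {
  s <- cube_spec(shape = c(96, 96, 13), target_domain_volume_fraction = 0.02,
                 domain_major_um = c(1, 4), seed = 57)
  cube <- gen_cube(s)
  planted <- attr(cube, "planted")
  expect_gt(planted$volume_fraction, 0.019)
  expect_lt(planted$volume_fraction, 0.021)
  seg <- segment_domains(cube, threshold = 50)
  expect_equal(sum(seg$domains$voxel_count), planted$voxel_count)
  expect_gte(seg$n_domains, 1L)
  # all domain voxels carry domain-range intensities
  expect_true(all(cube$intensities[cube$intensities >= 50] <= 125))
})

test_that("recovered domain orientations align with the planted axis", {
  s <- cube_spec(shape = c(128, 128, 13),
                 target_domain_volume_fraction = 0.015,
                 domain_major_um = c(4, 8), domain_aspect = c(0.08, 0.12),
                 orientation_jitter_deg = 0, seed = 58)
  cube <- gen_cube(s)
  seg <- segment_domains(cube, threshold = 50)
  dm <- seg$domains
  elongated <- dm$axis1_um > 3 * dm$axis2_um & dm$voxel_count > 50
  expect_gt(sum(elongated), 0)
  u <- s$domain_orientation
  dots <- abs(dm$orient_x[elongated] * u[1] + dm$orient_y[elongated] * u[2] +
                dm$orient_z[elongated] * u[3])
  expect_true(all(dots > 0.95))
})

test_that("wash series follow the first-order blooming kinetics", {
  # no wash: all condition means equal the initial amount
  s0 <- bloom_spec(wash_efficiency = 0, noise_rsd = 0, seed = 2)
  tab0 <- intensity_ratio(gen_wash_series(s0))
  expect_true(all(abs(tab0$ratio - 5) < 1e-12))

  # fast transfer: the plateau is reached by day 4
  fast <- bloom_spec(transfer_rate = 2, noise_rsd = 0, seed = 3)
  m <- bloom_means(fast)
  expect_lt(abs(m[["incubated_10d"]] - m[["incubated_4d"]]) /
              m[["incubated_4d"]], 0.02)

  # closed form of the recovery curve
  sp <- bloom_spec(initial_surface_amount = 5, wash_efficiency = 0.8,
                   plateau_fraction_of_initial = 0.75, transfer_rate = 1)
  mm <- bloom_means(sp)
  expect_equal(mm[["initial"]], 5)
  expect_equal(mm[["washed"]], 1)
  expect_equal(mm[["incubated_4d"]], 1 + 2.75 * (1 - exp(-4)))
  expect_equal(mm[["incubated_10d"]], 1 + 2.75 * (1 - exp(-10)))
})

test_that("wash-series noise lands in the observed dispersion band", {
  spec <- bloom_spec(noise_rsd = 35, n_locations = 20, seed = 99)
  rep1 <- wash_report(gen_wash_series(spec))
  expect_true(all(rep1$stats$rsd_pct > 18 & rep1$stats$rsd_pct < 55))
})

test_that("surface maps are patchy in proportion to the requested density", {
  flat <- gen_surface_map(c(64, 64), patch_density = 0, patch_scale = 5,
                          seed = 1)
  expect_lt(max(flat$intensities), 50)

  m <- gen_surface_map(c(256, 256), patch_density = 0.1, patch_scale = 6,
                       seed = 12)
  amp <- attr(m, "patch_amplitude")
  frac <- mean(m$intensities >= amp / 2)
  expect_lt(abs(frac - 0.1) / 0.1, 0.2)
})

test_that("larger patch scales give more diffuse (lower RSD) maps", {
  rsd_at <- function(scale) {
    mean(vapply(1:5, function(s) {
      v <- as.numeric(gen_surface_map(c(128, 128), 0.1, scale,
                                      seed = s)$intensities)
      stats::sd(v) / mean(v)
    }, numeric(1)))
  }
  r <- vapply(c(3, 6, 12), rsd_at, numeric(1))
  expect_true(all(diff(r) < 0))
})
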