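test_that("histograms tally voxels exactly", {
  zero <- make_cube(array(0L, dim = c(3, 4, 2)))
  h0 <- intensity_histogram(zero)
  expect_equal(h0$counts[1], 24)
  expect_equal(h0$total_voxels, 24)
  expect_equal(h0$total_intensity, 0)

  set.seed(31)
  arr <- array(sample(0:12, 5 * 5 * 2, replace = TRUE), dim = c(5, 5, 2))
  h <- intensity_histogram(make_cube(arr))
  brute <- vapply(h$intensities, function(x) sum(arr == x), numeric(1))
  expect_equal(h$counts, brute)
  expect_equal(h$total_voxels, 50)
  expect_equal(h$total_intensity, sum(arr))
  expect_equal(sum(h$counts), h$total_voxels)
})

test_that("mode, median and mean follow the stated tie-break conventions", {
  h <- as_intensity_histogram(c(1, 3), intensities = c(0L, 10L))
  ds <- distribution_stats(h)
  expect_equal(ds$mode, 10)
  expect_equal(ds$median, 10)
  expect_equal(ds$mean, 7.5)

  single <- as_intensity_histogram(1, intensities = 7L)
  ds1 <- distribution_stats(single)
  expect_equal(c(ds1$mode, ds1$median, ds1$mean), c(7, 7, 7))

  # ties resolve to the smallest qualifying level
  tied <- as_intensity_histogram(c(2, 2), intensities = c(3L, 9L))
  expect_equal(distribution_stats(tied)$mode, 3)
  expect_equal(distribution_stats(tied)$median, 3)
})

test_that("the contribution CDF is normalised, monotone, and exact", {
  h1 <- as_intensity_histogram(10, intensities = 1L)
  cdf1 <- contribution_cdf(h1)
  expect_equal(cdf1$cumulative_fraction[cdf1$x == 1], 1)

  h2 <- as_intensity_histogram(c(10, 10), intensities = c(1L, 3L))
  cdf2 <- contribution_cdf(h2)
  expect_equal(cdf2$cumulative_fraction[cdf2$x == 1], 0.25)  # 10 / 40
  expect_equal(cdf2$cumulative_fraction[cdf2$x == 3], 1)

  set.seed(32)
  arr <- array(sample(0:40, 8 * 8 * 4, replace = TRUE), dim = c(8, 8, 4))
  h <- intensity_histogram(make_cube(arr))
  cdf <- contribution_cdf(h)
  expect_true(all(diff(cdf$cumulative_fraction) >= 0))
  expect_equal(cdf$cumulative_fraction[nrow(cdf)], 1)

  expect_error(contribution_cdf(intensity_histogram(
    make_cube(array(0L, dim = c(2, 2, 1))))), "zero")
})

test_that("empirical threshold fractions agree with hand arithmetic", {
  h <- as_intensity_histogram(c(10, 10), intensities = c(1L, 3L))
  expect_equal(fraction_above(h, 0), 1)
  expect_equal(fraction_above(h, 2), 0.75)   # 30 / 40
  expect_equal(fraction_above(h, 4), 0)
})

test_that("fraction above t and the CDF below t partition the signal", {
  set.seed(33)
  arr <- array(sample(0:60, 6 * 6 * 3, replace = TRUE), dim = c(6, 6, 3))
  h <- intensity_histogram(make_cube(arr))
  cdf <- contribution_cdf(h)
  for (t in 1:60) {
    below <- cdf$cumulative_fraction[cdf$x == t - 1]
    expect_equal(fraction_above(h, t) + below, 1)
  }
})

test_that("the log-logistic fit recovers exact curve parameters", {
  a <- 1.0089; x0 <- 17.990; b <- 2.3693
  x <- 1:125
  cdf <- data.frame(x = x, cumulative_fraction = a / (1 + (x / x0)^(-b)))
  fit <- fit_logistic(cdf)
  expect_lt(abs(fit$a - a) / a, 1e-6)
  expect_lt(abs(fit$x0 - x0) / x0, 1e-6)
  expect_lt(abs(fit$b - b) / b, 1e-6)
  expect_gt(fit$r2, 1 - 1e-10)
  # logistic midpoint identity: y(x0) = a / 2
  expect_equal(logistic_eval(fit, fit$x0), fit$a / 2)
})

test_that("fitting requires enough informative points", {
  expect_error(fit_logistic(data.frame(x = 0:2,
                                       cumulative_fraction = c(0, .5, 1))),
               "at least 4")
})

test_that("quantile solves invert the fitted curve in closed form", {
  fit <- list(a = 1.0089, x0 = 17.990, b = 2.3693)
  expect_equal(solve_quantile(fit, 0.5), fit$x0)
  # bisection oracle over random parameter draws
  set.seed(34)
  for (i in 1:20) {
    f <- list(a = 1, x0 = stats::runif(1, 5, 60),
              b = stats::runif(1, 0.8, 5))
    q <- stats::runif(1, 0.05, 0.95)
    xq <- solve_quantile(f, q)
    bisect <- stats::uniroot(function(x) 1 / (1 + (x / f$x0)^(-f$b)) - q,
                             c(1e-6, 1e6), tol = 1e-12)$root
    expect_equal(xq, bisect, tolerance = 1e-9)
  }
  # the unnormalized convention solves y(x) = q directly
  x_raw <- solve_quantile(fit, 0.5, normalized = FALSE)
  expect_equal(fit$a / (1 + (x_raw / fit$x0)^(-fit$b)), 0.5,
               tolerance = 1e-12)
  expect_lt(x_raw, fit$x0)   # a > 1 pulls the raw-curve median down
  expect_error(solve_quantile(fit, 1.2), "inside")
})

test_that("segmentation finds exactly the constructed domains", {
  arr <- array(0L, dim = c(12, 12, 6))
  arr[2:4, 2:5, 2:3] <- 60L     # 3 x 4 x 2 = 24 voxels
  arr[8:9, 8:9, 5] <- 80L       # 2 x 2 x 1 = 4 voxels
  arr[12, 1, 6] <- 125L         # single voxel
  cube <- make_cube(arr)
  seg <- segment_domains(cube, threshold = 50)
  expect_equal(seg$n_domains, 3L)
  expect_equal(sort(seg$domains$voxel_count), c(1, 4, 24))
  expect_equal(sum(seg$domains$voxel_count), sum(arr >= 50))
  expect_equal(seg$domains$voxel_count[1], 24)   # labels by size
  # volume and intensity bookkeeping
  expect_equal(sum(seg$domains$volume_fraction), 29 / prod(dim(arr)))
  expect_equal(sum(seg$domains$intensity_fraction),
               sum(arr[arr >= 50]) / sum(arr))

  none <- segment_domains(make_cube(array(1L, dim = c(4, 4, 2))), 50)
  expect_equal(none$n_domains, 0L)
  expect_equal(nrow(none$domains), 0L)
})

test_that("graph-based labelling matches a brute-force flood fill", {
  set.seed(35)
  for (i in 1:8) {
    d <- c(sample(4:8, 1), sample(4:8, 1), sample(2:4, 1))
    arr <- array(sample(0:9, prod(d), replace = TRUE), dim = d)
    cube <- make_cube(arr)
    for (conn in c(26, 6)) {
      seg <- segment_domains(cube, threshold = 5, connectivity = conn)
      oracle <- cc_oracle(arr >= 5, connectivity = conn)
      expect_equal(seg$n_domains, max(oracle))
      expect_equal(sort(seg$domains$voxel_count), cc_sizes(oracle))
      # identical partitions: labels must be a bijection of oracle labels
      mask <- arr >= 5
      if (any(mask)) {
        pairs <- unique(cbind(seg$label_volume[mask], oracle[mask]))
        expect_equal(nrow(pairs), max(oracle))
        expect_equal(anyDuplicated(pairs[, 1]), 0L)
        expect_equal(anyDuplicated(pairs[, 2]), 0L)
      }
    }
  }
})

test_that("domain morphology is reported in physical units", {
  # a 10-voxel rod along columns: physical length ~ 10 * pixel_size
  arr <- array(0L, dim = c(9, 20, 5))
  arr[5, 6:15, 3] <- 100L
  cube <- ion_cube(arr, pixel_size = 0.25,
                   level_depths = seq(0, 0.8, by = 0.2))
  seg <- segment_domains(cube, threshold = 50)
  expect_equal(seg$n_domains, 1L)
  dm <- seg$domains
  expect_equal(dm$axis1_um, 9 * 0.25)          # centre-to-centre extent
  expect_equal(abs(dm$orient_x), 1, tolerance = 1e-12)
  expect_equal(dm$orient_y, 0, tolerance = 1e-12)
  expect_equal(dm$centroid_x_um, mean((6:15 - 0.5) * 0.25))
  expect_equal(dm$centroid_y_um, 4.5 * 0.25)
  expect_equal(dm$centroid_z_um, 0.4)
  expect_equal(dm$min_depth_um, 0.4)
})

test_that("surface connectivity flags only domains reaching shallow depths", {
  arr <- array(0L, dim = c(8, 8, 5))
  arr[2, 2, 1:3] <- 90L      # spans the surface level
  arr[6, 6, 4:5] <- 90L      # deep only
  cube <- ion_cube(arr, pixel_size = 0.2,
                   level_depths = c(0, 0.4, 0.8, 1.2, 1.6))
  seg <- segment_domains(cube, threshold = 50)
  surf <- surface_connectivity(seg, depth_limit = 0.5)
  expect_equal(surf$n_surface_touching, 1L)
  touching <- surf$domains$domain_id[surf$domains$surface_touching]
  expect_equal(seg$domains$min_depth_um[seg$domains$domain_id == touching], 0)

  deep_only <- surface_connectivity(seg, depth_limit = 0)
  expect_equal(deep_only$n_surface_touching, 0L)
})
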