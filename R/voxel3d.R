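#' Intensity histogram of an ion cube
#'
#' Tallies the number of voxels `N_x` at each integer intensity level `x`
#' from 0 to the cube maximum. The total signal `sum_x N_x * x` is
#' proportional to the total amount of the imaged element in the analysed
#' volume, so this histogram is the basis of all contribution statistics.
#'
#' @param cube An [ion_cube].
#' @return An object of class `intensity_histogram` with fields
#'   `intensities` (levels `0:x_max`), `counts` (`N_x`), `total_voxels`,
#'   and `total_intensity`.
#' @export
intensity_histogram <- function(cube) {
  stopifnot(inherits(cube, "ion_cube"))
  v <- as.vector(cube$intensities)
  x_max <- max(v)
  counts <- tabulate(v + 1L, nbins = x_max + 1L)
  structure(
    list(intensities = 0:x_max, counts = counts,
         total_voxels = length(v),
         total_intensity = sum(as.numeric(counts) * (0:x_max))),
    class = "intensity_histogram")
}

#' Build an intensity histogram directly from level counts
#'
#' @param counts Named or plain vector of voxel counts; `intensities` gives
#'   the corresponding integer levels (default `0:(length(counts)-1)`).
#' @param intensities Integer intensity levels.
#' @return An `intensity_histogram`.
#' @export
as_intensity_histogram <- function(counts, intensities = seq_along(counts) - 1L) {
  if (length(counts) != length(intensities))
    stopf("'counts' and 'intensities' must have equal length")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(intensities != floor(intensities)) || any(intensities < 0))
    stopf("intensities must be non-negative integers")
  x_max <- max(intensities)
  full <- numeric(x_max + 1L)
  full[intensities + 1L] <- counts
  structure(
    list(intensities = 0:x_max, counts = full,
         total_voxels = sum(full),
         total_intensity = sum(full * (0:x_max))),
    class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d voxels, levels 0-%d, total intensity %.6g\n",
              x$total_voxels, max(x$intensities), x$total_intensity))
  invisible(x)
}

#' Mode, median and mean of an intensity histogram
#'
#' Mode is the level with the largest voxel count, median the smallest
#' level at which the cumulative voxel count reaches half the total; ties
#' resolve to the smallest qualifying level. Mean is
#' `total_intensity / total_voxels`.
#'
#' @param h An [intensity_histogram].
#' @return An object of class `distribution_stats` with fields `mode`,
#'   `median`, `mean`.
#' @export
distribution_stats <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (h$total_voxels < 1L) stopf("histogram is empty")
  cum <- cumsum(h$counts)
  structure(
    list(mode = h$intensities[which.max(h$counts)],
         median = h$intensities[which(cum >= h$total_voxels / 2)[1L]],
         mean = h$total_intensity / h$total_voxels),
    class = "distribution_stats")
}

#' @export
print.distribution_stats <- function(x, ...) {
  cat(sprintf("<distribution_stats> mode %d, median %d, mean %.4g\n",
              x$mode, x$median, x$mean))
  invisible(x)
}

#' Cumulative contribution distribution of intensity levels
#'
#' The contribution of level `x` to the total signal is `N_x * x` (many dim
#' voxels can carry as much of the element as few bright ones). This
#' function returns the normalised cumulative contribution
#' `F(x) = sum_{x' <= x} N_{x'} x' / total_intensity`, a non-decreasing
#' curve reaching exactly 1 at the maximum level.
#'
#' @param h An [intensity_histogram] with positive total intensity.
#' @return A data frame of class `contribution_cdf` with columns `x` and
#'   `cumulative_fraction`.
#' @export
contribution_cdf <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (h$total_intensity <= 0)
    stopf("total intensity is zero; contribution CDF undefined")
  contrib <- h$counts * h$intensities
  out <- data.frame(x = h$intensities,
                    cumulative_fraction = cumsum(contrib) / sum(contrib))
  class(out) <- c("contribution_cdf", "data.frame")
  out
}

#' Fit a 3-parameter log-logistic curve to a contribution CDF
#'
#' Fits `y = a / (1 + (x / x0)^(-b))` to the points of a contribution CDF
#' by unweighted Levenberg-Marquardt least squares. The level `x = 0` is
#' excluded (it contributes nothing to intensity and the model is undefined
#' there). Initialisation is deterministic: `a = 1`, `x0` at the empirical
#' contribution median, `b = 2`, so repeated fits are identical.
#'
#' @param cdf A [contribution_cdf] (or data frame with columns `x`,
#'   `cumulative_fraction`) with at least 4 points at `x >= 1`.
#' @return An object of class `logistic_fit` with fields `a`, `x0`, `b`,
#'   `r2`, and `fitted` (data frame of the fitted points).
#' @export
fit_logistic <- function(cdf) {
  if (!all(c("x", "cumulative_fraction") %in% names(cdf)))
    stopf("'cdf' must have columns 'x' and 'cumulative_fraction'")
  d <- data.frame(x = cdf$x, y = cdf$cumulative_fraction)
  d <- d[d$x >= 1, , drop = FALSE]
  if (nrow(d) < 4L)
    stopf("need at least 4 CDF points at x >= 1 to fit 3 parameters")
  x0_init <- d$x[which(d$y >= 0.5)[1L]]
  if (is.na(x0_init)) x0_init <- stats::median(d$x)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a / (1 + (x / x0)^(-b)), data = d,
                      start = list(a = 1, x0 = x0_init, b = 2),
                      lower = c(1e-8, 1e-8, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stopf("logistic fit did not converge: %s", conditionMessage(e)))
  p <- stats::coef(fit)
  res <- d$y - stats::predict(fit)
  r2 <- 1 - sum(res^2) / sum((d$y - mean(d$y))^2)
  structure(
    list(a = unname(p["a"]), x0 = unname(p["x0"]), b = unname(p["b"]),
         r2 = r2,
         fitted = data.frame(x = d$x, y = d$y, yhat = stats::predict(fit))),
    class = "logistic_fit")
}

#' Evaluate a fitted log-logistic curve
#'
#' @param fit A [logistic_fit][fit_logistic] (or list with `a`, `x0`, `b`).
#' @param x Positive intensity values.
#' @return `a / (1 + (x / x0)^(-b))`.
#' @export
logistic_eval <- function(fit, x) {
  fit$a / (1 + (x / fit$x0)^(-fit$b))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> y = %.4f / (1 + (x/%.3f)^-%.4f), R^2 = %.4f\n",
              x$a, x$x0, x$b, x$r2))
  invisible(x)
}

#' Intensity level below which a given fraction of the signal resides
#'
#' Inverts the fitted log-logistic contribution curve in closed form. With
#' `normalized = TRUE` (default) the curve is first scaled by its fitted
#' asymptote `a` so that `q` is a true fraction of the total:
#' `x = x0 * (1/q - 1)^(-1/b)`. With `normalized = FALSE` the raw curve is
#' solved (`a/q - 1` in place of `1/q - 1`), which is only defined for
#' `q < a`.
#'
#' @param fit A [logistic_fit][fit_logistic].
#' @param q Fraction in (0, 1).
#' @param normalized Normalise by the fitted asymptote before solving
#'   (default `TRUE`).
#' @return The intensity level `x` with fitted fraction `q` at or below it.
#' @export
#' @examples
#' f <- list(a = 1.0089, x0 = 17.990, b = 2.3693)
#' solve_quantile(f, 0.5)   # contribution median of the fitted curve
solve_quantile <- function(fit, q, normalized = TRUE) {
  if (!is_number(q) || q <= 0 || q >= 1)
    stopf("'q' must be a single number strictly inside (0, 1)")
  ratio <- if (normalized) 1 / q - 1 else fit$a / q - 1
  if (ratio <= 0)
    stopf("q = %g is not reachable by the unnormalized curve (asymptote a = %g)",
          q, fit$a)
  fit$x0 * ratio^(-1 / fit$b)
}

#' Fraction of total signal at or above an intensity threshold
#'
#' Computed on the empirical histogram (not a fitted curve):
#' `sum_{x >= t} N_x x / total_intensity`. This is the primary route for
#' threshold statements such as "how much of the element sits in
#' high-intensity regions"; fitted-curve quantiles are a separate operation
#' ([solve_quantile()]).
#'
#' @param h An [intensity_histogram] with positive total intensity.
#' @param threshold Non-negative intensity threshold.
#' @return Fraction in \[0, 1\].
#' @export
fraction_above <- function(h, threshold) {
  stopifnot(inherits(h, "intensity_histogram"))
  if (!is_number(threshold) || threshold < 0)
    stopf("'threshold' must be a single non-negative number")
  if (h$total_intensity <= 0)
    stopf("total intensity is zero; fraction undefined")
  sel <- h$intensities >= threshold
  sum(h$counts[sel] * h$intensities[sel]) / h$total_intensity
}

# ---------------------------------------------------------------------------
# Domain segmentation

# Offsets of the 13 "forward" neighbours of the 26-neighbourhood; the other
# 13 are their negatives, so scanning the forward half enumerates each
# neighbour pair once.
half_offsets_26 <- function() {
  off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dl = -1:1))
  keep <- off[, "dl"] > 0 |
    (off[, "dl"] == 0 & off[, "dc"] > 0) |
    (off[, "dl"] == 0 & off[, "dc"] == 0 & off[, "dr"] > 0)
  off[keep, , drop = FALSE]
}

half_offsets_6 <- function() {
  matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), nrow = 3, byrow = TRUE,
         dimnames = list(NULL, c("dr", "dc", "dl")))
}

#' Segment connected high-intensity domains in an ion cube
#'
#' Voxels at or above `threshold` are grouped into connected components
#' (26-connectivity by default: faces, edges and corners; 6-connectivity
#' available). Per-domain morphology is computed in physical units using
#' the cube's pixel size laterally and its `level_depths` axially, so
#' anisotropic voxels are handled correctly: centroid, principal axes of
#' the voxel-coordinate covariance, full extents along those axes, the
#' orientation unit vector of the longest axis, voxel count and volume
#' fraction, and the domain's share of the cube's total intensity.
#'
#' @param cube An [ion_cube].
#' @param threshold Intensity threshold defining domain membership
#'   (default 50).
#' @param connectivity 26 (default) or 6.
#' @return An object of class `domain_segmentation` with fields
#'   \describe{
#'     \item{label_volume}{integer array of the cube's shape; 0 is
#'       background, `k` the k-th domain (labels ordered by decreasing
#'       voxel count).}
#'     \item{domains}{data frame with one row per domain: `domain_id`,
#'       `voxel_count`, `volume_fraction`, `centroid_x/y/z_um`,
#'       `axis1/2/3_um` (full extents, descending), `orient_x/y/z`
#'       (unit vector of the major axis), `intensity_fraction`,
#'       `min_depth_um`.}
#'     \item{n_domains, threshold, connectivity}{scalars.}
#'     \item{pixel_size, level_depths}{geometry, carried from the cube.}
#'   }
#' @seealso [surface_connectivity()]
#' @export
segment_domains <- function(cube, threshold = 50, connectivity = 26) {
  stopifnot(inherits(cube, "ion_cube"))
  if (!is_number(threshold)) stopf("'threshold' must be a single number")
  if (!connectivity %in% c(6, 26))
    stopf("'connectivity' must be 6 or 26")
  d <- dim(cube$intensities)
  idx <- which(cube$intensities >= threshold)
  label_volume <- array(0L, dim = d)
  empty <- data.frame(
    domain_id = integer(), voxel_count = integer(),
    volume_fraction = numeric(), centroid_x_um = numeric(),
    centroid_y_um = numeric(), centroid_z_um = numeric(),
    axis1_um = numeric(), axis2_um = numeric(), axis3_um = numeric(),
    orient_x = numeric(), orient_y = numeric(), orient_z = numeric(),
    intensity_fraction = numeric(), min_depth_um = numeric())
  if (length(idx) == 0L)
    return(structure(list(label_volume = label_volume, n_domains = 0L,
                          domains = empty, threshold = threshold,
                          connectivity = connectivity,
                          pixel_size = cube$pixel_size,
                          level_depths = cube$level_depths),
                     class = "domain_segmentation"))

  coords <- arrayInd(idx, d)
  off <- if (connectivity == 26) half_offsets_26() else half_offsets_6()
  edges <- integer(0)
  for (k in seq_len(nrow(off))) {
    r <- coords[, 1L] + off[k, 1L]
    cc <- coords[, 2L] + off[k, 2L]
    l <- coords[, 3L] + off[k, 3L]
    ok <- r >= 1L & r <= d[1L] & cc >= 1L & cc <= d[2L] &
      l >= 1L & l <= d[3L]
    if (!any(ok)) next
    nb_lin <- r[ok] + (cc[ok] - 1L) * d[1L] + (l[ok] - 1L) * d[1L] * d[2L]
    hit <- match(nb_lin, idx)
    found <- which(!is.na(hit))
    if (length(found))
      edges <- c(edges, rbind(which(ok)[found], hit[found]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership

  # relabel so domain 1 is the largest, ties by first occurrence
  sizes <- tabulate(comp)
  ord <- order(-sizes, seq_along(sizes))
  relab <- integer(length(sizes)); relab[ord] <- seq_along(ord)
  comp <- relab[comp]
  label_volume[idx] <- comp

  # physical coordinates: x along columns, y along rows, z depth
  px <- cube$pixel_size
  phys <- cbind(x = (coords[, 2L] - 0.5) * px,
                y = (coords[, 1L] - 0.5) * px,
                z = cube$level_depths[coords[, 3L]])
  inten <- as.numeric(cube$intensities[idx])
  total_int <- sum(as.numeric(cube$intensities))
  n_dom <- max(comp)

  rows <- vector("list", n_dom)
  for (k in seq_len(n_dom)) {
    sel <- comp == k
    p <- phys[sel, , drop = FALSE]
    cen <- colMeans(p)
    if (sum(sel) >= 2L) {
      ev <- eigen(stats::cov(p), symmetric = TRUE)
      proj <- p %*% ev$vectors
      ext <- apply(proj, 2L, function(v) max(v) - min(v))
      ordax <- order(-ext)
      ext <- ext[ordax]
      u <- ev$vectors[, ordax[1L]]
      u <- u / sqrt(sum(u^2))
      if (u[which.max(abs(u))] < 0) u <- -u   # deterministic sign
    } else {
      ext <- c(0, 0, 0)
      u <- c(1, 0, 0)
    }
    rows[[k]] <- data.frame(
      domain_id = k, voxel_count = sum(sel),
      volume_fraction = sum(sel) / prod(d),
      centroid_x_um = cen[["x"]], centroid_y_um = cen[["y"]],
      centroid_z_um = cen[["z"]],
      axis1_um = ext[1L], axis2_um = ext[2L], axis3_um = ext[3L],
      orient_x = u[1L], orient_y = u[2L], orient_z = u[3L],
      intensity_fraction = sum(inten[sel]) / total_int,
      min_depth_um = min(p[, "z"]))
  }
  domains <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(list(label_volume = label_volume, n_domains = n_dom,
                 domains = domains, threshold = threshold,
                 connectivity = connectivity, pixel_size = cube$pixel_size,
                 level_depths = cube$level_depths),
            class = "domain_segmentation")
}

#' @export
print.domain_segmentation <- function(x, ...) {
  cat(sprintf("<domain_segmentation> %d domain(s) at intensity >= %g (%d-connectivity)\n",
              x$n_domains, x$threshold, x$connectivity))
  if (x$n_domains > 0) {
    cat(sprintf("  total volume fraction %.4g, total intensity fraction %.4g\n",
                sum(x$domains$volume_fraction),
                sum(x$domains$intensity_fraction)))
    cat(sprintf("  largest domain: %d voxels, %.3g x %.3g x %.3g um\n",
                x$domains$voxel_count[1L], x$domains$axis1_um[1L],
                x$domains$axis2_um[1L], x$domains$axis3_um[1L]))
  }
  invisible(x)
}

#' Which domains reach the near-surface region?
#'
#' Flags every domain having at least one voxel shallower than
#' `depth_limit`. Used to ask whether high-intensity domains connect to the
#' specimen surface or sit isolated in the bulk.
#'
#' @param seg A [domain_segmentation][segment_domains].
#' @param depth_limit Depth in micrometres; voxels with depth strictly
#'   below it count as near-surface.
#' @return A list of class `surface_connectivity` with `depth_limit`,
#'   `n_surface_touching`, and `domains` (data frame with `domain_id`,
#'   `min_depth_um`, `surface_touching`).
#' @export
surface_connectivity <- function(seg, depth_limit) {
  stopifnot(inherits(seg, "domain_segmentation"))
  if (!is_number(depth_limit) || depth_limit < 0)
    stopf("'depth_limit' must be a single non-negative depth (um)")
  dm <- seg$domains
  flags <- data.frame(domain_id = dm$domain_id,
                      min_depth_um = dm$min_depth_um,
                      surface_touching = dm$min_depth_um < depth_limit)
  structure(list(depth_limit = depth_limit,
                 n_surface_touching = sum(flags$surface_touching),
                 domains = flags),
            class = "surface_connectivity")
}

#' @export
print.surface_connectivity <- function(x, ...) {
  cat(sprintf("<surface_connectivity> %d of %d domain(s) reach depth < %g um\n",
              x$n_surface_touching, nrow(x$domains), x$depth_limit))
  invisible(x)
}
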