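# Independent oracles and fixture builders used across the suite.

# Brute-force connected-component labelling by flood fill over a logical
# 3D mask. Deliberately independent of the package's graph-based
# implementation; only usable on small cubes.
cc_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, dim = d)
  nxt <- 0L
  for (i in which(mask)) {
    if (labels[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    labels[i] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      pos <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        p <- pos + offs[k, ]
        if (any(p < 1L) || any(p > d)) next
        j <- p[1L] + (p[2L] - 1L) * d[1L] + (p[3L] - 1L) * d[1L] * d[2L]
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# Multiset of component sizes from an oracle labelling.
cc_sizes <- function(labels) sort(tabulate(labels[labels > 0L]))

# A numeric vector of length n with exactly the requested mean and sample
# standard deviation (affine transform of a fixed spread).
vector_with_moments <- function(n, mean, sd) {
  v <- seq_len(n)
  v <- (v - base::mean(v)) / stats::sd(v)
  v * sd + mean
}

# Small valid ion cube with the given dimensions and integer intensities.
make_cube <- function(intensities, pixel_size = 0.2,
                      level_spacing = 0.15) {
  d <- dim(intensities)
  ion_cube(intensities, pixel_size = pixel_size,
           level_depths = (seq_len(d[3L]) - 1L) * level_spacing + 0.01)
}

# Spot data frame with n locations per (sample, condition) cell.
make_spot_df <- function(samples, conditions, n = 20,
                         analyte = function(s, cc) stats::runif(n, 1, 6)) {
  rows <- list()
  for (s in samples) for (cc in conditions)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, condition = cc, location_id = seq_len(n),
      analyte_intensity = analyte(s, cc), reference_intensity = 1)
  do.call(rbind, rows)
}
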