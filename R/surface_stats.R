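#' Normalised analyte/reference intensity ratios
#'
#' Per-location surface loading is reported as the ratio of the analyte ion
#' intensity to a matrix reference ion intensity (e.g. 35Cl- over C4H3-),
#' which cancels instrument and topography variation between spots.
#'
#' @param table A [spot_table].
#' @return The table with an added numeric `ratio` column.
#' @export
intensity_ratio <- function(table) {
  stopifnot(inherits(table, "spot_table"))
  bad <- which(table$reference_intensity <= 0)
  if (length(bad))
    stopf("zero or negative reference intensity at location %d (sample '%s', condition '%s')",
          table$location_id[bad[1L]], table$sample_id[bad[1L]],
          table$condition[bad[1L]])
  table$ratio <- table$analyte_intensity / table$reference_intensity
  table
}

#' Descriptive statistics of a set of intensity ratios
#'
#' Computes the summary reported for each specimen/condition: sample size,
#' median, mean, sample standard deviation (n - 1 denominator), relative
#' standard deviation (100 * sd / mean), and the normal-approximation 95%
#' confidence interval for the mean, `mean +/- 1.96 * sd / sqrt(n)`. The
#' z-based interval (rather than Student's t) is the convention these
#' summary tables use.
#'
#' With fewer than two observations the dispersion fields are `NA`.
#'
#' @param ratios Numeric vector of non-negative intensity ratios.
#' @return An object of class `summary_stats`: a one-row data frame with
#'   columns `n`, `median`, `mean`, `sd`, `rsd_pct`, `ci95_low`, `ci95_high`.
#' @export
#' @examples
#' summarize_ratios(c(2.1, 3.3, 4.0, 5.2))
summarize_ratios <- function(ratios) {
  if (!is.numeric(ratios) || length(ratios) < 1L || anyNA(ratios))
    stopf("'ratios' must be a non-empty numeric vector without NA")
  n <- length(ratios)
  m <- mean(ratios)
  if (n >= 2L) {
    s <- stats::sd(ratios)
    half <- 1.96 * s / sqrt(n)
    rsd <- if (m > 0) 100 * s / m else NA_real_
    lo <- m - half; hi <- m + half
  } else {
    s <- NA_real_; rsd <- NA_real_; lo <- NA_real_; hi <- NA_real_
  }
  out <- data.frame(n = n, median = stats::median(ratios), mean = m,
                    sd = s, rsd_pct = rsd, ci95_low = lo, ci95_high = hi)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Percent change of a condition mean against a baseline
#'
#' @param base A [summary_stats][summarize_ratios] for the baseline
#'   condition (its mean must be positive).
#' @param cond A [summary_stats][summarize_ratios] for the comparison
#'   condition.
#' @param sample_id,baseline_condition,condition Optional labels carried
#'   into the result.
#' @return A one-row data frame of class `condition_comparison` with
#'   `pct_change_mean = 100 * (mean_cond - mean_base) / mean_base`.
#' @export
percent_change <- function(base, cond, sample_id = NA_character_,
                           baseline_condition = NA_character_,
                           condition = NA_character_) {
  stopifnot(inherits(base, "summary_stats"), inherits(cond, "summary_stats"))
  if (!is.finite(base$mean) || base$mean <= 0)
    stopf("baseline mean must be positive for a percent change")
  out <- data.frame(sample_id = sample_id,
                    baseline_condition = baseline_condition,
                    condition = condition,
                    pct_change_mean = 100 * (cond$mean - base$mean) /
                      base$mean)
  class(out) <- c("condition_comparison", "data.frame")
  out
}

#' Wash/regeneration report over a spot table
#'
#' Summarises every (sample, condition) cell of a spot table and compares
#' each non-baseline condition mean to the sample's baseline. This is the
#' machine-readable form of the wash/incubation summary tables: one
#' statistics row per cell, one percent-change row per non-baseline cell.
#'
#' @param table A [spot_table] containing the baseline condition for every
#'   sample.
#' @param baseline Baseline condition label (default `"initial"`).
#' @return A list of class `wash_report` with elements
#'   \describe{
#'     \item{stats}{data frame: `sample_id`, `condition` plus the
#'       [summarize_ratios()] columns, one row per (sample, condition).}
#'     \item{comparisons}{data frame of percent changes versus baseline.}
#'     \item{baseline}{the baseline label.}
#'   }
#' @export
wash_report <- function(table, baseline = "initial") {
  table <- intensity_ratio(table)
  baseline <- normalize_condition(baseline)
  samples <- unique(table$sample_id)
  miss <- samples[!vapply(samples, function(s)
    baseline %in% table$condition[table$sample_id == s], logical(1))]
  if (length(miss))
    stopf("missing baseline condition '%s' for sample(s): %s",
          baseline, paste(miss, collapse = ", "))

  cells <- unique(table[c("sample_id", "condition")])
  # keep conditions in the order of the controlled vocabulary within sample
  cells <- cells[order(match(cells$sample_id, samples),
                       match(cells$condition, SPOT_CONDITIONS)), ]
  stats_rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$sample_id == cells$sample_id[i] &
      table$condition == cells$condition[i]
    cbind(cells[i, , drop = FALSE], summarize_ratios(table$ratio[sel]))
  })
  stats <- do.call(rbind, c(stats_rows, make.row.names = FALSE))
  class(stats) <- "data.frame"

  cmp_rows <- list()
  for (s in samples) {
    base <- stats[stats$sample_id == s & stats$condition == baseline, ]
    class(base) <- c("summary_stats", "data.frame")
    for (cc in stats$condition[stats$sample_id == s]) {
      if (cc == baseline) next
      cond <- stats[stats$sample_id == s & stats$condition == cc, ]
      class(cond) <- c("summary_stats", "data.frame")
      cmp_rows[[length(cmp_rows) + 1L]] <-
        percent_change(base, cond, sample_id = s,
                       baseline_condition = baseline, condition = cc)
    }
  }
  comparisons <- if (length(cmp_rows))
    do.call(rbind, c(cmp_rows, make.row.names = FALSE))
  else
    data.frame(sample_id = character(), baseline_condition = character(),
               condition = character(), pct_change_mean = numeric())
  class(comparisons) <- "data.frame"
  structure(list(stats = stats, comparisons = comparisons,
                 baseline = baseline),
            class = "wash_report")
}

#' @export
print.wash_report <- function(x, digits = 3, ...) {
  cat(sprintf("<wash_report> baseline '%s': %d (sample, condition) cells\n",
              x$baseline, nrow(x$stats)))
  print(format(x$stats, digits = digits), row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("\n% change in mean vs baseline:\n")
    print(format(x$comparisons, digits = digits), row.names = FALSE)
  }
  invisible(x)
}
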