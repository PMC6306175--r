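#' Depth profile of secondary-ion counts
#'
#' A depth profile records the counts of one secondary-ion species over
#' successive sputter cycles together with the total crater depth measured
#' by profilometry after the run. Depth scaling assumes a uniform sputter
#' rate, so the crater depth is the only depth calibration required (see
#' [depth_scale()]).
#'
#' @param counts Numeric vector of non-negative per-cycle ion counts.
#' @param crater_depth Total sputter-crater depth in nm (must be positive).
#' @param species_label Label of the ion species, e.g. `"35Cl-"`.
#' @param analysis_area Optional `c(width, height)` of the analysed area in
#'   micrometres.
#' @param sputter_params Optional free-text description of the sputter beam
#'   (e.g. `"3 keV Cs+, 20 nA"`).
#'
#' @return An object of class `depth_profile` with fields `counts`,
#'   `n_cycles`, `crater_depth`, `species_label`, `analysis_area`,
#'   `sputter_params`.
#' @seealso [read_depth_profile()], [depth_scale()], [quantify_profile()]
#' @export
#' @examples
#' dp <- depth_profile(counts = rep(100, 10), crater_depth = 100)
#' dp$n_cycles
depth_profile <- function(counts, crater_depth, species_label = "35Cl-",
                          analysis_area = NULL, sputter_params = NULL) {
  if (!is.numeric(counts) || length(counts) < 1L)
    stopf("'counts' must be a non-empty numeric vector")
  bad <- which(!is.finite(counts) | counts < 0)
  if (length(bad))
    stopf("invalid count at cycle %d: counts must be finite and >= 0",
          bad[1L])
  if (!is_number(crater_depth) || crater_depth <= 0)
    stopf("'crater_depth' must be a single positive number (nm)")
  structure(
    list(counts = as.numeric(counts), n_cycles = length(counts),
         crater_depth = as.numeric(crater_depth),
         species_label = as.character(species_label),
         analysis_area = analysis_area, sputter_params = sputter_params),
    class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s: %d cycles, crater %.4g nm\n",
              x$species_label, x$n_cycles, x$crater_depth))
  cat(sprintf("  counts: min %.4g, max %.4g, total %.6g\n",
              min(x$counts), max(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read depth profiles from a delimited text file
#'
#' The file must be comma- or tab-delimited with a header row naming one
#' column per ion species and one data row per sputter cycle, in acquisition
#' order. The crater depth is supplied separately because it comes from
#' profilometry of the finished crater, not from the instrument export.
#'
#' @param path Path to the delimited file.
#' @param crater_depth Measured crater depth in nm, shared by all species
#'   columns (they come from the same crater).
#' @param sep Field separator; the default sniffs `","` vs tab from the
#'   header line.
#' @param drop If `TRUE` (default) and the file holds a single species
#'   column, return the `depth_profile` itself rather than a list of one.
#' @param ... Passed to [depth_profile()] (e.g. `sputter_params`).
#'
#' @return A named list of [depth_profile] objects (one per species column),
#'   or a single `depth_profile` when `drop = TRUE` and there is one column.
#' @export
read_depth_profile <- function(path, crater_depth, sep = NULL,
                               drop = TRUE, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "numeric")
  if (nrow(df) < 1L) stopf("no data rows in %s", path)
  profiles <- lapply(names(df), function(sp) {
    counts <- df[[sp]]
    bad <- which(is.na(counts) | counts < 0)
    if (length(bad))
      stopf("species '%s': missing or negative count at data row %d",
            sp, bad[1L])
    depth_profile(counts, crater_depth, species_label = sp, ...)
  })
  names(profiles) <- names(df)
  if (drop && length(profiles) == 1L) profiles[[1L]] else profiles
}

#' Write depth profiles to a delimited text file
#'
#' @param profiles A `depth_profile` or named list of them sharing
#'   `n_cycles`.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_depth_profile <- function(profiles, path, sep = ",") {
  if (inherits(profiles, "depth_profile")) profiles <- list(profiles)
  labs <- vapply(profiles, function(p) p$species_label, character(1))
  ncyc <- vapply(profiles, function(p) p$n_cycles, integer(1))
  if (length(unique(ncyc)) != 1L)
    stopf("all profiles must have the same number of cycles")
  df <- as.data.frame(lapply(profiles, function(p) p$counts),
                      check.names = FALSE)
  names(df) <- labs
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

# ---------------------------------------------------------------------------
# Ion cubes

#' 3D secondary-ion intensity cube
#'
#' An ion cube is the stack of 2D secondary-ion maps acquired at successive
#' sputter levels: an integer intensity raster of dimension
#' rows x cols x levels with a lateral pixel size and a physical depth per
#' level.
#'
#' @param intensities 3D array of non-negative integer intensities
#'   (rows x cols x levels).
#' @param pixel_size Lateral size of one pixel in micrometres.
#' @param level_depths Strictly increasing vector of level depths in
#'   micrometres, one per sputter level (the surface level may sit at 0).
#' @param species_label Ion species label.
#'
#' @return An object of class `ion_cube`.
#' @seealso [read_ion_cube()], [intensity_histogram()], [segment_domains()]
#' @export
ion_cube <- function(intensities, pixel_size, level_depths,
                     species_label = "35Cl-") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stopf("'intensities' must be a 3D array (rows x cols x levels)")
  d <- dim(intensities)
  if (any(d < 1L)) stopf("all cube dimensions must be >= 1")
  if (anyNA(intensities) || any(intensities < 0))
    stopf("intensities must be non-negative and non-missing")
  if (any(intensities != floor(intensities)))
    stopf("intensities must be integers")
  if (!is_number(pixel_size) || pixel_size <= 0)
    stopf("'pixel_size' must be a single positive number (um)")
  if (!is.numeric(level_depths) || length(level_depths) != d[3L])
    stopf("'level_depths' must have one entry per level (%d)", d[3L])
  if (any(diff(level_depths) <= 0) || any(level_depths < 0))
    stopf("'level_depths' must be non-negative and strictly increasing")
  storage.mode(intensities) <- "integer"
  structure(
    list(intensities = intensities, pixel_size = as.numeric(pixel_size),
         level_depths = as.numeric(level_depths),
         species_label = as.character(species_label)),
    class = "ion_cube")
}

#' @export
print.ion_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<ion_cube> %s: %d x %d x %d (%.3g um/px, depth %.3g-%.3g um)\n",
    x$species_label, d[1], d[2], d[3], x$pixel_size,
    min(x$level_depths), max(x$level_depths)))
  cat(sprintf("  intensity range %d-%d, total %.6g\n",
              min(x$intensities), max(x$intensities),
              sum(as.numeric(x$intensities))))
  invisible(x)
}

#' Read/write an ion cube in the plain-text `.icube` container
#'
#' The container is a single text file: a magic line `#ICUBE 1`, one line of
#' JSON metadata (`species_label`, `pixel_size`, `level_depths`, `dim`), and
#' then one whitespace-separated line of row-major integers per sputter
#' level. Integer rasters and metadata round-trip losslessly.
#'
#' @param path File path.
#' @return For `read_ion_cube`, an [ion_cube]; for `write_ion_cube`, `path`
#'   invisibly.
#' @export
read_ion_cube <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "r")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "#ICUBE 1"))
    stopf("%s is not an ICUBE v1 container (bad magic line)", path)
  meta <- jsonlite::fromJSON(readLines(con, n = 1L))
  for (f in c("species_label", "pixel_size", "level_depths", "dim"))
    if (is.null(meta[[f]])) stopf("ICUBE metadata missing field '%s'", f)
  d <- as.integer(meta$dim)
  if (length(d) != 3L || any(d < 1L)) stopf("ICUBE metadata 'dim' invalid")
  if (meta$pixel_size <= 0) stopf("ICUBE metadata 'pixel_size' must be > 0")
  vals <- scan(con, what = integer(), n = prod(d), quiet = TRUE)
  if (length(vals) != prod(d))
    stopf("ICUBE data truncated: expected %d values, got %d",
          prod(d), length(vals))
  # levels were written row-major; restore R's column-major layout per level
  arr <- array(0L, dim = d)
  per_level <- d[1L] * d[2L]
  for (k in seq_len(d[3L])) {
    lev <- vals[((k - 1L) * per_level + 1L):(k * per_level)]
    arr[, , k] <- matrix(lev, nrow = d[1L], byrow = TRUE)
  }
  ion_cube(arr, pixel_size = meta$pixel_size,
           level_depths = as.numeric(meta$level_depths),
           species_label = meta$species_label)
}

#' @rdname read_ion_cube
#' @param cube An [ion_cube].
#' @export
write_ion_cube <- function(cube, path) {
  stopifnot(inherits(cube, "ion_cube"))
  d <- dim(cube$intensities)
  meta <- jsonlite::toJSON(
    list(species_label = cube$species_label, pixel_size = cube$pixel_size,
         level_depths = cube$level_depths, dim = d),
    auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#ICUBE 1", meta), con)
  for (k in seq_len(d[3L]))
    writeLines(paste(t(cube$intensities[, , k]), collapse = " "), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Spot tables

#' Table of per-location spot measurements
#'
#' Each record is one analysis location on one specimen: the analyte ion
#' intensity (e.g. 35Cl-) and a matrix reference intensity (e.g. C4H3- from
#' the polyethylene) used for normalisation. Conditions are restricted to a
#' controlled vocabulary covering the pressing/sputtering and the
#' wash/regeneration designs.
#'
#' @param df Data frame with columns `sample_id`, `condition`, `location_id`,
#'   `analyte_intensity`, `reference_intensity`.
#' @return A validated data frame of class `spot_table`.
#' @export
spot_table <- function(df) {
  req <- c("sample_id", "condition", "location_id",
           "analyte_intensity", "reference_intensity")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("spot table missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$sample_id <- as.character(df$sample_id)
  df$condition <- normalize_condition(df$condition)
  df$location_id <- as.integer(df$location_id)
  if (anyNA(df$location_id)) stopf("'location_id' must be integer")
  if (anyNA(df$analyte_intensity) || any(df$analyte_intensity < 0))
    stopf("'analyte_intensity' must be non-negative and non-missing")
  if (anyNA(df$reference_intensity))
    stopf("'reference_intensity' must be non-missing")
  key <- paste(df$sample_id, df$condition, df$location_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stopf("duplicate location_id %d within (sample '%s', condition '%s')",
          df$location_id[i], df$sample_id[i], df$condition[i])
  }
  class(df) <- c("spot_table", "data.frame")
  df
}

normalize_condition <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ -]+", "_", x)
  unknown <- setdiff(unique(x), SPOT_CONDITIONS)
  if (length(unknown))
    stopf("unknown condition label(s): %s\n  allowed: %s",
          paste(unknown, collapse = ", "),
          paste(SPOT_CONDITIONS, collapse = ", "))
  x
}

#' Read or write a spot table as delimited text
#'
#' @param path Path to a comma- or tab-delimited file with a header naming
#'   the columns `sample_id`, `condition`, `location_id`,
#'   `analyte_intensity`, `reference_intensity`.
#' @param sep Field separator; default sniffs comma vs tab.
#' @return For `read_spot_table`, a [spot_table]; for `write_spot_table`,
#'   `path` invisibly.
#' @export
read_spot_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  spot_table(df)
}

#' @rdname read_spot_table
#' @param table A [spot_table].
#' @export
write_spot_table <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
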