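#' Assemble a run configuration
#'
#' A run configuration drives [run_pipeline()]. It can be built in R or
#' loaded from a YAML file with [read_run_config()]. Sections are optional;
#' a stage runs only when its section is present:
#' \describe{
#'   \item{calibration}{`profile` (delimited counts file), `crater_nm`,
#'     `dose` (atoms/cm^2), `background_cycles` (`c(from, to)`), optional
#'     `lod_sigma` (default 3).}
#'   \item{profiles}{list of `list(path=, crater_nm=)` raw depth profiles
#'     to quantify (requires the calibration stage).}
#'   \item{matrix}{overrides for [matrix_model()] constants.}
#'   \item{spots}{`path` to a spot table and optional `baseline`
#'     (default "initial").}
#'   \item{cube}{`path` to an `.icube` file, optional `threshold`
#'     (default 50), `surface_depth_um` (default 0.5), `connectivity`
#'     (default 26).}
#' }
#'
#' @param output_dir Directory for the report bundle (created if needed).
#' @param seed Integer seed recorded in the manifest (the analysis stages
#'   are deterministic; the seed matters when configs point at generated
#'   inputs).
#' @param calibration,profiles,matrix,spots,cube Stage sections as above.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L, calibration = NULL,
                       profiles = NULL, matrix = NULL, spots = NULL,
                       cube = NULL) {
  if (!is.character(output_dir) || length(output_dir) != 1L)
    stopf("'output_dir' must be a single path")
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 calibration = calibration, profiles = profiles,
                 matrix = matrix, spots = spots, cube = cube),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose top-level keys mirror the
#'   `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage_error <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}

check_file <- function(stage, path, what) {
  if (is.null(path)) stage_error(stage, "missing required field '%s'", what)
  if (!file.exists(path)) stage_error(stage, "%s file not found: %s",
                                      what, path)
  path
}

#' Run the full calibrate / quantify / analyze pipeline
#'
#' Executes every stage configured in a [run_config()] and writes a report
#' bundle into the output directory: `calibration.json`, one
#' `concentration_*.csv` per quantified profile, `surface_stats.csv` and
#' `surface_comparisons.csv`, `cube_histogram.csv`, `cube_cdf.csv`,
#' `cube_fit.json`, `cube_domains.csv`, a machine-readable `summary.json`,
#' a `manifest.json` with input checksums and the package version, and a
#' `run.log` recording every parameter used (so no silent conventions
#' exist). Outputs are staged in a temporary directory and only moved into
#' place when every stage succeeds, so a failed run leaves no partial
#' bundle. Identical configs produce byte-identical numeric outputs.
#'
#' @param config A [run_config()], or the path to a YAML config file.
#' @return Invisibly, a list with `output_dir`, `summary` (the parsed
#'   summary), and `files` written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)

  stage_dir <- tempfile("simsquant_run_")
  dir.create(stage_dir, recursive = TRUE)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  log_lines <- c(sprintf("simsquant %s",
                         as.character(utils::packageVersion("simsquant"))),
                 sprintf("seed: %d", config$seed))
  logp <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  summary <- list(package_version =
                    as.character(utils::packageVersion("simsquant")),
                  seed = config$seed)
  inputs <- character(0)

  mm_args <- config$matrix %||% list()
  mm <- do.call(matrix_model, mm_args)
  logp("matrix: density %g g/cm^3, molar mass %g g/mol, %d Cl/molecule",
       mm$matrix_density, mm$analyte_molar_mass, mm$cl_atoms_per_molecule)

  cal <- NULL
  if (!is.null(config$calibration)) {
    cc <- config$calibration
    path <- check_file("calibrate", cc$profile, "profile")
    inputs <- c(inputs, path)
    if (is.null(cc$crater_nm))
      stage_error("calibrate", "missing required field 'crater_nm'")
    if (is.null(cc$dose))
      stage_error("calibrate", "missing required field 'dose'")
    if (is.null(cc$background_cycles))
      stage_error("calibrate", "missing required field 'background_cycles'")
    prof <- tryCatch(read_depth_profile(path, cc$crater_nm),
                     error = function(e)
                       stage_error("calibrate", "%s", conditionMessage(e)))
    bg <- cc$background_cycles
    bg_idx <- seq.int(bg[[1L]], bg[[length(bg)]])
    cal <- tryCatch(
      compute_rsf(prof, dose = cc$dose, background_cycles = bg_idx,
                  lod_sigma = cc$lod_sigma %||% 3),
      error = function(e) stage_error("calibrate", "%s",
                                      conditionMessage(e)))
    logp("calibrate: dose %g, crater %g nm, background cycles %d-%d, lod_sigma %g",
         cc$dose, cc$crater_nm, min(bg_idx), max(bg_idx),
         cc$lod_sigma %||% 3)
    cal_report <- list(
      species_label = cal$species_label, dose = cal$dose, rsf = cal$rsf,
      background_mean = cal$background_mean,
      background_sd = cal$background_sd, lod_sigma = cal$lod_sigma,
      lod_density = cal$lod_density,
      lod_wtpct = lod_wtpct(cal, mm))
    jsonlite::write_json(cal_report, file.path(stage_dir,
                                               "calibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$calibration <- cal_report
  }

  if (!is.null(config$profiles)) {
    if (is.null(cal))
      stage_error("quantify-profile",
                  "profile quantification requires a calibration section")
    summary$profiles <- list()
    for (i in seq_along(config$profiles)) {
      pp <- config$profiles[[i]]
      path <- check_file("quantify-profile", pp$path, "profile")
      inputs <- c(inputs, path)
      if (is.null(pp$crater_nm))
        stage_error("quantify-profile",
                    "missing required field 'crater_nm' for profile %d", i)
      prof <- tryCatch(read_depth_profile(path, pp$crater_nm),
                       error = function(e)
                         stage_error("quantify-profile", "%s",
                                     conditionMessage(e)))
      cp <- tryCatch(quantify_profile(prof, cal),
                     error = function(e)
                       stage_error("quantify-profile", "%s",
                                   conditionMessage(e)))
      df <- as.data.frame(cp)
      df$wtpct <- cl_density_to_wtpct(df$concentration, mm)
      stem <- tools::file_path_sans_ext(basename(path))
      out <- file.path(stage_dir, sprintf("concentration_%s.csv", stem))
      utils::write.table(df, out, sep = ",", row.names = FALSE,
                         quote = FALSE)
      logp("quantify-profile: %s, crater %g nm -> %s", path, pp$crater_nm,
           basename(out))
      summary$profiles[[stem]] <-
        list(n_cycles = prof$n_cycles, crater_nm = prof$crater_depth,
             max_wtpct = max(df$wtpct))
    }
  }

  if (!is.null(config$spots)) {
    sc <- config$spots
    path <- check_file("surface-stats", sc$path, "spots")
    inputs <- c(inputs, path)
    baseline <- sc$baseline %||% "initial"
    tab <- tryCatch(read_spot_table(path),
                    error = function(e)
                      stage_error("surface-stats", "%s",
                                  conditionMessage(e)))
    rep <- tryCatch(wash_report(tab, baseline = baseline),
                    error = function(e)
                      stage_error("surface-stats", "%s",
                                  conditionMessage(e)))
    utils::write.table(rep$stats, file.path(stage_dir, "surface_stats.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(rep$comparisons,
                       file.path(stage_dir, "surface_comparisons.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    logp("surface-stats: %s, baseline '%s', %d cells, %d comparisons",
         path, baseline, nrow(rep$stats), nrow(rep$comparisons))
    summary$surface_stats <- list(n_cells = nrow(rep$stats),
                                  n_comparisons = nrow(rep$comparisons),
                                  baseline = baseline)
  }

  if (!is.null(config$cube)) {
    kc <- config$cube
    path <- check_file("cube-analyze", kc$path, "cube")
    inputs <- c(inputs, path)
    threshold <- kc$threshold %||% 50
    surface_depth <- kc$surface_depth_um %||% 0.5
    connectivity <- kc$connectivity %||% 26
    cube <- tryCatch(read_ion_cube(path),
                     error = function(e)
                       stage_error("cube-analyze", "%s",
                                   conditionMessage(e)))
    h <- intensity_histogram(cube)
    ds <- distribution_stats(h)
    cdf <- contribution_cdf(h)
    fit <- tryCatch(fit_logistic(cdf),
                    error = function(e)
                      stage_error("cube-analyze", "%s",
                                  conditionMessage(e)))
    seg <- segment_domains(cube, threshold = threshold,
                           connectivity = connectivity)
    surf <- surface_connectivity(seg, surface_depth)
    utils::write.table(
      data.frame(intensity = h$intensities, n_voxels = h$counts),
      file.path(stage_dir, "cube_histogram.csv"), sep = ",",
      row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(cdf),
                       file.path(stage_dir, "cube_cdf.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    fit_report <- list(a = fit$a, x0 = fit$x0, b = fit$b, r2 = fit$r2,
                       contribution_median = solve_quantile(fit, 0.5))
    jsonlite::write_json(fit_report, file.path(stage_dir, "cube_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    dom <- merge(seg$domains, surf$domains[c("domain_id",
                                             "surface_touching")],
                 by = "domain_id")
    utils::write.table(dom, file.path(stage_dir, "cube_domains.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    logp("cube-analyze: %s, threshold %g, %d-connectivity, surface depth %g um",
         path, threshold, connectivity, surface_depth)
    summary$cube <- list(
      total_voxels = h$total_voxels, mode = ds$mode, median = ds$median,
      mean = ds$mean, fit = fit_report,
      fraction_above_threshold = fraction_above(h, threshold),
      n_domains = seg$n_domains,
      domain_volume_fraction = sum(seg$domains$volume_fraction),
      n_surface_touching = surf$n_surface_touching)
  }

  manifest <- list(
    package = "simsquant",
    version = as.character(utils::packageVersion("simsquant")),
    seed = config$seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(summary, file.path(stage_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(stage_dir, "run.log"))

  # all stages succeeded: move the bundle into place
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  files <- list.files(stage_dir)
  ok <- file.copy(file.path(stage_dir, files), config$output_dir,
                  overwrite = TRUE)
  if (!all(ok)) stage_error("report", "failed to write output bundle")
  invisible(list(output_dir = config$output_dir, summary = summary,
                 files = files))
}
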