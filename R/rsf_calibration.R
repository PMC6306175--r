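#' Depth scale of a profile under a uniform sputter rate
#'
#' Only the total crater depth is measured (by profilometry), so per-cycle
#' depths are assigned by the standard single-matrix SIMS assumption of a
#' constant sputter rate: cycle i (1-based) is placed at its midpoint depth
#' `(i - 0.5) / n_cycles * crater_depth`.
#'
#' @param profile A [depth_profile].
#' @return Numeric vector of cycle midpoint depths in nm, strictly
#'   increasing, spanning (0, crater_depth).
#' @export
#' @examples
#' depth_scale(depth_profile(rep(1, 10), crater_depth = 100))
depth_scale <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  (seq_len(profile$n_cycles) - 0.5) / profile$n_cycles * profile$crater_depth
}

#' RSF calibration from an ion-implanted standard
#'
#' The relative sensitivity factor (RSF) converts a species' secondary-ion
#' counts into atomic density (atoms/cm^3 per count). It is calibrated from
#' the depth profile of a standard implanted with a known areal dose
#' `phi` (atoms/cm^2): after subtracting the background count level, the
#' profile integral must equal the dose, so
#'
#'   `rsf = phi / (dz_cm * sum_i max(I_i - background_mean, 0))`
#'
#' where `dz_cm` is the constant per-cycle depth increment in cm. The
#' detection limit is the atomic density equivalent of the background:
#' by default `rsf * (background_mean + 3 * background_sd)` (a mean-only
#' convention is available via `lod_sigma = 0`).
#'
#' @param implant_profile A [depth_profile] that fully contains the implant
#'   peak.
#' @param dose Implanted areal dose in atoms/cm^2.
#' @param background_cycles Integer vector of cycle indices past the implant
#'   peak used to estimate the count background (e.g. `45:50`), or `NULL`
#'   when the background is known to be zero.
#' @param lod_sigma Number of background standard deviations added to the
#'   background mean in the detection-limit rule (default 3).
#' @param matrix_label Label of the host matrix (metadata only).
#'
#' @return An object of class `rsf_calibration` with fields `dose`, `rsf`
#'   (atoms/cm^3 per count), `background_mean`, `background_sd`,
#'   `lod_density` (atoms/cm^3), `lod_sigma`, `species_label`,
#'   `matrix_label`, and `dz_nm`.
#' @seealso [quantify_profile()], [cl_density_to_wtpct()]
#' @export
compute_rsf <- function(implant_profile, dose, background_cycles,
                        lod_sigma = 3, matrix_label = "HDPE") {
  stopifnot(inherits(implant_profile, "depth_profile"))
  if (!is_number(dose) || dose <= 0)
    stopf("'dose' must be a single positive areal density (atoms/cm^2)")
  n <- implant_profile$n_cycles
  counts <- implant_profile$counts
  if (is.null(background_cycles)) {
    bg_mean <- 0
    bg_sd <- 0
  } else {
    bg_idx <- as.integer(background_cycles)
    if (length(bg_idx) < 1L || any(bg_idx < 1L) || any(bg_idx > n))
      stopf("'background_cycles' must index cycles within 1..%d", n)
    if (which.max(counts) %in% bg_idx)
      warnf("background cycle range includes the profile maximum (cycle %d); background estimate is likely contaminated by the implant peak",
            which.max(counts))
    bg_mean <- mean(counts[bg_idx])
    bg_sd <- if (length(bg_idx) > 1L) stats::sd(counts[bg_idx]) else 0
  }
  net <- pmax(counts - bg_mean, 0)
  if (sum(net) <= 0)
    stopf("net implant integral is not positive; profile does not contain an implant above background")
  dz_nm <- implant_profile$crater_depth / n
  dz_cm <- dz_nm * 1e-7
  rsf <- dose / (dz_cm * sum(net))
  structure(
    list(dose = dose, rsf = rsf,
         background_mean = bg_mean, background_sd = bg_sd,
         lod_density = rsf * (bg_mean + lod_sigma * bg_sd),
         lod_sigma = lod_sigma,
         species_label = implant_profile$species_label,
         matrix_label = matrix_label, dz_nm = dz_nm),
    class = "rsf_calibration")
}

#' @export
print.rsf_calibration <- function(x, ...) {
  cat(sprintf("<rsf_calibration> %s in %s\n", x$species_label,
              x$matrix_label))
  cat(sprintf("  dose       %.4g atoms/cm^2\n", x$dose))
  cat(sprintf("  RSF        %.4g atoms/cm^3 per count\n", x$rsf))
  cat(sprintf("  background %.4g +/- %.4g counts\n",
              x$background_mean, x$background_sd))
  cat(sprintf("  LOD        %.4g atoms/cm^3 (mean + %g sd)\n",
              x$lod_density, x$lod_sigma))
  invisible(x)
}

#' Convert a raw depth profile to a concentration-versus-depth profile
#'
#' Applies a calibration to per-cycle counts:
#' `concentration_i = rsf * max(I_i - background_mean, 0)` at the depths
#' from [depth_scale()]. Truncation at zero keeps concentrations physical
#' when counts dip below the background estimate.
#'
#' @param profile A [depth_profile].
#' @param cal An [rsf_calibration][compute_rsf] for the same species.
#' @return An object of class `concentration_profile` with fields `depths`
#'   (nm), `concentrations` (atoms/cm^3), and `species_label`.
#' @export
quantify_profile <- function(profile, cal) {
  stopifnot(inherits(profile, "depth_profile"),
            inherits(cal, "rsf_calibration"))
  if (!identical(profile$species_label, cal$species_label))
    stopf("species mismatch: profile is '%s', calibration is for '%s'",
          profile$species_label, cal$species_label)
  structure(
    list(depths = depth_scale(profile),
         concentrations = cal$rsf * pmax(profile$counts -
                                           cal$background_mean, 0),
         species_label = profile$species_label),
    class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("<concentration_profile> %s: %d points, %.4g-%.4g nm\n",
              x$species_label, length(x$depths), min(x$depths),
              max(x$depths)))
  cat(sprintf("  concentration max %.4g atoms/cm^3\n",
              max(x$concentrations)))
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(depth_nm = x$depths, concentration = x$concentrations)
}
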