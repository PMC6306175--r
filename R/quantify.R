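#' Stoichiometric matrix model for density/weight-percent conversion
#'
#' Holds the constants linking a chlorine atomic density in the polymer to
#' an analyte mass fraction. Defaults describe permethrin (C21H20Cl2O3,
#' 391.29 g/mol, two Cl atoms per molecule) in high-density polyethylene
#' (0.95 g/cm^3); all are overridable for other analytes or matrices.
#'
#' @param matrix_density Host matrix density in g/cm^3.
#' @param analyte_molar_mass Analyte molar mass in g/mol.
#' @param cl_atoms_per_molecule Number of Cl atoms per analyte molecule.
#' @param avogadro Avogadro constant in 1/mol.
#' @return An object of class `matrix_model`.
#' @export
matrix_model <- function(matrix_density = 0.95,
                         analyte_molar_mass = 391.29,
                         cl_atoms_per_molecule = 2L,
                         avogadro = 6.02214076e23) {
  vals <- c(matrix_density, analyte_molar_mass, cl_atoms_per_molecule,
            avogadro)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all matrix_model constants must be positive and finite")
  if (cl_atoms_per_molecule != floor(cl_atoms_per_molecule))
    stopf("'cl_atoms_per_molecule' must be a positive integer")
  structure(
    list(matrix_density = matrix_density,
         analyte_molar_mass = analyte_molar_mass,
         cl_atoms_per_molecule = as.integer(cl_atoms_per_molecule),
         avogadro = avogadro),
    class = "matrix_model")
}

#' @export
print.matrix_model <- function(x, ...) {
  cat(sprintf(
    "<matrix_model> %g g/mol analyte (%d Cl/molecule) in %.3g g/cm^3 matrix\n",
    x$analyte_molar_mass, x$cl_atoms_per_molecule, x$matrix_density))
  invisible(x)
}

#' Convert between Cl atomic density and analyte weight percent
#'
#' Under the dilute approximation (sample density ~ matrix density), a Cl
#' atomic density `c_cl` (atoms/cm^3) corresponds to
#'
#'   `wt% = 100 * (c_cl / n_Cl) * M / N_A / rho`
#'
#' with `n_Cl` chlorine atoms per analyte molecule, molar mass `M`, Avogadro
#' constant `N_A`, and matrix density `rho`. `wtpct_to_cl_density()` is the
#' exact inverse. Both are linear and vectorised.
#'
#' @param c_cl Cl atomic density in atoms/cm^3 (non-negative).
#' @param m A [matrix_model] (defaults to permethrin in HDPE).
#' @return Weight percent of the analyte.
#' @export
#' @examples
#' cl_density_to_wtpct(1.5e18)   # detection limit of the Cl calibration
cl_density_to_wtpct <- function(c_cl, m = matrix_model()) {
  stopifnot(inherits(m, "matrix_model"))
  if (any(!is.finite(c_cl)) || any(c_cl < 0))
    stopf("'c_cl' must be non-negative and finite")
  100 * (c_cl / m$cl_atoms_per_molecule) * m$analyte_molar_mass /
    m$avogadro / m$matrix_density
}

#' @rdname cl_density_to_wtpct
#' @param w Analyte weight percent (non-negative).
#' @export
wtpct_to_cl_density <- function(w, m = matrix_model()) {
  stopifnot(inherits(m, "matrix_model"))
  if (any(!is.finite(w)) || any(w < 0))
    stopf("'w' must be non-negative and finite")
  w / 100 * m$matrix_density * m$avogadro / m$analyte_molar_mass *
    m$cl_atoms_per_molecule
}

#' Detection limit of a calibration expressed as analyte weight percent
#'
#' @param cal An [rsf_calibration][compute_rsf].
#' @param m A [matrix_model].
#' @return The calibration's `lod_density` converted to wt%.
#' @export
lod_wtpct <- function(cal, m = matrix_model()) {
  stopifnot(inherits(cal, "rsf_calibration"))
  cl_density_to_wtpct(cal$lod_density, m)
}
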