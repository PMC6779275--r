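#' Cell geometry for unit conversion
#'
#' Concentrations are handled in nM and stochastic species in molecules per
#' cell; the conversion needs a cell volume. The default volume is
#' 2.5e-12 L, a typical HeLa cell volume; it is configurable and reported in
#' all output metadata.
#'
#' @param volume_l cell volume in litres (> 0).
#' @return object of class `cell_geometry` with fields `volume_l` and
#'   `avogadro`.
#' @export
#' @examples
#' geom <- cell_geometry()
#' concentration_to_copies(63, geom)  # XIAP at 63 nM
cell_geometry <- function(volume_l = 2.5e-12) {
  if (!is.numeric(volume_l) || length(volume_l) != 1L || !is.finite(volume_l) ||
      volume_l <= 0) {
    stop("`volume_l` must be a single positive number", call. = FALSE)
  }
  structure(list(volume_l = volume_l, avogadro = 6.02214076e23),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> volume %.3g L (1 nM = %.1f molecules)\n",
              x$volume_l, nm_to_molecules_factor(x)))
  invisible(x)
}

# molecules per cell corresponding to 1 nM
nm_to_molecules_factor <- function(geom) {
  1e-9 * geom$avogadro * geom$volume_l
}

#' Convert a concentration in nM to a molecule count
#'
#' @param c_nm concentration in nM (vectorised, all >= 0).
#' @param geom a [cell_geometry()].
#' @return integer-valued molecule counts, `round(c * 1e-9 * N_A * V)`.
#' @export
concentration_to_copies <- function(c_nm, geom = cell_geometry()) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (!is.numeric(c_nm) || any(!is.finite(c_nm)) || any(c_nm < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  round(c_nm * nm_to_molecules_factor(geom))
}

#' Convert a molecule count to a concentration in nM
#'
#' Inverse of [concentration_to_copies()]; round-trips within half a molecule.
#'
#' @param n molecule count (>= 0).
#' @inheritParams concentration_to_copies
#' @return concentration in nM.
#' @export
copies_to_concentration <- function(n, geom = cell_geometry()) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0)) {
    stop("molecule counts must be finite and >= 0", call. = FALSE)
  }
  n / nm_to_molecules_factor(geom)
}

#' Convert a ligand dose from ng/mL to nM
#'
#' Death-ligand doses are quoted in ng/mL; mass-action needs nM. The
#' conversion uses the ligand monomer mass (default 19.6 kDa, rhTRAIL).
#'
#' @param dose_ng_ml dose in ng/mL (>= 0).
#' @param ligand_mass_kda monomer mass in kDa (> 0).
#' @return concentration in nM.
#' @export
#' @examples
#' dose_to_nm(5)   # low dose
#' dose_to_nm(50)  # high dose
dose_to_nm <- function(dose_ng_ml, ligand_mass_kda = 19.6) {
  if (any(dose_ng_ml < 0)) stop("dose must be >= 0", call. = FALSE)
  if (ligand_mass_kda <= 0) stop("ligand mass must be > 0", call. = FALSE)
  # ng/mL = 1e-9 g / 1e-3 L = 1e-6 g/L; / (kDa * 1000 g/mol) -> mol/L; * 1e9 -> nM
  dose_ng_ml * 1e-6 / (ligand_mass_kda * 1000) * 1e9
}
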