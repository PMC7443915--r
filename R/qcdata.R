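# Data model for excited-state calculation records: geometry, AO basis map,
# overlap matrix, MO coefficients and TDDFT excitations. Restricted
# (closed-shell) calculations only; one coefficient set.

#' Energy-wavelength conversion constant (eV nm)
#'
#' Product of Planck's constant and the speed of light, in eV nm. Fixed so
#' that every energy/wavelength conversion in the package uses one value.
#' @export
EV_NM <- 1239.841984

#' Convert excitation energy (eV) to wavelength (nm) and back
#'
#' The conversion is its own inverse: `ev_to_nm(ev_to_nm(x)) == x` up to
#' floating point.
#'
#' @param energy_ev Energy in eV (or, by symmetry, wavelength in nm).
#' @return Wavelength in nm (or energy in eV).
#' @export
ev_to_nm <- function(energy_ev) {
  stopifnot(is.numeric(energy_ev), all(is.finite(energy_ev)), all(energy_ev > 0))
  EV_NM / energy_ev
}

# Valid element symbols for Z = 1..103 (index = atomic number)
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr")

#' Build a molecular geometry
#'
#' @param element Character vector of chemical symbols, one per atom.
#' @param coords Numeric matrix `n_atoms x 3` of Cartesian positions in
#'   Angstrom.
#' @return An object of class `rc_geometry`: a data frame with columns
#'   `index`, `element`, `x`, `y`, `z`.
#' @export
geometry <- function(element, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) != length(element))
    stop("coords must be an n_atoms x 3 matrix matching 'element'")
  if (!all(is.finite(coords))) stop("geometry positions must be finite")
  bad <- setdiff(element, .ELEMENTS)
  if (length(bad)) stop("invalid element symbol(s): ", paste(bad, collapse = ", "))
  g <- data.frame(index = seq_along(element), element = element,
                  x = coords[, 1], y = coords[, 2], z = coords[, 3],
                  stringsAsFactors = FALSE)
  class(g) <- c("rc_geometry", "data.frame")
  g
}

#' @export
print.rc_geometry <- function(x, ...) {
  cat(sprintf("<rc_geometry> %d atoms (%s)\n", nrow(x),
              paste(utils::head(unique(x$element), 8), collapse = " ")))
  invisible(x)
}

coords_matrix <- function(geom) as.matrix(geom[, c("x", "y", "z")])

#' Validate an AO overlap matrix
#'
#' Checks symmetry (1e-10), unit diagonal (1e-8, normalized AO basis) and
#' positive definiteness.
#'
#' @param S Square numeric matrix over basis functions.
#' @return `S`, invisibly, on success; error otherwise.
#' @export
validate_overlap <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("overlap must be a square matrix")
  if (max(abs(S - t(S))) > 1e-10) stop("overlap matrix not symmetric to 1e-10")
  if (max(abs(diag(S) - 1)) > 1e-8) stop("overlap diagonal deviates from 1 beyond 1e-8")
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop(sprintf("overlap matrix not positive definite (min eigenvalue %.3e)", ev))
  invisible(S)
}

#' Build a set of molecular orbitals
#'
#' @param C Coefficient matrix, rows = basis functions, columns = MOs.
#' @param n_occupied Number of doubly-occupied MOs (restricted convention).
#' @param energies Optional per-MO energies; defaults to `NA`.
#' @param energy_unit `"eV"` or `"hartree"`.
#' @param S Optional overlap matrix; when supplied each column is checked for
#'   S-normalization (`|c' S c - 1| <= 1e-6`).
#' @return Object of class `rc_moset` with fields `C`, `energies`,
#'   `energy_unit`, `n_occupied`.
#' @export
moset <- function(C, n_occupied, energies = NULL, energy_unit = "hartree", S = NULL) {
  C <- as.matrix(C)
  n_mo <- ncol(C)
  if (!(n_occupied > 0 && n_occupied < n_mo))
    stop("need 0 < n_occupied < n_MOs")
  if (is.null(energies)) energies <- rep(NA_real_, n_mo)
  if (length(energies) != n_mo) stop("energies length must equal number of MOs")
  if (!energy_unit %in% c("eV", "hartree")) stop("energy_unit must be 'eV' or 'hartree'")
  if (!is.null(S)) {
    norms <- colSums(C * (S %*% C))
    if (max(abs(norms - 1)) > 1e-6)
      stop(sprintf("MO columns not S-normalized (max |norm-1| = %.3e)", max(abs(norms - 1))))
  }
  structure(list(C = C, energies = as.numeric(energies),
                 energy_unit = energy_unit, n_occupied = as.integer(n_occupied)),
            class = "rc_moset")
}

#' Build an excited state
#'
#' @param k 1-based state index.
#' @param energy Excitation energy in eV.
#' @param f Oscillator strength (dimensionless, `>= 0`).
#' @param transitions Data frame with columns `occ`, `virt`, `amplitude` and
#'   optionally `deexcitation` (zero when absent): signed occupied->virtual
#'   CI amplitudes as printed by the electronic-structure program.
#' @param n_occupied Optional; when given, `occ <= n_occupied < virt` is
#'   enforced for every transition.
#' @return Object of class `rc_state`. The wavelength field (nm) is always
#'   computed from the energy via [ev_to_nm()].
#' @export
excited_state <- function(k, energy, f, transitions, n_occupied = NULL) {
  if (!is.data.frame(transitions) || nrow(transitions) == 0)
    stop("transitions must be a non-empty data frame")
  if (!all(c("occ", "virt", "amplitude") %in% names(transitions)))
    stop("transitions needs columns occ, virt, amplitude")
  if (is.null(transitions$deexcitation)) transitions$deexcitation <- 0
  if (!all(is.finite(transitions$amplitude))) stop("amplitudes must be finite")
  if (f < 0) stop("oscillator strength must be >= 0")
  if (!is.null(n_occupied)) {
    if (any(transitions$occ > n_occupied) || any(transitions$virt <= n_occupied))
      stop("transition indices violate occ <= n_occupied < virt")
  }
  structure(list(k = as.integer(k), energy = as.numeric(energy),
                 wavelength = ev_to_nm(energy), f = as.numeric(f),
                 transitions = transitions[, c("occ", "virt", "amplitude", "deexcitation")]),
            class = "rc_state")
}

#' @export
print.rc_state <- function(x, ...) {
  cat(sprintf("<rc_state %d> %.4f eV (%.2f nm) f=%.4f, %d transition(s)\n",
              x$k, x$energy, x$wavelength, x$f, nrow(x$transitions)))
  invisible(x)
}

#' Assemble a calculation record
#'
#' Bundles geometry, AO basis-to-atom map, overlap, MOs and excited states
#' and checks cross-dimensional consistency. The overlap may be `NULL`
#' ("to be supplied"): then operations needing Mulliken populations refuse
#' to run.
#'
#' @param geometry An [geometry()] object.
#' @param basis_map Integer vector: owning atom index per basis function.
#' @param overlap AO overlap matrix, or `NULL` if not yet supplied.
#' @param mos An [moset()] object.
#' @param states List of [excited_state()] objects, sorted by increasing
#'   energy (enforced).
#' @param meta Named list of metadata (model label, mutation tag, source).
#' @return Object of class `rc_record`.
#' @export
calculation_record <- function(geometry, basis_map, overlap, mos, states = list(),
                               meta = list()) {
  n_atoms <- nrow(geometry)
  basis_map <- as.integer(basis_map)
  if (any(basis_map < 1L) || any(basis_map > n_atoms))
    stop("basis_map refers to atoms outside 1..", n_atoms)
  n_bf <- length(basis_map)
  if (!is.null(overlap)) {
    validate_overlap(overlap)
    if (nrow(overlap) != n_bf)
      stop(sprintf("overlap dimension %d != basis_map length %d", nrow(overlap), n_bf))
  }
  if (nrow(mos$C) != n_bf)
    stop(sprintf("MO coefficient rows %d != basis_map length %d", nrow(mos$C), n_bf))
  if (length(states)) {
    en <- vapply(states, function(s) s$energy, numeric(1))
    if (is.unsorted(en)) stop("states must be sorted by increasing energy")
    for (s in states) {
      if (any(s$transitions$occ > mos$n_occupied) ||
          any(s$transitions$virt <= mos$n_occupied) ||
          any(s$transitions$virt > ncol(mos$C)))
        stop(sprintf("state %d transition indices inconsistent with MO set", s$k))
    }
  }
  structure(list(geometry = geometry, basis_map = basis_map, overlap = overlap,
                 mos = mos, states = states, meta = meta),
            class = "rc_record")
}

#' @export
print.rc_record <- function(x, ...) {
  cat(sprintf("<rc_record> %d atoms, %d basis functions, %d MOs (%d occ), %d states%s\n",
              nrow(x$geometry), length(x$basis_map), ncol(x$mos$C),
              x$mos$n_occupied, length(x$states),
              if (is.null(x$overlap)) " [overlap pending]" else ""))
  invisible(x)
}

has_overlap <- function(record) !is.null(record$overlap)

require_overlap <- function(record, stage = "population") {
  if (!has_overlap(record))
    stop(stage, " stage: overlap matrix not supplied for this record; ",
         "Mulliken operations refuse to run", call. = FALSE)
  record$overlap
}
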