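# Mulliken population decomposition of molecular orbitals into per-atom and
# per-fragment percentage contributions.

#' Mulliken per-basis-function weight of one MO
#'
#' For an S-normalized MO with coefficients `c`, the Mulliken weight of basis
#' function mu is Theta_mu = sum_nu c_mu c_nu S_munu, i.e. the diagonal of
#' P S for the rank-1 density P = c c'. Off-diagonal overlap terms are split
#' half-and-half between the two centers, the standard Mulliken MO-composition
#' convention. The weights sum to 1; individual entries may be slightly
#' negative (a known Mulliken artifact) and are reported as-is.
#'
#' @param C MO coefficient matrix (basis functions x MOs).
#' @param S AO overlap matrix.
#' @param mo MO column index.
#' @return Numeric vector of per-basis-function weights summing to 1.
#' @export
bf_contribution <- function(C, S, mo) {
  c_i <- C[, mo]
  nrm <- sum(c_i * (S %*% c_i))
  if (abs(nrm - 1) > 1e-6)
    stop(sprintf("MO %d is not S-normalized: measured norm %.8f", mo, nrm))
  as.numeric(c_i * (S %*% c_i))
}

#' Per-fragment percentage contributions to one MO
#'
#' Sums the Mulliken basis-function weights of [bf_contribution()] over the
#' atoms of each fragment; the implicit environment bucket absorbs the rest.
#' Percentages total 100 (up to rounding in the output).
#'
#' @param record A [calculation_record()] with an overlap matrix.
#' @param fmap An [fragment_map()].
#' @param mo MO column index.
#' @return Named numeric vector of percentages over
#'   `c(names(fmap$fragments), "environment")`, with attribute `subject` set
#'   to the MO index.
#' @export
fragment_profile <- function(record, fmap, mo) {
  S <- require_overlap(record)
  theta <- bf_contribution(record$mos$C, S, mo)
  atom_of_bf <- record$basis_map
  frag_of_bf <- fragment_of_atom(fmap)[atom_of_bf]
  lev <- fragment_names(fmap)
  pct <- 100 * vapply(lev, function(f) sum(theta[frag_of_bf == f]), numeric(1))
  attr(pct, "subject") <- mo
  pct
}

#' Fragment profiles for all MOs
#'
#' @inheritParams fragment_profile
#' @return Numeric matrix, rows = MOs, columns = fragments plus
#'   `environment`; each row sums to 100.
#' @export
all_profiles <- function(record, fmap) {
  n_mo <- ncol(record$mos$C)
  lev <- fragment_names(fmap)
  out <- matrix(NA_real_, n_mo, length(lev), dimnames = list(seq_len(n_mo), lev))
  for (i in seq_len(n_mo)) out[i, ] <- fragment_profile(record, fmap, i)
  out
}

#' Export MO fragment profiles as TSV
#'
#' Rows = MOs, columns = fragments + environment, percentages to 2 dp.
#'
#' @param profiles Matrix from [all_profiles()].
#' @param path Output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  tab <- data.frame(mo = as.integer(rownames(profiles)),
                    round(profiles, 2), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
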