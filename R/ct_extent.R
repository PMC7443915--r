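# Charge-transfer extent from the unrelaxed difference density: per-atom
# population changes, barycenters of density depletion and increment, and
# the nearest-atom/cofactor CT criterion.

#' Per-atom electron-population change of an excited state
#'
#' Builds the CI-weighted unrelaxed difference density
#' `DeltaP = sum_t w_t (c_a c_a' - c_i c_i')` (normalized weights `w_t` from
#' [transition_weights()]) and Mulliken-partitions it onto atoms:
#' `Delta n_A = sum_{mu on A} (DeltaP S)_mumu`. Electron gain is positive;
#' the changes sum to zero (particle conservation).
#'
#' @param state An [excited_state()].
#' @param record A [calculation_record()] with an overlap matrix.
#' @param config An [analysis_config()].
#' @return Numeric vector of length `n_atoms`, summing to 0.
#' @export
difference_density_populations <- function(state, record,
                                           config = analysis_config()) {
  S <- require_overlap(record, stage = "ct-extent")
  w <- transition_weights(state, config)
  C <- record$mos$C
  # diag((c c') S) is just the per-bf Mulliken weight of that MO, so the
  # difference density's diagonal partition is a weighted Theta difference
  dn_bf <- numeric(nrow(C))
  for (i in seq_len(nrow(w))) {
    th_a <- bf_contribution(C, S, w$virt[i])
    th_i <- bf_contribution(C, S, w$occ[i])
    dn_bf <- dn_bf + w$weight[i] * (th_a - th_i)
  }
  dn <- vapply(seq_len(nrow(record$geometry)),
               function(a) sum(dn_bf[record$basis_map == a]), numeric(1))
  if (abs(sum(dn)) > 1e-8)
    stop(sprintf("difference-density populations do not conserve charge (sum %.3e)",
                 sum(dn)))
  dn
}

#' Charge-transfer extent report for one state
#'
#' The increment centroid `R_plus` is the barycenter of the atoms that gain
#' electron density (weights `Delta n_A > 0`), the depletion centroid
#' `R_minus` the barycenter of the losers (weights `|Delta n_A|`), and
#' `D_CT = |R_plus - R_minus|` in Angstrom. The state is flagged CT when the
#' nearest atoms to the two centroids (Euclidean distance, ties to the lower
#' atom index) sit on different fragments.
#'
#' @param deltas Per-atom population changes from
#'   [difference_density_populations()].
#' @param geom The [geometry()].
#' @param fmap An [fragment_map()].
#' @return Object of class `rc_ct_extent`: list with `r_plus`, `r_minus`
#'   (Cartesian, Angstrom), `d_ct`, `nearest_plus`, `nearest_minus` (each a
#'   list of `element`, `atom`, `fragment`) and `is_ct`. Degenerate inputs
#'   (no gain or no loss anywhere) give `d_ct = 0`, `is_ct = FALSE`.
#' @export
ct_extent <- function(deltas, geom, fmap) {
  if (length(deltas) != nrow(geom))
    stop("deltas length must equal the number of atoms")
  if (abs(sum(deltas)) > 1e-8)
    stop("deltas must conserve charge (sum to 0)")
  xyz <- coords_matrix(geom)
  pos <- deltas > 0; neg <- deltas < 0
  if (!any(pos) || !any(neg)) {
    return(structure(list(r_plus = NULL, r_minus = NULL, d_ct = 0,
                          nearest_plus = NULL, nearest_minus = NULL,
                          is_ct = FALSE), class = "rc_ct_extent"))
  }
  bary <- function(sel, w) colSums(xyz[sel, , drop = FALSE] * w) / sum(w)
  r_plus <- bary(pos, deltas[pos])
  r_minus <- bary(neg, abs(deltas[neg]))
  frag <- fragment_of_atom(fmap)
  nearest <- function(r) {
    d2 <- rowSums((xyz - matrix(r, nrow(xyz), 3, byrow = TRUE))^2)
    a <- which.min(d2)  # which.min takes the lowest index on ties
    list(element = geom$element[a], atom = a, fragment = frag[a])
  }
  np <- nearest(r_plus); nm <- nearest(r_minus)
  structure(list(r_plus = r_plus, r_minus = r_minus,
                 d_ct = sqrt(sum((r_plus - r_minus)^2)),
                 nearest_plus = np, nearest_minus = nm,
                 is_ct = np$fragment != nm$fragment),
            class = "rc_ct_extent")
}

#' @export
print.rc_ct_extent <- function(x, ...) {
  if (is.null(x$r_plus)) {
    cat("<rc_ct_extent> degenerate (no transfer), D_CT = 0\n")
  } else {
    cat(sprintf("<rc_ct_extent> D_CT = %.3f A  %s(%s %d) -> %s(%s %d)  is_ct=%s\n",
                x$d_ct, x$nearest_minus$fragment, x$nearest_minus$element,
                x$nearest_minus$atom, x$nearest_plus$fragment,
                x$nearest_plus$element, x$nearest_plus$atom, x$is_ct))
  }
  invisible(x)
}

#' CT-extent table for all states of a record
#'
#' @param record A [calculation_record()] with overlap and states.
#' @param fmap An [fragment_map()].
#' @param config An [analysis_config()].
#' @return Data frame: `state`, `d_ct_A`, tail (`minus`) and head (`plus`)
#'   element/atom/fragment, `is_ct`.
#' @export
ct_extent_table <- function(record, fmap, config = analysis_config()) {
  do.call(rbind, lapply(record$states, function(s) {
    dn <- difference_density_populations(s, record, config)
    e <- ct_extent(dn, record$geometry, fmap)
    deg <- is.null(e$r_plus)
    data.frame(state = s$k, d_ct_A = round(e$d_ct, 4),
               minus_element = if (deg) NA else e$nearest_minus$element,
               minus_atom = if (deg) NA else e$nearest_minus$atom,
               minus_fragment = if (deg) NA else e$nearest_minus$fragment,
               plus_element = if (deg) NA else e$nearest_plus$element,
               plus_atom = if (deg) NA else e$nearest_plus$atom,
               plus_fragment = if (deg) NA else e$nearest_plus$fragment,
               is_ct = e$is_ct)
  }))
}
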