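# Per-transition weights, state-to-cofactor assignment, charge-transfer
# direction classification and the per-state aggregations used for the
# cofactor-contribution and CT-character summaries.

#' Analysis configuration
#'
#' @param ct_threshold Minimum inter-fragment transfer, in percentage points
#'   of Mulliken weight, for a transition to be called charge transfer rather
#'   than local. Default 5.
#' @param amplitude_convention Printed-amplitude convention. `"restricted"`
#'   (the default, and the only one implemented) treats printed CI amplitudes
#'   c as normalized so that the percentage contribution of a transition is
#'   200 c^2 (so sum c^2 ~ 0.5 over a state).
#' @return Object of class `rc_analysis_config`.
#' @export
analysis_config <- function(ct_threshold = 5, amplitude_convention = "restricted") {
  if (ct_threshold < 0) stop("ct_threshold must be >= 0")
  amplitude_convention <- match.arg(amplitude_convention, "restricted")
  structure(list(ct_threshold = ct_threshold,
                 amplitude_convention = amplitude_convention),
            class = "rc_analysis_config")
}

CT_CATEGORIES <- c("up-active", "down-active", "up-inactive", "down-inactive",
                   "within-P", "local", "other")

#' Per-transition percentage contributions and normalized weights
#'
#' Under the restricted printed-amplitude convention the percentage
#' contribution of transition i->a with amplitude c is 200 c^2 (so |c| =
#' 0.57 reads as ~65%). De-excitation amplitudes do not enter the weights.
#' Normalized weights renormalize c^2 over the state's transitions to sum 1.
#'
#' @param state An [excited_state()].
#' @param config An [analysis_config()].
#' @return Data frame with columns `occ`, `virt`, `amplitude`, `percent`,
#'   `weight` (normalized, sums to 1).
#' @export
transition_weights <- function(state, config = analysis_config()) {
  tr <- state$transitions
  c2 <- tr$amplitude^2
  if (sum(c2) == 0) stop(sprintf("state %d has all-zero amplitudes", state$k))
  data.frame(occ = tr$occ, virt = tr$virt, amplitude = tr$amplitude,
             percent = 200 * c2, weight = c2 / sum(c2))
}

#' Assign an excited state to the cofactor dominating its occupied orbitals
#'
#' The state is labeled as an excitation of the fragment with the largest
#' normalized-weight-averaged Mulliken contribution to the occupied MOs of
#' its transitions. Ties within 1e-6 are broken toward the dominant
#' transition's own occupied-MO argmax, then lexicographically. The
#' environment bucket wins only if it exceeds every cofactor.
#'
#' @param state An [excited_state()].
#' @param mo_profiles Matrix from [all_profiles()] (rows = MOs).
#' @param config An [analysis_config()].
#' @return Fragment name (character scalar).
#' @export
assign_state_label <- function(state, mo_profiles, config = analysis_config()) {
  w <- transition_weights(state, config)
  if (any(w$occ > nrow(mo_profiles)))
    stop("missing MO profile for occupied MO(s) of state ", state$k)
  avg <- colSums(mo_profiles[w$occ, , drop = FALSE] * w$weight)
  pick_among <- function(v) {
    frg <- setdiff(names(v), ENVIRONMENT_NAME)
    best_cof <- max(v[frg])
    cand <- if (!is.na(v[ENVIRONMENT_NAME]) && v[ENVIRONMENT_NAME] > best_cof)
      ENVIRONMENT_NAME else frg[v[frg] >= best_cof - 1e-6]
    cand
  }
  cand <- pick_among(avg)
  if (length(cand) > 1) {
    dom <- w$occ[which.max(w$weight)]
    dom_prof <- mo_profiles[dom, ]
    dom_best <- cand[which.max(dom_prof[cand])]
    also_top <- cand[dom_prof[cand] >= dom_prof[dom_best] - 1e-6]
    cand <- sort(also_top)[1]
  }
  cand[1]
}

#' Classify the charge-transfer direction of one transition
#'
#' Compares the fragment profiles of the occupied and virtual MOs: Delta_F =
#' percent_virt[F] - percent_occ[F]. The donor is the fragment with the most
#' negative Delta, the acceptor the most positive; the transfer magnitude is
#' Delta at the acceptor, in percentage points. Transfers below the
#' `ct_threshold` are local. Transfers between the two special-pair
#' chlorophylls are `within-P`; from the P pair up a branch `up-<branch>`;
#' toward the P pair `down-<branch>`; within one branch by rank; anything
#' involving a fragment outside the topology (or crossing branches away from
#' P) is `other`.
#'
#' @param occ_profile,virt_profile Named percentage vectors from
#'   [fragment_profile()] for the occupied and virtual MO.
#' @param topology An `rc_topology` from [default_topology()].
#' @param config An [analysis_config()].
#' @return List with `category`, `donor`, `acceptor`, `magnitude`.
#' @export
transition_ct <- function(occ_profile, virt_profile, topology,
                          config = analysis_config()) {
  if (!identical(names(occ_profile), names(virt_profile)))
    stop("occupied and virtual profiles must cover the same fragments")
  delta <- virt_profile - occ_profile
  donor <- names(delta)[which.min(delta)]
  acceptor <- names(delta)[which.max(delta)]
  magnitude <- unname(delta[acceptor])
  category <- if (donor == acceptor || magnitude < config$ct_threshold) {
    "local"
  } else {
    bd <- branch_of(topology, donor); ba <- branch_of(topology, acceptor)
    rd <- rank_of(topology, donor); ra <- rank_of(topology, acceptor)
    if (bd == "none" || ba == "none") {
      "other"
    } else if (bd == "P-pair" && ba == "P-pair") {
      "within-P"
    } else if (bd == "P-pair") {
      if (ba == "D1") "up-active" else "up-inactive"
    } else if (ba == "P-pair") {
      if (bd == "D1") "down-active" else "down-inactive"
    } else if (bd == ba) {
      dir <- if (ra > rd) "up" else "down"
      paste0(dir, if (bd == "D1") "-active" else "-inactive")
    } else {
      "other"
    }
  }
  list(category = category, donor = donor, acceptor = acceptor,
       magnitude = magnitude)
}

#' Full per-state characterization
#'
#' Aggregates over a state's transitions with normalized CI weights: the
#' CI-weighted occupied-MO fragment profile (which cofactor is excited), the
#' CI-weight mass per CT-direction category, and the cofactor label.
#'
#' @param state An [excited_state()].
#' @param record A [calculation_record()] with overlap.
#' @param fmap An [fragment_map()].
#' @param topology An `rc_topology`.
#' @param config An [analysis_config()].
#' @param mo_profiles Optional precomputed [all_profiles()] matrix.
#' @return Object of class `rc_state_character`: list with `k`, `energy`,
#'   `wavelength`, `f`, `label`, `occ_profile` (sums to 100), `ct_profile`
#'   (per-category weight mass, sums to 1), `dominant` (occ, virt, percent)
#'   and per-transition `directions`.
#' @export
state_character <- function(state, record, fmap, topology = default_topology(),
                            config = analysis_config(), mo_profiles = NULL) {
  if (is.null(mo_profiles)) mo_profiles <- all_profiles(record, fmap)
  w <- transition_weights(state, config)
  occ_profile <- colSums(mo_profiles[w$occ, , drop = FALSE] * w$weight)
  ct_profile <- stats::setNames(numeric(length(CT_CATEGORIES)), CT_CATEGORIES)
  dirs <- vector("list", nrow(w))
  for (i in seq_len(nrow(w))) {
    d <- transition_ct(mo_profiles[w$occ[i], ], mo_profiles[w$virt[i], ],
                       topology, config)
    ct_profile[d$category] <- ct_profile[d$category] + w$weight[i]
    dirs[[i]] <- d
  }
  idom <- which.max(w$weight)
  structure(list(
    k = state$k, energy = state$energy, wavelength = state$wavelength,
    f = state$f,
    label = assign_state_label(state, mo_profiles, config),
    occ_profile = occ_profile, ct_profile = ct_profile,
    dominant = list(occ = w$occ[idom], virt = w$virt[idom],
                    percent = w$percent[idom]),
    directions = dirs), class = "rc_state_character")
}

#' @export
print.rc_state_character <- function(x, ...) {
  top_ct <- names(x$ct_profile)[which.max(x$ct_profile)]
  cat(sprintf("<state %d> %.4f eV f=%.4f  label=%s  dominant %d->%d (%.1f%%)  ct=%s\n",
              x$k, x$energy, x$f, x$label, x$dominant$occ, x$dominant$virt,
              x$dominant$percent, top_ct))
  invisible(x)
}

#' Count state labels inside a wavelength window
#'
#' @param states List of [excited_state()] objects.
#' @param labels Character vector of cofactor labels, parallel to `states`.
#' @param window Numeric length-2 wavelength interval in nm (closed; order
#'   irrelevant).
#' @return Named integer vector: number of in-window states per label.
#' @export
count_labels <- function(states, labels, window) {
  if (length(window) != 2 || diff(range(window)) <= 0)
    stop("window must be a non-empty wavelength interval [min, max] nm")
  if (length(labels) != length(states))
    stop("labels must be parallel to states")
  wl <- vapply(states, function(s) s$wavelength, numeric(1))
  keep <- wl >= min(window) & wl <= max(window)
  tab <- table(factor(labels[keep], levels = sort(unique(labels))))
  out <- stats::setNames(as.integer(tab), names(tab))
  out
}

#' Characterize all states of a record
#'
#' @inheritParams state_character
#' @return List of `rc_state_character`, one per state.
#' @export
characterize_states <- function(record, fmap, topology = default_topology(),
                                config = analysis_config()) {
  mo_profiles <- all_profiles(record, fmap)
  lapply(record$states, state_character, record = record, fmap = fmap,
         topology = topology, config = config, mo_profiles = mo_profiles)
}

#' Per-state summary table (machine-readable twin of the state table)
#'
#' @param chars List from [characterize_states()].
#' @return Data frame: `state`, `energy_eV`, `wavelength_nm`, `f`, `label`,
#'   `dominant_occ`, `dominant_virt`, `dominant_percent`.
#' @export
state_table <- function(chars) {
  do.call(rbind, lapply(chars, function(x)
    data.frame(state = x$k, energy_eV = round(x$energy, 4),
               wavelength_nm = round(x$wavelength, 2), f = round(x$f, 4),
               label = x$label, dominant_occ = x$dominant$occ,
               dominant_virt = x$dominant$virt,
               dominant_percent = round(x$dominant$percent, 2))))
}

#' Per-state CT-category weight table
#'
#' @param chars List from [characterize_states()].
#' @return Data frame: `state` plus one column per CT category, each row the
#'   normalized CI-weight mass (sums to 1).
#' @export
ct_profile_table <- function(chars) {
  do.call(rbind, lapply(chars, function(x) {
    row <- as.data.frame(as.list(round(x$ct_profile, 4)), check.names = FALSE)
    cbind(data.frame(state = x$k), row)
  }))
}
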