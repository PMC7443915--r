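# Synthetic calculation records with known ground truth: fragment-localized
# MOs over a controllable overlap, states with planted dominant transitions
# and CT character, band structure and mutant shifts. Every record carries a
# sidecar of intentions so pipeline recovery is testable end to end.

SCENARIO_NAMES <- c("local-excitation", "ct-up-active", "ct-down-active",
                    "ct-up-inactive", "ct-down-inactive", "within-P",
                    "mixed", "soret-pd1", "mutant-shift-pair")

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Describe a synthetic scenario
#'
#' @param name One of `"local-excitation"`, `"ct-up-active"`,
#'   `"ct-down-active"`, `"ct-up-inactive"`, `"ct-down-inactive"`,
#'   `"within-P"`, `"mixed"`, `"soret-pd1"`, `"mutant-shift-pair"`.
#' @param n_fragments Number of cofactors (2-6, canonical names in order);
#'   forced to 6 for scenarios that reference both branches.
#' @param atoms_per_fragment Atoms per cofactor cluster (default 2).
#' @param bf_per_atom Basis functions per atom (default 5).
#' @param localization Target Mulliken home-fragment weight rho of each MO,
#'   in (0.5, 1] (default 0.9).
#' @param coupling Off-diagonal overlap scale epsilon in [0, 0.3)
#'   (default 0.1).
#' @param n_states Number of excited states (default 6; fixed at 22 for
#'   `soret-pd1` and `mutant-shift-pair`).
#' @param delta_e Energy offset (eV) applied to PD1-labeled states of the
#'   mutant record in `mutant-shift-pair` (default +0.02; positive =
#'   blue shift).
#' @param seed Integer seed; every stochastic choice of the generator flows
#'   from it.
#' @return Object of class `rc_scenario`.
#' @export
scenario <- function(name, n_fragments = 6, atoms_per_fragment = 2,
                     bf_per_atom = 5, localization = 0.9, coupling = 0.1,
                     n_states = 6, delta_e = 0.02, seed = 1) {
  name <- match.arg(name, SCENARIO_NAMES)
  if (!(localization > 0.5 && localization <= 1))
    stop("localization must lie in (0.5, 1]")
  if (!(coupling >= 0 && coupling < 0.3))
    stop("coupling must lie in [0, 0.3)")
  needs_six <- name != "local-excitation"
  if (needs_six) n_fragments <- 6
  if (!(n_fragments >= 2 && n_fragments <= 6))
    stop("n_fragments must be 2-6")
  if (name %in% c("soret-pd1", "mutant-shift-pair")) n_states <- 22
  structure(list(name = name, n_fragments = n_fragments,
                 atoms_per_fragment = atoms_per_fragment,
                 bf_per_atom = bf_per_atom, localization = localization,
                 coupling = coupling, n_states = n_states, delta_e = delta_e,
                 seed = as.integer(seed)),
            class = "rc_scenario")
}

#' Random SPD overlap matrix with unit diagonal
#'
#' `S = I + eps (R + R') / 2` with `R` uniform(-1, 1) off-diagonal and the
#' diagonal reset to 1. If the smallest eigenvalue is not above 0.05 the
#' coupling is halved and the matrix regenerated, at most 10 times.
#'
#' @param n_bf Dimension.
#' @param eps Coupling scale, `< 0.3`.
#' @param seed Integer seed.
#' @return Symmetric positive-definite matrix with unit diagonal.
#' @export
make_overlap <- function(n_bf, eps, seed) {
  if (eps >= 0.3) stop("eps must be < 0.3")
  with_seed(seed, {
    for (try in 1:10) {
      R <- matrix(stats::runif(n_bf * n_bf, -1, 1), n_bf, n_bf)
      S <- diag(n_bf) + eps * (R + t(R)) / 2
      diag(S) <- 1
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0.05)
        return(S)
      eps <- eps / 2
    }
    stop("could not build an SPD overlap with min eigenvalue > 0.05")
  })
}

# Mulliken weight of one coefficient vector on a set of basis functions
mulliken_weight_on <- function(c_vec, S, on_bf) {
  th <- c_vec * (S %*% c_vec)
  sum(th[on_bf]) / sum(th)
}

#' Build fragment-localized molecular orbitals
#'
#' Each MO is constructed so that its Mulliken weight on its home fragment is
#' within 0.02 of the target `rho`, by iterative rescaling of the on-fragment
#' versus off-fragment coefficient blocks followed by S-normalization (at
#' most 100 iterations).
#'
#' @param S Overlap matrix.
#' @param basis_map Owning atom per basis function.
#' @param fmap An [fragment_map()].
#' @param homes Character vector: home fragment per MO (occupied MOs first).
#' @param rho Target home-fragment weight in (0.5, 1].
#' @param seed Integer seed.
#' @param n_occupied Number of occupied MOs (default `length(homes) / 2`).
#' @param emphasis Optional integer vector, one atom index per MO: within the
#'   home fragment that atom's basis functions are weighted up, giving
#'   occupied and virtual MOs of one chromophore distinct atomic
#'   distributions (as the nodal-structure change of a real excitation
#'   does), so a local excitation carries a definite intra-fragment
#'   redistribution.
#' @return An [moset()] whose columns are S-normalized.
#' @export
make_localized_moset <- function(S, basis_map, fmap, homes, rho, seed,
                                 n_occupied = length(homes) %/% 2,
                                 emphasis = NULL) {
  bad <- setdiff(homes, names(fmap$fragments))
  if (length(bad)) stop("unknown home fragment(s): ", paste(bad, collapse = ", "))
  n_bf <- nrow(S)
  frag_of_bf <- fragment_of_atom(fmap)[basis_map]
  with_seed(seed, {
    C <- matrix(0, n_bf, length(homes))
    for (j in seq_along(homes)) {
      on <- which(frag_of_bf == homes[j])
      off <- setdiff(seq_len(n_bf), on)
      c_vec <- numeric(n_bf)
      # mostly-positive on-fragment block keeps Mulliken cross terms benign
      c_vec[on] <- stats::runif(length(on), 0.5, 1.5) *
        sample(c(1, -1), length(on), replace = TRUE, prob = c(0.9, 0.1))
      if (!is.null(emphasis) && !is.na(emphasis[j])) {
        emph_bf <- which(basis_map == emphasis[j])
        c_vec[intersect(on, emph_bf)] <- 3 * c_vec[intersect(on, emph_bf)]
      }
      if (rho < 1) c_vec[off] <- stats::runif(length(off), -0.25, 0.25)
      c_vec <- c_vec / sqrt(sum(c_vec * (S %*% c_vec)))
      if (rho < 1 && length(off)) {
        ok <- FALSE
        w <- mulliken_weight_on(c_vec, S, on)
        for (it in 1:100) {
          if (abs(w - rho) <= 0.005) { ok <- TRUE; break }
          # Mulliken weights can exceed [0, 1]; fall back to damped steps there
          alpha <- if (w <= 0) 1.25
          else if (w >= 1) 0.8
          else sqrt((rho / (1 - rho)) / (w / (1 - w)))
          c_vec[on] <- c_vec[on] * alpha
          c_vec <- c_vec / sqrt(sum(c_vec * (S %*% c_vec)))
          w <- mulliken_weight_on(c_vec, S, on)
        }
        if (!ok)
          stop(sprintf("MO %d: could not reach home weight %.3f (achieved %.3f)",
                       j, rho, w))
      }
      C[, j] <- c_vec
    }
    moset(C, n_occupied = n_occupied, S = S)
  })
}

# donor -> acceptor pairs realizing each planted CT category
.CATEGORY_PAIRS <- list(
  "up-active" = list(c("PD1", "ChlD1"), c("PD2", "ChlD1"), c("PD1", "PheD1"),
                     c("PD2", "PheD1"), c("ChlD1", "PheD1")),
  "down-active" = list(c("ChlD1", "PD1"), c("ChlD1", "PD2"), c("PheD1", "PD1"),
                       c("PheD1", "PD2"), c("PheD1", "ChlD1")),
  "up-inactive" = list(c("PD1", "ChlD2"), c("PD2", "ChlD2"), c("PD1", "PheD2"),
                       c("PD2", "PheD2"), c("ChlD2", "PheD2")),
  "down-inactive" = list(c("ChlD2", "PD1"), c("ChlD2", "PD2"), c("PheD2", "PD1"),
                         c("PheD2", "PD2"), c("PheD2", "ChlD2")),
  "within-P" = list(c("PD1", "PD2"), c("PD2", "PD1")))

scenario_category <- function(name) {
  switch(name, "local-excitation" = "local",
         "ct-up-active" = "up-active", "ct-down-active" = "down-active",
         "ct-up-inactive" = "up-inactive", "ct-down-inactive" = "down-inactive",
         "within-P" = "within-P", name)
}

# evenly spaced energies with deterministic jitter; min gap stays > 0.025 eV
spaced_energies <- function(n, lo, hi) {
  base <- seq(lo, hi, length.out = n)
  base + stats::runif(n, -0.002, 0.002)
}

#' Generate a synthetic calculation record with ground truth
#'
#' Cofactors are placed as disjoint atom clusters 10 Angstrom apart (so the
#' nearest-atom CT-extent rule is unambiguous), MOs are localized per
#' fragment at the scenario's `localization`, and each state is given a
#' dominant transition whose printed contribution (200 c^2) falls in 50-80%
#' plus a weak local minor transition. Bright states draw oscillator
#' strengths uniform(0.3, 0.6), dark states uniform(0, 0.05). The sidecar
#' records every intention (per-MO home fragment, per-state label, CT
#' category and dominant transition).
#'
#' @param sc An [scenario()].
#' @return For most scenarios, a list with `record` ([calculation_record()]),
#'   `fmap` ([fragment_map()]) and `sidecar`. For `"mutant-shift-pair"`, the
#'   same plus `mutant`: a record differing only by `delta_e` added to the
#'   energy of every PD1-labeled state.
#' @export
make_record <- function(sc) {
  stopifnot(inherits(sc, "rc_scenario"))
  n_frag <- sc$n_fragments
  frag_names <- CANONICAL_COFACTORS[seq_len(n_frag)]
  n_atoms <- n_frag * sc$atoms_per_fragment
  n_bf <- n_atoms * sc$bf_per_atom

  # disjoint clusters >= 8 A apart, arranged like the compact two-branch
  # pigment cluster of the reaction center (PD1/PD2 special pair at the
  # origin end, accessory chlorophylls and pheophytins down each branch)
  # rather than a long chain, so the nearest-atom rule stays unambiguous
  centers <- rbind(PD1 = c(0, 0, 0), PD2 = c(0, 10, 0),
                   ChlD1 = c(10, 0, 0), ChlD2 = c(10, 10, 0),
                   PheD1 = c(20, 0, 0), PheD2 = c(20, 10, 0))
  coords <- matrix(0, n_atoms, 3)
  elements <- character(n_atoms)
  frs <- list()
  for (i in seq_len(n_frag)) {
    a0 <- (i - 1L) * sc$atoms_per_fragment
    idx <- a0 + seq_len(sc$atoms_per_fragment)
    frs[[frag_names[i]]] <- idx
    coords[idx, ] <- rep(centers[frag_names[i], ], each = length(idx))
    coords[idx, 2] <- coords[idx, 2] + 0.7 * (seq_along(idx) - 1)
    coords[idx, 3] <- coords[idx, 3] + 0.3 * ((seq_along(idx) - 1) %% 2)
    elements[idx] <- c("N", rep("C", sc$atoms_per_fragment - 1L))
  }
  geom <- geometry(elements, coords)
  fmap <- fragment_map(frs, n_atoms)
  basis_map <- rep(seq_len(n_atoms), each = sc$bf_per_atom)

  S <- make_overlap(n_bf, sc$coupling, seed = sc$seed)
  # one occupied and two virtual MOs per fragment, so a state's weak minor
  # transition can stay on its own chromophore (as in real multi-transition
  # excitations) without duplicating the dominant occ->virt pair
  homes <- c(frag_names, frag_names, frag_names)
  # occupied MOs lean on the first atom of their cluster, virtuals on the
  # last, so every excitation redistributes density within its chromophore
  first_atom <- vapply(frs, function(x) as.integer(min(x)), integer(1))
  last_atom <- vapply(frs, function(x) as.integer(max(x)), integer(1))
  emphasis <- c(first_atom[frag_names], last_atom[frag_names],
                last_atom[frag_names])
  mos <- make_localized_moset(S, basis_map, fmap, homes, sc$localization,
                              seed = sc$seed + 1L, n_occupied = n_frag,
                              emphasis = emphasis)
  occ_of <- stats::setNames(seq_len(n_frag), frag_names)
  virt_of <- stats::setNames(n_frag + seq_len(n_frag), frag_names)
  virt2_of <- stats::setNames(2L * n_frag + seq_len(n_frag), frag_names)

  built <- with_seed(sc$seed + 2L, {
    if (sc$name %in% c("soret-pd1", "mutant-shift-pair")) {
      qy_labels <- c("PheD1", "PheD2", "PD1", "PD2", "ChlD1", "ChlD2")
      soret_labels <- c("PD2", "PD1", "PD1", "PD2", "PD1", "PD1", "PD1",
                        "PheD1", "PheD2", "PD1")
      labels <- c(qy_labels, qy_labels, soret_labels)
      energies <- c(spaced_energies(6, 1.78, 2.02),   # Qy
                    spaced_energies(6, 2.22, 2.48),   # Qx
                    spaced_energies(10, 2.81, 3.10))  # Soret, inside 396-443 nm
                    # (with margin so a +-0.02 eV mutant shift stays in window)
      bright <- c(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                  rep(FALSE, 6), rep(TRUE, 10))
      cats <- rep("local", 22)
    } else {
      labels <- character(sc$n_states)
      cats <- character(sc$n_states)
      energies <- spaced_energies(sc$n_states, 1.80, 2.20)
      bright <- rep(TRUE, sc$n_states)
    }
    states <- vector("list", length(labels))
    donors <- character(length(labels)); acceptors <- character(length(labels))
    for (k in seq_along(labels)) {
      cat_k <- scenario_category(sc$name)
      if (sc$name == "mixed")
        cat_k <- sample(c(names(.CATEGORY_PAIRS), "local"), 1)
      if (sc$name %in% c("soret-pd1", "mutant-shift-pair")) cat_k <- "local"
      if (cat_k == "local") {
        lab <- if (nzchar(labels[k] %||% "")) labels[k]
               else sample(frag_names, 1)
        donor <- acceptor <- lab
      } else {
        pair <- .CATEGORY_PAIRS[[cat_k]][[sample(length(.CATEGORY_PAIRS[[cat_k]]), 1)]]
        donor <- pair[1]; acceptor <- pair[2]
        lab <- donor  # label follows the occupied side
      }
      labels[k] <- lab; cats[k] <- cat_k
      donors[k] <- donor; acceptors[k] <- acceptor
      c_dom <- sample(c(1, -1), 1) * sqrt(stats::runif(1, 50, 80) / 200)
      c_min <- sample(c(1, -1), 1) * stats::runif(1, 0.05, 0.12)
      minor_virt <- if (acceptor == donor) virt2_of[donor] else virt_of[donor]
      tr <- data.frame(
        occ = unname(c(occ_of[donor], occ_of[donor])),
        virt = unname(c(virt_of[acceptor], minor_virt)),
        amplitude = c(c_dom, c_min), deexcitation = 0)
      f_k <- if (bright[k]) stats::runif(1, 0.3, 0.6) else stats::runif(1, 0, 0.05)
      states[[k]] <- excited_state(k, energies[k], f_k, tr, n_occupied = n_frag)
    }
    list(states = states, labels = labels, cats = cats,
         donors = donors, acceptors = acceptors)
  })

  record <- calculation_record(
    geom, basis_map, S, mos, built$states,
    meta = list(label = sc$name, mutation = "W-T",
                scenario = sc$name, seed = sc$seed))
  sidecar <- list(
    scenario = sc$name, seed = sc$seed, localization = sc$localization,
    coupling = sc$coupling,
    mo_home = homes,
    states = data.frame(
      k = seq_along(built$labels), label = built$labels,
      category = built$cats, donor = built$donors,
      acceptor = built$acceptors,
      dominant_occ = vapply(built$states, function(s) s$transitions$occ[1], numeric(1)),
      dominant_virt = vapply(built$states, function(s) s$transitions$virt[1], numeric(1)),
      stringsAsFactors = FALSE))

  if (sc$name == "mutant-shift-pair") {
    shift_idx <- which(built$labels == "PD1")
    mut_states <- built$states
    for (k in shift_idx) {
      s <- mut_states[[k]]
      mut_states[[k]] <- excited_state(s$k, s$energy + sc$delta_e, s$f,
                                       s$transitions, n_occupied = n_frag)
    }
    mutant <- calculation_record(
      geom, basis_map, S, mos, mut_states,
      meta = list(label = sc$name, mutation = if (sc$delta_e >= 0) "H198A" else "H197A",
                  scenario = sc$name, seed = sc$seed))
    sidecar$delta_e <- sc$delta_e
    sidecar$shifted_states <- shift_idx
    return(list(record = record, mutant = mutant, fmap = fmap, sidecar = sidecar))
  }
  list(record = record, fmap = fmap, sidecar = sidecar)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Write / read a ground-truth sidecar (JSON)
#' @param sidecar Sidecar list from [make_record()].
#' @param path File path.
#' @export
write_sidecar <- function(sidecar, path) {
  writeLines(jsonlite::toJSON(sidecar, digits = I(17), auto_unbox = TRUE,
                              dataframe = "columns"), path)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  x$states <- as.data.frame(x$states, stringsAsFactors = FALSE)
  x
}
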