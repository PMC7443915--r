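# Atom-to-cofactor assignment and the D1/D2 branch topology that defines
# charge-transfer directions.

#' Canonical cofactor names of the reaction-center core
#'
#' The six chlorins: the special-pair chlorophylls PD1/PD2, the accessory
#' chlorophylls ChlD1/ChlD2 and the pheophytins PheD1/PheD2.
#' @export
CANONICAL_COFACTORS <- c("PD1", "PD2", "ChlD1", "ChlD2", "PheD1", "PheD2")

ENVIRONMENT_NAME <- "environment"

#' Build a fragment map
#'
#' @param fragments Named list of integer vectors: atom indices (1-based) per
#'   fragment. Fragments must be non-empty and pairwise disjoint. All
#'   unassigned atoms belong to the implicit `environment` fragment.
#' @param n_atoms Total number of atoms in the geometry.
#' @return Object of class `rc_fragment_map`.
#' @export
fragment_map <- function(fragments, n_atoms) {
  if (is.null(names(fragments)) || any(!nzchar(names(fragments))))
    stop("every fragment needs a name")
  if (ENVIRONMENT_NAME %in% names(fragments))
    stop("'environment' is reserved for unassigned atoms")
  all_idx <- integer(0)
  for (nm in names(fragments)) {
    idx <- as.integer(fragments[[nm]])
    if (!length(idx)) stop("fragment '", nm, "' is empty")
    if (any(idx < 1L | idx > n_atoms))
      stop("fragment '", nm, "' refers to atoms outside 1..", n_atoms)
    if (anyDuplicated(idx)) stop("fragment '", nm, "' lists an atom twice")
    fragments[[nm]] <- idx
    all_idx <- c(all_idx, idx)
  }
  dup <- all_idx[duplicated(all_idx)]
  if (length(dup))
    stop("atom(s) assigned to more than one fragment: ",
         paste(sort(unique(dup)), collapse = ", "))
  structure(list(fragments = fragments, n_atoms = as.integer(n_atoms)),
            class = "rc_fragment_map")
}

#' @export
print.rc_fragment_map <- function(x, ...) {
  cat(sprintf("<rc_fragment_map> %d fragment(s) over %d atoms (%d in environment)\n",
              length(x$fragments), x$n_atoms,
              x$n_atoms - length(unlist(x$fragments))))
  invisible(x)
}

#' Fragment name of each atom
#'
#' @param fmap An [fragment_map()].
#' @return Character vector of length `n_atoms`; unassigned atoms report
#'   `"environment"`.
#' @export
fragment_of_atom <- function(fmap) {
  out <- rep(ENVIRONMENT_NAME, fmap$n_atoms)
  for (nm in names(fmap$fragments)) out[fmap$fragments[[nm]]] <- nm
  out
}

#' Fragment names including the implicit environment bucket
#' @param fmap An [fragment_map()].
#' @export
fragment_names <- function(fmap) c(names(fmap$fragments), ENVIRONMENT_NAME)

#' Load a fragment map from a TSV file
#'
#' Expected format: header `atom_index<TAB>fragment`, then one row per
#' assigned atom, indices 1-based in parsed-geometry order. Duplicate
#' assignments and out-of-range indices are rejected.
#'
#' @param path Path to the TSV file.
#' @param geom The [geometry()] the indices refer to.
#' @return An [fragment_map()].
#' @export
load_fragment_map <- function(path, geom) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("atom_index", "fragment") %in% names(tab)))
    stop("fragment map TSV needs columns 'atom_index' and 'fragment'")
  if (anyDuplicated(tab$atom_index)) {
    dup <- tab$atom_index[duplicated(tab$atom_index)]
    stop("atom(s) assigned twice in ", path, ": ", paste(dup, collapse = ", "))
  }
  frs <- split(as.integer(tab$atom_index), tab$fragment)
  fragment_map(frs, n_atoms = nrow(geom))
}

#' Write a fragment map to TSV
#' @param fmap An [fragment_map()].
#' @param path Output path.
#' @export
write_fragment_map <- function(fmap, path) {
  rows <- do.call(rbind, lapply(names(fmap$fragments), function(nm)
    data.frame(atom_index = fmap$fragments[[nm]], fragment = nm)))
  rows <- rows[order(rows$atom_index), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default six-cofactor branch topology
#'
#' Encodes the two pigment branches of the reaction center: the special pair
#' (PD1, PD2) at rank 0 is a shared origin, the accessory chlorophylls rank 1
#' and the pheophytins rank 2 on their respective branches. "Up" a branch
#' means increasing rank (toward the pheophytin), the direction of productive
#' charge separation on the active (D1) branch.
#'
#' @return Object of class `rc_topology`: a data frame with columns
#'   `fragment`, `branch` (`D1`, `D2` or `P-pair`) and `rank`.
#' @export
default_topology <- function() {
  t <- data.frame(
    fragment = c("PD1", "PD2", "ChlD1", "PheD1", "ChlD2", "PheD2"),
    branch = c("P-pair", "P-pair", "D1", "D1", "D2", "D2"),
    rank = c(0L, 0L, 1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE)
  class(t) <- c("rc_topology", "data.frame")
  t
}

#' Branch of a fragment under a topology
#'
#' @param topology An `rc_topology`.
#' @param fragment Fragment name(s).
#' @return `"D1"`, `"D2"`, `"P-pair"`, or `"none"` for fragments outside the
#'   topology (residues, waters, environment).
#' @export
branch_of <- function(topology, fragment) {
  i <- match(fragment, topology$fragment)
  out <- topology$branch[i]
  out[is.na(i)] <- "none"
  out
}

#' Rank of a fragment under a topology (NA outside the topology)
#' @inheritParams branch_of
#' @export
rank_of <- function(topology, fragment) {
  topology$rank[match(fragment, topology$fragment)]
}
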