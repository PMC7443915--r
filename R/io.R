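# Readers and writers for the external formats the pipeline touches:
# a formatted-checkpoint (FCHK) subset, the textual excitation-log dialect,
# and the package's own lossless JSON record container.

BOHR_ANGSTROM <- 0.52917721067

# basis functions carried by each FCHK shell type code
.SHELL_NBF <- c("0" = 1L, "1" = 3L, "-1" = 4L, "2" = 6L, "-2" = 5L,
                "3" = 10L, "-3" = 7L)

fchk_find_key <- function(lines, key) {
  grep(paste0("^", key, "\\s"), lines)
}

fchk_read_array <- function(lines, idx, key) {
  header <- lines[idx]
  m <- regmatches(header, regexec(
    "^(.*?)\\s+([IR])\\s+N=\\s*(-?[0-9]+)\\s*$", header))[[1]]
  if (length(m) == 0)
    stop(sprintf("malformed FCHK key line %d for '%s': %s", idx, key, header))
  n <- as.integer(m[4])  # groups: [2]=key text, [3]=type, [4]=count
  vals <- numeric(0)
  j <- idx + 1L
  while (length(vals) < n) {
    if (j > length(lines))
      stop(sprintf("FCHK array '%s' truncated: expected %d values", key, n))
    row <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
    if (any(is.na(row)))
      stop(sprintf("unparsable numeric data at line %d under key '%s'", j, key))
    vals <- c(vals, row)
    j <- j + 1L
  }
  if (length(vals) != n)
    stop(sprintf("FCHK array '%s': read %d values, expected %d (line %d)",
                 key, length(vals), n, idx))
  vals
}

fchk_read_scalar_int <- function(lines, key) {
  idx <- fchk_find_key(lines, key)
  if (!length(idx)) return(NULL)
  m <- regmatches(lines[idx[1]], regexec(
    "^.*?\\s+I\\s+(-?[0-9]+)\\s*$", lines[idx[1]]))[[1]]
  if (length(m) == 0)
    stop(sprintf("malformed scalar key '%s' at line %d", key, idx[1]))
  as.integer(m[2])
}

fchk_array_or_null <- function(lines, key) {
  idx <- fchk_find_key(lines, key)
  if (!length(idx)) return(NULL)
  fchk_read_array(lines, idx[1], key)
}

#' Read the supported subset of a formatted checkpoint file
#'
#' Parses geometry, the shell-derived basis-function-to-atom map, MO
#' coefficients and (when present) the AO overlap matrix from a
#' formatted-checkpoint file. Coordinates are stored in the file in Bohr and
#' converted to Angstrom. Supported shell types: s, p, sp, d (Cartesian and
#' pure), f (Cartesian and pure). If no overlap array is present the record
#' is returned with `overlap = NULL` and downstream Mulliken operations
#' refuse to run until one is supplied.
#'
#' @param path Path to the FCHK file.
#' @return A partial [calculation_record()] (no excited states).
#' @export
read_fchk_subset <- function(path) {
  lines <- readLines(path)
  need <- function(key) {
    idx <- fchk_find_key(lines, key)
    if (!length(idx)) stop(sprintf("FCHK missing required key '%s'", key))
    fchk_read_array(lines, idx[1], key)
  }
  z <- as.integer(need("Atomic numbers"))
  xyz_bohr <- need("Current cartesian coordinates")
  if (length(xyz_bohr) != 3L * length(z))
    stop(sprintf("coordinate count %d != 3 x %d atoms", length(xyz_bohr), length(z)))
  coords <- matrix(xyz_bohr, ncol = 3, byrow = TRUE) * BOHR_ANGSTROM
  if (any(z < 1L) || any(z > length(.ELEMENTS)))
    stop("atomic number out of supported range under key 'Atomic numbers'")
  geom <- geometry(.ELEMENTS[z], coords)

  shell_types <- as.integer(need("Shell types"))
  shell_atom <- as.integer(need("Shell to atom map"))
  if (length(shell_types) != length(shell_atom))
    stop("'Shell types' and 'Shell to atom map' lengths differ")
  unknown <- setdiff(as.character(shell_types), names(.SHELL_NBF))
  if (length(unknown))
    stop("unsupported shell type(s) under key 'Shell types': ",
         paste(unknown, collapse = ", "))
  basis_map <- rep(shell_atom, times = .SHELL_NBF[as.character(shell_types)])
  n_bf <- length(basis_map)

  nbf_key <- fchk_read_scalar_int(lines, "Number of basis functions")
  if (!is.null(nbf_key) && nbf_key != n_bf)
    stop(sprintf("'Number of basis functions' %d != %d implied by shells",
                 nbf_key, n_bf))

  cmo <- need("Alpha MO coefficients")
  if (length(cmo) %% n_bf != 0)
    stop(sprintf("'Alpha MO coefficients' length %d not a multiple of %d basis functions",
                 length(cmo), n_bf))
  n_mo <- length(cmo) %/% n_bf
  C <- matrix(cmo, nrow = n_bf, ncol = n_mo)  # column-major: one MO per column

  n_alpha <- fchk_read_scalar_int(lines, "Number of alpha electrons")
  if (is.null(n_alpha))
    stop("FCHK missing required key 'Number of alpha electrons'")
  en <- fchk_array_or_null(lines, "Alpha Orbital Energies")
  mos <- moset(C, n_occupied = n_alpha, energies = en, energy_unit = "hartree")

  ov <- fchk_array_or_null(lines, "Overlap Matrix")
  S <- NULL
  if (!is.null(ov)) {
    if (length(ov) != n_bf * (n_bf + 1) / 2)
      stop(sprintf("'Overlap Matrix' length %d != lower triangle of %d basis functions",
                   length(ov), n_bf))
    S <- matrix(0, n_bf, n_bf)
    S[upper.tri(S, diag = TRUE)] <- ov   # column-wise upper == row-wise lower
    S <- S + t(S) - diag(diag(S))
  }
  calculation_record(geom, basis_map, S, mos,
                     meta = list(source = path, format = "fchk-subset"))
}

#' Write the FCHK subset dialect
#'
#' Inverse of [read_fchk_subset()] for records whose basis is expressible as
#' one s shell per basis function (the synthetic generator's layout).
#' Coordinates are written in Bohr.
#'
#' @param record A [calculation_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fchk_subset <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  warr <- function(key, type, vals) {
    wl("%-43s%s   N=%12d", key, type, length(vals))
    per <- if (type == "I") 6L else 5L
    fmt <- if (type == "I") "%12d" else "%16.8E"
    for (i in seq(1, length(vals), by = per)) {
      chunk <- vals[i:min(i + per - 1L, length(vals))]
      writeLines(paste0(sprintf(fmt, chunk), collapse = ""), con)
    }
  }
  wl("synthetic record%s", if (length(record$meta$label)) paste0(": ", record$meta$label) else "")
  wl("SP        synthetic                 synthetic")
  z <- match(record$geometry$element, .ELEMENTS)
  wl("%-43s%s%17d", "Number of atoms", "I", nrow(record$geometry))
  wl("%-43s%s%17d", "Number of basis functions", "I", length(record$basis_map))
  wl("%-43s%s%17d", "Number of alpha electrons", "I", record$mos$n_occupied)
  warr("Atomic numbers", "I", z)
  warr("Current cartesian coordinates", "R",
       as.vector(t(coords_matrix(record$geometry))) / BOHR_ANGSTROM)
  warr("Shell types", "I", rep(0L, length(record$basis_map)))
  warr("Shell to atom map", "I", record$basis_map)
  if (!all(is.na(record$mos$energies)))
    warr("Alpha Orbital Energies", "R", record$mos$energies)
  warr("Alpha MO coefficients", "R", as.vector(record$mos$C))
  if (!is.null(record$overlap))
    warr("Overlap Matrix", "R", record$overlap[upper.tri(record$overlap, diag = TRUE)])
  invisible(path)
}

#' Read excited states from a text excitation log
#'
#' Parses `Excited State k: ... x.xxxx eV yyy.yy nm f=z.zzzz` blocks followed
#' by `i -> a  c` amplitude lines (`i <- a  c` lines, when present, are
#' stored as de-excitation amplitudes of the matching pair). Whitespace
#' tolerant. The wavelength is recomputed from the printed energy.
#'
#' @param path Path to the log file.
#' @return List of [excited_state()] objects in file order.
#' @export
read_excitations_log <- function(path) {
  lines <- readLines(path)
  head_re <- "Excited State\\s+([0-9]+)\\s*:\\s*\\S*\\s+(-?[0-9.]+)\\s*eV\\s+(-?[0-9.]+)\\s*nm\\s+f\\s*=\\s*(-?[0-9.]+)"
  heads <- grep(head_re, lines)
  if (!length(heads))
    stop("no 'Excited State' block found in ", path)
  starts <- c(heads, length(lines) + 1L)
  states <- vector("list", length(heads))
  for (b in seq_along(heads)) {
    m <- regmatches(lines[heads[b]], regexec(head_re, lines[heads[b]]))[[1]]
    k <- as.integer(m[2]); en <- as.numeric(m[3]); f <- as.numeric(m[5])
    block <- lines[seq(heads[b] + 1L, starts[b + 1L] - 1L)]
    amp_re <- "^\\s*([0-9]+)\\s*(->|<-)\\s*([0-9]+)\\s+(-?[0-9.]+([eE][+-]?[0-9]+)?)\\s*$"
    tr <- data.frame(occ = integer(0), virt = integer(0),
                     amplitude = numeric(0), deexcitation = numeric(0))
    for (j in seq_along(block)) {
      ln <- block[j]
      if (!nzchar(trimws(ln))) next
      if (grepl("Excited State", ln)) break
      am <- regmatches(ln, regexec(amp_re, ln))[[1]]
      if (length(am) == 0) {
        # tolerate unrelated log chatter only if it clearly isn't an amplitude
        if (grepl("->|<-", ln))
          stop(sprintf("unparsable amplitude line %d: %s", heads[b] + j, ln))
        next
      }
      occ <- as.integer(am[2]); virt <- as.integer(am[4]); c_ia <- as.numeric(am[5])
      if (am[3] == "->") {
        tr <- rbind(tr, data.frame(occ = occ, virt = virt,
                                   amplitude = c_ia, deexcitation = 0))
      } else {
        hit <- which(tr$occ == occ & tr$virt == virt)
        if (length(hit)) tr$deexcitation[hit[1]] <- c_ia
        else tr <- rbind(tr, data.frame(occ = occ, virt = virt,
                                        amplitude = 0, deexcitation = c_ia))
      }
    }
    if (nrow(tr) == 0)
      stop(sprintf("state %d (line %d) has no transition lines", k, heads[b]))
    states[[b]] <- excited_state(k, en, f, tr)
  }
  states
}

#' Write the excitation-log dialect
#'
#' Inverse of [read_excitations_log()]. Amplitudes are printed to 6 decimal
#' places; energies to 4.
#'
#' @param states List of [excited_state()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_excitations_log <- function(states, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in states) {
    writeLines(sprintf(" Excited State %3d:      Singlet-A    %10.4f eV %9.2f nm  f=%.4f",
                       s$k, s$energy, s$wavelength, s$f), con)
    tr <- s$transitions
    for (i in seq_len(nrow(tr))) {
      writeLines(sprintf("    %4d -> %4d     %12.6f", tr$occ[i], tr$virt[i],
                         tr$amplitude[i]), con)
      if (tr$deexcitation[i] != 0)
        writeLines(sprintf("    %4d <- %4d     %12.6f", tr$occ[i], tr$virt[i],
                           tr$deexcitation[i]), con)
    }
  }
  invisible(path)
}

RECORD_FORMAT <- "rcexciton-record"
RECORD_VERSION <- 1L

#' Write a calculation record to the package's JSON container
#'
#' Single-file, versioned, self-describing, with numbers serialized at full
#' precision so that [read_record()] round-trips floating point bit-exactly.
#'
#' @param record A valid [calculation_record()] (invariants re-checked).
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  # re-validate: constructor invariants must hold at write time
  record <- calculation_record(record$geometry, record$basis_map, record$overlap,
                               record$mos, record$states, record$meta)
  payload <- list(
    format = RECORD_FORMAT, version = RECORD_VERSION,
    geometry = list(element = record$geometry$element,
                    coords = coords_matrix(record$geometry)),
    basis_map = record$basis_map,
    overlap = record$overlap,
    mos = list(C = record$mos$C, energies = record$mos$energies,
               energy_unit = record$mos$energy_unit,
               n_occupied = record$mos$n_occupied),
    states = lapply(record$states, function(s)
      list(k = s$k, energy = s$energy, f = s$f,
           transitions = as.list(s$transitions))),
    meta = record$meta)
  # digits = I(17): 17 significant digits round-trip IEEE doubles bit-exactly
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a calculation record from the JSON container
#'
#' @param path Path written by [write_record()].
#' @return A [calculation_record()].
#' @export
read_record <- function(path) {
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (is.null(x$format) || x$format != RECORD_FORMAT)
    stop("not an rcexciton record container: ", path)
  if (x$version != RECORD_VERSION)
    stop(sprintf("record container version %s unsupported (expected %d)",
                 x$version, RECORD_VERSION))
  geom <- geometry(x$geometry$element, x$geometry$coords)
  mos <- moset(x$mos$C, n_occupied = x$mos$n_occupied, energies = x$mos$energies,
               energy_unit = x$mos$energy_unit)
  states <- lapply(x$states, function(s)
    excited_state(s$k, s$energy, s$f, as.data.frame(s$transitions)))
  ov <- x$overlap
  if (!is.null(ov)) ov <- as.matrix(ov)
  calculation_record(geom, x$basis_map, ov, mos, states, as.list(x$meta))
}
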