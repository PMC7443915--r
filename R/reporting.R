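# End-to-end drivers tying the stages together: generate synthetic inputs,
# analyze a record into tables, and build spectra / band-shift reports.
# These functions back the thin command-line wrapper in inst/cli/.

msg <- function(..., verbose = TRUE) if (verbose) message(...)

#' Generate a synthetic record and write all its file forms
#'
#' Writes, under `out_dir`: the JSON record container (`record.json`, and
#' `mutant.json` for the mutant-shift pair), the FCHK-subset file
#' (`record.fchk`), the excitation log (`excitations.log`), the fragment map
#' TSV (`fragment_map.tsv`) and the ground-truth sidecar (`sidecar.json`).
#' Re-running with the same scenario and seed reproduces every file
#' byte-identically.
#'
#' @param sc An [scenario()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log to stderr (default `TRUE`).
#' @return Invisibly, the list from [make_record()] plus `files`.
#' @export
rc_synth <- function(sc, out_dir, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msg(sprintf("[synth] scenario '%s' seed %d", sc$name, sc$seed), verbose = verbose)
  made <- make_record(sc)
  p <- function(f) file.path(out_dir, f)
  write_record(made$record, p("record.json"))
  write_fchk_subset(made$record, p("record.fchk"))
  write_excitations_log(made$record$states, p("excitations.log"))
  write_fragment_map(made$fmap, p("fragment_map.tsv"))
  write_sidecar(made$sidecar, p("sidecar.json"))
  files <- c("record.json", "record.fchk", "excitations.log",
             "fragment_map.tsv", "sidecar.json")
  if (!is.null(made$mutant)) {
    write_record(made$mutant, p("mutant.json"))
    files <- c(files, "mutant.json")
  }
  made$files <- file.path(out_dir, files)
  invisible(made)
}

resolve_record <- function(x) {
  if (inherits(x, "rc_record")) x else read_record(x)
}

#' Analyze a record into the standard tables
#'
#' Runs the full characterization pipeline and writes, under `out_dir`:
#' `mo_profiles.tsv` (per-MO cofactor percentages), `states.tsv` (per-state
#' energy, oscillator strength, label and dominant transition),
#' `ct_profiles.tsv` (per-state CI-weight mass per CT-direction category)
#' and `ct_extent.tsv` (D_CT and nearest tail/head atoms per state).
#'
#' @param record A [calculation_record()] or a path to a record container.
#' @param fmap An [fragment_map()] or a path to a fragment-map TSV.
#' @param out_dir Output directory.
#' @param topology An `rc_topology`.
#' @param config An [analysis_config()].
#' @param verbose Log to stderr.
#' @return Invisibly: list with `chars`, `state_table`, `ct_table`,
#'   `extent_table`, `profiles`.
#' @export
rc_analyze <- function(record, fmap, out_dir, topology = default_topology(),
                       config = analysis_config(), verbose = TRUE) {
  record <- resolve_record(record)
  if (is.character(fmap)) fmap <- load_fragment_map(fmap, record$geometry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  require_overlap(record)  # fail early, naming the population stage
  msg(sprintf("[analyze] %d states, %d MOs, %d fragments",
              length(record$states), ncol(record$mos$C),
              length(fmap$fragments)), verbose = verbose)
  profiles <- all_profiles(record, fmap)
  chars <- characterize_states(record, fmap, topology, config)
  st <- state_table(chars)
  ct <- ct_profile_table(chars)
  ext <- ct_extent_table(record, fmap, config)
  write_profiles_tsv(profiles, file.path(out_dir, "mo_profiles.tsv"))
  utils::write.table(st, file.path(out_dir, "states.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ct, file.path(out_dir, "ct_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ext, file.path(out_dir, "ct_extent.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(chars = chars, state_table = st, ct_table = ct,
                 extent_table = ext, profiles = profiles))
}

#' Build spectra, band reports and (optionally) a mutant shift report
#'
#' Writes `spectrum.csv` for the record (and `spectrum_mutant.csv` when a
#' mutant is given), a `band_report.tsv` for the filtered cofactor band,
#' and - when a mutant record is supplied - `shift_report.tsv` comparing
#' the two bands, with the shift direction logged.
#'
#' @param record Wild-type [calculation_record()] or container path.
#' @param fmap Fragment map or TSV path.
#' @param out_dir Output directory.
#' @param mutant Optional mutant record (or path) sharing the geometry.
#' @param band_filter Cofactor whose band is isolated (default `"PD1"`).
#' @param window Wavelength window in nm (default: the config's Soret
#'   window).
#' @param spec_config A [spectrum_config()].
#' @param topology,config Passed to the labeling stage.
#' @param verbose Log to stderr.
#' @return Invisibly: list with `spectrum`, `band`, and when a mutant is
#'   given `mutant_band` and `shift`.
#' @export
rc_spectrum_report <- function(record, fmap, out_dir, mutant = NULL,
                               band_filter = "PD1", window = NULL,
                               spec_config = spectrum_config(),
                               topology = default_topology(),
                               config = analysis_config(), verbose = TRUE) {
  record <- resolve_record(record)
  if (is.character(fmap)) fmap <- load_fragment_map(fmap, record$geometry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(window)) window <- spec_config$soret_window_nm

  label_states <- function(rec) {
    profiles <- all_profiles(rec, fmap)
    vapply(rec$states, assign_state_label, character(1),
           mo_profiles = profiles, config = config)
  }
  labels <- label_states(record)
  spec <- broaden(record$states, spec_config)
  write_spectrum_csv(spec, file.path(out_dir, "spectrum.csv"))
  band <- cofactor_band(record$states, labels, band_filter, window, spec_config)
  band_tab <- if (band$empty) {
    data.frame(band = band_filter, states = "", peak_wavelength_nm = NA,
               empty = TRUE)
  } else {
    data.frame(band = band_filter,
               states = paste(band$states, collapse = ","),
               peak_wavelength_nm = round(band$peak_wavelength_nm, 2),
               empty = FALSE)
  }
  utils::write.table(band_tab, file.path(out_dir, "band_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (band$empty)
    msg(sprintf("[spectrum] warning: no %s state in the %g-%g nm window",
                band_filter, min(window), max(window)), verbose = verbose)
  out <- list(spectrum = spec, band = band)

  if (!is.null(mutant)) {
    mutant <- resolve_record(mutant)
    mlabels <- label_states(mutant)
    mspec <- broaden(mutant$states, spec_config)
    write_spectrum_csv(mspec, file.path(out_dir, "spectrum_mutant.csv"))
    mband <- cofactor_band(mutant$states, mlabels, band_filter, window,
                           spec_config)
    shift <- compare_bands(band, mband)
    shift_tab <- data.frame(
      model = record$meta$label %||% "record",
      mutant = mutant$meta$mutation %||% "mutant",
      lambda_wt_nm = round(shift$lambda_wt_nm, 2),
      lambda_mut_nm = round(shift$lambda_mutant_nm, 2),
      delta_lambda_nm = round(shift$delta_lambda_nm, 3),
      direction = shift$direction)
    utils::write.table(shift_tab, file.path(out_dir, "shift_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    msg(sprintf("[spectrum] %s band shift: %+.3f nm (%s)", band_filter,
                shift$delta_lambda_nm, shift$direction), verbose = verbose)
    out$mutant_band <- mband
    out$shift <- shift
  }
  invisible(out)
}
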