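# End-to-end orchestration: simulate/read -> deisotope -> calibrate ->
# full search -> greedy deconvolution -> XIC refinement -> per-feature
# deduplication -> multi-level target-decoy FDR -> report/export. All stages
# are pure functions of (inputs, config, seed); per-stage counts are logged.

#' Default pipeline configuration
#'
#' All tunable parameters of the engine with their defaults: restricted
#' trypsin with 1 missed cleavage, fixed carbamidomethyl C, variable Met
#' oxidation and protein N-terminal acetylation (at most 3 per peptide),
#' peptide length 7-50 and mass 500-5000 Da, fragment bin width 0.02 Th,
#' precursor charges 1-4 (2-3 for the calibration search), 20 ppm
#' pre-calibration / 10 ppm post-calibration fragment tolerance, candidate
#' list length chosen from the window scheme (128 wide / 32 narrow), 0.1 min
#' XIC retention-time tolerance, minimum 4 surviving fragments, isotope
#' cosine 0.80, greedy floor of 4 remaining peaks, and 1% FDR.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    precursor_charges = c(1L, 2L, 3L, 4L),
    top_n = NA_integer_,            # NA = choose by window scheme
    frag_tol_ppm = 10,
    precal_tol_ppm = 20,
    calibrate = TRUE,
    deisotope = TRUE,
    deisotope_max_charge = 3L,
    enzyme = "restricted_trypsin",  # or "trypsin" (P-suppressed)
    max_missed_cleavages = 1L,
    peptide_length_range = c(7L, 50L),
    peptide_mass_range = c(500, 5000),
    max_variable_mods = 3L,
    fragment_bin_width = 0.02,
    fragment_charges = 1L,
    rt_tol_min = 0.1,
    xic_halfwidth_min = 1,
    min_fragments = 4L,
    isotope_cosine_threshold = 0.80,
    min_peaks_remaining = 4L,
    hyperscore_floor = 0,
    fdr_threshold = 0.01
  )
}

#' Validate a pipeline configuration
#'
#' Unknown keys and out-of-range values are errors, raised before any stage
#' runs. Unspecified keys take their defaults.
#'
#' @param config Named list of overrides.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  stopifnot(
    all(cfg$precursor_charges >= 1L),
    is.na(cfg$top_n) || cfg$top_n >= 1L,
    cfg$frag_tol_ppm > 0, cfg$precal_tol_ppm > 0,
    cfg$enzyme %in% c("restricted_trypsin", "trypsin"),
    cfg$max_missed_cleavages >= 0L,
    cfg$peptide_length_range[1L] >= 1L,
    diff(cfg$peptide_length_range) >= 0,
    diff(cfg$peptide_mass_range) > 0,
    cfg$max_variable_mods >= 0L,
    cfg$fragment_bin_width > 0,
    cfg$rt_tol_min > 0, cfg$xic_halfwidth_min > 0,
    cfg$min_fragments >= 1L,
    cfg$isotope_cosine_threshold >= 0, cfg$isotope_cosine_threshold <= 1,
    cfg$min_peaks_remaining >= 1L,
    cfg$fdr_threshold > 0, cfg$fdr_threshold <= 1
  )
  cfg
}

#' Build the searchable peptide database and fragment index
#'
#' @param proteins data.table from [load_fasta_with_decoys()] (or a target
#'   table; decoys are appended if none are present).
#' @param config A [validate_config()]-completed configuration.
#' @param modifications Modification specs (default
#'   [default_modifications()]).
#' @return A `fragment_index` over all modified peptide forms.
#' @export
build_search_database <- function(proteins, config = validate_config(),
                                  modifications = default_modifications()) {
  prot <- data.table::as.data.table(proteins)
  if (!any(prot$is_decoy)) {
    decoys <- data.table::data.table(
      accession = paste0("rev_", prot$accession),
      sequence = reverse_sequence(prot$sequence), is_decoy = TRUE)
    prot <- rbind(prot[, .(accession, sequence, is_decoy)],
                  decoys)
  }
  peptides <- digest(prot, max_missed = config$max_missed_cleavages,
                     length_range = config$peptide_length_range,
                     mass_range = config$peptide_mass_range,
                     cleave_before_proline =
                       config$enzyme == "restricted_trypsin")
  forms <- enumerate_modified_forms(peptides, modifications,
                                    max_variable = config$max_variable_mods)
  build_fragment_index(forms, bin_width = config$fragment_bin_width,
                       fragment_charges = config$fragment_charges)
}

#' Search one DIA run end to end
#'
#' Deisotopes MS2 spectra, optionally calibrates fragment masses, runs the
#' full search per spectrum, greedily deconvolves each spectrum into PSMs,
#' refines every PSM by targeted XIC tracing and deduplicates PSMs per
#' chromatographic feature.
#'
#' @param run A [dia_run()].
#' @param index Fragment index from [build_search_database()].
#' @param config Completed configuration.
#' @param verbose Log per-stage counts (default TRUE).
#' @return List: psms (deduplicated retained PSM table), all_psms (before
#'   deduplication, with rejection reasons), calibration (mass-error model),
#'   counts (named list of stage counts).
#' @export
search_dia_run <- function(run, index, config = validate_config(),
                           verbose = TRUE) {
  log_ <- function(...) if (verbose) message(sprintf(...))
  ms2_idx <- which(vapply(run$spectra, `[[`, integer(1), "ms_level") == 2L)
  log_("[%s] %d spectra read (%d MS2)", run$run_id, length(run$spectra),
       length(ms2_idx))
  if (config$deisotope) {
    for (i in ms2_idx) {
      run$spectra[[i]] <- deisotope_spectrum(
        run$spectra[[i]], max_charge = config$deisotope_max_charge,
        tol_ppm = config$precal_tol_ppm)
    }
  }
  model <- structure(list(intercept = 0, slope = 0, residual_ppm = NA_real_,
                          n_psms = 0L), class = "mass_error_model")
  if (isTRUE(config$calibrate)) {
    model <- suppressWarnings(
      calibration_search(run, index, frag_tol_ppm = config$precal_tol_ppm))
    run <- apply_calibration(run, model)
    log_("[%s] calibration: %d PSMs, %+.2f ppm at 500 Th", run$run_id,
         model$n_psms, predict_ppm_error(model, 500))
  }
  top_n <- if (is.na(config$top_n)) default_top_n(run) else config$top_n
  sidx <- build_spectral_index(run)
  psm_rows <- list()
  n_candidates <- 0L
  for (i in ms2_idx) {
    s <- run$spectra[[i]]
    if (!length(s$mz)) next
    hyp <- precursor_mass_bounds(s$window, config$precursor_charges)
    cl <- score_spectrum(s, index, hyp, top_n = top_n,
                         frag_tol_ppm = config$frag_tol_ppm)
    n_candidates <- n_candidates + nrow(cl$candidates)
    emitted <- greedy_deconvolution(s, cl,
                                    min_peaks = config$min_peaks_remaining,
                                    score_floor = config$hyperscore_floor)
    if (!nrow(emitted)) next
    emitted[, rt := s$rt]
    emitted[, window_key := window_key(s$window)]
    emitted[, spectrum_idx := i]
    psm_rows[[length(psm_rows) + 1L]] <- emitted
  }
  psms <- data.table::rbindlist(psm_rows)
  log_("[%s] search: %d candidates, %d PSMs emitted over %d spectra",
       run$run_id, n_candidates, nrow(psms), length(ms2_idx))
  counts <- list(n_spectra = length(run$spectra), n_ms2 = length(ms2_idx),
                 n_candidates = n_candidates, n_psms_emitted = nrow(psms))
  if (!nrow(psms)) {
    return(list(psms = psms, all_psms = psms, calibration = model,
                counts = counts))
  }
  # annotate with peptide metadata
  pep <- index$peptides
  midx <- match(psms$peptide_id, pep$peptide_id)
  psms[, sequence := pep$sequence[midx]]
  psms[, modified_peptide := pep$modified_peptide[midx]]
  psms[, neutral_mass := pep$neutral_mass[midx]]
  psms[, proteins := pep$proteins[midx]]
  psms[, is_decoy := pep$is_decoy[midx]]
  psms[, missed_cleavages := pep$missed_cleavages[midx]]
  psms[, deltas := pep$deltas[midx]]
  psms[, precursor_mz := neutral_mass / assumed_charge + PROTON_MASS]
  # XIC refinement (column access only; row subsetting is too slow here)
  refined <- vector("list", nrow(psms))
  v_scan <- psms$scan_id; v_pid <- psms$peptide_id; v_rt <- psms$rt
  v_sidx <- psms$spectrum_idx; v_frag <- psms$fragments
  v_pmz <- psms$precursor_mz; v_z <- psms$assumed_charge
  for (j in seq_len(nrow(psms))) {
    refined[[j]] <- refine_psm(
      list(scan_id = v_scan[j], peptide_id = v_pid[j], rt = v_rt[j],
           window = run$spectra[[v_sidx[j]]]$window,
           fragments = v_frag[[j]], precursor_mz = v_pmz[j],
           assumed_charge = v_z[j]),
      sidx, rt_tol = config$rt_tol_min,
      xic_halfwidth = config$xic_halfwidth_min,
      min_fragments = config$min_fragments,
      frag_tol_ppm = config$frag_tol_ppm,
      isotope_cosine = config$isotope_cosine_threshold)
  }
  psms[, retained := vapply(refined, `[[`, logical(1), "retained")]
  psms[, rejection_reason := vapply(refined, `[[`, character(1),
                                    "rejection_reason")]
  psms[, median_apex_rt := vapply(refined, `[[`, numeric(1),
                                  "median_apex_rt")]
  psms[, precursor_detected := vapply(refined, `[[`, logical(1),
                                      "precursor_detected")]
  psms[, fragments := lapply(refined, `[[`, "fragments")]
  psms[, n_surviving := vapply(fragments, nrow, integer(1))]
  psms[, mass_error_ppm := vapply(seq_len(.N), function(j) {
    fr <- fragments[[j]]
    if (!nrow(fr)) return(NA_real_)
    mean(abs((fr$obs_mz - fr$theo_mz) / fr$theo_mz * 1e6))
  }, numeric(1))]
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  psms[, matched_intensity_fraction := vapply(seq_len(.N), function(j) {
    total <- tic[spectrum_idx[j]]
    if (total <= 0) return(0)
    min(1, sum(fragments[[j]]$intensity) / total)
  }, numeric(1))]
  reject_counts <- psms[retained == FALSE, .N, by = rejection_reason]
  log_("[%s] refinement: %d retained / %d (%s)", run$run_id,
       sum(psms$retained), nrow(psms),
       paste(sprintf("%s: %d", reject_counts$rejection_reason,
                     reject_counts$N), collapse = ", "))
  kept <- psms[retained == TRUE]
  dedup <- deduplicate_by_feature(kept, rt_tol = config$rt_tol_min)
  log_("[%s] deduplication: %d features from %d PSMs", run$run_id,
       nrow(dedup), nrow(kept))
  counts$n_retained <- nrow(kept)
  counts$n_rejected <- nrow(psms) - nrow(kept)
  counts$n_features <- nrow(dedup)
  dedup[, run_id := run$run_id]
  list(psms = dedup, all_psms = psms, calibration = model, counts = counts)
}

#' Run the full DIA identification pipeline over one or more runs
#'
#' Searches every run, pools PSMs (the "hybrid" route when runs of
#' different acquisition schemes are combined), applies the combined
#' run-specific and global precursor/protein 1% FDR filter, groups
#' proteins, and optionally writes pepXML/pin/spectral-library files.
#'
#' @param runs A [dia_run()] or list of them.
#' @param proteins Protein table (see [build_search_database()]) or a FASTA
#'   path.
#' @param config Configuration overrides (list).
#' @param output_dir If non-NULL, pepXML/pin/library files are written here.
#' @param verbose Log per-stage counts.
#' @return List: psms (all deduplicated retained PSMs across runs), passing
#'   (FDR-passing target PSMs), qvalues (precursor-level global q-value
#'   table), protein_groups, library (library table or NULL), counts,
#'   config.
#' @export
run_pipeline <- function(runs, proteins, config = list(), output_dir = NULL,
                         verbose = TRUE) {
  cfg <- validate_config(config)
  if (inherits(runs, "dia_run")) runs <- list(runs)
  if (is.character(proteins)) proteins <- load_fasta_with_decoys(proteins)
  index <- build_search_database(proteins, cfg)
  if (verbose)
    message(sprintf("database: %d peptide forms, %d fragments",
                    nrow(index$peptides), nrow(index$fragments)))
  results <- lapply(runs, search_dia_run, index = index, config = cfg,
                    verbose = verbose)
  psms <- data.table::rbindlist(lapply(results, `[[`, "psms"), fill = TRUE)
  out <- list(psms = psms, counts = lapply(results, `[[`, "counts"),
              config = cfg, index_size = nrow(index$peptides))
  if (!nrow(psms)) {
    out$passing <- psms
    out$qvalues <- NULL
    out$protein_groups <- data.table::data.table()
    return(out)
  }
  psms[, precursor_id := paste0(modified_peptide, "/", assumed_charge)]
  psms[, protein_id := proteins]
  psms[, score := hyperscore]
  passing <- filter_multilevel(psms, threshold = cfg$fdr_threshold)
  qtab <- target_decoy_qvalues(
    psms[, .(score = max(score), is_decoy = all(is_decoy)),
         by = .(id = precursor_id)])
  groups <- if (nrow(passing)) {
    group_proteins(passing[, .(peptide = sequence, proteins)])
  } else data.table::data.table()
  if (verbose)
    message(sprintf("FDR: %d of %d precursor features pass %.0f%% FDR; %d protein groups",
                    nrow(passing), nrow(psms), 100 * cfg$fdr_threshold,
                    nrow(groups)))
  out$passing <- passing
  out$qvalues <- qtab
  out$protein_groups <- groups
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_pepxml(psms, file.path(output_dir, "psms.pep.xml"))
    write_pin(psms, file.path(output_dir, "psms.pin"))
    out$library <- build_spectral_library(
      passing, file.path(output_dir, "library.tsv"))
    data.table::fwrite(
      passing[, .(run_id, precursor_id, sequence, modified_peptide,
                  assumed_charge, precursor_mz, hyperscore,
                  median_apex_rt, proteins)],
      file.path(output_dir, "precursors.tsv"), sep = "\t")
  }
  out
}
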