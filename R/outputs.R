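# Output writers: pepXML (PSM-level results for downstream validation
# tools), Percolator input (pin) feature tables, and a simplified
# tab-separated spectral library for targeted DIA quantification. Readers
# for pepXML and pin support lossless round-trip checks.

#' Write PSMs to pepXML
#'
#' One `spectrum_query` per PSM with assumed charge, precursor neutral mass,
#' hyperscore, matched-ion counts and 1-based modification positions.
#'
#' @param psms data.table with columns scan_id, rt, modified_peptide,
#'   sequence, assumed_charge, neutral_mass, hyperscore, n_matched,
#'   proteins, is_decoy, deltas (list column of per-residue mass deltas).
#' @param path Output path.
#' @param run_id Run identifier recorded in the file.
#' @return `path`, invisibly.
#' @export
write_pepxml <- function(psms, path, run_id = "run") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<msms_pipeline_analysis xmlns="http://regis-web.systemsbiology.net/pepXML">')
  w('<msms_run_summary base_name="%s" raw_data=".mzML">', xml_escape(run_id))
  w('<search_summary search_engine="diadirect" precursor_mass_type="monoisotopic" fragment_mass_type="monoisotopic"/>')
  n <- if (is.null(psms)) 0L else nrow(psms)
  for (i in seq_len(n)) {
    p <- psms[i]
    w(paste0('<spectrum_query spectrum="%s.%d.%d.%d" start_scan="%d" end_scan="%d" ',
             'precursor_neutral_mass="%.9f" assumed_charge="%d" retention_time_sec="%.6f" index="%d">'),
      xml_escape(run_id), p$scan_id, p$scan_id, p$assumed_charge,
      p$scan_id, p$scan_id, p$neutral_mass, p$assumed_charge, p$rt * 60, i)
    w('<search_result>')
    prots <- strsplit(p$proteins, ";", fixed = TRUE)[[1L]]
    w(paste0('<search_hit hit_rank="1" peptide="%s" protein="%s" num_tot_proteins="%d" ',
             'num_matched_ions="%d" calc_neutral_pep_mass="%.9f" is_decoy="%d">'),
      p$sequence, xml_escape(prots[1L]), length(prots), p$n_matched,
      p$neutral_mass, as.integer(p$is_decoy))
    for (alt in prots[-1L])
      w('<alternative_protein protein="%s"/>', xml_escape(alt))
    deltas <- p$deltas[[1L]]
    if (!is.null(deltas) && any(deltas != 0)) {
      w('<modification_info modified_peptide="%s">', p$modified_peptide)
      for (pos in which(deltas != 0)) {
        aa_mass <- RESIDUE_MASS[[substring(p$sequence, pos, pos)]]
        w('<mod_aminoacid_mass position="%d" mass="%.9f"/>',
          pos, aa_mass + deltas[pos])
      }
      w('</modification_info>')
    }
    w('<search_score name="hyperscore" value="%.9f"/>', p$hyperscore)
    w('</search_hit>')
    w('</search_result>')
    w('</spectrum_query>')
  }
  w('</msms_run_summary>')
  w('</msms_pipeline_analysis>')
  invisible(path)
}

#' Read a pepXML file written by [write_pepxml()]
#'
#' @param path Path to a pepXML file.
#' @return data.table with one row per spectrum query.
#' @export
read_pepxml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  queries <- xml2::xml_find_all(doc, ".//spectrum_query")
  rows <- lapply(queries, function(q) {
    hit <- xml2::xml_find_first(q, ".//search_hit")
    score <- xml2::xml_find_first(q, ".//search_score[@name='hyperscore']")
    mods <- xml2::xml_find_all(q, ".//mod_aminoacid_mass")
    data.table::data.table(
      scan_id = as.integer(xml2::xml_attr(q, "start_scan")),
      rt = as.numeric(xml2::xml_attr(q, "retention_time_sec")) / 60,
      assumed_charge = as.integer(xml2::xml_attr(q, "assumed_charge")),
      neutral_mass = as.numeric(xml2::xml_attr(q, "precursor_neutral_mass")),
      sequence = xml2::xml_attr(hit, "peptide"),
      n_matched = as.integer(xml2::xml_attr(hit, "num_matched_ions")),
      hyperscore = as.numeric(xml2::xml_attr(score, "value")),
      is_decoy = xml2::xml_attr(hit, "is_decoy") == "1",
      mod_positions = list(as.integer(xml2::xml_attr(mods, "position"))),
      mod_masses = list(as.numeric(xml2::xml_attr(mods, "mass")))
    )
  })
  data.table::rbindlist(rows)
}

#' Write a Percolator input (pin) file
#'
#' Tab-separated feature table: SpecId, Label (1 target / -1 decoy), ScanNr,
#' score features (hyperscore, matched-fragment count, matched-intensity
#' fraction, absolute precursor mass error in ppm, missed cleavages, peptide
#' length, charge one-hot), flanked Peptide and Proteins.
#'
#' @param psms data.table as for [write_pepxml()], plus columns
#'   matched_intensity_fraction, mass_error_ppm, missed_cleavages.
#' @param path Output path.
#' @param max_charge Highest charge one-hot column (default 4).
#' @return `path`, invisibly.
#' @export
write_pin <- function(psms, path, max_charge = 4L) {
  charge_cols <- paste0("Charge", seq_len(max_charge))
  header <- c("SpecId", "Label", "ScanNr", "hyperscore", "n_matched",
              "matched_intensity_fraction", "abs_mass_error_ppm",
              "missed_cleavages", "peptide_length", charge_cols,
              "Peptide", "Proteins")
  n <- if (is.null(psms)) 0L else nrow(psms)
  if (n == 0L) {
    writeLines(paste(header, collapse = "\t"), path)
    return(invisible(path))
  }
  onehot <- vapply(seq_len(max_charge), function(z) {
    as.integer(psms$assumed_charge == z)
  }, integer(n))
  if (n == 1L) onehot <- matrix(onehot, nrow = 1L)
  dt <- data.table::data.table(
    SpecId = sprintf("%s_%d_%d", ifelse(psms$is_decoy, "decoy", "target"),
                     psms$scan_id, psms$assumed_charge),
    Label = ifelse(psms$is_decoy, -1L, 1L),
    ScanNr = psms$scan_id,
    hyperscore = psms$hyperscore,
    n_matched = psms$n_matched,
    matched_intensity_fraction = psms$matched_intensity_fraction,
    abs_mass_error_ppm = psms$mass_error_ppm,
    missed_cleavages = psms$missed_cleavages,
    peptide_length = nchar(psms$sequence)
  )
  dt <- cbind(dt, data.table::as.data.table(onehot))
  data.table::setnames(dt, paste0("V", seq_len(max_charge)), charge_cols,
                       skip_absent = TRUE)
  dt[, Peptide := sprintf("-.%s.-", psms$modified_peptide)]
  dt[, Proteins := gsub(";", "\t", psms$proteins, fixed = TRUE)]
  lines <- c(paste(header, collapse = "\t"),
             dt[, do.call(paste, c(.SD, sep = "\t"))])
  writeLines(lines, path)
  invisible(path)
}

#' Read a pin file written by [write_pin()]
#' @param path Path to a pin file.
#' @return data.table (the Proteins column keeps only the first accession).
#' @export
read_pin <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(lines) == 1L) {
    dt <- data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(header)), header))
    return(dt)
  }
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  dt <- data.table::as.data.table(do.call(rbind, lapply(fields, function(f) {
    c(f[seq_len(length(header) - 1L)],
      paste(f[seq(length(header), length(f))], collapse = ";"))
  })))
  data.table::setnames(dt, header)
  num_cols <- setdiff(header, c("SpecId", "Peptide", "Proteins"))
  dt[, (num_cols) := lapply(.SD, as.numeric), .SDcols = num_cols]
  dt[]
}

#' Build a simplified spectral library
#'
#' One entry per (modified peptide, charge), taking the highest-hyperscore
#' passing PSM; fragment intensities are the XIC apex intensities of that
#' PSM's surviving fragments (per-scan intensities available via
#' `intensity_source = "scan"`). Fragments are written in descending
#' intensity order.
#'
#' @param psms data.table of FDR-passing PSMs with columns modified_peptide,
#'   sequence, assumed_charge, precursor_mz, hyperscore, rt
#'   (apex rt, minutes), proteins, fragments (list column with series,
#'   ordinal, frag_charge, theo_mz, apex_intensity, intensity).
#' @param path Output path (tab-separated).
#' @param intensity_source "apex" (default) or "scan".
#' @return The library data.table, invisibly; written with columns
#'   PrecursorMz, ProductMz, LibraryIntensity, NormalizedRetentionTime,
#'   PeptideSequence, ModifiedPeptideSequence, PrecursorCharge, FragmentType,
#'   FragmentSeriesNumber, FragmentCharge, ProteinId.
#' @export
build_spectral_library <- function(psms, path, intensity_source = c("apex", "scan")) {
  intensity_source <- match.arg(intensity_source)
  cols <- c("PrecursorMz", "ProductMz", "LibraryIntensity",
            "NormalizedRetentionTime", "PeptideSequence",
            "ModifiedPeptideSequence", "PrecursorCharge", "FragmentType",
            "FragmentSeriesNumber", "FragmentCharge", "ProteinId")
  dt <- data.table::as.data.table(psms)
  if (!nrow(dt)) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(data.table::as.data.table(
      stats::setNames(rep(list(character(0)), length(cols)), cols))))
  }
  data.table::setorder(dt, -hyperscore, scan_id)
  best <- dt[, .SD[1L], by = .(modified_peptide, assumed_charge)]
  entries <- lapply(seq_len(nrow(best)), function(i) {
    p <- best[i]
    fr <- data.table::as.data.table(p$fragments[[1L]])
    if (!nrow(fr)) return(NULL)
    inten <- if (intensity_source == "apex" && "apex_intensity" %in% names(fr))
      fr$apex_intensity else fr$intensity
    data.table::data.table(
      PrecursorMz = p$precursor_mz,
      ProductMz = fr$theo_mz,
      LibraryIntensity = inten,
      NormalizedRetentionTime = p$rt,
      PeptideSequence = p$sequence,
      ModifiedPeptideSequence = p$modified_peptide,
      PrecursorCharge = p$assumed_charge,
      FragmentType = fr$series,
      FragmentSeriesNumber = fr$ordinal,
      FragmentCharge = fr$frag_charge,
      ProteinId = p$proteins
    )[order(-LibraryIntensity, ProductMz)]
  })
  lib <- data.table::rbindlist(entries)
  data.table::fwrite(lib, path, sep = "\t")
  invisible(lib)
}
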