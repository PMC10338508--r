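# Minimal standards-conformant mzML I/O built on xml2. Binary data arrays are
# 64-bit little-endian floats, base64-encoded, uncompressed. Only the subset
# of PSI-MS terms this engine needs is emitted/consumed: MS level, scan start
# time, isolation window target/offsets, centroid flag, m/z and intensity
# arrays.

MS_CV <- c(
  ms_level = "MS:1000511",
  centroid = "MS:1000127",
  profile = "MS:1000128",
  scan_start_time = "MS:1000016",
  iso_target = "MS:1000827",
  iso_lower = "MS:1000828",
  iso_upper = "MS:1000829",
  mz_array = "MS:1000514",
  intensity_array = "MS:1000515",
  float64 = "MS:1000523",
  no_compression = "MS:1000576",
  ms1_spectrum = "MS:1000579",
  msn_spectrum = "MS:1000580"
)

encode_binary <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

decode_binary <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(numeric())
  readBin(jsonlite::base64_dec(txt), what = "numeric", size = 8L,
          n = 1e7, endian = "little")
}

#' Write a DIA run to an mzML file
#'
#' Emits centroided spectra with 64-bit uncompressed binary arrays; retention
#' times are written in minutes (unit annotated), isolation-window metadata is
#' preserved exactly.
#'
#' @param run A [dia_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_mzml()]
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "dia_run"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  cv <- function(acc, name, value = NULL, unit = NULL) {
    s <- sprintf('<cvParam cvRef="MS" accession="%s" name="%s"', acc, name)
    if (!is.null(value)) s <- sprintf('%s value="%s"', s, value)
    if (!is.null(unit)) {
      s <- sprintf('%s unitCvRef="UO" unitAccession="%s" unitName="%s"',
                   s, unit[1L], unit[2L])
    }
    paste0(s, "/>")
  }
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('<cvList count="2">')
  w('<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>')
  w('<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>')
  w('</cvList>')
  w('<run id="%s">', xml_escape(run$run_id))
  w('<spectrumList count="%d">', length(run$spectra))
  for (i in seq_along(run$spectra)) {
    s <- run$spectra[[i]]
    w('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      i - 1L, s$scan_id, length(s$mz))
    writeLines(cv(MS_CV[["ms_level"]], "ms level", s$ms_level), con)
    writeLines(cv(MS_CV[["centroid"]], "centroid spectrum"), con)
    writeLines(cv(if (s$ms_level == 1L) MS_CV[["ms1_spectrum"]] else MS_CV[["msn_spectrum"]],
                  if (s$ms_level == 1L) "MS1 spectrum" else "MSn spectrum"), con)
    w('<scanList count="1"><scan>')
    writeLines(cv(MS_CV[["scan_start_time"]], "scan start time",
                  format(s$rt, digits = 12),
                  c("UO:0000031", "minute")), con)
    w('</scan></scanList>')
    if (!is.null(s$window)) {
      w('<precursorList count="1"><precursor><isolationWindow>')
      writeLines(cv(MS_CV[["iso_target"]], "isolation window target m/z",
                    format(s$window$target_mz, digits = 12)), con)
      writeLines(cv(MS_CV[["iso_lower"]], "isolation window lower offset",
                    format(s$window$lower_offset, digits = 12)), con)
      writeLines(cv(MS_CV[["iso_upper"]], "isolation window upper offset",
                    format(s$window$upper_offset, digits = 12)), con)
      w('</isolationWindow></precursor></precursorList>')
    }
    w('<binaryDataArrayList count="2">')
    for (arr in c("mz", "intensity")) {
      acc <- if (arr == "mz") MS_CV[["mz_array"]] else MS_CV[["intensity_array"]]
      nm <- if (arr == "mz") "m/z array" else "intensity array"
      enc <- encode_binary(s[[arr]])
      w('<binaryDataArray encodedLength="%d">', nchar(enc))
      writeLines(cv(MS_CV[["float64"]], "64-bit float"), con)
      writeLines(cv(MS_CV[["no_compression"]], "no compression"), con)
      writeLines(cv(acc, nm), con)
      w('<binary>%s</binary>', enc)
      w('</binaryDataArray>')
    }
    w('</binaryDataArrayList>')
    w('</spectrum>')
  }
  w('</spectrumList>')
  w('</run>')
  w('</mzML>')
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Read a centroided DIA run from an mzML file
#'
#' Retention times are converted to minutes regardless of the unit recorded
#' in the file. Every MS2 spectrum must carry isolation-window metadata and
#' all spectra must be centroided; violations are hard errors naming the
#' offending scan.
#'
#' @param path Path to an mzML file.
#' @param run_id Run identifier; defaults to the file's run id attribute.
#' @return A [dia_run()].
#' @export
read_mzml <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  run_node <- xml2::xml_find_first(doc, ".//run")
  if (is.null(run_id)) {
    run_id <- if (inherits(run_node, "xml_missing")) basename(path)
              else xml2::xml_attr(run_node, "id")
  }
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  spectra <- lapply(nodes, parse_spectrum_node)
  ord <- order(vapply(spectra, `[[`, numeric(1), "rt"))
  dia_run(run_id, spectra[ord])
}

parse_spectrum_node <- function(node) {
  id <- xml2::xml_attr(node, "id")
  scan_id <- suppressWarnings(as.integer(sub(".*scan=([0-9]+).*", "\\1", id)))
  if (is.na(scan_id)) scan_id <- as.integer(xml2::xml_attr(node, "index")) + 1L
  param <- function(where, acc) {
    xml2::xml_attr(
      xml2::xml_find_first(where, sprintf(".//cvParam[@accession='%s']", acc)),
      "value")
  }
  has_param <- function(where, acc) {
    !inherits(xml2::xml_find_first(
      where, sprintf(".//cvParam[@accession='%s']", acc)), "xml_missing")
  }
  if (has_param(node, MS_CV[["profile"]]))
    stop("spectrum scan=", scan_id,
         " is profile mode; centroid upstream (e.g. during raw conversion)")
  ms_level <- as.integer(param(node, MS_CV[["ms_level"]]))
  rt_node <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", MS_CV[["scan_start_time"]]))
  rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
  unit <- xml2::xml_attr(rt_node, "unitName")
  if (!is.na(unit) && grepl("second", unit)) rt <- rt / 60
  win <- NULL
  iso <- xml2::xml_find_first(node, ".//isolationWindow")
  if (!inherits(iso, "xml_missing")) {
    win <- isolation_window(
      as.numeric(param(iso, MS_CV[["iso_target"]])),
      as.numeric(param(iso, MS_CV[["iso_lower"]])),
      as.numeric(param(iso, MS_CV[["iso_upper"]]))
    )
  }
  if (ms_level == 2L && is.null(win))
    stop("MS2 spectrum scan=", scan_id, " lacks isolation window metadata")
  arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
  mz <- numeric(); inten <- numeric()
  for (arr in arrays) {
    vals <- decode_binary(xml2::xml_text(xml2::xml_find_first(arr, ".//binary")))
    if (has_param(arr, MS_CV[["mz_array"]])) mz <- vals
    if (has_param(arr, MS_CV[["intensity_array"]])) inten <- vals
  }
  ord <- order(mz)
  spectrum(scan_id, ms_level, rt, mz[ord], inten[ord], win)
}
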