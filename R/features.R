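# Targeted feature extraction behind PSM refinement: per-window MS2 and MS1
# spectral indexes for constant-time XIC lookups, apex detection, the median
# apex retention-time fragment filter, the averagine isotope-envelope check,
# and per-feature PSM deduplication.

#' Build MS1/MS2 spectral indexes over a run
#'
#' One m/z-sorted peak table per chromatographic series (the MS1 series and
#' one series per distinct isolation window), each carrying cycle number and
#' retention time, so any (m/z, tolerance, rt range) lookup is a binary
#' search plus a contiguous slice — equivalent to a linear scan over the run.
#'
#' @param run A [dia_run()].
#' @return A `spectral_index`: list of per-series peak tables (`series`),
#'   per-series cycle/rt tables (`cycles`), and window definitions.
#' @export
build_spectral_index <- function(run) {
  stopifnot(inherits(run, "dia_run"), length(run$spectra) > 0L)
  cm <- run$cycle_map
  keys <- unique(cm$window_key)
  series <- list()
  cycles <- list()
  windows <- list()
  for (key in keys) {
    scans <- cm[window_key == key]
    sp <- run$spectra[match(scans$scan_id,
                            vapply(run$spectra, `[[`, integer(1), "scan_id"))]
    tabs <- lapply(seq_along(sp), function(i) {
      s <- sp[[i]]
      if (!length(s$mz)) return(NULL)
      data.table::data.table(mz = s$mz, intensity = s$intensity,
                             rt = s$rt, cycle = scans$cycle[i],
                             scan_id = s$scan_id)
    })
    tab <- data.table::rbindlist(tabs)
    if (nrow(tab)) data.table::setorder(tab, mz)
    series[[key]] <- tab
    cycles[[key]] <- data.table::data.table(cycle = scans$cycle, rt = scans$rt)
    if (key != "MS1") windows[[key]] <- sp[[1L]]$window
  }
  structure(list(series = series, cycles = cycles, windows = windows),
            class = "spectral_index")
}

series_key_for <- function(level, window) {
  if (level == 1L) "MS1" else window_key(window)
}

#' Trace an extracted ion chromatogram
#'
#' For every acquisition cycle of the addressed series whose retention time
#' falls within `rt_center +/- rt_halfwidth`, the most intense peak within
#' the ppm tolerance of `mz` (or 0) is appended. The apex is the maximum
#' after 3-point moving-average smoothing (ties broken toward earlier rt);
#' the trace is trimmed to the contiguous non-zero region around the apex.
#'
#' @param sidx A [build_spectral_index()] result.
#' @param mz Target m/z (Th).
#' @param tol_ppm Match tolerance in ppm.
#' @param rt_center,rt_halfwidth Retention-time window in minutes.
#' @param level 1 (MS1 series) or 2.
#' @param window The [isolation_window()] addressing the MS2 series
#'   (ignored for level 1).
#' @return An `xic`: list(rt, intensity, apex_rt, apex_intensity, n_nonzero);
#'   `apex_intensity = 0` and `apex_rt = NA` when no signal was found.
#' @export
trace_xic <- function(sidx, mz, tol_ppm, rt_center, rt_halfwidth = 1,
                      level = 2L, window = NULL) {
  stopifnot(rt_halfwidth > 0)
  key <- series_key_for(level, window)
  tab <- sidx$series[[key]]
  cyc <- sidx$cycles[[key]]
  no_signal <- structure(list(rt = numeric(), intensity = numeric(),
                              apex_rt = NA_real_, apex_intensity = 0,
                              n_nonzero = 0L), class = "xic")
  if (is.null(cyc)) return(no_signal)
  # hot path: plain vector ops only (called once per fragment per PSM)
  in_rt <- cyc$rt >= rt_center - rt_halfwidth & cyc$rt <= rt_center + rt_halfwidth
  if (!any(in_rt)) return(no_signal)
  g_cycle <- cyc$cycle[in_rt]
  g_rt <- cyc$rt[in_rt]
  ord_g <- order(g_rt)
  g_cycle <- g_cycle[ord_g]; g_rt <- g_rt[ord_g]
  inten <- numeric(length(g_rt))
  if (!is.null(tab) && length(tab$mz)) {
    tol <- mz * tol_ppm * 1e-6
    lo <- findInterval(mz - tol, tab$mz) + 1L
    hi <- findInterval(mz + tol, tab$mz)
    if (hi >= lo) {
      idx <- lo:hi
      h_rt <- tab$rt[idx]
      ok <- h_rt >= rt_center - rt_halfwidth & h_rt <= rt_center + rt_halfwidth
      if (any(ok)) {
        h_cycle <- tab$cycle[idx][ok]
        h_int <- tab$intensity[idx][ok]
        pos <- match(h_cycle, g_cycle)
        for (k in seq_along(pos)) {
          if (h_int[k] > inten[pos[k]]) inten[pos[k]] <- h_int[k]
        }
      }
    }
  }
  if (max(inten) == 0) return(no_signal)
  sm <- smooth3(inten)
  apex <- which.max(sm)  # which.max takes the first (earlier rt) on ties
  keep_lo <- apex
  while (keep_lo > 1L && inten[keep_lo - 1L] > 0) keep_lo <- keep_lo - 1L
  keep_hi <- apex
  while (keep_hi < length(inten) && inten[keep_hi + 1L] > 0)
    keep_hi <- keep_hi + 1L
  idx <- keep_lo:keep_hi
  structure(list(rt = g_rt[idx], intensity = inten[idx],
                 apex_rt = g_rt[apex], apex_intensity = inten[apex],
                 n_nonzero = sum(inten > 0)),
            class = "xic")
}

smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  out[1L] <- (x[1L] + x[2L]) / 2
  out[n] <- (x[n - 1L] + x[n]) / 2
  out
}

#' Check an observed precursor isotope envelope against the averagine model
#'
#' Cosine similarity between the observed first `length(envelope)` isotope
#' intensities and the averagine-predicted envelope at the given neutral
#' mass. Envelopes with fewer than 2 non-zero isotopes carry too little
#' evidence to reject and return `TRUE`.
#'
#' @param envelope Numeric vector of observed isotope intensities
#'   (M, M+1, M+2, ...).
#' @param neutral_mass Precursor neutral mass in Da.
#' @param threshold Minimum cosine similarity (default 0.80).
#' @return `TRUE` if the envelope is consistent with averagine.
#' @export
isotope_envelope_check <- function(envelope, neutral_mass, threshold = 0.80) {
  if (sum(envelope > 0) < 2L) return(TRUE)
  pred <- averagine_envelope(neutral_mass, length(envelope))
  cosine <- sum(envelope * pred) /
    sqrt(sum(envelope^2) * sum(pred^2))
  cosine >= threshold
}

#' Refine a PSM by targeted XIC tracing
#'
#' Traces an XIC for every matched fragment and for the precursor
#' monoisotopic m/z in MS1. The median apex retention time over fragment
#' apexes (plus the precursor apex when the precursor is detected; for an
#' even count, the lower middle value) anchors the elution group: fragments
#' whose apex deviates by more than `rt_tol` are removed. A detected
#' precursor whose own apex deviates by more than `rt_tol` rejects the PSM
#' (`precursor_rt`); an undetected precursor does not — fragment evidence can
#' exist without a visible precursor. A detected precursor must also pass
#' the averagine isotope-envelope check (`isotope`). Finally at least
#' `min_fragments` fragments must survive (`too_few_fragments`).
#'
#' @param psm List or one-row data.frame with fields `scan_id`, `rt`
#'   (triggering scan rt, minutes), `window` ([isolation_window()]),
#'   `fragments` (data.table with columns series, ordinal, frag_charge,
#'   theo_mz, intensity), `precursor_mz` (mono m/z), `assumed_charge`.
#' @param sidx A [build_spectral_index()] result.
#' @param rt_tol Maximum apex deviation from the median, minutes
#'   (default 0.1).
#' @param xic_halfwidth XIC trace half-width in minutes (default 1).
#' @param min_fragments Minimum surviving fragments (default 4).
#' @param frag_tol_ppm XIC m/z tolerance (default 10).
#' @param isotope_cosine Isotope-check cosine threshold (default 0.80).
#' @param min_precursor_cycles Non-zero MS1 cycles required to call the
#'   precursor detected (default 3).
#' @return List (`refined_psm`): fragments (surviving, with apex_rt and
#'   apex_intensity columns), removed_fragments, median_apex_rt, retained,
#'   rejection_reason ("none", "precursor_rt", "isotope",
#'   "too_few_fragments"), precursor_detected, precursor_apex_rt,
#'   isotope_envelope.
#' @export
refine_psm <- function(psm, sidx, rt_tol = 0.1, xic_halfwidth = 1,
                       min_fragments = 4L, frag_tol_ppm = 10,
                       isotope_cosine = 0.80, min_precursor_cycles = 3L) {
  frags <- data.table::as.data.table(psm$fragments)
  stopifnot(nrow(frags) >= 1L)
  xics <- lapply(seq_len(nrow(frags)), function(j) {
    trace_xic(sidx, frags$theo_mz[j], frag_tol_ppm, psm$rt, xic_halfwidth,
              level = 2L, window = psm$window)
  })
  frags[, apex_rt := vapply(xics, `[[`, numeric(1), "apex_rt")]
  frags[, apex_intensity := vapply(xics, `[[`, numeric(1), "apex_intensity")]
  # a matched fragment with no traceable signal cannot support co-elution
  traced <- !is.na(frags$apex_rt)

  neutral_mass <- (psm$precursor_mz - PROTON_MASS) * psm$assumed_charge
  iso_mz <- psm$precursor_mz +
    (0:2) * ISOTOPE_SPACING / psm$assumed_charge
  pre_xic <- trace_xic(sidx, psm$precursor_mz, frag_tol_ppm, psm$rt,
                       xic_halfwidth, level = 1L)
  detected <- pre_xic$n_nonzero >= min_precursor_cycles
  envelope <- rep(0, 3L)
  if (detected) {
    for (k in 1:3) {
      x <- trace_xic(sidx, iso_mz[k], frag_tol_ppm, pre_xic$apex_rt,
                     max(0.05, 1.5 * rt_tol), level = 1L)
      envelope[k] <- x$apex_intensity
    }
  }

  apexes <- frags$apex_rt[traced]
  if (detected) apexes <- c(apexes, pre_xic$apex_rt)
  if (!length(apexes)) {
    return(refined_result(psm, frags[0L], frags, NA_real_, FALSE,
                          "too_few_fragments", detected, pre_xic$apex_rt,
                          envelope))
  }
  median_rt <- lower_median(apexes)
  keep <- traced & abs(frags$apex_rt - median_rt) <= rt_tol
  surviving <- frags[keep]
  removed <- frags[!keep]

  reason <- "none"
  if (detected && abs(pre_xic$apex_rt - median_rt) > rt_tol) {
    reason <- "precursor_rt"
  } else if (detected &&
             !isotope_envelope_check(envelope, neutral_mass, isotope_cosine)) {
    reason <- "isotope"
  } else if (nrow(surviving) < min_fragments) {
    reason <- "too_few_fragments"
  }
  refined_result(psm, surviving, removed, median_rt, reason == "none",
                 reason, detected, pre_xic$apex_rt, envelope)
}

refined_result <- function(psm, surviving, removed, median_rt, retained,
                           reason, detected, pre_apex, envelope) {
  structure(list(
    scan_id = psm$scan_id, peptide_id = psm$peptide_id,
    assumed_charge = psm$assumed_charge,
    fragments = surviving, removed_fragments = removed,
    median_apex_rt = median_rt, retained = retained,
    rejection_reason = reason, precursor_detected = detected,
    precursor_apex_rt = pre_apex, isotope_envelope = envelope),
    class = "refined_psm")
}

# Lower middle value for even counts: deterministic, always an observed rt.
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Keep the best PSM per chromatographic feature
#'
#' PSMs of the same peptide form and charge, within the same isolation
#' window, whose apex retention times fall within `rt_tol` of each other
#' (single-linkage clustering along rt) are considered repeated samplings of
#' one elution feature across cycles; only the highest-hyperscore PSM is
#' kept (ties: earlier scan).
#'
#' @param psms data.table with columns peptide_id, assumed_charge,
#'   window_key, median_apex_rt, hyperscore, scan_id.
#' @param rt_tol Apex clustering tolerance in minutes (default 0.1).
#' @return The deduplicated subset, one row per feature.
#' @export
deduplicate_by_feature <- function(psms, rt_tol = 0.1) {
  if (!nrow(psms)) return(psms)
  dt <- data.table::copy(data.table::as.data.table(psms))
  data.table::setorder(dt, peptide_id, assumed_charge, window_key,
                       median_apex_rt, scan_id)
  dt[, feature_cluster := {
    gap <- c(0, diff(median_apex_rt))
    cumsum(gap > rt_tol)
  }, by = .(peptide_id, assumed_charge, window_key)]
  data.table::setorder(dt, peptide_id, assumed_charge, window_key,
                       feature_cluster, -hyperscore, scan_id)
  out <- dt[, .SD[1L],
            by = .(peptide_id, assumed_charge, window_key, feature_cluster)]
  out[, feature_cluster := NULL]
  out[]
}
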