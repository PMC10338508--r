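# Hyperscore rescoring and greedy spectrum deconvolution. In DIA, one MS/MS
# spectrum mixes fragments of several co-isolated precursors, so the same
# experimental peak can drive the score of multiple candidates; the greedy
# loop prevents this by emitting the best candidate, deleting its matched
# peaks, renormalizing and rescoring the remainder.

#' Normalize spectrum intensities to a maximum of 1
#'
#' @param s A [spectrum()].
#' @return The spectrum with intensities linearly scaled so max = 1; empty
#'   spectra are returned unchanged. Idempotent.
#' @export
normalize_peaks <- function(s) {
  if (!length(s$intensity) || max(s$intensity) == 0) return(s)
  spectrum(s$scan_id, s$ms_level, s$rt, s$mz,
           s$intensity / max(s$intensity), s$window)
}

#' X!Tandem-style hyperscore
#'
#' `ln(Nb! * Ny! * (1 + sum Ib) * (1 + sum Iy))` where Nb/Ny are the counts of
#' matched b/y ions and the sums are matched normalized intensities.
#' Factorials are capped at 20! to avoid overflow; the (1 + .) terms guard
#' zero-intensity sums. Zero matches give a score of 0.
#'
#' @param n_b,n_y Matched b/y ion counts.
#' @param sum_ib,sum_iy Summed matched normalized b/y intensities.
#' @return The hyperscore (>= 0).
#' @export
hyperscore <- function(n_b, n_y, sum_ib, sum_iy) {
  stopifnot(n_b >= 0, n_y >= 0, sum_ib >= 0, sum_iy >= 0)
  lfact <- function(n) lfactorial(min(n, 20L))
  lfact(n_b) + lfact(n_y) + log1p(sum_ib) + log1p(sum_iy)
}

#' Greedy iterative deconvolution of one MS/MS spectrum
#'
#' Repeatedly: rescore every remaining candidate by hyperscore over the
#' remaining normalized peaks, emit the best one (ties broken by lower
#' peptide id), remove its matched peaks and drop it from the candidate
#' list. Stops when fewer than `min_peaks` peaks remain, candidates are
#' exhausted, or the best hyperscore does not exceed `score_floor`.
#' Intensities are normalized to the spectrum's base peak, fixed over the
#' whole loop, which guarantees emitted hyperscores never increase from one
#' iteration to the next.
#'
#' @param s The deisotoped MS2 [spectrum()].
#' @param candidate_list A `candidate_list` from [score_spectrum()] (its
#'   `matches` table must be present).
#' @param min_peaks Stop when fewer than this many peaks remain (default 4).
#' @param score_floor Minimum hyperscore to emit (default 0; a PSM must
#'   score strictly above the floor).
#' @return data.table of emitted PSMs: scan_id, peptide_id, assumed_charge,
#'   hyperscore, n_b, n_y, sum_ib, sum_iy, n_matched, matched_peaks (list
#'   column of peak indices into the spectrum), iteration.
#' @export
greedy_deconvolution <- function(s, candidate_list, min_peaks = 4L,
                                 score_floor = 0) {
  empty <- data.table::data.table(
    scan_id = integer(), peptide_id = integer(), assumed_charge = integer(),
    hyperscore = numeric(), n_b = integer(), n_y = integer(),
    sum_ib = numeric(), sum_iy = numeric(), n_matched = integer(),
    matched_peaks = list(), fragments = list(), iteration = integer())
  cand <- candidate_list$candidates
  matches <- candidate_list$matches
  if (is.null(matches) || !nrow(cand)) return(empty)
  matches <- matches[peptide_id %in% cand$peptide_id]
  if (!nrow(matches)) return(empty)
  # hot loop: unpack the match table into plain vectors once
  m_peak <- matches$peak_idx
  m_pid <- matches$peptide_id
  m_is_b <- matches$series == "b"
  m_int <- matches$intensity
  # distinct theoretical fragment per (peptide, series, ordinal, charge)
  m_frag <- as.integer(factor(paste0(m_pid, "_", matches$series, "_",
                                     matches$ordinal, "_",
                                     matches$frag_charge)))
  alive <- rep(TRUE, length(s$mz))
  in_play <- rep(TRUE, nrow(matches))
  charge_of <- stats::setNames(cand$assumed_charge, cand$peptide_id)
  out <- list()
  iter <- 0L
  # one normalization factor for the whole loop: peak removal then never
  # inflates a remaining candidate's intensity sums, so emitted hyperscores
  # are non-increasing across iterations
  mx <- if (length(s$intensity)) max(s$intensity) else 0
  if (mx <= 0) return(empty)
  norm_all <- s$intensity / mx
  while (sum(alive) >= min_peaks) {
    sel <- which(in_play & alive[m_peak] & norm_all[m_peak] > 0)
    if (!length(sel)) break
    iter <- iter + 1L
    ni <- norm_all[m_peak[sel]]
    # best (most intense, then earliest peak) observation per fragment
    ord <- order(m_frag[sel], -ni, m_peak[sel])
    first <- ord[!duplicated(m_frag[sel][ord])]
    pid_f <- m_pid[sel][first]
    ni_f <- ni[first]
    is_b_f <- m_is_b[sel][first]
    agg <- rowsum(cbind(is_b_f, !is_b_f, ni_f * is_b_f, ni_f * !is_b_f),
                  group = pid_f)
    lf <- function(n) lfactorial(pmin(n, 20))
    hs <- lf(agg[, 1L]) + lf(agg[, 2L]) + log1p(agg[, 3L]) + log1p(agg[, 4L])
    pids <- as.integer(rownames(agg))
    best_i <- order(-hs, pids)[1L]
    if (hs[best_i] <= score_floor) break
    pid <- pids[best_i]
    rows <- sel[m_pid[sel] == pid]
    frows <- sel[first][pid_f == pid]
    frag <- data.table::data.table(
      series = matches$series[frows], ordinal = matches$ordinal[frows],
      frag_charge = matches$frag_charge[frows],
      theo_mz = matches$mz[frows], obs_mz = matches$obs_mz[frows],
      intensity = m_int[frows])
    peaks <- unique(m_peak[rows])
    out[[iter]] <- data.table::data.table(
      scan_id = s$scan_id, peptide_id = pid,
      assumed_charge = unname(charge_of[as.character(pid)]),
      hyperscore = hs[best_i], n_b = as.integer(agg[best_i, 1L]),
      n_y = as.integer(agg[best_i, 2L]),
      sum_ib = agg[best_i, 3L], sum_iy = agg[best_i, 4L],
      n_matched = as.integer(agg[best_i, 1L] + agg[best_i, 2L]),
      matched_peaks = list(sort(peaks)),
      fragments = list(frag), iteration = iter)
    alive[peaks] <- FALSE
    in_play[m_pid == pid] <- FALSE
  }
  if (!length(out)) return(empty)
  data.table::rbindlist(out)
}
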