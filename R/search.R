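# Direct search of DIA MS/MS spectra: precursor mass bounds enumerated from
# the isolation window (no precursor charge is recorded in DIA MS2 scans),
# candidate scoring against the fragment index, and two-pass mass
# calibration (restricted calibration search, then the full search on
# calibrated data).

#' Enumerate precursor mass bounds from an isolation window
#'
#' DIA MS2 scans carry no precursor charge, so every predefined charge state
#' is enumerated: for charge z the neutral-mass bounds are
#' `(window_bound - proton) * z`.
#'
#' @param window An [isolation_window()].
#' @param charges Integer vector of assumed precursor charges.
#' @return data.table with columns charge, mass_low, mass_high.
#' @export
precursor_mass_bounds <- function(window, charges) {
  stopifnot(length(charges) >= 1L)
  b <- window_bounds(window)
  if (b[1L] <= PROTON_MASS)
    stop("isolation window lower bound must exceed the proton mass")
  data.table::data.table(
    charge = as.integer(charges),
    mass_low = (b[1L] - PROTON_MASS) * charges,
    mass_high = (b[2L] - PROTON_MASS) * charges
  )
}

# All (peak, fragment) matches of a spectrum against the index within ppm
# tolerance, as a data.table: peak_idx, fragment columns, obs_mz, intensity,
# ppm_error. Vectorized binary search over the m/z-sorted fragment table.
match_peaks_to_index <- function(s, index, tol_ppm) {
  empty <- data.table::data.table(
    peak_idx = integer(), mz = numeric(), series = character(),
    ordinal = integer(), frag_charge = integer(), peptide_id = integer(),
    bin = integer(), obs_mz = numeric(), intensity = numeric(),
    ppm_error = numeric())
  if (!length(s$mz)) return(empty)
  fmz <- index$fragments$mz
  tol <- s$mz * tol_ppm * 1e-6
  lo <- findInterval(s$mz - tol, fmz) + 1L
  hi <- findInterval(s$mz + tol, fmz)
  n_hit <- pmax(0L, hi - lo + 1L)
  if (sum(n_hit) == 0L) return(empty)
  peak_idx <- rep.int(seq_along(s$mz), n_hit)
  frag_row <- unlist(lapply(which(n_hit > 0L), function(i) lo[i]:hi[i]),
                     use.names = FALSE)
  out <- index$fragments[frag_row]
  out[, peak_idx := peak_idx]
  out[, obs_mz := s$mz[peak_idx]]
  out[, intensity := s$intensity[peak_idx]]
  out[, ppm_error := (obs_mz - mz) / mz * 1e6]
  out
}

# Score a match table restricted to `alive` peaks: per peptide, the number of
# distinct matched theoretical fragments and the summed intensity (each
# fragment contributes its most intense matching peak).
aggregate_matches <- function(matches) {
  if (!nrow(matches)) {
    return(data.table::data.table(peptide_id = integer(), n_matched = integer(),
                                  matched_intensity = numeric()))
  }
  frag <- as.integer(factor(paste0(matches$peptide_id, "_", matches$series,
                                   "_", matches$ordinal, "_",
                                   matches$frag_charge)))
  ord <- order(frag, -matches$intensity, matches$peak_idx)
  first <- ord[!duplicated(frag[ord])]
  agg <- rowsum(cbind(1, matches$intensity[first]),
                group = matches$peptide_id[first])
  data.table::data.table(peptide_id = as.integer(rownames(agg)),
                         n_matched = as.integer(agg[, 1L]),
                         matched_intensity = agg[, 2L])
}

#' Score one MS/MS spectrum against the fragment index
#'
#' Every peptide form whose neutral mass falls inside any precursor
#' hypothesis range is scored by its number of matched theoretical fragments
#' within `frag_tol_ppm` (preliminary score), with ties broken by summed
#' matched intensity and then by peptide id. The `top_n` best candidates are
#' returned.
#'
#' @param s A deisotoped MS2 [spectrum()].
#' @param index A [build_fragment_index()] result.
#' @param hypotheses data.table from [precursor_mass_bounds()].
#' @param top_n Maximum candidates kept (128 wide-window default; 32 for
#'   narrow-window data).
#' @param frag_tol_ppm Fragment match tolerance in ppm.
#' @param matches Optional precomputed [match_peaks_to_index()] table.
#' @return A `candidate_list`: list(scan_id, candidates = data.table
#'   (peptide_id, assumed_charge, n_matched, matched_intensity), matches).
#' @export
score_spectrum <- function(s, index, hypotheses, top_n = 128L,
                           frag_tol_ppm = 10, matches = NULL) {
  stopifnot(s$ms_level == 2L)
  in_range <- peptides_in_mass_ranges(index, hypotheses$mass_low,
                                      hypotheses$mass_high)
  empty <- structure(list(
    scan_id = s$scan_id,
    candidates = data.table::data.table(peptide_id = integer(),
                                        assumed_charge = integer(),
                                        n_matched = integer(),
                                        matched_intensity = numeric()),
    matches = NULL), class = "candidate_list")
  if (!length(in_range) || !length(s$mz)) return(empty)
  if (is.null(matches)) matches <- match_peaks_to_index(s, index, frag_tol_ppm)
  matches <- matches[peptide_id %in% in_range]
  scores <- aggregate_matches(matches)
  if (!nrow(scores)) return(empty)
  data.table::setorder(scores, -n_matched, -matched_intensity, peptide_id)
  scores <- scores[seq_len(min(.N, top_n))]
  # assumed charge: the smallest hypothesis charge whose range contains the mass
  mass_of <- index$peptides$neutral_mass[match(scores$peptide_id,
                                               index$peptides$peptide_id)]
  hyp <- hypotheses[order(charge)]
  scores[, assumed_charge := vapply(mass_of, function(m) {
    as.integer(hyp$charge[which(m >= hyp$mass_low & m <= hyp$mass_high)[1L]])
  }, integer(1))]
  data.table::setcolorder(scores,
                          c("peptide_id", "assumed_charge", "n_matched",
                            "matched_intensity"))
  structure(list(scan_id = s$scan_id, candidates = scores,
                 matches = matches),
            class = "candidate_list")
}

#' Calibration search: fit a fragment mass-error model
#'
#' Runs a restricted search (precursor charges 2 and 3 only, small candidate
#' lists) over all MS2 spectra, keeps high-quality identifications (top
#' decile of preliminary scores with at least `min_matched` matched
#' fragments), and regresses the matched fragments' ppm errors on m/z by
#' least squares. With fewer than `min_psms` high-quality identifications an
#' identity model is returned with a warning.
#'
#' @param run A [dia_run()] with deisotoped MS2 spectra.
#' @param index Fragment index.
#' @param frag_tol_ppm Pre-calibration match tolerance (default 20 ppm).
#' @param min_matched Minimum matched fragments for a high-quality PSM.
#' @param min_psms Minimum high-quality PSMs to fit a model (default 50).
#' @return A `mass_error_model`: list(intercept, slope [ppm per Th],
#'   residual_ppm, n_psms).
#' @export
calibration_search <- function(run, index, frag_tol_ppm = 20,
                               min_matched = 6L, min_psms = 50L) {
  ms2 <- Filter(function(s) s$ms_level == 2L, run$spectra)
  stopifnot(length(ms2) >= 1L)
  identity_model <- structure(list(intercept = 0, slope = 0,
                                   residual_ppm = NA_real_, n_psms = 0L),
                              class = "mass_error_model")
  rows <- vector("list", length(ms2))
  scores <- numeric(length(ms2))
  for (i in seq_along(ms2)) {
    s <- ms2[[i]]
    hyp <- precursor_mass_bounds(s$window, c(2L, 3L))
    cl <- score_spectrum(s, index, hyp, top_n = 8L,
                         frag_tol_ppm = frag_tol_ppm)
    if (!nrow(cl$candidates)) next
    best <- cl$candidates[1L]
    if (best$n_matched < min_matched) next
    scores[i] <- best$n_matched
    rows[[i]] <- cl$matches[peptide_id == best$peptide_id,
                            .(mz = obs_mz, ppm_error)]
  }
  ok <- which(scores > 0)
  if (length(ok) >= min_psms) {
    cutoff <- stats::quantile(scores[ok], 0.9, names = FALSE)
    decile <- ok[scores[ok] >= cutoff]
    # the top decile, but never fewer than min_psms spectra when available
    ok <- if (length(decile) >= min_psms) decile
          else ok[order(scores[ok], decreasing = TRUE)][seq_len(min_psms)]
  }
  if (length(ok) < min_psms) {
    warning(sprintf(
      "calibration: only %d high-quality PSMs (need %d); returning identity model",
      length(ok), min_psms))
    return(identity_model)
  }
  err <- data.table::rbindlist(rows[ok])
  fit <- stats::lm.fit(cbind(1, err$mz), err$ppm_error)
  structure(list(intercept = fit$coefficients[[1L]],
                 slope = fit$coefficients[[2L]],
                 residual_ppm = stats::sd(fit$residuals),
                 n_psms = length(ok)),
            class = "mass_error_model")
}

#' Predict the ppm mass error at given m/z values
#' @param model A `mass_error_model`.
#' @param mz Numeric vector of m/z values.
#' @return Predicted ppm errors.
#' @export
predict_ppm_error <- function(model, mz) {
  model$intercept + model$slope * mz
}

#' Apply a mass-error model to every peak of a run
#'
#' Each peak m/z is corrected by subtracting the model-predicted relative
#' error: `mz * (1 - ppm(mz) * 1e-6)`. Peak order is preserved.
#'
#' @param run A [dia_run()].
#' @param model A `mass_error_model` from [calibration_search()].
#' @return The calibrated run.
#' @export
apply_calibration <- function(run, model) {
  if (model$intercept == 0 && model$slope == 0) return(run)
  spectra <- lapply(run$spectra, function(s) {
    if (!length(s$mz)) return(s)
    mz <- s$mz * (1 - predict_ppm_error(model, s$mz) * 1e-6)
    ord <- order(mz)
    spectrum(s$scan_id, s$ms_level, s$rt, mz[ord], s$intensity[ord], s$window)
  })
  dia_run(run$run_id, spectra)
}

#' Pick the default candidate-list length from the window scheme
#'
#' Wide isolation windows (median width > 5 Th) use 128 candidates per
#' spectrum; narrow-window (gas-phase fractionation style) runs use 32.
#'
#' @param run A [dia_run()].
#' @return 128L or 32L.
#' @export
default_top_n <- function(run) {
  widths <- vapply(Filter(function(s) s$ms_level == 2L, run$spectra),
                   function(s) diff(window_bounds(s$window)), numeric(1))
  if (!length(widths)) return(128L)
  if (stats::median(widths) > 5) 128L else 32L
}
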