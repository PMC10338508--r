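# Spectrum and run containers. A spectrum is a light list; a run bundles
# spectra with a cycle map grouping MS2 scans that share an isolation window.

#' Construct an isolation window
#'
#' @param target_mz Window centre m/z (Th).
#' @param lower_offset,upper_offset Non-negative half-widths (Th); the window
#'   covers `[target_mz - lower_offset, target_mz + upper_offset]`.
#' @return An `isolation_window` object.
#' @export
isolation_window <- function(target_mz, lower_offset, upper_offset) {
  stopifnot(lower_offset >= 0, upper_offset >= 0,
            target_mz - lower_offset < target_mz + upper_offset)
  structure(list(target_mz = target_mz, lower_offset = lower_offset,
                 upper_offset = upper_offset),
            class = "isolation_window")
}

window_bounds <- function(w) {
  c(w$target_mz - w$lower_offset, w$target_mz + w$upper_offset)
}

window_key <- function(w) {
  sprintf("%.4f:%.4f:%.4f", w$target_mz, w$lower_offset, w$upper_offset)
}

#' Construct a centroided mass spectrum
#'
#' @param scan_id Integer scan identifier, unique within a run.
#' @param ms_level 1 or 2.
#' @param rt Retention time in minutes.
#' @param mz,intensity Parallel numeric vectors; `mz` must be sorted
#'   ascending, intensities non-negative.
#' @param window An [isolation_window()]; required for MS2, absent for MS1.
#' @return A `dia_spectrum` object.
#' @export
spectrum <- function(scan_id, ms_level, rt, mz = numeric(), intensity = numeric(),
                     window = NULL) {
  stopifnot(ms_level %in% c(1L, 2L), rt >= 0,
            length(mz) == length(intensity))
  if (length(mz) && (any(mz <= 0) || any(intensity < 0)))
    stop("peaks must have mz > 0 and intensity >= 0")
  if (is.unsorted(mz)) stop("peaks must be sorted ascending in mz")
  if (ms_level == 2L && is.null(window))
    stop("MS2 spectrum requires an isolation window (scan ", scan_id, ")")
  if (ms_level == 1L && !is.null(window))
    stop("MS1 spectrum must not carry an isolation window")
  structure(list(scan_id = as.integer(scan_id), ms_level = as.integer(ms_level),
                 rt = rt, mz = as.numeric(mz), intensity = as.numeric(intensity),
                 window = window),
            class = "dia_spectrum")
}

#' Assemble spectra into a run with an acquisition cycle map
#'
#' MS2 scans sharing an identical isolation window are grouped into one
#' chromatographic series; the cycle number is the recurrence index of the
#' window. MS1 scans form their own series.
#'
#' @param run_id Character run identifier.
#' @param spectra List of [spectrum()] objects, ordered by retention time.
#' @return A `dia_run` object with elements `run_id`, `spectra`, `cycle_map`
#'   (data.table of scan_id, ms_level, rt, window_key, cycle).
#' @export
dia_run <- function(run_id, spectra) {
  if (length(spectra)) {
    rt <- vapply(spectra, `[[`, numeric(1), "rt")
    if (is.unsorted(rt)) stop("spectra must be ordered by retention time")
  }
  structure(list(run_id = run_id, spectra = spectra,
                 cycle_map = build_cycle_map(spectra)),
            class = "dia_run")
}

build_cycle_map <- function(spectra) {
  if (!length(spectra)) {
    return(data.table::data.table(scan_id = integer(), ms_level = integer(),
                                  rt = numeric(), window_key = character(),
                                  cycle = integer()))
  }
  keys <- vapply(spectra, function(s) {
    if (s$ms_level == 1L) "MS1" else window_key(s$window)
  }, character(1))
  dt <- data.table::data.table(
    scan_id = vapply(spectra, `[[`, integer(1), "scan_id"),
    ms_level = vapply(spectra, `[[`, integer(1), "ms_level"),
    rt = vapply(spectra, `[[`, numeric(1), "rt"),
    window_key = keys
  )
  dt[, cycle := seq_len(.N), by = window_key]
  dt[]
}

#' @export
print.dia_run <- function(x, ...) {
  n_ms1 <- sum(vapply(x$spectra, `[[`, integer(1), "ms_level") == 1L)
  n_windows <- length(setdiff(unique(x$cycle_map$window_key), "MS1"))
  cat(sprintf("<dia_run '%s'> %d spectra (%d MS1, %d MS2), %d isolation windows\n",
              x$run_id, length(x$spectra), n_ms1,
              length(x$spectra) - n_ms1, n_windows))
  invisible(x)
}

#' Collapse isotope clusters of a centroided MS/MS spectrum
#'
#' Scans peaks in ascending m/z for isotope partners spaced by
#' 1.00335483/z Th (z = 1..`max_charge`) within `tol_ppm`. A cluster is
#' collapsed to its monoisotopic peak, with intensities summed, only when
#' the first isotope ratio I(M+1)/I(M) lies within `envelope_band` times the
#' averagine-predicted ratio at the implied neutral mass; this bounds false
#' merges of unrelated peaks. Higher isotopes are absorbed while their
#' intensity does not grow by more than 3x step-to-step.
#'
#' @param s A [spectrum()].
#' @param max_charge Maximum isotope-spacing charge considered (>= 1).
#' @param tol_ppm Matching tolerance in ppm.
#' @param envelope_band Multiplicative acceptance band around the averagine
#'   M+1/M ratio (default `c(0.1, 3)`).
#' @return The deisotoped spectrum; peak count never increases and total ion
#'   current is conserved.
#' @export
deisotope_spectrum <- function(s, max_charge = 3L, tol_ppm = 20,
                               envelope_band = c(0.1, 3)) {
  stopifnot(inherits(s, "dia_spectrum"), max_charge >= 1L)
  n <- length(s$mz)
  if (n < 2L) return(s)
  mz <- s$mz
  inten <- s$intensity
  absorbed <- logical(n)
  out_int <- inten
  for (i in seq_len(n - 1L)) {
    if (absorbed[i]) next
    for (z in seq_len(max_charge)) {
      step <- ISOTOPE_SPACING / z
      tol <- mz[i] * tol_ppm * 1e-6
      # candidate M+1 partner
      j <- find_peak_near(mz, mz[i] + step, tol, exclude = absorbed)
      if (is.na(j)) next
      neutral <- (mz[i] - PROTON_MASS) * z
      if (neutral <= 0) next
      pred <- averagine_envelope(neutral, 2L)[2L]
      ratio <- inten[j] / inten[i]
      if (!is.finite(ratio) || pred <= 0) next
      if (ratio < envelope_band[1L] * pred || ratio > envelope_band[2L] * pred)
        next
      # absorb the chain while spacing matches and intensity does not blow up
      prev <- j
      chain <- j
      k <- 2L
      repeat {
        nxt <- find_peak_near(mz, mz[i] + k * step, tol, exclude = absorbed)
        if (is.na(nxt) || inten[nxt] > 3 * inten[prev]) break
        chain <- c(chain, nxt)
        prev <- nxt
        k <- k + 1L
      }
      absorbed[chain] <- TRUE
      out_int[i] <- out_int[i] + sum(inten[chain])
      break
    }
  }
  keep <- !absorbed
  spectrum(s$scan_id, s$ms_level, s$rt, mz[keep], out_int[keep], s$window)
}

# Index of the lowest-m/z unabsorbed peak within +/- tol of target, NA if none.
find_peak_near <- function(mz, target, tol, exclude) {
  lo <- findInterval(target - tol, mz) + 1L
  hi <- findInterval(target + tol, mz)
  if (hi < lo) return(NA_integer_)
  idx <- lo:hi
  idx <- idx[!exclude[idx]]
  if (!length(idx)) return(NA_integer_)
  idx[1L]
}
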