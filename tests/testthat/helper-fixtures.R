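# Shared fixtures: all generated in code at test time.

suppressMessages(library(data.table))

PROTON <- 1.00727646688

# A small deterministic proteome + unmodified peptide database and index.
tiny_database <- function(n_proteins = 12L, seed = 101L, bin_width = 0.02,
                          mods = list(), max_variable = 0L) {
  prot <- make_proteome(n_proteins, 240L, seed = seed)
  prot[, is_decoy := FALSE]
  peps <- digest(prot[, .(accession, sequence, is_decoy)])
  forms <- enumerate_modified_forms(peps, mods, max_variable = max_variable)
  build_fragment_index(forms, bin_width = bin_width)
}

# Exact b/y spectrum of one peptide form at the given charge.
exact_spectrum <- function(index, peptide_id, scan_id = 1L, rt = 1,
                           window = isolation_window(500, 6, 6),
                           intensity = 100) {
  pid_wanted <- peptide_id
  row <- index$peptides[peptide_id == pid_wanted]
  fr <- theoretical_fragments(row$sequence, row$deltas[[1L]])
  ord <- order(fr$mz)
  spectrum(scan_id, 2L, rt, fr$mz[ord],
           rep(intensity, nrow(fr)), window)
}

# Brute-force search oracle: enumerate every in-range peptide form by linear
# scan, match fragments peak by peak, score by (matched fragment count,
# summed best-peak intensity), order with the engine's tie-break.
brute_score_spectrum <- function(s, index, hypotheses, top_n = 128L,
                                 frag_tol_ppm = 10) {
  peps <- index$peptides
  in_range <- vapply(peps$neutral_mass, function(m) {
    any(m >= hypotheses$mass_low & m <= hypotheses$mass_high)
  }, logical(1))
  rows <- list()
  for (j in which(in_range)) {
    fr <- theoretical_fragments(peps$sequence[j], peps$deltas[[j]])
    n_matched <- 0L
    total <- 0
    for (k in seq_len(nrow(fr))) {
      tol <- s$mz * frag_tol_ppm * 1e-6
      hit <- which(abs(s$mz - fr$mz[k]) <= tol)
      if (length(hit)) {
        n_matched <- n_matched + 1L
        total <- total + max(s$intensity[hit])
      }
    }
    if (n_matched > 0L) {
      rows[[length(rows) + 1L]] <- data.table(
        peptide_id = peps$peptide_id[j], n_matched = n_matched,
        matched_intensity = total)
    }
  }
  out <- rbindlist(rows)
  if (!nrow(out)) return(out)
  setorder(out, -n_matched, -matched_intensity, peptide_id)
  out[seq_len(min(.N, top_n))]
}

# Hand-constructed run: one MS1 series and one MS2 window series on a fixed
# cycle grid; `traces` is a list of lists(mz, level, rts, intensities).
run_from_traces <- function(traces, window = isolation_window(500, 6, 6),
                            grid = seq(10, 11, by = 0.02)) {
  spectra <- list()
  scan <- 0L
  for (i in seq_along(grid)) {
    t_ms1 <- grid[i]
    for (level in c(1L, 2L)) {
      mz <- numeric(); inten <- numeric()
      for (tr in traces) {
        if (tr$level != level) next
        k <- match(TRUE, abs(tr$rts - t_ms1) < 1e-9)
        if (!is.na(k) && tr$intensities[k] > 0) {
          mz <- c(mz, tr$mz); inten <- c(inten, tr$intensities[k])
        }
      }
      scan <- scan + 1L
      ord <- order(mz)
      rt <- t_ms1 + if (level == 2L) 0.005 else 0
      spectra[[scan]] <- spectrum(scan, level, rt, mz[ord], inten[ord],
                                  if (level == 2L) window else NULL)
    }
  }
  dia_run("trace_fixture", spectra)
}

# Gaussian intensities over a grid, zeroed below the floor.
gaussian_trace <- function(grid, apex, sd_ = 0.05, height = 100, floor_ = 1) {
  y <- height * exp(-(grid - apex)^2 / (2 * sd_^2))
  y[y < floor_] <- 0
  y
}
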