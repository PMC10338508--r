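# Ground-truth DIA simulation: random proteomes, cyclic DIA acquisition
# (one MS1 scan then a sweep of isolation windows per cycle), Gaussian
# elution shared between a precursor and its b/y fragments, averagine MS1
# isotope envelopes, chemical noise, and two-species spike-in designs.

#' Generate a random toy proteome
#'
#' Sequences are drawn over the 20 canonical residues with the combined K/R
#' frequency set to 1/12, so the mean tryptic peptide length is about 12
#' residues. Deterministic under `seed`.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param mean_length Mean protein length (lengths are Poisson-spread around
#'   it, minimum 30).
#' @param seed Random seed.
#' @param species Species label recorded for every protein.
#' @param prefix Accession prefix.
#' @return data.table with columns accession, sequence, species.
#' @export
make_proteome <- function(n_proteins, mean_length = 360L, seed = 1L,
                          species = "synthetic", prefix = "sp") {
  stopifnot(n_proteins >= 1L)
  set.seed(seed)
  aa <- names(RESIDUE_MASS)
  kr <- c("K", "R")
  rest <- setdiff(aa, kr)
  prob <- stats::setNames(rep((1 - 1/12) / length(rest), length(aa)), aa)
  prob[kr] <- (1 / 12) / 2
  lens <- pmax(30L, stats::rpois(n_proteins, mean_length))
  seqs <- vapply(lens, function(n) {
    paste(sample(aa, n, replace = TRUE, prob = prob[aa]), collapse = "")
  }, character(1))
  data.table::data.table(
    accession = sprintf("%s|%s%04d", species, prefix, seq_len(n_proteins)),
    sequence = seqs, species = species)
}

#' Write a proteome table to FASTA
#' @param proteome data.table with accession, sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  set_ <- Biostrings::AAStringSet(proteome$sequence)
  names(set_) <- proteome$accession
  Biostrings::writeXStringSet(set_, path)
  invisible(path)
}

#' Tile a contiguous range of isolation windows
#'
#' @param n_windows Number of windows.
#' @param width Window width in Th.
#' @param start Lower bound of the first window (Th).
#' @return List of [isolation_window()] objects.
#' @export
dia_windows <- function(n_windows = 20L, width = 12, start = 400) {
  lapply(seq_len(n_windows), function(i) {
    isolation_window(start + (i - 0.5) * width, width / 2, width / 2)
  })
}

#' Select simulated precursors from a proteome
#'
#' Digests the proteome (restricted trypsin, no missed cleavages, unmodified
#' forms) and samples `n` distinct peptides whose precursor m/z at the given
#' charge falls within `mz_range`. Abundances are log-normal
#' (`meanlog = log(500)`, `sdlog = 0.7`, roughly two orders of magnitude of
#' dynamic range); elution apexes are uniform over the central gradient and
#' widths (Gaussian sd) uniform in 0.05-0.1 min.
#'
#' @param proteome data.table from [make_proteome()].
#' @param n Number of precursors.
#' @param mz_range Precursor m/z range to populate (match the window tiling).
#' @param charge Precursor charge (default 2).
#' @param gradient Gradient length in minutes.
#' @param seed Random seed.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance parameters.
#' @return data.table: sequence, proteins, species, charge, precursor_mz,
#'   neutral_mass, abundance, apex_rt, elution_sd.
#' @export
select_precursors <- function(proteome, n, mz_range = c(400, 640),
                              charge = 2L, gradient = 5, seed = 1L,
                              abundance_meanlog = log(500),
                              abundance_sdlog = 0.7) {
  prot <- data.table::as.data.table(proteome)[, .(accession, sequence)]
  prot[, is_decoy := FALSE]
  peps <- digest(prot)
  peps[, neutral_mass := vapply(sequence, peptide_neutral_mass, numeric(1),
                                USE.NAMES = FALSE)]
  peps[, precursor_mz := neutral_mass / charge + PROTON_MASS]
  # avoid Met/Cys so simulated signals are unmodified forms of the database
  ok <- peps[precursor_mz >= mz_range[1L] & precursor_mz <= mz_range[2L] &
               !grepl("[MC]", sequence)]
  if (nrow(ok) < n)
    stop(sprintf("proteome yields only %d candidate precursors (need %d)",
                 nrow(ok), n))
  set.seed(seed)
  sel <- ok[sample(.N, n)]
  species <- data.table::as.data.table(proteome)[, .(accession, species)]
  first_acc <- vapply(strsplit(sel$proteins, ";", fixed = TRUE), `[[`,
                      character(1), 1L)
  sel[, species := species$species[match(first_acc, species$accession)]]
  sel[, charge := as.integer(charge)]
  sel[, abundance := stats::rlnorm(.N, abundance_meanlog, abundance_sdlog)]
  sel[, apex_rt := stats::runif(.N, 0.1 * gradient, 0.9 * gradient)]
  sel[, elution_sd := stats::runif(.N, 0.05, 0.1)]
  sel[, .(sequence, proteins, species, charge, precursor_mz, neutral_mass,
          abundance, apex_rt, elution_sd)]
}

#' Simulate one cyclic DIA run with full ground truth
#'
#' Each acquisition cycle holds one MS1 scan followed by one MS2 scan per
#' isolation window. Precursors elute as Gaussians; MS1 carries their first
#' three averagine isotopes, MS2 scans carry singly charged b/y fragments of
#' the precursors isolated in the window, with per-fragment relative
#' intensities drawn once per precursor from a flat Dirichlet. Uniform
#' chemical noise peaks (log-uniform intensity in 0.1-10) are added to MS2
#' scans; peaks below the detection floor are dropped; all m/z values are
#' shifted by `ppm_shift`. Deterministic under `seed`.
#'
#' @param precursors data.table from [select_precursors()].
#' @param windows List of [isolation_window()] (must tile contiguously;
#'   overlaps beyond half a window are an error).
#' @param cycle_time Cycle duration in minutes (default 0.05).
#' @param gradient Run length in minutes (default 5).
#' @param noise_peaks_per_scan MS2 noise peaks per scan (default 0).
#' @param ppm_shift Systematic m/z shift in ppm (default 0).
#' @param seed Random seed.
#' @param detection_floor Minimum recorded intensity (default 1).
#' @param run_id Run identifier.
#' @return List with `run` (a [dia_run()]) and `truth` (list: precursors
#'   table with window_key and detectable flag, fragment table with
#'   per-fragment relative intensities, and the simulation parameters).
#' @export
simulate_dia_run <- function(precursors, windows = dia_windows(),
                             cycle_time = 0.05, gradient = 5,
                             noise_peaks_per_scan = 0L, ppm_shift = 0,
                             seed = 1L, detection_floor = 1,
                             run_id = "sim") {
  check_window_tiling(windows)
  set.seed(seed)
  pre <- data.table::copy(data.table::as.data.table(precursors))
  keys <- vapply(windows, window_key, character(1))
  bounds <- vapply(windows, window_bounds, numeric(2))
  widx <- vapply(pre$precursor_mz, function(m) {
    hit <- which(m >= bounds[1L, ] & m < bounds[2L, ])
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  pre[, window_key := ifelse(is.na(widx), NA_character_, keys[widx])]
  pre[, precursor_id := seq_len(.N)]

  # per-precursor fragment pattern: flat Dirichlet over singly charged b/y
  frag_list <- lapply(seq_len(nrow(pre)), function(i) {
    f <- theoretical_fragments(pre$sequence[i], fragment_charges = 1L)
    g <- stats::rgamma(nrow(f), shape = 1)
    f[, rel_intensity := g / sum(g)]
    f[, precursor_id := pre$precursor_id[i]]
    f
  })
  fragments <- data.table::rbindlist(frag_list)

  n_cycles <- max(1L, floor(gradient / cycle_time))
  n_win <- length(windows)
  shift <- function(mz) mz * (1 + ppm_shift * 1e-6)
  iso3 <- lapply(seq_len(nrow(pre)), function(i)
    averagine_envelope(pre$neutral_mass[i], 3L))
  spectra <- vector("list", n_cycles * (n_win + 1L))
  scan <- 0L
  for (cyc in seq_len(n_cycles)) {
    t0 <- (cyc - 1L) * cycle_time
    elut <- pre$abundance *
      exp(-(t0 - pre$apex_rt)^2 / (2 * pre$elution_sd^2))
    # MS1 scan at the top of the cycle
    mz1 <- numeric(); in1 <- numeric()
    for (i in which(elut >= detection_floor)) {
      imz <- pre$precursor_mz[i] +
        (0:2) * ISOTOPE_SPACING / pre$charge[i]
      iin <- elut[i] * iso3[[i]]
      keep <- iin >= detection_floor
      mz1 <- c(mz1, imz[keep]); in1 <- c(in1, iin[keep])
    }
    scan <- scan + 1L
    ord <- order(mz1)
    spectra[[scan]] <- spectrum(scan, 1L, t0, shift(mz1[ord]), in1[ord])
    for (j in seq_len(n_win)) {
      tj <- t0 + j * cycle_time / (n_win + 1L)
      elut_j <- pre$abundance *
        exp(-(tj - pre$apex_rt)^2 / (2 * pre$elution_sd^2))
      active <- which(!is.na(widx) & widx == j & elut_j >= detection_floor)
      mz2 <- numeric(); in2 <- numeric()
      if (length(active)) {
        fr <- fragments[precursor_id %in% pre$precursor_id[active]]
        fin <- fr$rel_intensity *
          elut_j[match(fr$precursor_id, pre$precursor_id)]
        keep <- fin >= detection_floor
        mz2 <- fr$mz[keep]; in2 <- fin[keep]
      }
      if (noise_peaks_per_scan > 0L) {
        nmz <- stats::runif(noise_peaks_per_scan, 150, 1700)
        nin <- exp(stats::runif(noise_peaks_per_scan, log(0.1), log(10)))
        keep <- nin >= detection_floor
        mz2 <- c(mz2, nmz[keep]); in2 <- c(in2, nin[keep])
      }
      scan <- scan + 1L
      ord <- order(mz2)
      # merge identical fragments from different precursors
      spectra[[scan]] <- spectrum(scan, 2L, tj, shift(mz2[ord]), in2[ord],
                                  windows[[j]])
    }
  }
  run <- dia_run(run_id, spectra)
  pre[, detectable := precursor_detectable(pre, fragments, detection_floor)]
  list(run = run,
       truth = list(precursors = pre, fragments = fragments,
                    cycle_time = cycle_time, gradient = gradient,
                    detection_floor = detection_floor, ppm_shift = ppm_shift,
                    seed = seed, windows = windows))
}

# a precursor is detectable when, at its apex, at least 4 fragments clear
# the detection floor and it is isolated by some window
precursor_detectable <- function(pre, fragments, floor_) {
  vapply(seq_len(nrow(pre)), function(i) {
    if (is.na(pre$window_key[i])) return(FALSE)
    fr <- fragments[precursor_id == pre$precursor_id[i]]
    sum(fr$rel_intensity * pre$abundance[i] >= floor_) >= 4L
  }, logical(1))
}

check_window_tiling <- function(windows) {
  stopifnot(length(windows) >= 1L)
  b <- vapply(windows, window_bounds, numeric(2))
  ord <- order(b[1L, ])
  b <- b[, ord, drop = FALSE]
  for (i in seq_len(ncol(b) - 1L)) {
    overlap <- b[2L, i] - b[1L, i + 1L]
    if (overlap > (b[2L, i] - b[1L, i]) / 2)
      stop("isolation windows overlap by more than half a window")
  }
  invisible(TRUE)
}

#' Simulate a two-species spike-in benchmark series
#'
#' One condition per entry of `ratios`: background-species abundances are
#' identical across conditions while spike-species abundances are scaled by
#' the ratio; ratio 0 denotes the background-only condition in which every
#' spike-species detection is false by construction. Every precursor is
#' labelled by species in the ground truth.
#'
#' @param background,spike Proteome tables from [make_proteome()] with
#'   distinct `species` labels.
#' @param ratios Spike:background abundance ratios (0 allowed).
#' @param n_runs_per_condition Replicate runs per condition.
#' @param n_background,n_spike Precursors sampled per species.
#' @param seed Random seed.
#' @param gradient Run length in minutes, shared by precursor selection and
#'   acquisition simulation.
#' @param ... Passed to [simulate_dia_run()] (windows, cycle_time,
#'   noise_peaks_per_scan, ...).
#' @return List of conditions; each has `ratio` and `runs`, a list of
#'   [simulate_dia_run()] results.
#' @export
simulate_spikein_benchmark <- function(background, spike, ratios = c(0, 1/6),
                                       n_runs_per_condition = 1L,
                                       n_background = 80L, n_spike = 30L,
                                       seed = 1L, gradient = 5, ...) {
  stopifnot(all(ratios >= 0))
  bg <- select_precursors(background, n_background, seed = seed,
                          gradient = gradient)
  sp <- select_precursors(spike, n_spike, seed = seed + 1L,
                          gradient = gradient)
  lapply(seq_along(ratios), function(ci) {
    ratio <- ratios[ci]
    runs <- lapply(seq_len(n_runs_per_condition), function(ri) {
      sp_scaled <- data.table::copy(sp)
      sp_scaled[, abundance := abundance * ratio]
      pre <- rbind(bg, sp_scaled[abundance > 0])
      simulate_dia_run(pre, gradient = gradient,
                       seed = seed + 1000L * ci + ri,
                       run_id = sprintf("cond%g_run%d", ratio, ri), ...)
    })
    list(ratio = ratio, runs = runs)
  })
}
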