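# Direct search: precursor bounds, candidate scoring vs the brute-force
# oracle, and mass calibration.

test_that("precursor mass bounds enumerate charges over the window", {
  w <- isolation_window(500, 6, 6)  # [494, 506] Th
  hyp <- precursor_mass_bounds(w, 2L)
  expect_equal(hyp$mass_low, 985.98545, tolerance = 1e-5)
  expect_equal(hyp$mass_high, 1009.98545, tolerance = 1e-5)
  hyp1 <- precursor_mass_bounds(w, 1L)
  expect_equal(hyp1$mass_low, 494 - 1.00727646688, tolerance = 1e-9)
  hyp3 <- precursor_mass_bounds(w, c(1L, 2L, 3L))
  expect_equal(nrow(hyp3), 3L)
  expect_equal(anyDuplicated(hyp3[, .(mass_low, mass_high)]), 0L)
  expect_error(precursor_mass_bounds(isolation_window(1, 0.5, 0.5), 1L),
               "proton")
})

test_that("a clean b/y spectrum ranks its own peptide first", {
  index <- tiny_database(n_proteins = 8L, seed = 55)
  # pick an in-window peptide (mass within z=2 bounds of [494,506] Th)
  w <- isolation_window(500, 6, 6)
  hyp <- precursor_mass_bounds(w, c(1L, 2L, 3L))
  ok <- index$peptides[neutral_mass >= hyp$mass_low[2] &
                         neutral_mass <= hyp$mass_high[2]]
  pid <- ok$peptide_id[1L]
  s <- exact_spectrum(index, pid, window = w)
  cl <- score_spectrum(s, index, hyp, top_n = 128L, frag_tol_ppm = 10)
  expect_equal(cl$candidates$peptide_id[1L], pid)
  expect_equal(cl$candidates$assumed_charge[1L], 2L)
  # empty spectrum
  s0 <- spectrum(9L, 2L, 1, numeric(), numeric(), w)
  expect_equal(nrow(score_spectrum(s0, index, hyp)$candidates), 0L)
})

test_that("ranked candidates equal the brute-force linear-scan oracle", {
  index <- tiny_database(n_proteins = 10L, seed = 91)
  w <- isolation_window(520, 10, 10)
  hyp <- precursor_mass_bounds(w, c(1L, 2L, 3L))
  set.seed(8)
  for (rep in 1:12) {
    # half-true spectra: fragments of a random in-range peptide + noise
    in_range <- index$peptides[neutral_mass >= min(hyp$mass_low) &
                                 neutral_mass <= max(hyp$mass_high)]
    pid <- sample(in_range$peptide_id, 1L)
    row <- index$peptides[peptide_id == pid]
    fr <- theoretical_fragments(row$sequence, row$deltas[[1L]])
    take <- sample(nrow(fr), sample(3:nrow(fr), 1L))
    mz <- c(fr$mz[take], runif(30, 150, 1500))
    inten <- c(rlnorm(length(take), 4, 1), rlnorm(30, 1, 1))
    ord <- order(mz)
    s <- spectrum(rep, 2L, 1, mz[ord], inten[ord], w)
    got <- score_spectrum(s, index, hyp, top_n = 50L, frag_tol_ppm = 15)
    want <- brute_score_spectrum(s, index, hyp, top_n = 50L,
                                 frag_tol_ppm = 15)
    expect_equal(nrow(got$candidates), nrow(want))
    if (nrow(want)) {
      expect_equal(got$candidates$peptide_id, want$peptide_id)
      expect_equal(got$candidates$n_matched, want$n_matched)
      expect_equal(got$candidates$matched_intensity, want$matched_intensity,
                   tolerance = 1e-9)
    }
  }
})

test_that("top_n = 32 candidates are a prefix of top_n = 128", {
  index <- tiny_database(n_proteins = 60L, seed = 14)
  w <- isolation_window(520, 15, 15)
  hyp <- precursor_mass_bounds(w, c(1L, 2L, 3L, 4L))
  set.seed(15)
  mz <- sort(runif(800, 150, 1500))
  s <- spectrum(1L, 2L, 1, mz, rlnorm(800, 3, 1), w)
  c32 <- score_spectrum(s, index, hyp, top_n = 32L, frag_tol_ppm = 20)
  c128 <- score_spectrum(s, index, hyp, top_n = 128L, frag_tol_ppm = 20)
  expect_gt(nrow(c128$candidates), 32L)
  expect_equal(c128$candidates$peptide_id[seq_len(nrow(c32$candidates))],
               c32$candidates$peptide_id)
})

test_that("calibration recovers an injected uniform +10 ppm shift", {
  prot <- make_proteome(25L, 300L, seed = 42)
  pre <- select_precursors(prot, 35L, gradient = 2.5, seed = 9)
  sim <- simulate_dia_run(pre, windows = dia_windows(8, 30, 400),
                          cycle_time = 0.05, gradient = 2.5,
                          ppm_shift = 10, seed = 9)
  cfg <- validate_config(list())
  prot[, is_decoy := FALSE]
  index <- build_search_database(prot[, .(accession, sequence, is_decoy)], cfg)
  m <- calibration_search(sim$run, index)
  grid <- seq(200, 1400, by = 100)
  expect_true(all(abs(predict_ppm_error(m, grid) - 10) < 1))
  # applying the model then re-fitting gives a residual model near zero
  run2 <- apply_calibration(sim$run, m)
  m2 <- calibration_search(run2, index)
  expect_true(all(abs(predict_ppm_error(m2, grid)) < 1))
})

test_that("an unshifted run calibrates to approximately zero everywhere", {
  prot <- make_proteome(25L, 300L, seed = 42)
  pre <- select_precursors(prot, 35L, gradient = 2.5, seed = 9)
  sim <- simulate_dia_run(pre, windows = dia_windows(8, 30, 400),
                          cycle_time = 0.05, gradient = 2.5,
                          ppm_shift = 0, seed = 9)
  cfg <- validate_config(list())
  prot[, is_decoy := FALSE]
  index <- build_search_database(prot[, .(accession, sequence, is_decoy)], cfg)
  m <- calibration_search(sim$run, index)
  expect_true(all(abs(predict_ppm_error(m, seq(200, 1400, by = 100))) < 1))
})

test_that("too few identifiable spectra fall back to the identity model", {
  index <- tiny_database(n_proteins = 3L, seed = 1)
  w <- isolation_window(500, 6, 6)
  noise <- lapply(1:5, function(i) {
    set.seed(i)
    mz <- sort(runif(10, 150, 1500))
    spectrum(i, 2L, i * 0.1, mz, rep(5, 10), w)
  })
  run <- dia_run("noise", noise)
  expect_warning(m <- calibration_search(run, index), "identity")
  expect_equal(predict_ppm_error(m, c(300, 900)), c(0, 0))
  # identity model leaves the run unchanged
  run2 <- apply_calibration(run, m)
  expect_equal(run2$spectra[[1L]]$mz, run$spectra[[1L]]$mz)
})

test_that("calibration correction follows mz * (1 - ppm * 1e-6)", {
  m <- structure(list(intercept = 10, slope = 0, residual_ppm = 0,
                      n_psms = 100L), class = "mass_error_model")
  run <- dia_run("r", list(spectrum(1L, 1L, 0, 1000, 5)))
  out <- apply_calibration(run, m)
  expect_equal(out$spectra[[1L]]$mz, 999.99)
})

test_that("linear ppm drifts up to 5 ppm per 1000 Th are recovered within 1 ppm", {
  prot <- make_proteome(25L, 300L, seed = 42)
  pre <- select_precursors(prot, 35L, gradient = 2.5, seed = 9)
  cfg <- validate_config(list())
  prot2 <- copy(prot)[, is_decoy := FALSE]
  index <- build_search_database(prot2[, .(accession, sequence, is_decoy)], cfg)
  sim <- simulate_dia_run(pre, windows = dia_windows(8, 30, 400),
                          cycle_time = 0.05, gradient = 2.5, seed = 9)
  # inject drift ppm(mz) = 2 + 5 * mz / 1000 after simulation
  drifted <- lapply(sim$run$spectra, function(s) {
    ppm <- 2 + 5 * s$mz / 1000
    spectrum(s$scan_id, s$ms_level, s$rt, s$mz * (1 + ppm * 1e-6),
             s$intensity, s$window)
  })
  run <- dia_run("drift", drifted)
  m <- calibration_search(run, index)
  grid <- seq(200, 1400, by = 100)
  expect_true(max(abs(predict_ppm_error(m, grid) - (2 + 5 * grid / 1000))) < 1)
})
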