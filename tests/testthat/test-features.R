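# Spectral indexing, XIC tracing, PSM refinement and feature deduplication.

window_key_test <- function(w) {
  sprintf("%.4f:%.4f:%.4f", w$target_mz, w$lower_offset, w$upper_offset)
}

test_that("spectral index lookups equal a linear scan over the run", {
  prot <- make_proteome(6L, 200L, seed = 21)
  pre <- select_precursors(prot, 5L, gradient = 1, seed = 21)
  sim <- simulate_dia_run(pre, windows = dia_windows(3, 80, 400),
                          cycle_time = 0.1, gradient = 1,
                          noise_peaks_per_scan = 5L, seed = 21)
  run <- sim$run
  sidx <- build_spectral_index(run)
  # every peak of the run is retrievable from its series
  total_indexed <- sum(vapply(sidx$series, nrow, integer(1)))
  total_run <- sum(vapply(run$spectra, function(s) length(s$mz), integer(1)))
  expect_equal(total_indexed, total_run)
  # lookups vs linear scan for a few random targets
  set.seed(2)
  keys <- setdiff(names(sidx$series), "MS1")
  for (key in keys) {
    tab <- sidx$series[[key]]
    if (!nrow(tab)) next
    for (q in sample(tab$mz, min(5L, nrow(tab)))) {
      win <- sidx$windows[[key]]
      x <- trace_xic(sidx, q, 10, rt_center = 0.5, rt_halfwidth = 2,
                     level = 2L, window = win)
      # linear scan oracle over all MS2 spectra of this window
      manual <- vapply(run$spectra, function(s) {
        if (s$ms_level != 2L || window_key_test(s$window) != key) return(0)
        hit <- abs(s$mz - q) <= q * 10e-6
        if (any(hit)) max(s$intensity[hit]) else 0
      }, numeric(1))
      expect_equal(sum(x$intensity > 0), sum(manual > 0))
      expect_equal(max(x$intensity), max(manual))
    }
  }
  # lookup far outside any recorded m/z is empty
  x <- trace_xic(sidx, 5000, 10, 0.5, 2, level = 2L,
                 window = sidx$windows[[keys[1L]]])
  expect_equal(x$apex_intensity, 0)
  expect_true(is.na(x$apex_rt))
})

test_that("XIC apex is the smoothed maximum with earlier-rt tie-break", {
  grid <- seq(10.0, 10.6, by = 0.1)
  tr <- list(list(mz = 500.25, level = 2L, rts = grid,
                  intensities = c(1, 5, 20, 50, 22, 6, 1)))
  run <- run_from_traces(tr, grid = grid)
  sidx <- build_spectral_index(run)
  x <- trace_xic(sidx, 500.25, 10, rt_center = 10.3, rt_halfwidth = 1,
                 level = 2L, window = run$spectra[[2L]]$window)
  expect_equal(x$apex_rt, 10.3 + 0.005)  # MS2 scans sit 0.005 min into the cycle
  expect_equal(x$apex_intensity, 50)
  # two equal maxima: the earlier rt wins
  tr2 <- list(list(mz = 600.5, level = 2L, rts = grid,
                   intensities = c(0, 10, 40, 40, 10, 0, 0)))
  run2 <- run_from_traces(tr2, grid = grid)
  sidx2 <- build_spectral_index(run2)
  x2 <- trace_xic(sidx2, 600.5, 10, 10.3, 1, level = 2L,
                  window = run2$spectra[[2L]]$window)
  expect_equal(x2$apex_rt, 10.2 + 0.005)
})

test_that("all-zero traces report no apex", {
  grid <- seq(10, 10.5, by = 0.1)
  run <- run_from_traces(list(list(mz = 500, level = 2L, rts = grid,
                                   intensities = rep(1, length(grid)))),
                         grid = grid)
  sidx <- build_spectral_index(run)
  x <- trace_xic(sidx, 900, 10, 10.2, 1, level = 2L,
                 window = run$spectra[[2L]]$window)
  expect_equal(x$apex_intensity, 0)
  expect_true(is.na(x$apex_rt))
  expect_equal(length(x$rt), 0L)
})

test_that("isotope envelope check follows the averagine model", {
  expect_true(isotope_envelope_check(averagine_envelope(1500, 3L), 1500))
  expect_false(isotope_envelope_check(c(1, 5, 9), 1000))
  expect_true(isotope_envelope_check(c(7, 0, 0), 1000))  # single isotope
})

# Build a fixture run where 4 fragments + optional precursor elute with
# chosen apexes, then refine a PSM matching them.
refine_fixture <- function(frag_apexes, precursor_apex = NA,
                           precursor_mz = 500.77, frag_mz = NULL,
                           aberrant_envelope = FALSE) {
  grid <- seq(9.5, 11.5, by = 0.02)
  if (is.null(frag_mz)) frag_mz <- seq(300.1, 300.1 + 100 * (length(frag_apexes) - 1),
                                       by = 100)
  traces <- lapply(seq_along(frag_apexes), function(i) {
    list(mz = frag_mz[i], level = 2L, rts = grid,
         intensities = gaussian_trace(grid, frag_apexes[i]))
  })
  if (!is.na(precursor_apex)) {
    iso <- if (aberrant_envelope) c(1, 5, 9) else averagine_envelope(
      (precursor_mz - 1.00727646688) * 2, 3L)
    for (k in 1:3) {
      traces[[length(traces) + 1L]] <- list(
        mz = precursor_mz + (k - 1) * 1.00335483 / 2, level = 1L, rts = grid,
        intensities = gaussian_trace(grid, precursor_apex, height = 200 * iso[k]))
    }
  }
  win <- isolation_window(500, 6, 6)
  run <- run_from_traces(traces, window = win, grid = grid)
  sidx <- build_spectral_index(run)
  frags <- data.table(series = rep("y", length(frag_apexes)),
                      ordinal = seq_along(frag_apexes), frag_charge = 1L,
                      theo_mz = frag_mz, obs_mz = frag_mz,
                      intensity = rep(50, length(frag_apexes)))
  psm <- list(scan_id = 1L, peptide_id = 1L, rt = mean(frag_apexes),
              window = win, fragments = frags, precursor_mz = precursor_mz,
              assumed_charge = 2L)
  list(psm = psm, sidx = sidx)
}

test_that("off-elution fragments are removed against the median apex rt", {
  fx <- refine_fixture(c(10.30, 10.31, 10.29, 10.95))
  r <- refine_psm(fx$psm, fx$sidx, rt_tol = 0.1, min_fragments = 4L)
  # the 10.95 fragment deviates by ~0.65 min and is removed; 3 remain < 4
  expect_equal(nrow(r$fragments), 3L)
  expect_equal(nrow(r$removed_fragments), 1L)
  expect_false(r$retained)
  expect_equal(r$rejection_reason, "too_few_fragments")
  expect_false(r$precursor_detected)
  # with min_fragments = 3 the same PSM is retained
  r2 <- refine_psm(fx$psm, fx$sidx, rt_tol = 0.1, min_fragments = 3L)
  expect_true(r2$retained)
  expect_equal(r2$rejection_reason, "none")
})

test_that("perfectly co-eluting fragments are all retained", {
  fx <- refine_fixture(rep(10.4, 5))
  r <- refine_psm(fx$psm, fx$sidx, rt_tol = 0.1, min_fragments = 4L)
  expect_equal(nrow(r$fragments), 5L)
  expect_true(r$retained)
  expect_true(all(abs(r$fragments$apex_rt - r$median_apex_rt) <= 0.1))
})

test_that("a detected precursor far from the fragment median rejects the PSM", {
  fx <- refine_fixture(rep(10.4, 5), precursor_apex = 11.4)
  r <- refine_psm(fx$psm, fx$sidx, rt_tol = 0.1, min_fragments = 4L)
  expect_true(r$precursor_detected)
  expect_false(r$retained)
  expect_equal(r$rejection_reason, "precursor_rt")
})

test_that("a co-eluting precursor with an aberrant isotope envelope rejects the PSM", {
  fx <- refine_fixture(rep(10.4, 5), precursor_apex = 10.4,
                       aberrant_envelope = TRUE)
  r <- refine_psm(fx$psm, fx$sidx, rt_tol = 0.1, min_fragments = 4L)
  expect_true(r$precursor_detected)
  expect_false(r$retained)
  expect_equal(r$rejection_reason, "isotope")
  # with a consistent envelope the same PSM passes
  fx2 <- refine_fixture(rep(10.4, 5), precursor_apex = 10.4)
  r2 <- refine_psm(fx2$psm, fx2$sidx, rt_tol = 0.1, min_fragments = 4L)
  expect_true(r2$retained)
})

test_that("a missing precursor never rejects a PSM by itself", {
  fx <- refine_fixture(rep(10.4, 6))
  r <- refine_psm(fx$psm, fx$sidx)
  expect_false(r$precursor_detected)
  expect_true(r$retained)
})

test_that("refinement is idempotent on the surviving fragment set", {
  fx <- refine_fixture(c(10.30, 10.32, 10.28, 10.34, 10.95))
  r <- refine_psm(fx$psm, fx$sidx, rt_tol = 0.1, min_fragments = 4L)
  psm2 <- fx$psm
  psm2$fragments <- r$fragments[, .(series, ordinal, frag_charge, theo_mz,
                                    obs_mz, intensity)]
  r2 <- refine_psm(psm2, fx$sidx, rt_tol = 0.1, min_fragments = 4L)
  expect_equal(nrow(r2$fragments), nrow(r$fragments))
  expect_equal(r2$fragments$theo_mz, r$fragments$theo_mz)
  expect_true(r2$retained)
})

test_that("deduplication keeps the top PSM per feature", {
  psms <- data.table(
    peptide_id = 1L, assumed_charge = 2L, window_key = "w1",
    median_apex_rt = c(10.40, 10.42, 10.44),
    hyperscore = c(12, 15, 13), scan_id = c(101L, 108L, 115L))
  out <- deduplicate_by_feature(psms, rt_tol = 0.1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$hyperscore, 15)
  expect_equal(out$scan_id, 108L)
  # different peptides in the same region are kept
  psms2 <- rbind(psms, data.table(peptide_id = 2L, assumed_charge = 2L,
                                  window_key = "w1", median_apex_rt = 10.41,
                                  hyperscore = 9, scan_id = 103L))
  out2 <- deduplicate_by_feature(psms2, rt_tol = 0.1)
  expect_equal(nrow(out2), 2L)
  expect_setequal(out2$peptide_id, c(1L, 2L))
  # distinct elution features of the same peptide are kept apart
  psms3 <- data.table(
    peptide_id = 1L, assumed_charge = 2L, window_key = "w1",
    median_apex_rt = c(10.40, 11.40), hyperscore = c(12, 13),
    scan_id = c(101L, 301L))
  expect_equal(nrow(deduplicate_by_feature(psms3, rt_tol = 0.1)), 2L)
  # empty input
  expect_equal(nrow(deduplicate_by_feature(psms[0L])), 0L)
})
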