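# FASTA + decoys, digestion, modifications, fragmentation, fragment index.

test_that("decoys are full-sequence reversals with rev_ prefix, doubling the database", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">prot1", "PEPTIDEK"), path)
  db <- load_fasta_with_decoys(path)
  expect_equal(nrow(db), 2L)
  expect_equal(db[is_decoy == TRUE, accession], "rev_prot1")
  expect_equal(db[is_decoy == TRUE, sequence], "KEDITPEP")
  unlink(path)

  prot <- make_proteome(25L, 150L, seed = 3)
  write_fasta(prot, path)
  db <- load_fasta_with_decoys(path)
  expect_equal(nrow(db), 50L)
  unlink(path)
})

test_that("duplicate accessions and empty FASTA files are errors", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "PEPTIDEK", ">p1", "AAAAKR"), path)
  expect_error(load_fasta_with_decoys(path), "duplicate")
  writeLines(character(), path)
  expect_error(load_fasta_with_decoys(path), "empty")
  unlink(path)
})

test_that("restricted trypsin cleaves after K/R including before proline", {
  prot <- data.table(accession = "p", sequence = "AKPGRCDE", is_decoy = FALSE)
  peps <- digest(prot, max_missed = 1L, length_range = c(1L, 50L),
                 mass_range = c(0, 1e5))
  expect_setequal(peps$sequence, c("AK", "PGR", "CDE", "AKPGR", "PGRCDE"))
  expect_equal(peps[sequence == "AKPGR", missed_cleavages], 1L)
  # classical trypsin suppresses cleavage before P
  peps2 <- digest(prot, max_missed = 0L, length_range = c(1L, 50L),
                  mass_range = c(0, 1e5), cleave_before_proline = FALSE)
  expect_setequal(peps2$sequence, c("AKPGR", "CDE"))
})

test_that("a sequence without K/R yields itself; shared peptides merge accessions", {
  prot <- data.table(accession = c("a", "b", "c"),
                     sequence = c("AGSTVNQ", "MLNPEWK", "MLNPEWK"),
                     is_decoy = FALSE)
  peps <- digest(prot, length_range = c(1L, 50L), mass_range = c(0, 1e5))
  expect_equal(peps[sequence == "AGSTVNQ", proteins], "a")
  expect_equal(peps[sequence == "MLNPEWK", proteins], "b;c")
})

test_that("fixed carbamidomethyl is applied unconditionally", {
  peps <- data.table(sequence = "PCK", proteins = "p", is_decoy = FALSE,
                     missed_cleavages = 0L, is_protein_nterm = FALSE)
  forms <- enumerate_modified_forms(peps)
  expect_equal(nrow(forms), 1L)
  expect_equal(forms$neutral_mass,
               peptide_neutral_mass("PCK") + 57.02146, tolerance = 1e-9)
})

test_that("variable oxidation enumerates all combinations up to the cap", {
  peps <- data.table(sequence = "MMK", proteins = "p", is_decoy = FALSE,
                     missed_cleavages = 0L, is_protein_nterm = FALSE)
  forms <- enumerate_modified_forms(peps, max_variable = 1L)
  expect_equal(nrow(forms), 3L)  # none, M1, M2
  expect_equal(sum(abs(forms$neutral_mass -
                         peptide_neutral_mass("MMK")) < 1e-9), 1L)
  expect_equal(sum(abs(forms$neutral_mass -
                         (peptide_neutral_mass("MMK") + 15.99491)) < 1e-9), 2L)
  # with both sites allowed: 1 + 2 + 1 forms
  forms2 <- enumerate_modified_forms(peps, max_variable = 2L)
  expect_equal(nrow(forms2), 4L)
})

test_that("protein N-terminal acetylation is restricted to N-terminal peptides", {
  peps <- data.table(sequence = c("AGSTVNK", "AGSTVNK"), proteins = "p",
                     is_decoy = FALSE, missed_cleavages = 0L,
                     is_protein_nterm = c(TRUE, FALSE))
  forms <- enumerate_modified_forms(peps, max_variable = 1L)
  expect_equal(nrow(forms), 3L)  # nterm peptide: 2 forms; internal: 1
})

test_that("no modifications yields the single unmodified form", {
  peps <- data.table(sequence = "AGSTVNQ", proteins = "p", is_decoy = FALSE,
                     missed_cleavages = 0L, is_protein_nterm = FALSE)
  forms <- enumerate_modified_forms(peps, max_variable = 0L)
  expect_equal(nrow(forms), 1L)
  expect_equal(forms$neutral_mass, peptide_neutral_mass("AGSTVNQ"))
})

test_that("modified-form counts equal the closed-form combinatorial count", {
  set.seed(77)
  prot <- make_proteome(6L, 200L, seed = 77)
  prot[, is_decoy := FALSE]
  peps <- digest(prot[, .(accession, sequence, is_decoy)])
  forms <- enumerate_modified_forms(peps, max_variable = 3L)
  counts <- forms[, .N, by = sequence]
  for (i in seq_len(nrow(peps))) {
    n_m <- lengths(regmatches(peps$sequence[i],
                              gregexpr("M", peps$sequence[i])))
    nterm <- peps$is_protein_nterm[i]
    n_sites <- n_m + as.integer(nterm)
    expected <- sum(choose(n_sites, 0:3))
    # acetylation and oxidation collide on residue 1 when the peptide
    # starts with M at the protein N-terminus: at most one mod per position
    if (nterm && startsWith(peps$sequence[i], "M")) {
      expected <- expected - sum(choose(n_sites - 2L, 0:1))
    }
    expect_equal(counts[sequence == peps$sequence[i], N], expected)
  }
})

test_that("b/y fragment masses follow residue-mass arithmetic", {
  fr <- theoretical_fragments("PEP")
  expect_equal(nrow(fr), 4L)  # b1 b2 y1 y2; no full-length ions
  y2 <- fr[series == "y" & ordinal == 2L, mz]
  expect_equal(y2, 129.04259 + 97.05276 + 18.0105646863 + 1.00727646688,
               tolerance = 1e-6)
  b1 <- fr[series == "b" & ordinal == 1L, mz]
  expect_equal(b1, 97.05276 + 1.00727646688, tolerance = 1e-6)
})

test_that("modification deltas land on the correct fragment side", {
  plain <- theoretical_fragments("MK")
  oxid <- theoretical_fragments("MK", deltas = c(15.99491, 0))
  expect_equal(oxid[series == "b" & ordinal == 1L, mz] -
                 plain[series == "b" & ordinal == 1L, mz], 15.99491,
               tolerance = 1e-9)
  expect_equal(oxid[series == "y" & ordinal == 1L, mz],
               plain[series == "y" & ordinal == 1L, mz])
})

test_that("fragment index retrieval equals a brute-force linear scan", {
  index <- tiny_database(n_proteins = 6L, seed = 19)
  frags <- index$fragments
  # every fragment of one peptide is retrievable by exact-mz query
  pid <- index$peptides$peptide_id[5L]
  own <- frags[peptide_id == pid]
  for (k in seq_len(min(6L, nrow(own)))) {
    hit <- query_fragment_index(index, own$mz[k], 5)
    expect_true(any(hit$peptide_id == pid & hit$ordinal == own$ordinal[k] &
                      hit$series == own$series[k]))
  }
  # random queries, including ones spanning bin boundaries
  set.seed(4)
  queries <- c(runif(40, 200, 1500),
               frags$bin[sample(nrow(frags), 10)] * index$bin_width)
  for (q in queries) {
    tol <- q * 20e-6
    expected <- frags[mz >= q - tol & mz <= q + tol]
    got <- query_fragment_index(index, q, 20)
    expect_equal(nrow(got), nrow(expected))
    expect_setequal(
      paste(got$peptide_id, got$series, got$ordinal),
      paste(expected$peptide_id, expected$series, expected$ordinal))
  }
  # empty query range
  expect_equal(nrow(query_fragment_index(index, 5000, 5)), 0L)
})

test_that("every fragment sits in exactly the floor(mz / bin_width) bin", {
  index <- tiny_database(n_proteins = 3L, seed = 23)
  expect_true(all(index$fragments$bin ==
                    floor(index$fragments$mz / index$bin_width)))
})

test_that("digestion output is independent of protein input order", {
  prot <- make_proteome(8L, 150L, seed = 12)
  prot[, is_decoy := FALSE]
  a <- digest(prot[, .(accession, sequence, is_decoy)])
  b <- digest(prot[sample(.N)][, .(accession, sequence, is_decoy)])
  expect_equal(a, b)
})
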