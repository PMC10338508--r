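# Target-decoy confidence estimation and the two empirical FDP estimators:
# the spike-in design (a second species spiked at known ratios; its
# detections in a background-only sample are false by construction) and the
# entrapment design (foreign-species proteins appended to the database).

#' Target-decoy q-values
#'
#' At each score threshold the FDR is estimated as
#' `#decoys >= s / max(1, #targets >= s)` (no +1 correction; set
#' `plus_one = TRUE` for the conservative variant); q-values are the running
#' minimum of the estimates from the lowest score upward.
#'
#' @param items data.frame/data.table with columns `id`, `score`,
#'   `is_decoy`.
#' @param plus_one Add 1 to the decoy count (default FALSE).
#' @return data.table sorted by descending score with an added `q_value`
#'   column (clamped to `[0, 1]`).
#' @export
target_decoy_qvalues <- function(items, plus_one = FALSE) {
  dt <- data.table::as.data.table(items)
  if (!any(!dt$is_decoy)) stop("no target entries")
  data.table::setorder(dt, -score, is_decoy, id)
  n_decoy <- cumsum(dt$is_decoy)
  n_target <- cumsum(!dt$is_decoy)
  fdr <- (n_decoy + as.integer(plus_one)) / pmax(1L, n_target)
  dt[, q_value := pmin(1, rev(cummin(rev(fdr))))]
  dt[]
}

#' Multi-level FDR filtering
#'
#' Mirrors the combination filter used for DIA identification lists: an item
#' passes only if it survives 1% FDR at the precursor level and at the
#' protein level, each computed both per run ("run-specific") and pooled
#' over all runs ("global"). Scores roll up by best score (precursor = best
#' PSM; protein = best precursor); protein decoy status is taken from the
#' precursor's decoy label.
#'
#' @param psms data.table with columns run_id, precursor_id, protein_id,
#'   score, is_decoy.
#' @param threshold q-value threshold (default 0.01).
#' @param levels Levels to apply (default precursor and protein).
#' @param scopes Scopes to apply (default run and global).
#' @return The subset of target `psms` passing every (level, scope)
#'   combination.
#' @export
filter_multilevel <- function(psms, threshold = 0.01,
                              levels = c("precursor", "protein"),
                              scopes = c("run", "global")) {
  dt <- data.table::as.data.table(psms)
  if (!nrow(dt)) return(dt[0L])
  pass <- rep(TRUE, nrow(dt))
  for (level in levels) {
    id_col <- if (level == "precursor") "precursor_id" else "protein_id"
    for (scope in scopes) {
      group_cols <- if (scope == "run") c("run_id", id_col) else id_col
      rolled <- dt[, .(score = max(score), is_decoy = all(is_decoy)),
                   by = group_cols]
      passing <- data.table::rbindlist(lapply(
        split(rolled, if (scope == "run") rolled$run_id else rep(1L, nrow(rolled))),
        function(g) {
          if (!any(!g$is_decoy)) return(g[0L])
          g[, id := get(id_col)]
          q <- target_decoy_qvalues(g)
          q[q_value <= threshold & !is_decoy]
        }), fill = TRUE)
      if (!nrow(passing)) return(dt[0L])
      if (scope == "run") {
        key_ok <- paste(passing$run_id, passing$id)
        pass <- pass & paste(dt$run_id, dt[[id_col]]) %in% key_ok
      } else {
        pass <- pass & dt[[id_col]] %in% passing$id
      }
    }
  }
  dt[pass & !is_decoy]
}

#' Spike-in false discovery proportion estimate
#'
#' In a two-species design where only the background species is present in a
#' given sample, detections of the spiked species estimate the false-match
#' rate. With `n_d` detected spike-species precursors out of `N_d` in the
#' library, and `n_t` detected background precursors out of `N_t`, the FDP
#' among background detections is estimated as
#' `(n_d / n_t) * (N_t - n_t) / N_d`, which assumes nearly all detected
#' background precursors are true.
#'
#' @param n_d Detected spike-species precursors.
#' @param N_d Spike-species precursors in the library.
#' @param N_t Background-species precursors in the library.
#' @param n_t Detected background-species precursors.
#' @return The estimated FDP.
#' @export
fdp_spikein <- function(n_d, N_d, N_t, n_t) {
  stopifnot(n_d >= 0, n_d <= N_d, n_t >= 0, n_t <= N_t)
  if (n_t == 0 || N_d == 0)
    stop("fdp_spikein undefined for n_t = 0 or N_d = 0")
  (n_d / n_t) * (N_t - n_t) / N_d
}

#' Entrapment false discovery proportion estimate
#'
#' With foreign-species (entrapment) proteins appended to the database,
#' quantified entrapment proteins are false by construction and the FDP
#' among the `n_h` quantified target-species proteins is estimated as
#' `(N_h / N_o) * (n_o / n_h)`, scaling the entrapment hit rate by the
#' relative database sizes.
#'
#' @param N_h Target-species proteins in the database.
#' @param N_o Entrapment proteins in the database.
#' @param n_h Quantified target-species proteins.
#' @param n_o Quantified entrapment proteins.
#' @return The estimated FDP.
#' @export
fdp_entrapment <- function(N_h, N_o, n_h, n_o) {
  stopifnot(N_h >= 0, N_o >= 0, n_h >= 0, n_h <= N_h, n_o >= 0, n_o <= N_o)
  if (n_h == 0 || N_o == 0)
    stop("fdp_entrapment undefined for n_h = 0 or N_o = 0")
  (N_h / N_o) * (n_o / n_h)
}

#' Greedy set-cover protein grouping
#'
#' A simple parsimony stand-in for full protein inference: proteins are
#' ranked by distinct-peptide count (ties: accession), each peptide is
#' assigned to the first protein covering it, proteins with identical
#' peptide sets are merged into one group, and proteins left with no
#' assigned peptides are subsumed.
#'
#' @param peptide_proteins data.table with columns `peptide` and `proteins`
#'   (";"-joined accessions), typically the passing peptides after FDR.
#' @return data.table of groups: group_id, accessions (";"-joined),
#'   n_peptides, peptides (";"-joined).
#' @export
group_proteins <- function(peptide_proteins) {
  empty <- data.table::data.table(group_id = integer(), accessions = character(),
                                  n_peptides = integer(), peptides = character())
  dt <- unique(data.table::as.data.table(peptide_proteins)[, .(peptide, proteins)])
  if (!nrow(dt)) return(empty)
  links <- dt[, .(accession = strsplit(proteins, ";", fixed = TRUE)[[1L]]),
              by = peptide]
  # merge proteins with identical peptide sets
  sets <- links[, .(pepset = paste(sort(unique(peptide)), collapse = "\r")),
                by = accession]
  groups <- sets[, .(accessions = paste(sort(accession), collapse = ";")),
                 by = pepset]
  groups[, n_total := lengths(strsplit(pepset, "\r", fixed = TRUE))]
  data.table::setorder(groups, -n_total, accessions)
  assigned <- character()
  out <- list()
  for (i in seq_len(nrow(groups))) {
    peps <- setdiff(strsplit(groups$pepset[i], "\r", fixed = TRUE)[[1L]],
                    assigned)
    if (!length(peps)) next  # subsumed by earlier groups
    assigned <- c(assigned, peps)
    out[[length(out) + 1L]] <- data.table::data.table(
      accessions = groups$accessions[i],
      n_peptides = length(peps),
      peptides = paste(sort(peps), collapse = ";"))
  }
  res <- data.table::rbindlist(out)
  res[, group_id := seq_len(.N)]
  data.table::setcolorder(res, "group_id")
  res[]
}
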