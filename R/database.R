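# Sequence database handling: FASTA ingestion with reversed decoys, in-silico
# restricted-tryptic digestion, fixed/variable modification enumeration,
# theoretical b/y fragmentation and the binned fragment-ion index.

#' Default modification set: fixed carbamidomethyl C, variable oxidation M
#' and protein N-terminal acetylation
#'
#' @return List of modification specs (name, delta_mass, targets, fixed);
#'   `targets` uses residue letters, with `"protN"` marking the protein
#'   N-terminus.
#' @export
default_modifications <- function() {
  list(
    list(name = "Carbamidomethyl", delta_mass = 57.02146, targets = "C",
         fixed = TRUE),
    list(name = "Oxidation", delta_mass = 15.99491, targets = "M",
         fixed = FALSE),
    list(name = "Acetyl", delta_mass = 42.01057, targets = "protN",
         fixed = FALSE)
  )
}

#' Load a FASTA database and append reversed decoys
#'
#' Each target protein is paired with a full-sequence-reversed decoy whose
#' accession carries the `rev_` prefix; digestion happens after reversal, so
#' decoy peptides are not simple reversals of target peptides at the termini.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param decoy_prefix Accession prefix for decoys (default `"rev_"`).
#' @return data.table with columns accession, sequence, is_decoy.
#' @export
load_fasta_with_decoys <- function(path, decoy_prefix = "rev_") {
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("empty FASTA: ", path)
  acc <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  sequence <- as.character(seqs)
  targets <- data.table::data.table(accession = acc, sequence = sequence,
                                    is_decoy = FALSE)
  decoys <- data.table::data.table(
    accession = paste0(decoy_prefix, acc),
    sequence = reverse_sequence(sequence),
    is_decoy = TRUE
  )
  rbind(targets, decoys)
}

reverse_sequence <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(a) paste(rev(a), collapse = ""), character(1))
}

#' Digest proteins with restricted trypsin
#'
#' Cleaves after every K or R, including before proline ("restricted"
#' trypsin); set `cleave_before_proline = FALSE` for classical P-suppressed
#' trypsin. Peptides with up to `max_missed` internal missed cleavages are
#' emitted, filtered to the given length and mass ranges, and identical
#' peptide sequences from different proteins are merged with their protein
#' accessions aggregated.
#'
#' @param proteins data.table from [load_fasta_with_decoys()] (accession,
#'   sequence, is_decoy).
#' @param max_missed Maximum missed cleavages (default 1).
#' @param length_range Allowed peptide length (default c(7, 50)).
#' @param mass_range Allowed peptide monoisotopic mass in Da
#'   (default c(500, 5000)). Applied to the unmodified peptide.
#' @param cleave_before_proline Cleave K/R-P bonds (default TRUE).
#' @return data.table with columns sequence, proteins (";"-joined), is_decoy,
#'   missed_cleavages, is_protein_nterm.
#' @export
digest <- function(proteins, max_missed = 1L, length_range = c(7L, 50L),
                   mass_range = c(500, 5000), cleave_before_proline = TRUE) {
  stopifnot(max_missed >= 0L)
  pieces <- lapply(seq_len(nrow(proteins)), function(i) {
    pep <- digest_one(proteins$sequence[i], max_missed, cleave_before_proline)
    if (!nrow(pep)) return(NULL)
    pep[, accession := proteins$accession[i]]
    pep[, is_decoy := proteins$is_decoy[i]]
    pep
  })
  all <- data.table::rbindlist(pieces)
  if (!nrow(all)) {
    return(data.table::data.table(sequence = character(), proteins = character(),
                                  is_decoy = logical(), missed_cleavages = integer(),
                                  is_protein_nterm = logical()))
  }
  len <- nchar(all$sequence)
  all <- all[len >= length_range[1L] & len <= length_range[2L]]
  if (nrow(all)) {
    mass <- vapply(all$sequence, peptide_neutral_mass, numeric(1),
                   USE.NAMES = FALSE)
    all <- all[mass >= mass_range[1L] & mass <= mass_range[2L]]
  }
  if (!nrow(all)) {
    return(data.table::data.table(sequence = character(), proteins = character(),
                                  is_decoy = logical(), missed_cleavages = integer(),
                                  is_protein_nterm = logical()))
  }
  # A shared sequence between a target and its decoy counts as target.
  merged <- all[, .(
    proteins = paste(sort(unique(accession)), collapse = ";"),
    is_decoy = all(is_decoy),
    missed_cleavages = min(missed_cleavages),
    is_protein_nterm = any(is_protein_nterm)
  ), by = sequence]
  data.table::setorder(merged, sequence)
  merged[]
}

digest_one <- function(sequence, max_missed, cleave_before_proline) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  if (!cleave_before_proline) {
    cut_after <- cut_after[cut_after == n | aa[cut_after + 1L] != "P"]
  }
  # cut positions: 0 (start), after each site, n (end)
  cuts <- unique(c(0L, cut_after[cut_after < n], n))
  starts <- head(cuts, -1L) + 1L
  ends <- cuts[-1L]
  out <- list()
  for (mc in 0:max_missed) {
    k <- length(starts) - mc
    if (k < 1L) break
    s <- starts[seq_len(k)]
    e <- ends[seq_len(k) + mc]
    out[[mc + 1L]] <- data.table::data.table(
      sequence = substring(sequence, s, e),
      missed_cleavages = mc,
      is_protein_nterm = s == 1L
    )
  }
  data.table::rbindlist(out)
}

#' Enumerate modified peptide forms
#'
#' Fixed modifications are applied unconditionally to every eligible residue;
#' all combinations of at most `max_variable` variable modifications are then
#' emitted. Protein N-terminal modifications (target `"protN"`) are only
#' placed on peptides flagged as protein N-terminal and are carried on
#' residue 1.
#'
#' @param peptides data.table from [digest()].
#' @param specs Modification specs as in [default_modifications()].
#' @param max_variable Maximum simultaneous variable modifications (default 3).
#' @return data.table with one row per modified form: peptide_id, sequence,
#'   modified_peptide (bracketed mass-delta notation), deltas (list column of
#'   per-residue mass deltas), neutral_mass, proteins, is_decoy,
#'   missed_cleavages.
#' @export
enumerate_modified_forms <- function(peptides, specs = default_modifications(),
                                     max_variable = 3L) {
  stopifnot(max_variable >= 0L)
  fixed <- Filter(function(m) isTRUE(m$fixed), specs)
  variable <- Filter(function(m) !isTRUE(m$fixed), specs)
  rows <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    seq_i <- peptides$sequence[i]
    aa <- strsplit(seq_i, "", fixed = TRUE)[[1L]]
    base <- numeric(length(aa))
    for (m in fixed) {
      hit <- aa %in% strsplit(gsub("protN", "", m$targets), "")[[1L]]
      base[hit] <- base[hit] + m$delta_mass
    }
    # variable sites: list of (position, delta)
    sites <- list()
    for (m in variable) {
      if (identical(m$targets, "protN")) {
        if (peptides$is_protein_nterm[i])
          sites[[length(sites) + 1L]] <- c(pos = 1, delta = m$delta_mass)
      } else {
        for (p in which(aa %in% strsplit(m$targets, "")[[1L]]))
          sites[[length(sites) + 1L]] <- c(pos = p, delta = m$delta_mass)
      }
    }
    combos <- list(integer())
    if (length(sites) && max_variable > 0L) {
      for (k in seq_len(min(max_variable, length(sites)))) {
        cmb <- utils::combn(length(sites), k, simplify = FALSE)
        # at most one modification per position
        cmb <- Filter(function(ix) {
          !anyDuplicated(vapply(sites[ix], `[[`, numeric(1), "pos"))
        }, cmb)
        combos <- c(combos, cmb)
      }
    }
    forms <- lapply(combos, function(ix) {
      d <- base
      for (s in sites[ix]) d[s[["pos"]]] <- d[s[["pos"]]] + s[["delta"]]
      d
    })
    rows[[i]] <- data.table::data.table(
      sequence = seq_i,
      deltas = forms,
      proteins = peptides$proteins[i],
      is_decoy = peptides$is_decoy[i],
      missed_cleavages = peptides$missed_cleavages[i]
    )
  }
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) {
    out <- data.table::data.table(sequence = character(), deltas = list(),
                                  proteins = character(), is_decoy = logical(),
                                  missed_cleavages = integer())
  }
  out[, neutral_mass := vapply(seq_len(.N), function(j) {
    peptide_neutral_mass(sequence[j], deltas[[j]])
  }, numeric(1))]
  out[, modified_peptide := vapply(seq_len(.N), function(j) {
    format_modified_peptide(sequence[j], deltas[[j]])
  }, character(1))]
  data.table::setorder(out, sequence, neutral_mass, modified_peptide)
  out[, peptide_id := seq_len(.N)]
  data.table::setcolorder(out, "peptide_id")
  out[]
}

format_modified_peptide <- function(sequence, deltas) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  mod <- deltas != 0
  aa[mod] <- sprintf("%s[+%.4f]", aa[mod], deltas[mod])
  paste(aa, collapse = "")
}

#' Theoretical b/y fragment ions of one peptide form
#'
#' All b_i and y_i for i in 1..len-1 at each requested fragment charge;
#' modification deltas are carried on the correct side of the backbone
#' cleavage. The full-length b_n / y_n ions are not emitted.
#'
#' @param sequence Peptide sequence.
#' @param deltas Per-residue modification deltas (NULL for none).
#' @param fragment_charges Integer vector of fragment charges (default 1).
#' @return data.table with columns mz, series ("b"/"y"), ordinal, frag_charge.
#' @export
theoretical_fragments <- function(sequence, deltas = NULL,
                                  fragment_charges = 1L) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(aa)
  stopifnot(n >= 2L)
  res <- unname(RESIDUE_MASS[aa])
  if (anyNA(res)) stop("non-canonical residue in sequence: ", sequence)
  if (!is.null(deltas)) res <- res + deltas
  cum <- cumsum(res)
  i <- seq_len(n - 1L)
  b_neutral <- cum[i]                       # sum of first i residues
  y_neutral <- cum[n] - cum[n - i] + WATER_MASS  # last i residues + water
  out <- lapply(fragment_charges, function(z) {
    data.table::data.table(
      mz = c((b_neutral + z * PROTON_MASS) / z,
             (y_neutral + z * PROTON_MASS) / z),
      series = rep(c("b", "y"), each = n - 1L),
      ordinal = c(i, i),
      frag_charge = as.integer(z)
    )
  })
  data.table::rbindlist(out)
}

#' Build the fragment-ion index over a peptide database
#'
#' Every theoretical fragment of every peptide form is placed in exactly one
#' m/z bin of width `bin_width` (bin = floor(mz / bin_width)); queries scan
#' the bins overlapped by the ppm tolerance and then apply the exact
#' tolerance, so indexed retrieval equals a linear scan.
#'
#' @param peptides data.table from [enumerate_modified_forms()].
#' @param bin_width Bin width in Th (default 0.02).
#' @param fragment_charges Fragment charges indexed (default 1).
#' @return A `fragment_index` object: peptide table (sorted by neutral mass),
#'   fragment table (sorted by m/z, with bin index), and bin width.
#' @export
build_fragment_index <- function(peptides, bin_width = 0.02,
                                 fragment_charges = 1L) {
  stopifnot(nrow(peptides) > 0L)
  # vectorized bulk fragmentation (equivalent to rbind-ing
  # theoretical_fragments() over every form, but without per-peptide
  # allocations; the per-peptide function remains the reference)
  n_pep <- nrow(peptides)
  b_list <- vector("list", n_pep)
  y_list <- vector("list", n_pep)
  lens <- integer(n_pep)
  for (j in seq_len(n_pep)) {
    aa <- strsplit(peptides$sequence[j], "", fixed = TRUE)[[1L]]
    res <- unname(RESIDUE_MASS[aa])
    d <- peptides$deltas[[j]]
    if (!is.null(d) && length(d)) res <- res + d
    cum <- cumsum(res)
    n <- length(aa)
    lens[j] <- n - 1L
    b_list[[j]] <- cum[seq_len(n - 1L)]
    y_list[[j]] <- cum[n] - cum[n - seq_len(n - 1L)] + WATER_MASS
  }
  b_all <- unlist(b_list, use.names = FALSE)
  y_all <- unlist(y_list, use.names = FALSE)
  ords <- unlist(lapply(lens, seq_len), use.names = FALSE)
  pid_all <- rep.int(peptides$peptide_id, lens)
  per_z <- lapply(fragment_charges, function(z) {
    data.table::data.table(
      mz = c((b_all + z * PROTON_MASS) / z, (y_all + z * PROTON_MASS) / z),
      series = rep(c("b", "y"), each = length(b_all)),
      ordinal = c(ords, ords),
      frag_charge = as.integer(z),
      peptide_id = c(pid_all, pid_all))
  })
  frags <- data.table::rbindlist(per_z)
  frags[, bin := as.integer(floor(mz / bin_width))]
  data.table::setorder(frags, mz, peptide_id, series, ordinal, frag_charge)
  peps <- data.table::copy(peptides)
  data.table::setorder(peps, neutral_mass, peptide_id)
  structure(list(bin_width = bin_width, fragments = frags, peptides = peps,
                 masses = peps$neutral_mass),
            class = "fragment_index")
}

#' @export
print.fragment_index <- function(x, ...) {
  cat(sprintf("<fragment_index> %d peptide forms, %d fragments, bin width %g Th\n",
              nrow(x$peptides), nrow(x$fragments), x$bin_width))
  invisible(x)
}

#' Query the fragment index by m/z and ppm tolerance
#'
#' @param index A [build_fragment_index()] result.
#' @param mz Query m/z (scalar).
#' @param tol_ppm Tolerance in ppm.
#' @return The matching fragment rows (possibly empty).
#' @export
query_fragment_index <- function(index, mz, tol_ppm) {
  tol <- mz * tol_ppm * 1e-6
  fmz <- index$fragments$mz
  lo <- findInterval(mz - tol, fmz) + 1L
  hi <- findInterval(mz + tol, fmz)
  if (hi < lo) return(index$fragments[0L])
  index$fragments[lo:hi]
}

# Peptide ids whose neutral mass falls within any [low, high] interval.
peptides_in_mass_ranges <- function(index, lows, highs) {
  m <- index$masses
  ids <- integer()
  for (k in seq_along(lows)) {
    lo <- findInterval(lows[k], m) + 1L
    hi <- findInterval(highs[k], m)
    if (hi >= lo) ids <- c(ids, index$peptides$peptide_id[lo:hi])
  }
  sort(unique(ids))
}
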