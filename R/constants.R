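# Physical constants and residue mass tables used throughout the engine.
# Monoisotopic masses (Da); sources: standard atomic mass evaluation values
# as used by all mainstream search engines.

#' @keywords internal
PROTON_MASS <- 1.00727646688

#' @keywords internal
ISOTOPE_SPACING <- 1.00335483

#' @keywords internal
WATER_MASS <- 18.0105646863

# Monoisotopic residue (not amino acid) masses, canonical 20 letters.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Averagine model: average elemental composition per 111.1254 Da of peptide.
AVERAGINE_COMPOSITION <- c(C = 4.9384, H = 7.7583, N = 1.3577,
                           O = 1.4773, S = 0.0417)
AVERAGINE_UNIT_MASS <- 111.1254

# Aggregated isotope abundance per element, indexed by nucleon shift 0,1,2,...
ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0001)
)

#' Predict a peptide isotope envelope from its neutral mass (averagine model)
#'
#' Approximates the elemental composition of a peptide of the given
#' monoisotopic neutral mass by the averagine average-residue model, then
#' convolves per-element isotope distributions to obtain the relative
#' abundances of the M, M+1, M+2, ... isotopologues.
#'
#' @param neutral_mass Monoisotopic neutral mass in Da.
#' @param n_isotopes Number of isotopologues to return (default 3).
#' @return Numeric vector of length `n_isotopes`, normalized so the
#'   monoisotopic abundance is 1.
#' @export
#' @examples
#' averagine_envelope(1500)
averagine_envelope <- function(neutral_mass, n_isotopes = 3L) {
  stopifnot(neutral_mass > 0, n_isotopes >= 1L)
  n_units <- neutral_mass / AVERAGINE_UNIT_MASS
  dist <- 1
  for (el in names(ELEMENT_ISOTOPES)) {
    n <- pmax(0L, round(AVERAGINE_COMPOSITION[[el]] * n_units))
    if (n == 0L) next
    dist <- convolve_truncate(dist, convolve_power(ELEMENT_ISOTOPES[[el]], n, n_isotopes),
                              n_isotopes)
  }
  out <- rep(0, n_isotopes)
  out[seq_along(dist)] <- dist
  out / out[1L]
}

# Distribution of the sum of n i.i.d. draws from `p`, truncated to `len` terms,
# by binary exponentiation of the polynomial.
convolve_power <- function(p, n, len) {
  result <- 1
  base <- p
  while (n > 0L) {
    if (n %% 2L == 1L) result <- convolve_truncate(result, base, len)
    n <- n %/% 2L
    if (n > 0L) base <- convolve_truncate(base, base, len)
  }
  result
}

convolve_truncate <- function(a, b, len) {
  out <- rep(0, min(len, length(a) + length(b) - 1L))
  for (i in seq_along(a)) {
    jmax <- min(length(b), length(out) - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Compute the monoisotopic neutral mass of a (modified) peptide
#'
#' @param sequence Amino-acid string over the 20 canonical letters.
#' @param deltas Optional numeric vector of per-residue modification mass
#'   deltas (Da), length `nchar(sequence)`; N-terminal modifications are
#'   carried on position 1.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_neutral_mass <- function(sequence, deltas = NULL) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- RESIDUE_MASS[aa]
  if (anyNA(m)) stop("non-canonical residue in sequence: ", sequence)
  total <- sum(m) + WATER_MASS
  if (!is.null(deltas)) total <- total + sum(deltas)
  unname(total)
}
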