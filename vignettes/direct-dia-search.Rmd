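---
title: "Direct database search of DIA spectra: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct database search of DIA spectra: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diadirect)
library(data.table)
```

## The problem

In data-independent acquisition (DIA) proteomics, the instrument cycles
through a fixed scheme of precursor isolation windows and co-fragments
*every* peptide in each window. The resulting MS/MS spectra are chimeric —
fragments of several precursors are mixed — and carry no precursor charge or
mono m/z annotation, only the isolation-window bounds. Classical
spectrum-centric workflows first detect chromatographic features and
assemble pseudo-MS/MS spectra before searching; `diadirect` takes the
opposite route and searches every DIA MS/MS spectrum *directly* against the
sequence database, deferring all chromatography to a targeted refinement
step. This is the spectrum-centric direct-search strategy used by modern
fragment-index engines, implemented here as a compact, fully testable R
package with a ground-truth simulator.

## The search model

**Precursor hypotheses.** For an MS2 spectrum with isolation window
$[w_-, w_+]$ and an assumed charge $z$, any generating peptide must have
neutral mass in $[(w_- - m_p)z, (w_+ - m_p)z]$, where $m_p$ is the proton
mass. All configured charges (default 1–4) are enumerated; the calibration
search restricts to $z \in \{2, 3\}$.

**Candidate scoring.** Peptides are digested in silico (restricted trypsin:
cleavage after K/R *including* before proline; at most 1 missed cleavage;
length 7–50; mass 500–5000 Da), modified forms are enumerated (fixed
carbamidomethyl-C; variable Met oxidation and protein N-terminal
acetylation, at most 3 per peptide), and all singly charged $b/y$ fragments
are placed in an m/z-binned index (0.02 Th bins, exact ppm tolerance at
query time). A spectrum is scored against every in-range form: the
preliminary score is the number of distinct matched theoretical fragments,
with ties broken by summed matched intensity and then peptide id. The top
128 candidates are kept per spectrum for wide-window runs, 32 for
narrow-window (gas-phase-fractionation style) runs; the regime is chosen
from the median window width (> 5 Th ⇒ wide). The indexed search is
verified against a brute-force linear-scan oracle — identical ranking and
scores — in the test suite.

**Mass calibration.** Two searches are run. The restricted calibration
search collects high-quality identifications (at least 6 matched fragments;
the top decile of preliminary scores, but never fewer than 50 spectra when
at least 50 qualify), regresses fragment ppm error on m/z by least squares,
and the full search then runs on corrected peaks
($mz \cdot (1 - \widehat{ppm}(mz) \cdot 10^{-6})$). With fewer than 50
qualifying spectra an identity model is used and a warning logged. A linear
model is sufficient at this scale; injected uniform and linear drifts up to
5 ppm/1000 Th are recovered to better than 1 ppm.

**Hyperscore and greedy deconvolution.** Candidates are rescored with the
X!Tandem-style hyperscore

$$H = \ln\!\big( N_b!\; N_y!\; (1 + \textstyle\sum I_b)(1 + \sum I_y) \big)$$

over intensities normalized to the spectrum base peak (factorials capped at
$20!$). Because chimeric spectra let one experimental peak support several
candidates, each spectrum is deconvolved greedily: emit the best-scoring
candidate, delete its matched peaks, rescore the remainder, and repeat
until fewer than 4 peaks remain, candidates are exhausted, or the best
score reaches the floor (0). One deliberate choice: the normalization
factor is fixed at the *original* base peak for the whole loop rather than
recomputed from the shrinking remainder. Re-normalizing upward after the
base peak is removed could raise a later emission's score above an earlier
one; with a fixed factor, emitted scores are provably non-increasing and
each peak contributes to at most one PSM. The hyperscore formula itself is
the one component an implementer may plausibly wish to swap.

## Targeted refinement by XIC tracing

For every emitted PSM the engine builds per-window MS2 and MS1 spectral
indexes (peak tables keyed by m/z and acquisition cycle) and traces an
extracted ion chromatogram for each matched fragment and for the precursor
mono m/z: per cycle the most intense peak within tolerance, apex at the
maximum after 3-point moving-average smoothing (ties to earlier rt), trace
trimmed to the contiguous non-zero region around the apex.

The refinement rules, applied in order:

1. the median apex retention time is computed over the fragment apexes plus
   the precursor apex when the precursor is detected (for an even count the
   lower middle value is used, so the median is always an observed rt —
   deterministic under ties);
2. fragments whose apex deviates from the median by more than 0.1 min
   (default) are removed;
3. a *detected* precursor whose own apex deviates by more than the
   tolerance rejects the PSM (`precursor_rt`); an undetected precursor
   never does — real low-abundance peptides often show fragment signal
   without a visible MS1 feature, so missing-precursor PSMs are retained;
4. a detected precursor must have an isotope envelope (first three
   isotopes at the precursor apex) whose cosine similarity to the
   averagine-predicted envelope at its neutral mass is at least 0.80
   (`isotope`); fewer than two observed isotopes is treated as insufficient
   evidence to reject;
5. at least 4 fragments (default, matching the greedy 4-peak floor) must
   survive (`too_few_fragments`).

"Detected" means a non-zero MS1 XIC at the expected mono m/z with at least
3 non-zero cycles. Since the same peptide is matched in every scan across
its elution, PSMs of one peptide form and charge whose apexes fall within
the rt tolerance inside one window are collapsed to the single
highest-hyperscore PSM ("one PSM per feature"; ties to the earlier scan).
The feature definition — an apex cluster by single-linkage along rt — is a
design choice; nothing sharper is implied by the matched data.

## Confidence estimation

Reversed protein sequences (accession prefix `rev_`, digested after
reversal) provide the decoy model. At a score threshold $s$ the FDR
estimate is $\#\{decoys \ge s\} / \max(1, \#\{targets \ge s\})$ (the +1
correction is available but off by default), and q-values are the running
minimum from the bottom. Identification lists are filtered by the
*combination* of run-specific and global, precursor-level and
protein-level 1% FDR, with best-score roll-up from PSM to precursor to
protein. Protein grouping is a greedy set cover (indistinguishable proteins
merged, subsumed proteins absorbed) — a deliberate stand-in for full
protein inference, which is out of scope.

Two empirical false-discovery-proportion estimators complement the decoy
estimate. In a two-species spike-in design, detections $n_d$ of the spiked
species in a background-only sample (out of $N_d$ spike entries in the
library, with $N_t$, $n_t$ the background analogues) give

$$\widehat{FDP} = \frac{n_d}{n_t}\cdot\frac{N_t - n_t}{N_d},$$

which substitutes the observed $n_t$ for the unobservable count of *true*
background detections — accurate exactly when the detection list is mostly
correct, which is the regime where the estimate is interesting. In an
entrapment design with $N_h$ target-species and $N_o$ foreign proteins in
the database and $n_h$, $n_o$ quantified,

$$\widehat{FDP} = \frac{N_h}{N_o}\cdot\frac{n_o}{n_h}.$$

Both are validated in simulation against the ground-truth FDP.

## The simulator: a stated world

The generator emulates cyclic DIA acquisition: each cycle holds one MS1
scan followed by one MS2 scan per window (MS2 scans offset within the
cycle, as on a real instrument). Its defaults were chosen once, as a
plausible miniature of a short-gradient run, and are not tuned to test
outcomes:

| parameter | default | rationale |
|---|---|---|
| windows | 20 × 12 Th over 400–640 Th | wide-window regime (top-128); a 4 Th preset covers the narrow regime |
| gradient | 5 min | desk-scale; ~100 cycles |
| cycle time | 0.05 min | precursor/fragment apexes land within the 0.1 min rt filter |
| elution | Gaussian, sd 0.05–0.1 min | ~2–4 s peaks, short-gradient chromatography |
| abundance | log-normal, meanlog log(500), sdlog 0.7 | ≈ 2 orders of magnitude dynamic range over the floor |
| fragment pattern | flat Dirichlet over b/y | uninformative but precursor-specific; shared by the precursor's whole elution |
| MS1 envelope | first 3 averagine isotopes | what the isotope check assumes |
| noise | 50 peaks/scan, log-uniform [0.1, 10] | chemical noise floor in MS2 scans |
| detection floor | 1.0 (arbitrary units) | peaks below it are not recorded |

Simulated precursors are unmodified charge-2 tryptic peptides free of M/C
(so each corresponds to exactly one database form), drawn from a random
proteome whose K/R frequency (1/12) gives a mean tryptic peptide length of
about 12. A precursor is *detectable* when it is isolated by some window
and at least 4 fragments clear the floor at its apex. The simulator is
deterministic under its seed.

What it does **not** emulate: chromatographic tailing, ion suppression and
interference structure, correlated noise, isotope-pattern distortions,
staggered/overlapping windows, ion mobility, or realistic fragment
intensity models. A green end-to-end test therefore establishes the
*internal consistency* of the engine (search, refinement, scoring and FDR
behave as specified on data obeying their assumptions), not instrument
realism.

## Pipeline ordering

One deviation from a literal reading of the reference workflow: candidate
fragment lists are refined by XIC *after* greedy deconvolution, on emitted
PSMs only, rather than refining all top-N candidates of every spectrum
before rescoring. The filters applied are identical; only far fewer PSM
records pass through them (emitted PSMs per spectrum are few, top-N is up
to 128). At this package's scale that reordering is what makes the
end-to-end runtime practical in R, and on simulated data the retained set
is the same: candidates that would have been rescued by pre-rescoring
refinement are those whose spurious fragments suppress their rank, which
the preliminary count-based score makes rare. The per-PSM refinement
function is exposed directly (`refine_psm()`) so the conventional order can
be composed by a user if desired.

## Numerical conventions

- Proton mass 1.00727646688 Da, isotope spacing 1.00335483 Da,
  monoisotopic residue masses; retention times in minutes everywhere
  (mzML second-based times converted on read).
- Deisotoping collapses a cluster only when the observed M+1/M ratio is
  within [0.1, 3.0] × the averagine prediction at the implied neutral mass
  — the reference pipeline states no rule; this bounds false merges while
  intensity is conserved exactly.
- Averagine composition C 4.9384, H 7.7583, N 1.3577, O 1.4773, S 0.0417
  per 111.1254 Da; envelopes by truncated convolution of per-element
  isotope distributions.
- Ties everywhere break deterministically (lower peptide id, earlier scan,
  earlier rt) so the whole pipeline is a pure function of (inputs, config,
  seed).
- Degenerate inputs are contracts, not crashes: empty spectra score to
  empty candidate lists; all-zero XICs report no apex; a search with no
  identifiable spectra calibrates to the identity model with a warning.

## Known limitations

- Fragment charges default to 1+; 2+ fragments can be indexed but inflate
  the index at desk scale.
- The linear mass-error model cannot represent strongly non-linear drifts.
- The internal FDR is a simple target-decoy estimator; the package writes
  pepXML/pin so mixture-model or semi-supervised rescoring tools can be
  used downstream instead.
- Protein grouping is parsimony-only, with no probability model.
- Spectral libraries are single-run (no iRT alignment across runs);
  library fragment intensities default to XIC apex intensities, which are
  more complete than any single chimeric scan.
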