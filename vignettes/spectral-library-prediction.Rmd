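---
title: "Predicting DIA spectral libraries from peptide sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DIA spectral libraries from peptide sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialib)
```

## The problem

Peptide-centric analysis of data-independent acquisition (DIA) proteomics
data queries a *spectral library* — per-precursor lists of fragment ions
with relative intensities plus a normalized retention time (iRT) — against
highly multiplexed MS/MS data. Libraries are conventionally built from
data-dependent acquisition (DDA) runs of the same sample, which is costly
and restricts DIA to what DDA happened to identify. `dialib` replaces the
experimental library with predictions: instrument-specific neural networks
learn fragmentation intensities, retention and MS detectability from DDA
training data, and a digestion/assembly pipeline turns a bare protein FASTA
(or a peptide list) into an importable library CSV, optionally spiked with
an entrapment set of foreign-organism proteins for empirical error-rate
checks.

## The models

All three predictors share one hybrid architecture operating on one-hot
encoded sequence:

* **MS/MS model** (one per precursor charge, 2+ and 3+): input 20 x 50
  (amino acids x positions, right-padded), a 1-D convolution with 64
  filters of width 2 (pairs of adjacent residues — exactly the two residues
  flanking each backbone cleavage site), a 128-unit bidirectional LSTM over
  the 49 site positions, dropout 0.5, and a position-wise dense layer of 12
  ReLU units. The output is a 12 x 49 matrix: one column per cleavage site,
  one row per ion type in the fixed order b1+, b1+-NH3, b1+-H2O, b2+,
  b2+-NH3, b2+-H2O, then the same for y. Column j holds b_j and y_(L-j).
  Targets are max-normalized experimental intensities in [0, 1]; the loss
  is mean squared error over all 12 x 49 cells with zero padding beyond the
  L-1 real sites (an optional masked loss restricts to real sites). At
  prediction time cells beyond the real sites are forced to zero and the
  matrix is re-normalized to max 1.
* **iRT model**: the same stack with convolution width 5 and a scalar
  linear head on the concatenated final LSTM states. iRT targets are
  divided by 100 during optimization and rescaled on output. Peptides are
  pooled across charges (retention does not depend on precursor charge);
  duplicate sequences with conflicting iRT collapse to their median.
* **Detectability model**: the iRT variant on a 22 x 66 flanked encoding —
  seven residues of true protein context on each side of the peptide,
  separated by dots, with a blank symbol where the protein ends (template:
  columns 1-7 N-flank right-aligned, 8 dot, 9-58 peptide, 59 dot, 60-66
  C-flank) — and a sigmoid head trained with binary cross-entropy, so
  scores are calibrated probabilities in [0, 1]. A regression head cannot
  emit calibrated scores, hence the sigmoid/cross-entropy choice.

Training uses Adam (learning rate 1e-3 unless stated), mini-batches, an
optional validation set with best-epoch restoration, and early stopping
(default patience 10). Weights are Glorot-uniform from a stated seed; the
LSTM forget-gate bias starts at 1. All computation is dense linear algebra
through R's BLAS with exact analytic backpropagation; the gradient
implementation is verified against finite differences in the test suite.

## From search results to training data

One PSM per precursor is kept, the one with minimum Q-value; ties break by
higher summed matched intensity, then lexicographic spectrum reference, so
selection is deterministic. Precursors outside charge 2-3 are excluded from
MS/MS training. Experimental spectra (MGF, or mzML via `mzR`) are annotated
against the theoretical b/y fragment set — singly and doubly charged, with
ammonia and water losses generated for every fragment regardless of
composition (unobserved losses simply train toward zero) — using a 20 ppm
match window by default (Orbitrap HCD practice; configurable in ppm or Th),
assigning each theoretical cell the most intense peak in its window and
max-normalizing. iRT comes from the search engine when present, otherwise
from a per-run least-squares line through spiked reference peptides.
Training/test sets are a seeded 2/3-1/3 split at unique-sequence level, so
no peptide ever straddles the partition.

## Digestion and library assembly

In silico proteolysis cuts after K/R; plain Trypsin suppresses cleavage
before proline, Trypsin/P does not. Peptides keep their true protein flanks
and exact missed-cleavage counts. Two digestion recipes mirror library
practice: without detectability filtering, the union of Trypsin and
Trypsin/P digests at zero missed cleavages; with filtering, Trypsin/P with
up to two missed cleavages. Library filters keep peptides of 7-50 residues
with monoisotopic mass at most 6000 Da (carbamidomethylated cysteine is a
fixed modification everywhere; +57.021464 Da). I and L are distinct
letters; N-terminal methionine is not clipped.

Entrapment sets are seeded samples from a foreign-organism FASTA, matched
in protein count to the target set; a peptide shared between target and
entrapment proteins counts as target, which is the conservative direction
for the entrapment percentage.

Assembly predicts a fragment matrix and iRT per peptide/charge, computes
precursor and fragment m/z from a standard monoisotopic residue table
(proton 1.007276, water 18.010565, ammonia 17.026549), and exports
fragments with predicted relative intensity at least 0.05, ranked by
intensity, at most 20 per precursor, requiring at least 6 (entries below
the minimum are dropped and reported). The CSV uses Spectronaut-style assay
columns (ModifiedPeptide with `C[Carbamidomethyl (C)]`, StrippedPeptide,
PrecursorCharge, PrecursorMz, iRT, ProteinId, FragmentType, FragmentNumber,
FragmentCharge, FragmentLossType, FragmentMz, RelativeIntensity). The
two-step (second-pass) build re-digests first-pass proteins, filters by
detectability, and regroups proteins by identical retained peptide sets —
a deliberate simplification of protein inference (no parsimony cover).

## Evaluation metrics

* Dot product: cosine similarity of the flattened 12 x 49 cell vectors
  (zeros included; an option restricts to plain b/y rows). Scale-invariant,
  symmetric, in [0, 1]; all-zero inputs return 0 with a warning.
* iRT statistics: Pearson r of predicted vs observed iRT and the IQR (and
  quantiles) of their differences.
* Entrapment percentage: 100 x (entrapment hits) / (all accepted hits),
  after id deduplication.
* Sensitivity: 100 x |predicted-library ids shared with reference| /
  |reference ids|.
* CV per feature across replicates (sample standard deviation, n-1) and
  percent change of group means; RT matching uses a strict < 0.5 min
  window by default.

## Synthetic ground truth

Because real training corpora require raw instrument data plus commercial
search software, every stage is validated against seeded generators whose
rules are known exactly:

* `fragmentation_rule()`: y-ion intensity decays exponentially with the
  distance of the cleavage site from the C-terminus and is modulated by
  lognormal per-residue "basicity" weights of the two site-flanking
  residues; b ions are a scaled mirror image; 2+ rows grow with fragment
  length; ammonia/water losses are strong only when the fragment contains
  R/K/Q/N or S/T/E/D. Realized peak lists sit at the theoretical m/z with
  optional multiplicative noise and a 5% admixture of spurious peaks.
* `retention_rule()`: additive per-residue coefficients plus a length term
  and Gaussian noise — classical retention-index behaviour.
* `detectability_rule()`: P(observed) is logistic in the hydrophobic
  fraction, log-length and C-terminal residue; labels are Bernoulli draws.
  The default weights give the rule itself a Bayes-optimal AUC of roughly
  0.97: the weights must be strong enough that label noise does not cap
  every possible classifier below the recovery threshold being tested,
  and weak enough that labels remain genuinely stochastic.

These generators emulate the *statistical shape* of HCD DDA data — smooth
sequence- and position-dependent intensities, additive retention,
probabilistic observability — not its physics. Passing rule-recovery tests
demonstrates that the models, losses and data plumbing learn what is
learnable; it does not certify prediction accuracy on real spectra, which
depends on instrument-specific training data.

## Numerical choices and degenerate cases

* Match tolerance 20 ppm. Distinct theoretical fragments can share one
  match window — often exactly (in AVLGTSNFK the doubly charged b4 equals
  b2 because A+V and L+G have identical residue mass) — so annotation
  collapses such collisions onto the most intense peak. Raw rule matrices
  therefore re-annotate only approximately (the handful of collided cells
  change), but matrices that are themselves annotation outputs — which is
  what all real training targets are — are exact fixed points of
  synthesize-then-annotate, and the closed-loop checks assert that
  identity exactly.
* Dropout 0.5 imposes a stochastic-optimization noise floor of ~1-2 iRT
  units on degenerate constant-target regressions; the builders expose
  `dropout_rate` so wiring checks can disable it, while the default
  architecture keeps 0.5.
* Empty spectra annotate to an all-zero matrix flagged via an attribute;
  all-zero intensity vectors give dot product 0 with a warning; thresholds
  for detectability filtering are clamped to [0, 1] and the comparison is
  inclusive (score >= threshold).
* Rule-recovery problem sizes used by the validation suite: 5,000 peptides
  for the MS/MS and iRT models and 10,000 for detectability, trained for a
  small fixed number of epochs (9 for MS/MS; 12 + 8 with a 1e-3 -> 3e-4
  learning-rate step for iRT; 3 for detectability) at batch size 256 —
  enough for the recovery thresholds with margin while keeping a full
  validation run on one CPU in the tens of minutes. The learning-rate step
  for iRT buys most of a longer constant-rate schedule's accuracy at half
  the epochs.

## Limitations

Only b/y ions with NH3/H2O losses at charges 1-2 are modelled (no a/c/x/z
ions, no isotope envelopes); no variable modifications (carbamidomethyl C
is fixed); no collision-energy conditioning — models are intentionally
instrument-specific rather than global; protein grouping is
identical-peptide-set merging; DDA database search and the DIA extraction
itself are out of scope (the library CSV is the hand-off point).
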