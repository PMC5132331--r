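---
title: "Predicting DNA-binding proteins from sequence-derived features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA-binding proteins from sequence-derived features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnabindR)
```

## The problem

DNA-binding proteins — transcription factors, polymerases, histones,
repair enzymes — are central to chromatin biology, and annotating them
from sequence alone remains a routine need whenever structures and
experimental annotations are missing. `dnabindR` implements a
sequence-only predictor built from three complementary views of a
protein:

1. **Evolutionary conservation projected onto chemistry (120
   features).** A PSI-BLAST position-specific scoring matrix (PSSM)
   records, for every sequence position, the log-odds of observing each
   of the 20 amino acids at that position across a protein family.
   Each score `x` is squashed to `(0, 1)` with the logistic map
   `f(x) = 1 / (1 + exp(-x))`, the rows belonging to the same residue
   type `k` are summed column-wise (giving a 20×20 matrix independent
   of protein length), and each pooled row is projected onto six
   min-max-normalised physicochemical scales — the pKa of the amino
   and carboxyl groups, the electron-ion interaction potential, the
   number of side-chain lone electron pairs, the Wiener index of the
   molecular graph, and the molecular mass:
   `S[a, k] = sum_i NP_a(i) * pooled[k, i]`.
2. **Binding and non-binding propensities (4 features).** A residue-level
   predictor supplies, for every position, a binding / non-binding call
   with an integer reliability index `RI` in 0–10. The first-order
   propensity `BP(1) = sum(RI) / (10 N)` measures how much confidently
   predicted binding material the chain carries. The second-order
   propensity `BP(2)` compares, at every sequence separation `i`, the
   reliability-weighted density of binding-residue *pairs*,
   `p_i = ri_sum(i) / (10 (N - i))`, with the density `q^2` expected if
   binding calls were scattered independently (`q` is the global
   reliability density), through relative-entropy terms
   `p_i log2(p_i / q^2)`. Binding residues cluster on DNA-contacting
   surfaces, so positive proteins show excess short-range pair density.
   `NBP(1)`/`NBP(2)` are the same statistics for non-binding calls.
3. **Global physicochemical texture (168 features).** Classical
   composition/transition/distribution (CTD) descriptors: eight
   property scales (hydrophobicity, polarity, polarizability, charge,
   surface tension, secondary-structure propensity, solvent
   accessibility, normalised van der Waals volume) each partition the
   amino acids into three groups; the sequence is recoded into group
   labels and summarised by group fractions (3), adjacent-pair
   transition rates (3) and five positional landmarks per group (15),
   i.e. 21 descriptors per scale.

The 292-dimensional vector (120 + 4 + 168) feeds a random forest
(1000 trees, 20 candidate features per split). Feature selection is
minimum-redundancy maximum-relevance (mRMR) ranking followed by
incremental feature selection (IFS): classifiers are evaluated on
growing ranked prefixes under stratified five-fold cross-validation and
the smallest prefix attaining the peak Matthews correlation coefficient
(MCC) is kept.

## Numerical and design choices

Several details are deliberate conventions of this package; they are
the points where more than one reasonable implementation exists.

* **PSSM block and column order.** PSI-BLAST ASCII profiles carry two
  20-column blocks; the log-odds block is used (selectable via
  `block = "percent"`), the conventional choice in PSSM-feature work.
  Columns are remapped from the file header's order to alphabetical
  order internally, so profiles from any PSI-BLAST version produce
  identically named features. Positions are 1-based throughout.
* **Pooling without length normalisation.** Pooled rows are plain sums
  over positions; no division by the residue-type count is applied.
  Length effects are left to the classifier, which sees 292 correlated
  views of them.
* **Property values.** The six projection properties ship as a built-in
  table (`default_property_table()`), with pKa and mass taken from
  standard free-amino-acid references and Wiener indices computed from
  the heavy-atom molecular graphs. Because every scale passes through
  min-max normalisation, any positive affine variant of a published
  scale yields bit-identical features — a property the test suite
  asserts — so the exact source edition of a scale is immaterial.
* **Pair reliability in `BP(2)`.** The pair-density numerator needs a
  reliability per *pair* of residues; the arithmetic mean of the two
  members' indices is used (symmetric, and exact when the two agree),
  with `min` and `product` available.
* **The Taylor form.** The exact `p log2(p / q^2)` terms are undefined
  at `p = 0` (`0 · log 0`). `BP(2)` therefore evaluates, per separation,
  the second-order expansion around `p = q^2`:
  `(1/ln 2) (d + d^2/q^2)` with `d = p - q^2`, which is exactly 0 for
  empty separations, making sparse tracks cost `O(#pairs)`. The
  expansion's quadratic coefficient differs from the textbook expansion
  of `p ln(p/q^2)` (which carries `d^2/2q^2`); the implemented bracket
  follows the method's published form, and the exact logarithmic form
  is kept (`form = "exact"`) for comparison. Near `p = q^2` the two
  agree to `O(d^2)`, which the tests verify by halving the deviation
  and observing the gap shrink four-fold.
* **Degenerate propensities.** A protein with no binding calls has
  `q = 0`; both propensities are defined as 0 there rather than raising
  an error, because such proteins are legitimate negative-class inputs.
  Tracks shorter than 2 residues are rejected (they cannot occur after
  the 50-residue dataset filter).
* **CTD landmarks.** The distribution descriptor uses five landmarks
  per group (first occurrence plus the 25/50/75/100% occurrence
  quantiles, rank `ceiling(fraction × count)`), the only count
  consistent with 21 descriptors per property; a group absent from a
  sequence contributes five zeros.
* **Discretisation for mRMR.** Features are cut once, globally, into
  three states at mean ± one standard deviation — the convention of the
  classical mRMR distribution. The MID (difference) criterion is the
  default, MIQ selectable. Ties break by original column order, making
  the whole selection deterministic given data and seed.
* **"Peak" of the IFS curve.** Read as the global maximum of MCC with
  smallest-`k` tie-breaking. A `stride` option thins the prefix sweep
  for desk-scale runs; the default evaluates every prefix.
* **Cross-validation.** Folds are stratified by class (per-class sizes
  differ by at most one), and aggregate metrics are computed from the
  pooled confusion counts, with per-fold means reported alongside.
  MCC is defined as 0 whenever a denominator factor vanishes, so a
  degenerate all-negative classifier scores 0, not an error.
* **Filtering.** Chains shorter than 50 residues (likely fragments) or
  longer than 6000 (likely complexes) are removed, bounds inclusive of
  50 and 6000; any sequence containing a non-canonical code
  (X, Z, B, U, O, J, `*`) is removed, since every encoder requires the
  20-letter alphabet.
* **Prediction ties.** With an even forest a 50/50 vote is possible;
  ties go to the positive class, so reported winning vote fractions lie
  in [0.5, 1].

## What the synthetic generator emulates

Real inputs require a PSI-BLAST search against a large database and a
residue-level binding predictor. The generator (`synth_config()`,
`gen_dataset()`) emulates all three streams with controllable class
signal so the full pipeline is testable offline:

* sequences are i.i.d. draws over a configurable residue frequency
  table, with lengths uniform on a configurable range;
* profile scores are integers from a discretised normal clipped to
  [-10, 13] — the typical PSI-BLAST log-odds range, chosen so the
  sigmoid's saturation regions are exercised — with a configurable
  shift added to each position's own-residue column in positive
  proteins (a crude stand-in for family conservation signal);
* binding calls are per-residue Bernoulli draws at a class-specific
  rate, with reliability indices `10 - Geometric(c)` truncated at 0,
  concentrating near 10 as the confidence parameter `c` grows.

The default condition — 100 proteins per class, lengths 50–200, binding
rates 0.15 (positives) vs 0.02 (negatives), profile shift 2, `c = 0.5`
(mean RI ≈ 9) — gives two strongly separated classes; setting both
rates equal and the shift to 0 gives an exchangeable null. Lengths
50–200 keep a 200-protein dataset's encoding and cross-validation at
interactive speed while staying inside the dataset filter's [50, 6000]
window.

What passing tests on these data do **not** show: synthetic sequences
have no compositional structure, no homology between proteins, no
length–class confounding, and position-independent profile noise, so
performance numbers on them say nothing about accuracy on real
proteomes — they verify that the machinery recovers signal that is
present and reports none when it is absent. Published figures for this
family of methods (cross-validated accuracies in the mid-80s on
balanced UniProt-derived sets) require the original curated dataset,
database-derived profiles and residue predictor, all outside this
package's scope.

## Known limitations

* `BP(2)` enumerates all target-call pairs; for a 6000-residue protein
  with thousands of calls this is a few million pairs — fine in
  vectorised R, but a compiled kernel would be the next step for
  proteome-scale runs.
* Mutual information uses the plug-in estimator on three-state
  discretised features; no bias correction is applied, matching the
  classical mRMR tool.
* The random forest consumes raw (undiscretised) features; only the
  mRMR ranking sees the discretised table.
* The generator draws residues i.i.d.; propensity features computed on
  it therefore lack the autocorrelation real binding-site clusters
  show, which mildly *understates* `BP(2)`'s real-data value.

## Problem sizes used in the shipped checks

The package's own test suite and the reproduction script run the full
pipeline at 100 proteins per class (lengths 50–200), five seeds for the
signal-recovery and selection-sanity properties, brute-force oracle
comparisons at 100+ random small instances per statistic, and a
stride-thinned IFS sweep — sizes chosen so a complete run stays within
a few minutes on a laptop core while every stage (generation, parsing,
encoding, ranking, selection, training, evaluation) is exercised end
to end.
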