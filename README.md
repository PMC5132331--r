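# dnabindR

Sequence-based prediction of DNA-binding proteins in R.

Deciding from sequence alone whether a protein binds DNA is a recurring
annotation task for transcription factors, polymerases, histones and
repair enzymes. `dnabindR` implements a complete predictor of the
profile-plus-propensity family for bioinformaticians who have, per
protein, (i) the amino-acid sequence, (ii) a PSI-BLAST
position-specific scoring matrix (PSSM), and (iii) per-residue
binding/non-binding calls with 0–10 reliability indices from a
residue-level predictor.

## The method

Each protein is encoded as a 292-dimensional vector:

* **PSSM–physicochemical projection (120).** Profile scores are
  sigmoid-scaled, `f(x) = 1/(1 + e^{-x})`, pooled by residue type into
  a 20×20 matrix `pooled[k, i]`, and projected onto six min-max
  normalised property scales:
  `S[a,k] = Σ_i NP_a(i) · pooled[k,i]` (6 properties × 20 types).
* **Binding/non-binding propensities (4).** With reliability indices
  `RI ∈ 0..10` and protein length `N`:
  `BP(1) = Σ RI / (10N)` over binding calls, and `BP(2)` sums, over
  sequence separations `i = 1..N−1`, relative-entropy terms comparing
  the pair density `p_i = ri_sum(i)/(10(N−i))` with its independence
  expectation `q²` — evaluated in a Taylor form that is exact at
  `p_i = 0`. `NBP(1)`, `NBP(2)` repeat this for non-binding calls.
* **Composition/transition/distribution descriptors (168).** Eight
  three-group amino-acid partitions × 21 descriptors (group
  composition, adjacent-pair transitions, five positional landmarks
  per group).

Classification is a random forest (`ntree = 1000`, `mtry = 20`);
feature selection is mRMR ranking (MID criterion on three-state
discretised features) followed by incremental feature selection
against stratified five-fold cross-validated MCC. Accuracy,
sensitivity, specificity and MCC are reported throughout. A synthetic
generator emulates all three input streams with controllable class
signal, so every stage is testable without external databases.

## Worked example

```r
library(dnabindR)

# Synthetic study condition: 50 proteins per class, binding-call rates
# 0.15 (positives) vs 0.02 (negatives), own-residue profile shift 2.
cfg <- synth_config(n_positive = 50, n_negative = 50,
                    length_range = c(50, 150), seed = 7)
ds  <- gen_dataset(cfg)

tab    <- assemble_feature_table(ds)   # 100 x (292 features + label)
feats  <- tab[, setdiff(names(tab), "label")]
labels <- tab$label

cross_validate(feats, labels, folds = 5, seed = 7)
#> cross-validation (pooled): ACC 1.0000  SE 1.0000  SP 1.0000  MCC 1.000

rk <- mrmr_rank(suppressWarnings(discretize_features(feats)), labels)
head(rk, 5)
#> [1] "NBP1"                               "PSSMPP.lone_pairs.C"
#> [3] "BP1"                                "PHY.hydrophobicity.D.g1.p100"
#> [5] "PHY.solvent_accessibility.D.g1.p75"

signif(feature_ttest(feats, labels)[c("BP1", "BP2", "NBP1", "NBP2")], 3)
#>      BP1      BP2     NBP1     NBP2
#> 7.28e-31 1.94e-01 1.11e-32 6.51e-02
```

At this separation the classes are cleanly learnable (MCC 1 under
five-fold cross-validation), the propensity features dominate the mRMR
ranking, and the per-feature two-sample t-tests flag the first-order
propensities as overwhelmingly separated. On the exchangeable null
(equal rates, zero shift) the same pipeline reports MCC ≈ 0.

Real PSI-BLAST profiles are read with `parse_ascii_pssm()`, FASTA with
`read_fasta()` (filter with `filter_proteins()`: 50–6000 residues,
canonical alphabet), and residue-call tables with
`read_binding_track()`. A thin command-line front end with
`synth` / `encode` / `cv` / `select` / `predict` subcommands is
installed at `inst/cli/dnabind.R`.

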