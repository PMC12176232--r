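---
title: "Methods: compositional encoders, redundancy filtering and classifier evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional encoders, redundancy filtering and classifier evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protclass)
```

`protclass` implements a complete FASTA-to-classifier pipeline for binary
protein classification, built around the task of recognizing chronic
myeloid leukemia (CML)-associated proteins from sequence alone. This
vignette is the package's own account of the methods: the encoders and
their mathematics, every tunable parameter with its default and rationale,
the synthetic data model the tests rely on, and the numerical and design
choices made where the problem left the design open.

## Sequence model and input assumptions

A record is an identified sequence over the 20 canonical amino-acid
letters, length L ≥ 1. Headers follow the UniProt FASTA convention: the
token after the first `|` identifies the record when present, otherwise the
first whitespace-delimited token. Real UniProt keyword dumps contain
noncanonical letters (X, U, B, Z, J, O, `*`, gaps); the default policy
removes those residues with a warning (`drop_residue`), because composition
statistics are only defined over the canonical alphabet. `reject` is
available for strict runs and `map_to_exclusion` discards whole records.
Sanitization is idempotent, and sequences are uppercased on read so that
composition counts are case-insensitive.

## Redundancy filtering

Homology filtering follows the CD-HIT convention: greedy incremental
clustering at an identity cutoff (default 0.6, the cutoff used by the CML
benchmark study). Records are sorted by decreasing length (ties broken by
ascending id, for determinism); each record joins the first representative
it matches at or above the cutoff, else founds a new cluster.

Identity between two sequences is computed from an exact global
(Needleman–Wunsch) alignment with match +1, mismatch 0 and a linear gap
penalty of −1, as the number of identical aligned columns divided by the
length of the **shorter** sequence — CD-HIT's denominator. CD-HIT itself
never publishes its alignment scoring, and at the scale this package
targets (hundreds to a few thousand sequences) exact alignment via
`Biostrings::pairwiseAlignment()` is affordable, so none of CD-HIT's k-mer
prefilter heuristics are reproduced. Clustering runs within each class
separately so that a positive sequence can never be absorbed (and thus
deleted) by a negative representative.

Note one consequence of the shorter-length denominator: a sequence that is
an exact prefix of a longer one has identity 1 regardless of the length
difference. That is the tool convention, not an accident.

## Encoders

**AAC.** Component i is 100·n_i/L; the vector always sums to 100 and is
invariant under residue shuffling.

**DPC.** Counts of the 400 ordered dipeptides over the L−1 overlapping
windows. Two normalizations are provided. The default, `fraction`, divides
by L−1 so the vector sums to 1 — the standard definition. The `per400`
mode divides by 400 (the number of dipeptide *types*), which makes the
vector sum to (L−1)/400, i.e. scale with sequence length; it exists because
the benchmark study prints its dipeptide formula that way. `fraction` is
the default because a length-dependent feature scale is almost never what a
classifier should see.

**PseAAC.** The classical formulation with the three canonical
physicochemical properties — hydrophobicity, Hopp–Woods hydrophilicity and
side-chain mass — shipped as a plain-text table
(`inst/extdata/aa_properties.tsv`) and replaceable by the user. Each
property is standardized to mean 0 and *population* standard deviation 1
(divisor 20) over the residues before use. The residue dissimilarity is
Θ(r₁, r₂) = mean of the three squared standardized differences, the tier-k
correlation factor is T_k = (1/(L−k)) Σ Θ(Rᵢ, Rᵢ₊ₖ), and with residue
fractions f_u (Σf = 1):

* PAAC_u = f_u / (1 + w ΣT_k) for u ≤ 20,
* PAAC_{20+k} = w T_k / (1 + w ΣT_k) for k ≤ λ,

so the vector sums to 1 and reduces exactly to AAC/100 at λ = 0. Defaults
are λ = 5 — chosen to match the 25-dimensional encoding the benchmark
study reports (20 + λ = 25) — and w = 0.05, the conventional weight.
Neither value is stated explicitly in that study; both are documented
inferences. A sequence must satisfy L > λ, enforced with an error that
names the offending record.

## Preprocessing

All stages are pure functions of (input, configuration, seed).

* **Outlier removal** (`iqr_outlier_mask`): per feature, values outside
  [Q1 − k·IQR, Q3 + k·IQR] are flagged (k = 1.5, the classical Tukey
  fence); a row is dropped only when more than `row_fraction` (default
  0.10) of its features are flagged. The row-fraction trigger exists for
  high-dimensional encodings: with 400 mostly-sparse DPC columns, flagging
  any single extreme value would annihilate the dataset. The filter is not
  a mathematical fixpoint — removing rows shifts the recomputed quartiles —
  but with a gross outlier and the default trigger a second pass removes
  nothing, which is what the test suite asserts.
* **Feature scoring and selection**: absolute point-biserial (Pearson)
  correlation of each feature with the 0/1 label; zero-variance features
  score 0 by convention. Selection drops features below `min_abs_r`
  (default 0 = keep all), then scans survivors in decreasing score (ties:
  original column order) and drops any feature whose pairwise |r| with an
  already-kept feature exceeds `redundancy_r` (default 0.95). The full
  report (score, kept, dropping rule) travels with the reduced matrix.
* **Augmentation**: class-wise jittered replication. Each original row
  yields factor − 1 replicas; each feature is perturbed with Gaussian noise
  of sd = eps × the feature's class-wise sd (eps default 0.01, i.e. within
  measurement noise of compositional vectors; eps = 0 gives exact copies).
  Class proportions and feature count are preserved exactly. By default
  augmentation is applied to the **training partition only**; the
  `augment_before_split` flag reproduces the benchmark study's apparent
  order (its test-set sizes exceed its sequence count by two orders of
  magnitude, implying replicas crossed the split), at the cost of
  train/test leakage — scientific hygiene by default, fidelity on request.
* **Splitting**: stratified, per-class test size = floor(n_class ×
  `test_fraction`), remainder to train (default 0.25, matching the
  2536/845 ≈ 75/25 split the study reports for DPC).

## Classifier registry

Seven families, all delegated to their standard R implementations and
wrapped with provenance (scheme, parameters, selected features, seed,
format version) sufficient to featurize and predict on new FASTA input from
the archive alone:

| algo | implementation | defaults |
|------|----------------|----------|
| svc  | `e1071::svm`   | RBF, C = 10000, γ = 100000, degree 8 (inert under RBF), probabilities on |
| rf   | `randomForest` | 150 trees for DPC, 50 otherwise |
| knn  | `class::knn`   | k = 5, Euclidean |
| nb   | `e1071::naiveBayes` | Gaussian, equal priors |
| xgb  | `xgboost::xgb.train` | 100 rounds, eta 0.3, depth 6, single thread |
| lr   | `glmnet` ridge | C = 10 (λ = 1/(C·n)), tol 0.1, L2 |
| dt   | `rpart`        | CART defaults (minsplit 20, cp 0.01) |

The SVC, RF and LR settings are the benchmark study's printed values; k-NN's
k, XGBoost's and the tree's settings are pinned library defaults recorded in
provenance, because the study does not state them. Naive Bayes is included
in the registry but absent from the study's result tables.

**On the printed kernel width.** γ = 100000 deserves a warning. On
compositional features (fractions summing to 1, or percentages), typical
squared distances between same-class vectors are of order 10⁻², so the RBF
kernel exp(−γ·d²) evaluates to exp(−1000) ≈ 0 for *every* distinct pair:
the kernel matrix degenerates to the identity, the decision function
collapses to its bias, and held-out accuracy is exactly chance (we measure
0.50). The printed value can only have appeared to work on data where
near-duplicates of training rows sat in the test set — which is what
pre-split augmentation produces. The registry therefore keeps the printed
value verbatim (it is the documented configuration), but `gamma = "scale"`
resolves at training time to 1/(d·Var(X)) — the conventional data-scaled
width — and is what the package's own end-to-end experiments use.

Prediction returns the class-1 probability and the label 1 iff probability
≥ 0.5 (ties to 1; the study states no decision threshold, so 0.5 is fixed
and documented). `class::knn` breaks exact-distance ties randomly, so k-NN
prediction pins the RNG to the model seed to stay a pure function of
(model, input). Model archives are single RDS containers with an explicit
format-version field; mismatched or truncated archives are refused, never
silently coerced.

## Evaluation

From TN/FP/FN/TP counts: accuracy = 100(TN+TP)/total, recall =
100·TP/(TP+FN), specificity = 100·TN/(TN+FP), precision = 100·TP/(TP+FP),
F1 = harmonic mean of precision and recall. Any metric whose denominator is
zero is **0 by convention** — required so that an all-negative classifier
reports F1 = 0 rather than NaN, as the benchmark tables themselves do.
Display rounding is half-to-even at one decimal.

`table_check()` recomputes metrics from a confusion matrix and compares
them with reported values (points or [lo, hi] ranges), passing a cell when
the recomputed value falls within the range widened by half a unit in the
last printed decimal. Applied to the 18 reported confusion matrices of the
CML benchmark study (`check_benchmark_tables()`), 39 of 72 cells are
self-consistent; the rest — e.g. an SVC accuracy printed as 54.95 whose own
matrix yields 73.3, or an XGBoost accuracy printed as 56.8 that recomputes
to 78.3 — are flagged as findings, never forced to match. The package
reports both numbers and takes no side on which of the two published
figures is the typo.

## Synthetic data model

`generate_dataset()` draws negatives i.i.d. from the uniform composition
over the 20 residues and positives from a composition in which a designated
subset (default {A, L, K}, arbitrary but fixed and recorded) has its
probabilities multiplied by (1 + δ) and renormalized; lengths are uniform
on [80, 120] by default. This model was chosen because AAC and PseAAC are
exactly the statistics it shifts: the planted signal has an analytic ground
truth (boosted residues sit at 3/26 vs 1/20 of composition at δ = 2), so
end-to-end recovery can be verified against a known answer, and δ = 0 gives
exchangeable classes for null experiments.

What the generator does **not** emulate: real protein composition (residue
frequencies are far from uniform), domain structure, phylogenetic
correlation between sequences, or any CML-specific biology of the BCL2 /
HSP90 / PARP / RB families. Passing the recovery test therefore shows the
pipeline machinery is sound — not that the disease signal in real data is
as recoverable.

The study conditions used by the package's own experiments: 200 positives +
200 negatives, lengths 80–120, δ = 2, a 25% stratified held-out split. At
these sizes the SVC pipeline recovers the signal with held-out accuracy
well above 0.90. For the null check (δ = 0, permuted labels) the fitted
model is scored on 400 freshly generated null sequences: at 400 evaluation
points the binomial standard deviation of a chance accuracy is 2.5
percentage points, so the [0.40, 0.60] acceptance band is a four-sigma
bound. (At the 100-point held-out split the same band would be only
±1.7σ and would fail roughly one seed in ten by pure chance — a check
that sharp would be testing the random number generator, not the
pipeline.)

## Numerical and determinism choices

* Feature order is fixed (residues alphabetical, dipeptides row-major,
  PseAAC components indexed) and written into every CSV header.
* All stochastic operations take explicit seeds and use scoped RNG
  (`withr::with_seed`), never mutating the caller's RNG state; repeated
  runs with the same seed are bit-identical, which the tests assert down
  to serialized report JSON.
* Greedy tie-breaks (clustering order, feature-selection order) always
  fall back to input order, never hash order.
* Degenerate inputs error early with the offending record named: empty
  sequences, single-class training data, L ≤ λ, zero-variance property
  tables, selection that removes every feature.

## Known limitations

* Exact all-pairs alignment makes clustering O(n²) alignments; it is meant
  for desk-scale datasets, not millions of sequences.
* Feature selection runs before the train/test split in the pipeline (as
  the upstream protocol implies); with `min_abs_r = 0` (the default) the
  relevance stage is label-blind so no leakage occurs, but a nonzero
  threshold uses test labels and should be interpreted accordingly.
* Only binary classification; no probability calibration, ROC analysis or
  cross-validated aggregation.
* The published headline accuracies (92–94%) of the CML study cannot be
  reproduced here: its curated UniProt dataset was never deposited. What
  the package reproduces is the study's evaluation arithmetic and the
  behaviour of its pipeline on data with a known planted signal.
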