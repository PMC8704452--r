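---
title: "Methods: evolutionary-profile DTI prediction with dtiforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary-profile DTI prediction with dtiforest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dtiforest` predicts drug–target interactions (DTIs) by casting the problem
as binary classification over a bipartite grid: every (target protein,
drug compound) pair is a sample, pairs with a known interaction are
positives, and *every* remaining grid pair is a negative. This vignette
documents the model, the parameters that matter, the synthetic-data
generator used throughout the tests, and the numerical and design choices a
maintainer should know about.

## The interaction grid and its assumptions

A study consists of target proteins (each with a PSI-BLAST evolutionary
profile), drugs (each with an FP2 path fingerprint), and an edge list of
known interactions. Treating all non-edges as negatives is the standard
gold-standard-benchmark convention, and it is an *assumption*: some
"negatives" are simply undiscovered interactions, so measured specificity is
a lower bound on the truth. No negative subsampling is applied before
balancing; the full grid enters the pipeline, which is why the class
imbalance (`sample_ratio()`, negatives/positives) can reach two orders of
magnitude on realistic collections.

## Protein descriptors

The raw input per protein is an L × 20 matrix of integer log-odds scores,
one row per residue, columns in the fixed amino-acid order
`A R N D C Q E G H I L K M F P S T W Y V`. Scores are mapped through the
logistic function `1 / (1 + exp(-E))`, which is strictly increasing and
keeps every value inside (0, 1).

**PsePSSM** compresses the variable-length profile into `20 + 20 * lambda`
numbers: the 20 column means, then for each lag `lambda' = 1..lambda` the
per-column mean squared difference between scores `lambda'` residues apart.
The lag blocks capture sequence-order information that plain column means
discard; at `lambda = 0` the descriptor *is* the column-mean profile.

**DCCA coefficients** treat the 20 normalized columns as non-stationary
series. For a column pair, both series are cumulated, the cumulative
profiles are cut into `L - s` overlapping windows of `s + 1` points
(stride 1), each window is detrended by an ordinary least-squares straight
line in the index, and the coefficient is the window-averaged residual
covariance over the product of window-averaged residual standard
deviations. All 190 unordered pairs are reported, in the fixed
lexicographic order (A,R), (A,N), ..., (Y,V). The implementation projects
each window matrix through the (symmetric, idempotent) OLS residual maker,
so one matrix crossproduct yields all 190 coefficients; the unit tests pin
this against a literal window-by-window re-implementation at 1e-12.

## Drug descriptors

A 1024-bit FP2 fingerprint is consumed as 256 hexadecimal characters and
decoded nibble-wise — leftmost character first — into 256 integers in 0..15.
Nibble order within the bitstring is a serialization convention; it affects
cross-tool reproducibility of individual columns but not classifier quality,
since the forest is invariant to column permutation. Fingerprint
*generation* from structures is out of scope: produce the hex strings with
a fingerprinting tool (e.g. Open Babel's FP2 output) upstream.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda_order` | 3 | PsePSSM lag depth (features: 20 + 20λ); selected by mean CV accuracy over 0..15 via `scan_lambda()` |
| `s` | 36 | DCCA window parameter (window length s + 1 residues); selected over 9..81 via `scan_s()`; requires `s <= L_min - 1` |
| `lambda_reg` | chosen by CV | L1 penalty weight on the sum-of-squares scale; `choose_lambda_reg()` picks the CV-best grid value, ties toward the sparser model |
| `perc_over` | 500 | % oversampling: 5 synthetic rows per minority row |
| `perc_under` | 120 | % undersampling: kept majority = 1.2 × synthetic count |
| `k_neighbors` | 5 | minority nearest-neighbour pool for interpolation |
| `n_trees` | 500 | forest size; vote fractions are the probabilities |
| `mtry` | ⌊√Q⌋ | candidate features per split |
| `n_folds` | 5 | cross-validation folds, pair-level partition |
| `threshold` | 0.5 | scalar-metric / reporting cutoff; a pair is called interacting iff its probability is *strictly* greater |

With the defaults the fused pair vector has 80 + 190 + 256 = 526 features.

## Balancing scope and leakage

`balance_scope = "train_only"` (default) fits the Lasso and applies SMOTE
inside each training split; held-out folds contain only original pairs.
`balance_scope = "global"` selects features and balances *before* splitting,
so test folds contain synthetic minority rows interpolated from — possibly —
training rows. That protocol matches how balanced-data cross-validation has
often been reported, and it is optimistic: on label-free noise it produces
AUCs far above 0.5, which the acceptance suite demonstrates directly
(global vs train-only on the same null data, direction checked over 10
seeds). Reports carry the scope used; comparisons across scopes are
comparisons of protocols, not of models.

## The synthetic-data generator

`simulate_dti()` generates the raw inputs of a study: integer profiles with
entries uniform on −9..11 (the empirical range of PSI-BLAST log-odds),
lengths uniform on `L_range` (default 83–120, mirroring benchmark
collections whose shortest sequence, 83 residues, caps `s` at 82), uniform
random hex fingerprints, and a uniform random edge set. Everything is
reproducible from one integer seed.

`signal_strength` plants a pair-level class signal at feature-assembly time:
positive rows receive a mean shift of `signal_strength` per-column standard
deviations on a fixed subset of ten feature columns (five PsePSSM means,
five fingerprint nibbles). The shift lives at the pair level because a
per-protein signal cannot separate classes — each protein occurs in both
positive and negative pairs. At strength 0 labels are pure noise
(cross-validated AUC compatible with 0.5); at ≥ 5 SD the classes are
separable by construction (mean CV AUC above 0.95 in the acceptance suite).

What the generator does *not* emulate: residue-composition structure and
autocorrelation of real profiles, fingerprint sparsity patterns (real FP2
bits are sparse and correlated), degree structure of real interaction
networks (hub drugs and promiscuous targets), and feature correlation
between a protein's descriptors and its interaction propensity. Passing
tests therefore certify the *machinery* — descriptor algebra, balancing
semantics, evaluation protocol — not biological performance on real
collections, which depends on the real feature distributions.

## Numerical choices

- **Window moments** use divisor `s + 1` (the window size) exactly as in
  the descriptor's defining form, not `s`; the bias is immaterial because
  it cancels in the ρ ratio's numerator and denominator scales.
- **Degenerate DCCA denominators** (a constant column ⇒ zero detrended
  fluctuation) make ρ undefined; the package defines ρ = 0 ("no
  cross-correlation") and warns, keeping descriptor vectors total and
  bounded. Constancy is detected on the raw series, not on residual
  magnitudes, so floating-point noise cannot flip the branch.
- **Clipping**: floating-point ρ can overshoot ±1 by ~1e-15; values are
  clipped into [−1, 1].
- **Lasso solver**: glmnet coordinate descent. The package's penalty
  `RSS + lambda * sum(|beta|)` equals glmnet's `RSS/(2N) + lambda_g * sum(|beta|)`
  objective at `lambda_g = lambda / (2N)`; a short descending path ending at
  the target value stabilizes the fit, and coefficients are read off the
  path directly. Features are standardized internally (sample SD), the
  label is centered, and constant features are forced out of the support.
- **SMOTE details**: one interpolation weight U ~ Uniform(0,1) per synthetic
  row (vector form); Euclidean neighbour distances in the *selected*
  feature space (selection precedes balancing in the pipeline);
  neighbour-distance ties broken by row index; majority rows sampled
  without replacement, capped at the majority count.
- **Evaluation**: threshold sweeps group tied scores; AUC is the trapezoidal
  ROC area (provably the tie-corrected normalized Mann–Whitney U, and
  cross-checked against a pairwise-comparison oracle and against pROC);
  AUPR is the step-wise integral of precision over recall increments —
  linear interpolation between PR points is deliberately avoided because it
  overestimates. Undefined ratios (zero denominators) are reported as `NaN`,
  never silently as 0.
- **Fold partition**: pair-level, near-equal (sizes differ by at most one;
  103 pairs split as 21/21/21/20/20). Per-fold and per-candidate seeds are
  derived deterministically from the master seed and the fold/candidate
  index, so parameter scans can be parallelized without changing results.
- **Domain guards**: `psepssm` requires `lambda < L`; `dcca` requires
  `2 <= s <= L - 1` and names the offending protein and its length;
  parsers report the offending line, drug id, or character position.

## Design decisions at genuinely open points

- PSI-BLAST ASCII files contain two 20-column blocks; only the first
  (log-odds) block is used — it is the one whose integer range matches the
  normalization. Columns are remapped by header letters, never by position.
- Rows for non-canonical residues (X, B, Z) keep their score rows; dropping
  them would change L and every downstream feature.
- The fused pair vector is protein-descriptor-then-drug-descriptor; the
  classifier is invariant to this, but serialized tables must be
  deterministic, as must the grid row order (targets outer, drugs inner,
  both lexicographic).
- The L1 weight is chosen by internal cross-validation *on the training
  portion only*; its grid scales with the row count (`2N × {1e-4, 1e-3, 1e-2}`)
  so penalty strength is comparable across dataset sizes.
- Parameter-scan ties select the smallest candidate (the cheaper model).
- The decision threshold is strict (`>` 0.5), so an exactly ambivalent
  vote is not called an interaction.

## Problem sizes in the shipped tests

The test and acceptance suites run on simulated studies of 6–12 targets ×
10–24 drugs (up to ~300 grid pairs, 150–300 trees, profile lengths 20–120),
with 10-seed replication for the stochastic properties; descriptor oracles
use 100 random series of length 8–25. These sizes were chosen as the
smallest at which the asymptotic properties under test (null AUC near 0.5,
out-of-bag accuracy near the majority rate, leakage direction) are stable.

## Known limitations

- Negative labels are unverified non-edges; prevalence-sensitive metrics
  inherit that bias.
- The forest scores the full query grid densely; very large grids
  (10⁵–10⁶ pairs) are memory- and CPU-hungry. Score in chunks if needed.
- Lasso operates on the squared-error objective against a 0/1 label — a
  selection heuristic, not a calibrated probability model; calibration
  comes from the forest's vote fractions only.
- `global` balancing scope exists to reproduce historical protocols and
  should not be used for new performance claims.
- FP2 generation and PSI-BLAST itself are upstream tools; this package
  consumes their outputs.
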