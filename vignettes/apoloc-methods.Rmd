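---
title: "Profile-based prediction of apoptosis-protein subcellular localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based prediction of apoptosis-protein subcellular localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoloc)
```

## The problem

Apoptosis proteins act in specific cellular compartments (cytoplasm,
membrane, mitochondrion, nucleus, secreted, endoplasmic reticulum), and the
compartment constrains their function. Given only sequence — and the
evolutionary profile a PSI-BLAST search attaches to it — we want to predict
that compartment. `apoloc` implements a profile-based predictor: two
feature extractors applied to the position-specific scoring matrix (PSSM),
a supervised linear reduction, and a one-vs-one RBF support-vector
classifier evaluated by the jackknife (leave-one-out) test.

The PSSM of a protein of length $L$ is an $L \times 20$ integer log-odds
matrix $E$, rows indexed by sequence position, columns by the 20 residue
types in the fixed PSI-BLAST order `A R N D C Q E G H I L K M F P S T W Y
V`. Typical scores lie in $[-9, 11]$; values outside only warn. Every
entry is first squashed by the logistic map $f(x) = 1/(1+e^{-x})$, so all
downstream computations see values in $(0,1)$.

## Feature extraction

**Pseudo-PSSM (composition + order).** For column $j$ the mean
$\bar P_j = \frac1L \sum_i P_{i,j}$ captures composition-like evolutionary
pressure; for lag $g = 1,\dots,\xi$ the term
$\theta_j^g = \frac{1}{L-g} \sum_{i=1}^{L-g} (P_{i,j} - P_{i+g,j})^2$
captures sequence-order information. The vector
$(\bar P_1,\dots,\bar P_{20},\theta^1_1,\dots,\theta^\xi_{20})$ has length
$20 + 20\xi$; the default $\xi = 3$ gives 80 values. $\xi = 0$ is read as
the means-only 20-vector, the only consistent reading of a lag-free sweep
entry.

**Detrended cross-correlation coefficients.** Each normalized column is
integrated ($M_k = \sum_{i \le k} m_i$) and treated as a non-stationary
series. For a window parameter $S$, all $L-S$ overlapping windows of $S+1$
points (stride 1 — the window count itself fixes the stride) get their own
ordinary-least-squares line fit against the position index, and

$$f^2_{xy}(S) = \frac{1}{L-S} \sum_{i=1}^{L-S} \frac{1}{S+1}
  \sum_{k=i}^{i+S} (M_k - \tilde M_{i,k}) (N_k - \tilde N_{i,k}), \qquad
\rho_{DCCA} = \frac{f^2_{xy}(S)}{\sqrt{f^2_{xx}(S)}\sqrt{f^2_{yy}(S)}}.$$

$\rho \in [-1, 1]$ by Cauchy–Schwarz over the concatenated window
residuals. All $\binom{20}{2} = 190$ unordered column pairs are reported,
ordered $(1,2), (1,3), \dots, (19,20)$ over the PSI-BLAST column order (a
layout choice of this package; no canonical ordering exists). A profile
that is exactly linear inside every window has zero detrended variance;
$\rho$ is then defined as 0 (the "no correlation" value) with a warning.
The default $S = 40$ requires $L \ge 41$; at $L = 50$ the largest
admissible $S$ is 49.

The fused feature vector is the plain concatenation, width
$(20 + 20\xi) + 190 = 270$ at the defaults. No per-block rescaling is
applied — none is part of the model — and column names carry block
provenance (`pse_*`, `dcca_*`) so single-block ablations remain possible.

## Local Fisher discriminant analysis

LFDA maximizes a locality-weighted between/within scatter trace ratio. The
affinity between samples uses Zelnik-Manor–Perona local scaling,
$A_{ij} = \exp(-\lVert x_i - x_j\rVert / \sigma_i \sigma_j)$ with
$\sigma_i$ the distance to the $K$-th nearest neighbor ($K = 7$). The
**unsquared** distance in the exponent is as the model prints it; the
original local-scaling construction uses the squared distance, so
`affinity = "squared"` is available, but the printed form is the default
and the discrepancy is surfaced rather than silently "fixed". Same-class
pairs get within-weights $A_{ij}/n_\ell$ and between-weights
$A_{ij}(1/n - 1/n_\ell)$; cross-class pairs get $0$ and $1/n$. The
transform solves $S^{(b)} t = \lambda (S^{(w)} + \varepsilon I) t$ with the
ridge $\varepsilon = 10^{-6}\,\mathrm{tr}(S^{(w)})/d$ (jackknife folds can
make $S^{(w)}$ singular), keeps the top $r = 10$ eigenvectors with unit
norm (the trace-ratio criterion fixes no scale), and fixes signs so each
column's largest-magnitude entry is positive.

### The leakage question

The published protocol reduces the **whole** dataset before the jackknife.
With $d = 270$ features and $n < d$ samples, $S^{(w)}$ has a large null
space and the top eigenvectors collapse every class to a single point —
for *any* labeling, including random ones. Whole-dataset reduction
followed by leave-one-out therefore memorizes labels: it reproduces the
near-perfect published accuracies, but a permutation null would score
nearly perfectly too. Both protocols are first class here:

* `lfda_mode = "paper"` — reduce once, then jackknife (reproduces the
  published pipeline order; optimistic);
* `lfda_mode = "strict"` — refit the transform on every fold's $n-1$
  training rows and project the held-out sample with that fold's
  transform (leakage-free; the mode in which null questions are
  meaningful).

Reports name the mode. The null checks in the acceptance suite run in
strict mode for exactly this reason; the signal check keeps paper mode as
specified.

## Classification and model selection

A one-vs-one soft-margin SVM with RBF kernel
$K(x, y) = \exp(-\gamma \lVert x - y \rVert^2)$ is trained for each of the
$k(k-1)/2$ class pairs; prediction is by voting, with ties resolved to the
tied class with the smallest index. No SVM package is assumed: the dual is
solved by an SMO solver (LibSVM-style maximal-violating-pair selection,
tolerance $10^{-3}$) in compiled code, verified against analytic
margin geometry and an external reference implementation during
development. Class-membership scores for ROC analysis come from Platt
sigmoids fitted on each pair's training decision values, combined by
pairwise coupling; fitting Platt on training decisions (rather than an
inner CV) is slightly optimistic but affects only score calibration, never
the voted class labels.

Hyperparameters are restricted to the power-of-two grid
$C \in 2^{-5},\dots,2^{15}$ and $\gamma \in 2^{-15},\dots,2^{5}$ (integer
exponents, $21 \times 21$ cells), searched exhaustively and scored by
cross-validated overall accuracy; ties prefer smaller $C$, then smaller
$\gamma$. Two scoring protocols exist:

* `cv_folds = "loo"` (pipeline default) — leave-one-out accuracy,
  deterministic;
* `cv_folds = K` — stratified seed-fixed $K$-fold accuracy.

The LOO default is deliberate. After whole-dataset LFDA with $d > n$ the
classes are point masses, so *every* grid cell ties at 1.0 on balanced
stratified folds and the tie-break would select the extreme corner
$(2^{-5}, 2^{-15})$ — a classifier that provably misclassifies every
leave-one-out fold (with two point masses of 29 vs 30 samples and a
near-constant kernel, the free support vector pins the majority mass at
decision $-1$ and the minority mass lands at $2a(1-k) - 1 < 0$). Scoring
the grid by the same protocol the evaluation uses removes the degeneracy,
and selecting parameters by jackknife accuracy is also how the original
model-building procedure describes itself. Hyperparameters are tuned once,
on the full reduced matrix, and held fixed across evaluation folds in both
LFDA modes.

Evaluation is the jackknife: each sample predicted once by a model trained
on the remaining $n-1$. Per class, one-vs-rest binarization gives
sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$ and Matthews
correlation coefficient, with the $0/0 \to 0$ convention; overall accuracy
is the fraction of correctly located proteins. ROC curves are one-vs-rest
per class, averaged on the union FPR grid, with trapezoidal AUC.

## The synthetic world

Real inputs require a PSI-BLAST search of the NR database, so the package
states a synthetic world (`synth_spec()` / `generate_dataset()`) in which
every stage is testable offline. Per class, profile rows are drawn as an
AR(1)-correlated Gaussian field (position-to-position correlation
`rho_lag`) around a class mean profile (classes shifted by `delta`
raw-score units via deterministic sign patterns), with a rank-one
class-specific column covariance scaled by `pair_signal`; scores are
rounded and clipped to $[-9, 11]$, and each sequence is the per-row argmax
residue. Each knob feeds exactly one feature family — `delta` the means,
`rho_lag` the lag terms, `pair_signal` the cross-correlations — so
ablations can switch mechanisms on and off individually.

Defaults state the test conditions: 3 classes of 30 proteins, lengths
50–120 (so $S = 40$ is always admissible), `delta = 6` (a strong but not
saturating shift against the row noise sd of 2.5), `rho_lag = 0.3` and
`pair_signal = 0.4` (moderate structure, values a real profile's
neighboring rows and co-conserved columns plausibly exhibit). What a green
test establishes is that the implementation separates classes whose
profile statistics differ in the stated ways, and stays at chance when
they do not (in strict mode); it does **not** establish the published
accuracies on CL317/ZW225/ZD98, which require NR-derived profiles supplied
by the user.

## Numerical choices and edge cases

* Sequences: non-standard residues map B→N, Z→Q, U→C, O→K; X and `*` map
  to the highest-scoring residue of the matching PSSM row when a profile
  is present, else alanine — always with a warning. Positions are 1-based
  everywhere.
* PSSM parsing autodetects the 40-column NCBI layout and a bare 20-column
  layout by field count; residue-column disagreements with the FASTA
  sequence warn with the first mismatching position.
* Duplicate samples give zero local scales; they are floored at $10^{-12}$
  with a warning.
* `lag_theta` requires $g < L$; `dcca_features` requires $L \ge S+1$;
  violations name the protein.
* The SMO intercept uses free support vectors when any exist, otherwise
  the midpoint of the KKT bounds.
* Degenerate MCC denominators yield 0; ROC classes absent from the truth
  are skipped with a warning.

## Known limitations

* Paper mode is reproduced faithfully, including its optimism; use strict
  mode for honest generalization estimates.
* Platt sigmoids are fitted on training decisions, not inner CV.
* The grid search's LOO scoring is exhaustive and exact but can be slow on
  large unstructured data (compiled warm-started solvers keep the default
  worlds to seconds).
* The synthetic generator emulates profile statistics, not evolution: no
  alignment depth variation, no gap structure, no phylogenetic
  correlation between proteins of one class.
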