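# apoloc

Predicts the subcellular compartment of apoptosis proteins from PSI-BLAST
position-specific scoring matrices (PSSMs). For bioinformaticians who have
per-protein PSSM profiles (the `-out_ascii_pssm` output of a PSI-BLAST
search) and a labeled training set, and want a reproducible
profile-feature + discriminant + SVM pipeline with honest evaluation
modes.

## Method

For a protein of length L with sigmoid-normalized profile
P (entries f(x) = 1/(1+e^-x) of the raw log-odds):

* **Pseudo-PSSM** (20 + 20ξ values, default ξ = 3 → 80): column means
  P̄_j = (1/L) Σᵢ P_ij plus lag terms
  θ_j^g = (1/(L−g)) Σᵢ (P_ij − P_(i+g)j)², g = 1..ξ.
* **DCCA coefficients** (190 values): for every pair of integrated
  columns, ρ = f²_xy(S) / √(f²_xx(S) f²_yy(S)), where f²(S) averages
  detrended covariances over all L−S overlapping windows of S+1 points,
  each window detrended by its own least-squares line (default S = 40).
* **LFDA**: local Fisher discriminant analysis — local-scaling affinities
  (K = 7), locality-weighted within/between scatter matrices, top-r
  generalized eigenvectors (default r = 10). Two protocols: `paper`
  (reduce the whole set once, the published order) and `strict`
  (leakage-free, refit per jackknife fold).
* **Classifier**: one-vs-one soft-margin RBF SVM (own SMO solver in
  compiled code), exhaustive power-of-two grid C ∈ 2⁻⁵..2¹⁵,
  γ ∈ 2⁻¹⁵..2⁵ scored by leave-one-out accuracy, jackknife evaluation,
  per-class Sens/Spec/MCC, overall accuracy (OA) and macro one-vs-rest
  AUC.

A synthetic PSSM generator with class-dependent column means, AR(1) row
correlation and inter-column correlation makes the whole pipeline testable
without any database search. See the methods vignette
(`vignettes/apoloc-methods.Rmd`) for the model details, parameter
rationale and the leakage discussion.

## Worked example

```r
library(apoloc)

# a labeled synthetic world: 3 compartments x 30 proteins, lengths 50-120,
# class column-mean shift delta = 6 raw-score units
d <- generate_dataset(synth_spec(seed = 1))

# defaults: xi = 3, S = 40, r = 10, K = 7, paper-mode LFDA, LOO grid search
report <- run_pipeline(pipeline_config(seed = 1), dataset = d)
#> extracting features for 90 proteins (xi = 3, S = 40)
#> fused feature width: 270 = (20 + 20*3) + 190
#> LFDA: 270 -> 10 dims (mode = paper, K = 7)
#> grid search: C = 2^-4, gamma = 2^-3, CV accuracy = 1.000
#> jackknife OA = 100.0%, macro AUC = 1.0000
report$OA      # 1 : every protein assigned to its true compartment
report$auc     # 1 : every class's scores rank perfectly
```

`report$per_class` holds per-compartment sensitivity, specificity and MCC;
`report$confusion` the c × c confusion matrix. With `delta = 0` (no class
signal) and `lfda_mode = "strict"`, the same pipeline stays at chance —
the green/red pattern the test suite asserts.

File-based inputs work the same way:

```r
run_pipeline(pipeline_config(),
             fasta = "proteins.fasta", labels = "labels.tsv",
             pssm_dir = "pssm/", out_dir = "results/")
```

writing `report.json`, `metrics.txt`, `features.csv`, `roc.csv`,
`confusion.csv`, `model.json` and `run.log`.

## Command line

```sh
apoloc synth --out data/ --classes 3 --per-class 30 --delta 6 --seed 1
apoloc run   --fasta data/proteins.fasta --labels data/labels.tsv \
             --pssm-dir data/pssm --xi 3 --S 40 --r 10 \
             --lfda-mode paper --seed 1 --out results/
apoloc sweep --param xi --values 0:10 --fasta ... --labels ... --pssm-dir ...
```

(the `apoloc` script is installed at
`system.file("cli", "apoloc", package = "apoloc")`).

## Scope

Running PSI-BLAST itself is out of scope: profiles are upstream inputs
(`psiblast -num_iterations 3 -evalue 0.001 -out_ascii_pssm ...` against
NR). The published benchmark accuracies on CL317/ZW225/ZD98 require those
NR-derived profiles and are therefore not reproduced by the test suite.
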