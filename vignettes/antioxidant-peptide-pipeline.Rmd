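---
title: "Predicting antioxidant peptides from sequence descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antioxidant peptides from sequence descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antioxpep)
```

## The problem

Antioxidant peptides (AOPs) are short amino-acid sequences that scavenge
radicals or inhibit lipid oxidation; screening candidates experimentally is
slow, so sequence-based classifiers are used to triage peptides before the
bench. `antioxpep` implements such a classifier as a pipeline of four
stages — descriptor encoding, descriptor fusion, split-count feature
selection, and a radial-kernel SVM — together with the evaluation harness
(seven metrics, stratified cross-validation, Friedman rank comparisons, 2-D
embeddings) needed to compare design choices, and a synthetic data
generator that makes every stage testable without any external dataset.

All sequences are over the 20 canonical residues and must have length
$L \ge 2$: the pair- and transition-based descriptors below are undefined
for single residues. Noncanonical residues (B, J, O, U, X, Z, gaps) reject
the record by default; `read_fasta(..., drop_invalid = TRUE)` (or the CLI
flag `--drop-invalid`) drops such records with a warning instead. No
maximum length is imposed. Benchmark corpora in this field are typically
de-duplicated with CD-HIT at a 90% similarity threshold before modeling;
redundancy filtering is out of scope here and assumed done upstream.

## The four descriptor encoders

**Averaged physicochemical properties (AAindex).** For property $j$ with
per-residue values $v_j(\cdot)$, the peptide is summarized by the mean
$F_j = \frac{1}{L}\sum_{i=1}^{L} v_j(r_i)$ over its residues $r_i$. One
dimension per property, in table order. The bundled table is the AAindex
release distributed with the seqinr project (release 9.1, 544 indices);
the current database release carries 566, so the encoder's dimension is
defined by the table, not hard-coded. A few raw entries are missing; they
are imputed with the mean of that property's available residue values and
flagged in `load_aaindex()$imputed`. Values are used raw by default
(`rescale = TRUE` enables per-property min–max scaling) because the
averaging formula operates on raw property values.

**Composition/transition/distribution (CTD).** Each of 13 physicochemical
attributes (seven hydrophobicity scales, normalized van der Waals volume,
polarity, polarizability, charge, secondary structure, solvent
accessibility — the standard three-group partitions used across the CTD
literature) splits the residues into groups 1–3. Per attribute the encoder
emits: composition $C_g = N_g/L$; transition
$T_{gh} = (N_{gh}+N_{hg})/(L-1)$ for the unordered group pairs; and
distribution — the normalized sequence positions of the first, 25%, 50%,
75% and last occurrence of each group (ceiling milestone indices; a group
absent from the sequence contributes zeros). Layout
$13 \times (3+3+15) = 273$. The distribution component follows the
conventional milestone-position formulation; a literal cumulative-share
variant ($N_{ik}/N_i$ within the first $k\%$ of positions) is retained
behind `d_variant = "cumulative"` for auditability, because that printed form
collapses to near-constant values and contradicts the descriptor
literature it cites.

**Adaptive skip dipeptide composition (ASDC).** Every ordered residue pair
$(r_i, r_j)$ with $i < j$ — all sequence separations, not just adjacency —
is counted and normalized by the total pair count $L(L-1)/2$, making the
400-vector a probability distribution (the natural denominator for a
quantity described as a pair probability). Pairs are laid out row-major in
alphabetical residue order.

**Frequency-weighted BLOSUM62 profiles.** The published BLOSUM62
substitution matrix (consumed as-is; its log-odds derivation is not
recomputed) is extended with an all-zero 21st column, and each residue's
21-entry row is scaled by that residue's relative frequency in the
peptide: $20 \times 21 = 420$ dimensions regardless of peptide length.
This per-residue-frequency weighting is the one reading of
"frequency-weighted substitution features" that produces a fixed
dimension for variable-length peptides; absent residues contribute
all-zero blocks.

Fusions concatenate member blocks in the fixed canonical order (aaindex,
asdc, blosum62, ctd) regardless of how the user orders them, so feature
indices are stable across runs. Four encoders give $2^4 - 1 = 15$
combinations, 11 of which are true fusions; the deployed default is
ctd + blosum62 (273 + 420 = 693 dimensions).

## Feature selection

`rank_features()` trains a gradient-boosted tree ensemble (binary
logistic objective, 100 trees, single thread, fixed seed — recorded in the
result) and scores each feature by its *split count*: the number of
internal nodes, across all trees, that split on it. Ties are broken by
original feature index, so rankings are deterministic. Constant features
are never split on and rank last with importance 0. The ensemble
hyperparameters are library defaults; the ranking is a screening device,
not a tuned model.

`sweep_topk()` evaluates nested top-$k$ subsets ($k = 5, 10, \dots, 300$
by convention, 60 candidates) and picks the $k$ maximizing accuracy, with
MCC as tie-break and the smallest $k$ (parsimony) as final tie-break. Two
protocols are provided: the default scores each $k$ by stratified 5-fold
cross-validation on the training set, so selection never touches held-out
data; `mode = "holdout"` scores on a supplied evaluation set instead,
reproducing the common (but leakage-prone) practice of sweeping directly
against an independent test set. The optimal $k$ is data-dependent — on
the generator's default conditions it lands anywhere between ~10 and ~110
across seeds with essentially equal accuracy, which is why the package
treats $k$ as an output, not a constant.

## Classifiers

Six shallow families are available behind one interface
(`train_classifier()`): the radial-kernel SVM (the deployed model family),
gradient-boosted trees (`"gbdt"`), ridge-penalized logistic regression
(`"lr"`, glmnet with $\alpha = 0$ and a small fixed $\lambda = 0.01$ —
penalized rather than plain maximum likelihood so fits remain defined when
features outnumber samples), random forest, $k$-nearest neighbours
($k = 5$, a documented choice), and Gaussian naive Bayes (features with
zero within-class variance are excluded from this learner, as their
Gaussian likelihood is degenerate). The final SVM uses the tuned constants
`C = 2.782559402207126`, `gamma = 0.005994842503189409` exposed by
`final_svm_params()`. Features are fed to the classifiers as encoded — all
encoders emit bounded values by construction — with an optional
standardization switch (off by default) that stores training-set
statistics in the model.

Prediction returns a 0/1 label and a real-valued score: the signed
decision value for the SVM (AUC is computed from this margin, not from
calibrated probabilities), the native class-1 probability for the other
learners. The label always equals thresholding the score (0 for margins,
0.5 for probabilities).

## Evaluation

`compute_metrics()` implements ACC, Sn, Sp, Pre, F1, the Matthews
correlation coefficient in its standard form
$\mathrm{MCC} = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}$,
and a rank-based AUC (Mann–Whitney formulation, ties counted half).
Zero-denominator policy, applied prominently rather than silently: Sn, Sp,
Pre and F1 report 0 with a warning when undefined; MCC reports 0 whenever
a confusion-matrix marginal is 0. `mean_score()` averages the six
comparison metrics (ACC, MCC, Sn, Sp, AUC, Pre) used to rank grid cells.

`friedman_test()` ranks treatments within each block (average ranks on
ties) and computes
$\chi^2_F = \frac{12}{Nk(k+1)}\sum_j R_j^2 - 3N(k+1)$ with $k-1$ degrees
of freedom; a tie-corrected statistic (dividing by
$1 - \sum(t^3-t)/(Nk(k^2-1))$) is reported alongside, and the two coincide
on tie-free data. `grid_friedman()` builds the score matrix from a
`model_grid()` result with the six metrics as blocks by default; block
construction is a parameter because other pairings are equally defensible.

`embed_2d()` provides deterministic 2-D projections (PCA, or classical
metric MDS) for qualitative inspection of class separation; stochastic
neighbour-embedding methods (e.g. UMAP) are not implemented, so published
neighbour-embedding figures are approximated only in spirit. The
embeddings are checked for shape, determinism and positive class
silhouette, nothing more — they are a diagnostic, not an inference tool.

## The synthetic generator and what it does (not) show

`generate_dataset()` draws negatives with uniform residue frequencies and
positives with each residue of an enriched set (default W, Y, C, H, M —
aromatic/sulfur/imidazole side chains typical of radical scavengers) at
`enrichment` times its $1/20$ background frequency, remaining mass spread
over the other residues. This makes `enrichment` a literal multiplicative
frequency bias: `enrichment = 1` is an exact null (classes exchangeable),
and the feasibility bound `enrichment <= 20 / |set|` means the default
set at `enrichment = 4` yields positives composed of enriched residues
only — separable by construction, which is the intended calibration for
end-to-end recovery tests. Lengths are uniform on 2–50 by default,
matching typical short bioactive peptides. `mode = "motif"` additionally
plants a fixed subsequence (default `"WYCH"`) at a random position of
every positive, giving pair- and transition-sensitive descriptors a
localized signal that pure composition bias cannot provide; the planted
motif's six ordered skip-pairs are the ground-truth informative ASDC
features in selection tests.

The generator emulates composition bias and localized motifs only. It does
not emulate real AOP length distributions, positional composition
gradients, homology structure between records (no CD-HIT-style redundancy),
or label noise. Tests passing on generated data therefore demonstrate that
the pipeline recovers signal it was designed to represent — they say
nothing about accuracy on curated benchmark corpora, which requires the
external datasets.

## Numerical and design notes

* Minimum length 2 is enforced globally ($T$ divides by $L-1$; ASDC needs
  one pair). Lowercase input is uppercased per FASTA convention.
* Milestone indices in the CTD distribution use `ceiling(q * N_g)` with
  the 0% milestone meaning the first occurrence; ties are impossible by
  construction.
* Splits are stratified with floor rounding of the per-class test share
  (a balanced 3022-record corpus at 8:2 yields exactly 604 test records);
  a `1e-9` guard protects the floor against binary representation of the
  fraction.
* All stochastic steps (generation, splitting, fold assignment, ensemble
  training) are seeded and restore the RNG state afterwards; repeated
  runs at a fixed seed produce byte-identical feature tables, rankings
  and predictions.
* Model bundles persist as a directory of human-readable `metadata.json`
  (algorithm, hyperparameters, encoder set, selected features, seeds,
  resource checksums) plus opaque fitted state; loading verifies the
  bundled lookup tables' checksums against the model's.
* Test problem sizes: unit and property tests use tens of records;
  end-to-end checks use 1000 generated records with 693 fused dimensions
  and the null control 500 records, sizes at which the full suite runs in
  about a minute on one CPU.

## Known limitations

* The bundled AAindex table has 544 properties (seqinr's release 9.1);
  pipelines exchanging AAindex features with tools built on the 566-index
  release are not dimension-compatible for that single block.
* Chance-level bands for null controls (CV accuracy $0.5 \pm 0.06$ at
  $n = 500$) assume exchangeable features; shuffling labels of strongly
  clustered data inflates cross-validation variance beyond such bands for
  any classifier.
* The six baseline learners run with library defaults (plus the fixed
  final-SVM constants); no hyperparameter search is included.
* The CLI covers single-machine workflows; there is no service interface.
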