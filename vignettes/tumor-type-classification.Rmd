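---
title: "Classifying tumor types from somatic mutation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tumor types from somatic mutation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumortracer)
```

## The problem

When a tumor is discovered at a metastatic site, or tumor DNA is detected in
a liquid biopsy, the tissue of origin may be unknown. Somatic mutation
catalogs carry two very different kinds of signal about that origin:

* **Driver mutations** — positively selected hits in oncogenes and tumor
  suppressors — are biologically interpretable but shared across many
  cancer types, so they identify the tissue only weakly.
* **Passenger mutations** — the neutral majority — record, in bulk, both
  the mutational processes the cell was exposed to and the chromatin
  organization of the cell of origin, because mutation rates along the
  genome track replication timing and accessibility in the source tissue.

`tumortracer` implements both feature families and the machinery to compare
them: regional mutation density (RMD) over megabase windows, the 96-channel
trinucleotide mutation spectrum (MS96), binary driver features (OGM), a
one-vs-rest SVM/random-forest classifier stack, a full evaluation harness
(ROC/AUC, precision–recall/AUPRC, recall at fixed precision,
complementarity, feature-importance consensus), perturbation tools, and a
synthetic cohort generator so that the whole pipeline is testable without
access to restricted patient-level data.

## Feature definitions

### Regional mutation density (RMD)

Autosomes are tiled into 1 Mb windows (0-based half-open coordinates; the
short terminal window of each chromosome is kept rather than merged — its
reduced length is handled by the alignability normalization, and the choice
is recorded in the output metadata). Sex chromosomes are excluded. A
mappability mask defines the alignable bases of each window; windows with
fewer than 100 kb alignable (whole genomes) or fewer than 10 kb of capture
overlap (exomes) are discarded. Windows exactly at the threshold are kept —
only strictly smaller ones are discarded. On a reference grid with a
perfect-mappability track this filtering yields the familiar
~2,650-window autosomal feature space; at desk scale the same rule runs on
synthetic grids.

For one tumor, mutations falling in the coding regions (±5 nt) of driver
genes are removed, remaining SNVs and indels are counted per retained
window, each count is divided by the window's alignable megabases, and the
densities are divided by their mean over retained windows. Two details are
deliberate:

* **Normalization order.** The per-tumor normalizer is the mean of per-Mb
  *densities*, not of raw counts. This makes every RMD vector have mean
  exactly 1 and renders it invariant to uniform changes in mutation burden;
  the alternative (mean of raw counts) would leave a residual dependence on
  the alignable-length profile. The choice is recorded in output metadata.
* **Window assignment.** A mutation belongs to the window containing its
  start position; an indel spanning a window boundary therefore goes to the
  window of its start (tie-break, logged).

Samples with zero usable mutations receive an all-zero vector plus a
quality flag, and a configurable minimum-mutation threshold (default 50)
marks low-content samples so they can be excluded from training.

Two reduced RMD representations are provided: `reduce_kmedoids()` keeps the
k medoid windows of a partitioning-around-medoids clustering under the
dissimilarity 1 − Pearson correlation between window columns (500 medoids
at full scale), and `reduce_pca()` projects onto the leading principal
components (100 at full scale). `pam` on a fixed dissimilarity matrix is
deterministic, so no seeding is required; correlation dissimilarity is used
because the purpose of the reduction is removing correlated windows.

### Trinucleotide spectrum (MS96)

Each SNV is classified by its substitution type read strand-symmetrically
— C>G, C>T, C>A, A>T, A>G, A>C, i.e. reference bases C and A — and its 5′
and 3′ neighbors, giving 96 channels; contexts with a G or T reference are
reverse-complemented first. Note this differs from the COSMIC pyrimidine
(C/T) convention; `ms96_to_cosmic()` converts for interoperability.
Driver-gene mutations are excluded using the same coding-exon ±5 nt
intervals as the RMD exclusion (the gene-body alternative is not used, so
both passenger features see the same exclusion set). Spectra are relative
frequencies; indels carry no channel. When contexts are extracted from a
reference FASTA, the reference base must match the record's ref allele;
mismatches are skipped and counted.

### Driver features (OGM)

Three concatenated blocks, in gene → pathway → hotspot order: a binary bit
per driver gene (any SNV/indel in coding exons ±5 nt), a bit per pathway
(OR over member genes), and a bit per recurrent hotspot (11-bp window,
center ±5 nt). Hotspot discovery itself (the "≥100 recurrences" rule
against a mutation database) is an offline preparation step; the pipeline
consumes prepared hotspot coordinates. Optional impact refinement accepts
per-variant scores: a strict `> threshold` filter before bit computation,
or score weighting where each indicator is replaced by the maximum score of
its supporting variants.

## Classification

One binary model per class against the pooled rest. Features are
standardized per feature (z-score fit on the training portion only —
RBF kernels effectively require it; recorded in model metadata). Class
imbalance is handled by the balanced weight formula `w_c = n / (K n_c)`
applied to the binary one-vs-rest labels. The SVM's C and gamma are chosen
by an inner stratified cross-validation maximizing class-weighted accuracy
over an exponential grid (defaults `C = 2^{-5..15}`, `gamma = 2^{-15..3}`,
inner 3-fold — all configurable; the exact grid is a documented default,
not a published protocol). The random forest trains 500 trees with no
tuning. Per-class decision scores (signed hyperplane distance, or tree vote
fraction) are used directly for ranking metrics — no probability
calibration, since AUC and AUPRC are rank-based. Multiclass assignment is
the argmax over per-class scores with exact ties broken alphabetically
(logged, fixed order); "correctly classified" in the confusion matrix and
complementarity partition means argmax equals truth.

`crossvalidate()` runs repeated stratified k-fold cross-validation
(defaults 5-fold × 10 runs); within each fold the full training pipeline —
scaling, grid search, optional in-fold elastic-net feature selection — sees
only the training portion, which the test suite verifies with a leakage
check. Per-run metrics pool held-out scores across folds.

## Evaluation

AUC is computed from the rank statistic (ties counted one half), identical
to Mann–Whitney pair counting — the suite checks this equivalence against a
brute-force pair counter and against an independent library
implementation. Precision–recall curves have one point per distinct score
threshold and the area uses **step-wise interpolation** (sum of recall
increments × precision), the conservative convention; linear interpolation
would report systematically higher areas, which is why the convention is
stated. Recall at precision 0.8 (20% FDR) is the maximum recall over
thresholds whose precision reaches the level, 0 if none does. Undefined
precision (a class never predicted) is reported as 0 with a flag.
Recall gains between nested feature sets are reported in percentage points
— the extra fraction of patients correctly classified at the same FDR.

Feature importance combines four rankings: elastic-net coefficient
magnitude, random-forest Gini importance, Relief-F, and information gain;
the consensus set is the features in the top 25 of two or more methods.
Relief-F uses k = 10 nearest hits/misses on z-scored features and
information gain discretizes into 10 equal-frequency bins — both
conventional defaults, both configurable.

## The synthetic cohort generator

Real tumor whole-genome cohorts are access-restricted, so the package
ships a generator that reproduces the statistical structure the analysis
assumes, with one `class_profile` per cancer type:

* **Burden**: per-sample passenger count drawn log-normal. Observed
  per-sample mutation counts in tumor cohorts are strongly right-skewed
  over several orders of magnitude, which the log-normal captures with two
  parameters; the family is this package's choice, not an established
  property of any particular cohort. Defaults `meanlog = log(3000)`,
  `sdlog = 0.4` give a few thousand mutations per genome.
* **Placement**: passengers fall into retained windows with probability ∝
  window intensity × alignable length, uniformly within the window. Each
  class's intensity landscape is an independent log-normal draw per window
  (`sdlog` 0.6), normalized to mean 1.
* **Spectrum**: each SNV draws one of the 96 channels from a class-specific
  sparse Dirichlet mixture (concentration 0.5); the context string is
  stored on the record so no reference FASTA is needed at desk scale (the
  real-data path extracts contexts from FASTA).
* **Indels**: a fraction (default 0.1) are emitted as 1-bp deletions with
  no spectrum channel, placed by the same window law.
* **Drivers**: independently of the passenger count, each driver gene is
  hit with a class-specific probability (background 0.05, three marker
  genes per class at 0.6), placed inside its coding interval. Driver
  mutations are additional to the passenger burden — they are excluded from
  passenger features anyway.

Per-sample seeds derive from the master seed by a stated counter scheme
(`derive_seed()`), so cohorts regenerate byte-for-byte, including under
parallel generation. The default study cohort used throughout the tests is
4 classes × 50 samples on a 4-chromosome × 25-window toy genome with
alignable fractions in (0.6, 1).

What the generator does **not** emulate: real mutational-signature
catalogs, real chromatin-derived RMD landscapes, inter-sample heterogeneity
within a class beyond Poisson/multinomial noise, subclonal structure, or
calling artifacts. Passing tests therefore demonstrate that the pipeline
recovers planted structure under its own assumptions — parameter recovery,
chance-level behavior under label permutation, monotone degradation under
dropout — not that any particular accuracy carries over to real cohorts,
whose headline numbers require the restricted data.

## Perturbation experiments

`simulate_wes()` intersects catalogs with capture intervals (optionally
with per-interval retention probabilities emulating uneven coverage; a
read-level coverage model is out of scope). Under exome mode, windows are
re-filtered at the 10 kb capture-coverage threshold. `dropout()` removes
mutations independently at a given rate, emulating false-negative calls;
it is applied to the raw catalog before any featurization, matching the
interpretation of removing mutations at random from the call set.
`degradation_experiment()` re-featurizes and re-cross-validates at each
rate with the same CV seed, so the rate-0 row reproduces the unperturbed
run exactly.

## Problem sizes and numerical choices

The packaged examples and tests run at desk scale: 100-window toy genomes,
cohorts of 48–200 samples, a reduced SVM grid (`C ∈ {1, 10}`,
`gamma ∈ {0.01, 0.1}`, inner 2-fold), 2–10 CV runs, and a dropout grid of
{0, 0.5, 0.75, 0.95}; these sizes keep the whole suite in the minutes
range while leaving every code path identical to a full-scale run, where
the published-scale settings (full LibSVM grids, 500 medoids, 100 PCs,
5-fold × 10 runs) are the defaults. The label-randomization control uses
ten independent permutation runs — independent permutations average out
the chance label–feature correlation that any single permutation retains.
Other conventions: windows at the retention threshold are kept; grid-search
ties take the first grid point; constant features get unit scale in the
z-score; PCA errors on all-constant input naming the offending columns;
zero-mutation samples yield flagged all-zero vectors rather than errors.

## Known limitations

* Copy-number features, pathway re-scoring against mutation-burden
  covariates, and per-variant impact-score computation are out of scope
  (impact scores are accepted as an input column only).
* The exome simulation is interval intersection plus optional thinning,
  not a coverage-model simulation.
* One assembly per run; no liftover.
* The generator's classes are exchangeable by construction; experiments
  about batch effects between sequencing centers can be emulated only
  coarsely through `dataset_tag`-based external splits.
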