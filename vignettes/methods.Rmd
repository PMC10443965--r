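---
title: "Methods: models, parameters and design choices in mirDevScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mirDevScreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, every tunable parameter that matters, the
numerical choices, what the synthetic generator does and does not emulate,
and the decisions we made where the design was genuinely open.

## Study design and data model

The pipeline analyses a paired-organ developmental time course: two organs
(generically `A` and `B`; in an auditory study these would be the cochlear
sensory epithelium and the superior olivary complex), three ordered
timepoints (`T0` the embryonic baseline, then `T1`, `T2`), and replicated
samples in each of the six (organ, timepoint) conditions.  Counts live in a
`DevCounts` object (a `SummarizedExperiment` subclass) whose validity
enforces unique feature ids, integer non-negative counts, exactly two organ
levels, three ordered timepoint levels and unique
(organ, timepoint, replicate) triples.  At least two replicates per
condition are required for differential expression.

## CPM, detection, and condition profiles

Counts are scaled to counts-per-million within each sample
(`cpmTransform`).  Detection (`detectionFilter`) retains a feature iff it
exceeds a CPM threshold *strictly* in at least `minReplicates` replicates
of at least one condition.  Defaults: 0.5 CPM in 3 replicates for mRNA,
1 CPM in 2 replicates for miRNA.  Two readings were open here:

* *Boundary*: "over X CPM" is read as a strict inequality; a feature at
  exactly the threshold in every sample is dropped.  The boundary case is
  tested explicitly.
* *Replicate pooling*: the replicate count is evaluated within a single
  (organ, timepoint) condition, not pooled across timepoints, for both
  feature kinds; the mRNA and miRNA rules then differ only in their
  thresholds.

`conditionProfiles` averages CPM over replicates per condition and
standardizes each feature's profile of `log2(mean CPM + 1)` values to mean
0 and *population* SD 1 (divisor n — a fixed convention, asserted by the
class validity).  The log scale is the conventional one for
expression-profile clustering: on the raw CPM scale the highest-expression
conditions dominate every distance and correlation, and multiplicative
(fold-change) structure — which is what the planted archetypes and any
biological program are — only becomes additive, hence shape-comparable,
after the log.  The `+1` pseudocount keeps zero means finite and slightly
compresses features below ~1 CPM; such features are near the detection
floor anyway.  Zero-variance (flat) features cannot be standardized; they
are flagged and excluded from standardized output rather than silently
coerced.

PCA QC runs on centred, unscaled `log2(CPM + 1)` of the 500 most variable
features.  The reference workflow's PCA uses a variance-stabilizing
transform of the top-500 features; log-CPM is the closest
annotation-free stand-in and this deviation is deliberate and documented.
On simulated data PC1 separates the organs and explains roughly 60% of the
variance, mirroring the organ-dominant structure expected of such designs.

## Differential expression

Each later timepoint is tested against the `T0` baseline within each organ
(four contrasts).  The model is the standard RNA-seq negative binomial
with mean μ and variance μ + αμ²:

* **Size factors** by median-of-ratios over features with all-positive
  counts, computed once from the full matrix.
* **Dispersion** α per feature by method of moments on normalized counts,
  pooling replicate residuals over all six conditions (12 residual degrees
  of freedom at 3 replicates), floored at 1e-8.  There is no trend or
  shrinkage across features, no LFC shrinkage, no independent filtering
  and no outlier handling — the full DESeq2 machinery is intentionally not
  reproduced, because the downstream DEG definition acts only on
  (p, fold change, consistency) and a plain NB Wald test keeps that
  contract simulation-testable.
* **Group means** by maximum likelihood with size-factor offsets, fitted
  by a damped Newton iteration on log μ (step clamp ±3, 50 iterations,
  convergence 1e-10, mean floor 1e-3 so an all-zero group yields a finite,
  appropriately uncertain estimate).
* **Wald test** of log2FC = 0, two-sided.  The statistic is referred to a
  t distribution with the dispersion estimate's residual degrees of
  freedom (samples − conditions, i.e. 12 by default) rather than a normal:
  with per-feature dispersions from few replicates the normal reference is
  visibly anti-conservative (~9% of null p-values below 0.05 in our null
  simulations), while the t reference restores ~5–6%.  Features with
  all-zero counts get `NA` and are excluded from the multiple-testing
  burden.

Benjamini–Hochberg adjustment is applied across features within each
contrast (`bhAdjust`, a thin wrapper over `stats::p.adjust` with the NA
pass-through semantics made explicit; an independent O(m²) step-up
reference implementation in the test suite guards the wrapper).

A feature is a DEG when it passes **three criteria simultaneously**
(`deCall`): FDR below α (mRNA 0.01, miRNA 0.05), |log2FC| above
log2(fcMin) (mRNA 2.5, miRNA 1.5), and *direction consistency* — every
later-timepoint replicate deviates from the baseline-condition mean CPM in
the same direction.  Replicates are unpaired across litters, so
consistency compares each later replicate with the baseline *mean* (the
only well-defined unpaired reading); a replicate exactly equal to that
mean has no direction and fails the feature.  The fold change used for
thresholding is the NB-estimated log2FC, keeping a single source of truth
with the test.  A feature DE in several contrasts with conflicting
directions is assigned the direction of the largest |log2FC| and flagged
`conflicted`.  The field's miRNA convention states the call as "criteria
met at either later timepoint"; we call each contrast separately for both
feature kinds and use the any-contrast union for cluster membership, which
subsumes that rule.

## Clustering of DEG profiles

DEGs of each direction are partitioned by k-means on the standardized
profiles (Euclidean distance, which on standardized rows is a monotone
transform of correlation distance), with k scanned over 2–12, 10 seeded
restarts per k, and k chosen by maximal mean silhouette width.  Two
post-passes reproduce the observable contract of homogeneity-driven
clustering tools such as CLICK/EXPANDER (whose graph-theoretic algorithm
we deliberately do not reimplement — membership and mean profiles are all
the downstream stages consume): members whose Pearson r
with their cluster mean falls below `homogeneity` (default 0.7, the
conventional homogeneity level; exposed as a parameter) are moved to
`UNASSIGNED`, and clusters smaller than `minClusterSize` (default 20) are
dissolved.  Everything is deterministic given the seed, and invariant to
feature order up to cluster relabelling.

Cluster labels are rule-based on the cluster's mean standardized profile:
per organ the three-point trajectory is `transient` if the middle
timepoint exceeds both ends by more than `transientTol` (1.0 standardized
units), monotone `up`/`down` if the end-to-end span exceeds `flatTol`
(0.5), else `flat`.  Combinations yield `shared-*`, `<organ>-specific-*`,
`transient-<organ>`, `divergent` or `unlabeled`; shared programs gain a
`-high-<organ>` qualifier when the organs' mean log2 CPM levels differ by
more than 1 (i.e. a twofold absolute-level difference).  The tolerances
were chosen once so that the six default archetypes land in distinct label
classes, and are parameters of `labelClusters`.

## Enrichment and the regulator screen

`hypergeomTail(k, K, n, N)` is the exact upper tail P(X ≥ k) of the
hypergeometric distribution (delegated to `stats::phyper`, which computes
in log space; p-values of 1e-12 and below are exact, as verified against
brute-force enumeration for every configuration with N ≤ 12).  The
enrichment factor EF = (k/n)/(K/N) accompanies every test.  Per
invocation, BH adjustment runs across the whole (cluster × set) batch, and
raw p-values are reported alongside because the screen's published
threshold convention ("p < 0.01") is a raw-tail cut.

The **universe** for enrichment is, by default, the detection-filtered
feature set of the matching kind — "detected in this dataset" is the
background a practitioner would reach for; an annotated-only universe
(genes present in the target map) can be passed instead, since both are
defensible and the choice is the caller's.

`screenRegulators` considers each differentially expressed miRNA against
each DEG cluster: targets-in-cluster enrichment (raw p), and Pearson
anti-correlation r between the miRNA's standardized 6-condition profile
and the mean standardized profile of its predicted targets *inside that
cluster*.  Correlation is computed jointly over all six conditions (one r
per miRNA-cluster pair, both organs on one axis) and on the standardized
scale, for scale invariance; both choices were open and are fixed here.
At least `minTargets` (default 5) usable targets are required before r is
computed — correlations from one or two targets are noise — and the floor
is exposed as a flag.  A candidate passes iff p < 0.01 *and* r < −0.4,
both strict.  The full table, including failing pairs, is emitted for
transparency.  Only DE miRNAs enter the screen, mirroring the workflow
that clusters DE miRNAs before integration.

## The synthetic generator

`simulateDataset` emulates exactly the statistical structure the analysis
assumes, and is itself first-class, tested code:

* **Design**: 2 organs × 3 timepoints × 3 replicates (the study-design
  convention of 3–4 independent samples per condition).
* **Archetypes**: six default mean-profile shapes (shared repression with
  equal or organ-biased levels, shared induction, organ-specific
  induction, transient induction) with log2 amplitudes of 3 — comfortably
  above the 2.5-fold DEG threshold, as developmental programs typically
  are — each planted in 150 genes of 2,000; the rest are flat.  Baseline
  abundances are log-normal (planted genes around 22 CPM, flat genes with
  a wider spread), exercising the detection filter's low end.
* **Counts**: NB with dispersion α = 0.1 (a typical bulk RNA-seq value)
  and log-normal library sizes (sdlog 0.3) around 5e6 (mRNA) and 1e6
  (miRNA) reads.  α = 0 gives Poisson noise; α = 0 together with fixed
  library sizes is the fully deterministic noise-free limit (counts are
  then the rounded expected means), used by the separable-limit tests.
  The dispersion and depths are conventions, not values taken from any
  particular dataset.
* **Compositional balance**: CPM is a relative measure, so planted
  programs would otherwise distort every feature's CPM profile through
  the per-condition total.  The generator rebalances each condition's
  total relative abundance through the flat features, so planted features
  show their archetype shape exactly on the CPM scale while flat features
  absorb a small common factor.  This is a deliberate idealization: in
  real data, compositional shifts are confounded with the biology and are
  *not* corrected by CPM — one reason passing tests here do not certify
  performance on strongly composition-shifted real libraries.
* **Regulators**: each of 6 planted regulator miRNAs carries the
  sign-flipped standardized profile of its coupled archetype, scaled by
  `couplingStrength` (default 1.5 log2 units) plus mild profile noise
  (SD 0.15); its true targets are 100 genes of that archetype.  Setting
  the coupling to 0 severs the relationship (the null used in the
  screen's false-positive tests); a negative coupling plants positively
  correlated "regulators", which the screen's sign logic must reject.
  A fifth of the non-regulator miRNAs carry a random archetype profile and
  act as differentially expressed distractors.
* **Target map**: true targets plus 50 per-miRNA decoys drawn uniformly
  without replacement from non-target genes, emulating target-prediction
  false positives without structure.  A synthetic "deafness-like" gene set
  (25 genes from the organ-biased shared-repression archetype plus 15
  random genes) exercises gene-set enrichment.
* **Reproducibility**: one RNG substream per output, derived from the
  master seed at fixed offsets, so e.g. enlarging the miRNA panel never
  perturbs the mRNA draws; a fixed seed reproduces every file
  byte-identically.

What the generator does **not** emulate: read-level artefacts (GC bias,
mapping multi-hits), batch effects, litter structure, isoform-level
competition, miRNA biogenesis, seed-type-dependent target efficacy, or
cell-composition drift within organs.  Recovery results on synthetic data
are therefore statements about the pipeline's statistical correctness
under its own model, not about biological sensitivity on any real tissue.

## Problem sizes used by the test suite

The shipped tests run the full generator defaults (2,000 genes, 300
miRNAs) where a property is stated at default scale — null calibration,
DE power, cluster recovery (adjusted Rand index ≥ 0.9 against the planted
partition) and screen recall each over 20 seeds — and a reduced
configuration (400 genes, 60 miRNAs) for fast unit tests of the module
surfaces.  These sizes keep the whole suite at a few minutes while leaving
every Monte-Carlo criterion with enough replication to be meaningful.

## Known limitations

* The NB Wald test with per-feature moment dispersions is slightly
  anti-conservative (~5.8% of null p-values below 0.05 in our
  simulations) even with the t reference; tools with cross-feature
  dispersion shrinkage will differ, and a pluggable backend can substitute
  one — the native test remains the reference implementation.
* P-values are not exactly invariant to a global rescaling of counts (the
  Poisson component of the information scales with depth); log2FC
  estimates are.
* k-means with silhouette selection can merge archetypes whose
  standardized shapes correlate strongly; the homogeneity post-pass then
  leaves their members unassigned rather than mislabelling them.
* Labels are heuristics over cluster means; clusters mixing shapes get
  `unlabeled`/`divergent` rather than a forced call.
* The screen's r is computed on six condition means; with so few points,
  |r| thresholds are coarse and `minTargets` guards only the target side.
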