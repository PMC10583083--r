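---
title: "Methods: pairwise signatures, core modules, and pathway activity in coresig"
author: "coresig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise signatures, core modules, and pathway activity in coresig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresig)
```

## The scientific problem

Skin-resident CD141+ dermal dendritic cells (DDCs) are a naturally
occurring regulatory antigen-presenting population, and vitamin-D3
treatment of monocyte-derived dendritic cells (moDCs) induces a
CD141-high fraction with a similar tolerogenic phenotype.  `coresig`
implements the discovery arm of that comparison as a reusable,
testable pipeline: if the two populations share a regulatory program,
it should surface as a *core module* of genes differential in the same
direction in two independent pairwise contrasts —

* contrast 1: CD141+ DDC versus CD1c+ DDC (skin),
* contrast 2: CD141hi VitD3 moDC versus untreated moDC (blood),

— and as gene sets ("pathways") whose aggregate activity separates the
two CD141+ populations from the rest.  The package covers the whole
chain: filtering, per-gene testing, signature calling, directional
intersection, bidirectional clustering, pathway activity scoring,
reference-anchored subset Z-scores, SVM pathway ranking, a local
over-representation test, and the ΔΔCt arithmetic used for qPCR
validation of candidate genes such as *UCN2*.

## Models and procedures

### Gene filtering

Genes that are not expressed, or barely vary, carry no usable signal
and inflate the multiple-testing burden.  Two filters run in sequence:

* **Unexpressed**: keep genes with at least `min_samples_above = 2`
  samples strictly above an intensity floor.  The default floor is the
  5th percentile of the whole log2 matrix plus 0.5 — a data-driven
  stand-in for the chip background, since no fixed platform constant
  generalises across arrays.
* **Low variability**: remove genes whose (n−1)-denominator variance
  falls strictly below the empirical `variance_quantile = 0.10` of all
  gene variances.  Zero-variance genes are always removed — downstream
  z-scoring is undefined for them.

Both thresholds are recorded in a `filter_report`.  Note that the
quantile is resolved to an absolute cutoff on the *input* matrix;
idempotence ("filtering twice changes nothing") holds when the filter
is re-applied with the resolved cutoff, not with the quantile, whose
reference distribution shrinks after the first pass.  Every count and
threshold is echoed into the run manifest because signature sizes are
acutely sensitive to them.

### Differential expression and signatures

Per gene, a two-sided two-sample t-test compares the two populations
of a contrast.  The default is the classic pooled-variance test;
Welch's form is available by flag.  Fold change is computed on
anti-logged group means, `fch = 2^(mean_log2_A − mean_log2_B)` — the
ratio of geometric means, which is the natural multiplicative reading
of log2 microarray data.  A gene enters the signature when

> p < 0.05 **and** max(fch, 1/fch) > 1.5,

both gates strict.  No multiple-testing correction is applied by
default, matching the raw-p convention of the original workflow;
Benjamini–Hochberg gating is available as an explicit opt-in and the
package reports it separately.  Genes flat in both groups are flagged
and can never be called.

### Core module

The core module is the direction-consistent intersection:
`(upA ∩ upB) ∪ (downA ∩ downB)`.  Genes differential in both
contrasts with *opposite* directions are biologically interesting but
are a different phenomenon; they are returned in a separate
`discordant` slot, never in the core.

### Bidirectional clustering

The core-module submatrix is clustered on both axes with
1 − Pearson correlation distance and average linkage (the standard
expression-heatmap convention; metric and linkage are configurable).
Rows are z-scored per gene before sample-axis distances so that highly
expressed genes do not dominate the sample tree.  `hierarchical_cluster()`
delegates the agglomeration to `stats::hclust`; the test suite checks
its merge heights against a naive O(n³) agglomerator that recomputes
cluster distances from the raw pairwise matrix at every step.  Tie
handling therefore follows `hclust`'s deterministic rule; with
continuous expression data exact ties have probability zero.

### Pathway activity and subset Z-scores

Expression values are z-transformed per gene across **all** samples
jointly (a single samples × genes matrix is the declared input; no
per-contrast re-standardisation).  For a pathway with k member genes
matched in the matrix, the activity in sample j is

\[ a_j = \frac{\sum_{g \in P} z_{gj}}{\sqrt{k}} , \]

the combined z-score with √k as denominator to stabilise the variance
of the mean: under independence a_j has unit variance regardless of
pathway size, so large and small sets are comparable.  Pathways
matching fewer than `min_genes = 5` genes are dropped and logged; k
always counts *matched* genes only.

The population-level table anchors every pathway to a reference
subset (CD141+ DDC by default): activities are standardised by the
reference samples' mean and SD, then averaged within each population.
This construction makes the interpretation literal: the reference row
is identically 0, a population with |Z| near 0 behaves like the
reference for that pathway, and a large |Z| marks strong divergence.
The exact subset-level standardisation is an interpretation committed
to by this package (the verbal description it implements does not pin
down the arithmetic); it was chosen precisely because it makes the
"close to 0 ⇒ similar to reference" reading exact.  One consequence
worth internalising: a pathway coherently shifted in *both* the
reference and a second population scores near 0 for that population —
similarity, the signal of interest — and scores extreme |Z| in the
populations that *lack* the shift.

### SVM pathway ranking

The pathway × sample activity matrix becomes the feature matrix of a
linear soft-margin SVM (libsvm via `e1071`), fitted one-vs-rest: one
binary machine per population, regularisation constant `cost = 1`,
features standardised internally.  Each pathway's discrimination
score is the sum over classes of its squared primal weight; ranking is
by descending score with lexicographic tie-break, deterministic given
the seed.  The formulation (one-vs-rest, squared-weight aggregation,
C = 1) is a package decision — the underlying method description names
only "an SVM classifier ranking pathways".  A label-permutation
control is part of the acceptance suite: with shuffled population
labels the planted pathway's rank collapses to the middle of the
field.

### Over-representation

As a local, reproducible stand-in for web-service enrichment tools,
`overrepresentation()` computes the upper hypergeometric tail
P(X ≥ overlap) per set against a stated gene universe, with
Benjamini–Hochberg q-values across sets.  It deliberately does not
reproduce any web service's EASE-style variants.

### ΔΔCt quantification

`delta_ct()` normalises each target to the housekeeping gene
(GAPDH by default): ΔCt = Ct_target − Ct_GAPDH.  `ddct_fold_change()`
anchors to a reference condition, ΔΔCt = ΔCt − mean(ΔCt_ref), and
reports fold = 2^−ΔΔCt, i.e. perfect amplification efficiency (the
classic ΔΔCt model; no Pfaffl correction).  The reference baseline is
the arithmetic mean of reference ΔCt.  Folds are invariant to
per-sample Ct shifts that hit target and housekeeping alike.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with planted ground truth as the recovery oracle:

* per-gene Gaussian log2 intensities, baseline ~ N(8, 1), gene SD
  uniform in 0.2–0.4 log2 units — the usual log-normal microarray
  approximation;
* five populations × 6 replicates (defaults), 1000 genes;
* 60 and 40 planted DE genes in contrasts 1 and 2, additive ±1.5 log2
  shifts (fold 2.8), including a 20-gene core module shifted with the
  same sign in both CD141+ populations — the size of the shared module
  the design is meant to recover;
* 50 floor genes at baseline − 4 with SD 0.01 ("unexpressed");
* a catalog of 50 gene sets of 20 genes; 49 draw members from null
  genes, and one planted set's members shift coherently by **0.5**
  log2 units in the two CD141+ populations.  The 0.5 shift (fold 1.41)
  is deliberately *below* the 1.5 single-gene gate: the planted set
  models a modest coordinated program that single-gene testing misses
  but √k-aggregated activity detects — the scenario pathway scoring
  exists for — and it keeps the planted core module cleanly separated
  from the planted pathway in the truth record.

One global seed drives derived substreams per stage (matrix, catalog,
Ct, SVM), so stages are independently regenerable and a pipeline rerun
is byte-identical.  The generator does **not** model probe-level bead
variation, batch or chip effects, intensity-dependent variance, or
correlated co-expression outside the planted structure; passing tests
demonstrate correctness of the arithmetic and calibration under the
stated noise model, not robustness to real-array artefacts.

`generate_ct_table()` encodes a declared true fold as −log2(fold)
added to treated-sample target Cts, with 0.15-cycle Gaussian well
noise, Cts clamped to the instrument-plausible 15–35 range.

## Numerical and design choices

* Duplicate gene rows at load time collapse by per-sample maximum
  (brightest-probe proxy); the collapse is logged.  Missing cells are
  a hard error by default, with an explicit `drop_gene` policy.
* Variances use the unbiased (n−1) estimator throughout.
* Zero-variance genes: error in `zscore_genes()` (the filters own that
  responsibility), flag in `two_group_stats()`, always-removed in
  `filter_low_variability()`.
* Gene identifiers match case-sensitively.
* Validation problem sizes (1000 genes, 6 replicates, 50 pathways, 10
  seeds) were chosen as the smallest sizes at which the calibration
  and recovery properties are statistically stable; the whole suite
  runs in well under a minute.

## Known limitations

* The pooled t-test has no moderation; at n = 6 per group it is noisy
  for genes with unstable variance estimates.  Empirical-Bayes
  moderation is out of scope by design.
* Raw-p gating does not control FDR; on ~1000 tested genes expect ~5%
  of nulls through the p-gate alone (the fold-change gate removes most
  of these).
* The filter thresholds that produced any particular published
  signature size are generally unstated in array studies; with other
  thresholds the counts shift.  This is why every threshold is config
  plus manifest, never hard-coded.
* Subset Z-scores divide by the reference SD per pathway; with few
  reference samples this is itself noisy, and a pathway with zero
  reference variance is flagged undefined rather than scored.
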