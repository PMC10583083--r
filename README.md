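# coresig

Pairwise expression signatures, shared core modules, and pathway
activity scoring for dendritic-cell transcriptomics.

## What problem this solves

Skin-resident CD141+ dermal dendritic cells (DDCs) and the CD141-high
fraction of vitamin-D3-treated monocyte-derived DCs (moDCs) both show
regulatory, tolerance-promoting behaviour.  If that reflects a shared
transcriptional program, it should be recoverable as (i) a **core
module** of genes differentially expressed *in the same direction* in
two independent pairwise contrasts — CD141+ DDC vs CD1c+ DDC in skin,
and CD141hi VitD3 moDC vs moDC in blood — and (ii) gene sets
("pathways") whose aggregate activity separates the two CD141+
populations from the other DC subsets.  `coresig` implements that
discovery pipeline for analysts working with log2 expression matrices
(microarray-style), plus the ΔΔCt arithmetic used to validate
candidate genes (e.g. *UCN2*) by qPCR.

## The statistics at its core

* **Per-gene testing.** Two-sample t-test (pooled variance by
  default, Welch optional); fold change on anti-logged means,
  `fch = 2^(Δ mean log2)`.  A gene is called when `p < 0.05` and
  `max(fch, 1/fch) > 1.5`.  No multiple-testing correction by default
  (BH is an opt-in flag), after a filter that removes unexpressed and
  low-variability genes.
* **Core module.** `(up₁ ∩ up₂) ∪ (down₁ ∩ down₂)`; direction-
  discordant genes are reported separately.
* **Pathway activity.** Per-gene z-scores across all samples, then
  for a pathway with k matched genes, `a_j = Σ z_gj / √k` — the
  combined z-score with √k stabilising the variance of the mean.
* **Subset Z-scores.** Activities standardised by a reference
  population's mean/SD, averaged per population: the reference row is
  exactly 0, |Z| ≈ 0 means "behaves like the reference", large |Z|
  means strong divergence.
* **SVM ranking.** Linear one-vs-rest SVMs on the activity matrix;
  pathways ranked by summed squared weights.
* **ΔΔCt.** `ΔCt = Ct_target − Ct_GAPDH`,
  `ΔΔCt = ΔCt − mean(ΔCt_ref)`, `fold = 2^−ΔΔCt`.

A synthetic-data generator plants DE genes, a core module, an
"unexpressed" floor, and one coherently shifted pathway, and returns
the truth record, so every stage is testable end to end without any
download.  See the methods vignette
(`vignettes/coresig-methods.Rmd`) for models, assumptions, defaults
and limitations.

## Worked example

```r
library(coresig)
run <- run_pipeline(pipeline_config(seed = 1))
print(run)
#> coresig pipeline run (seed 1)
#>   genes tested: 855 of 1000
#> Gene signature [CD141+DDC vs CD1c+DDC]: 66 genes (36 up, 30 down) at p<0.05, fch>1.5
#> Gene signature [CD141hi_VitD3_moDC vs moDC]: 49 genes (25 up, 24 down) at p<0.05, fch>1.5
#> Core module across [CD141+DDC vs CD1c+DDC] and [CD141hi_VitD3_moDC vs moDC]: 21 genes (8 up, 13 down); 0 discordant
#>   top pathway: PLANTED_CD141_SET (score 0.3951)
```

1000 simulated genes pass through the filters (855 tested), each
contrast yields a signature at the p < 0.05 / fch > 1.5 gates, and
their directional intersection recovers a 21-gene core module (20
were planted; at these settings one borderline null gene slips in or
a planted gene drops out per run — the Jaccard overlap with truth is
≥ 0.8 across seeds).  The planted pathway tops the SVM ranking, and
the subset Z-score table tells the similarity story directly:

```r
round(run$subset_z["PLANTED_CD141_SET", ], 2)
#>          CD141+DDC           CD1c+DDC               moDC CD141hi_VitD3_moDC CD141lo_VitD3_moDC
#>               0.00              -8.72              -8.35               1.07              -7.49
```

Relative to the CD141+ DDC reference, the pathway is equally active
in CD141hi VitD3 moDCs (Z ≈ 1, i.e. reference-like) and strongly
divergent in every population lacking the program (Z ≈ −8): the
shared-regulatory-signature readout.  qPCR validation arithmetic:

```r
ct <- generate_ct_table(12, "UCN2", fold_changes = c(UCN2 = 5), seed = 1)
fc <- ddct_fold_change(delta_ct(ct), "reference")
round(attr(fc, "condition_means"), 2)
#>      reference treated
#> UCN2      1.01    4.29
```

The treated-vs-reference fold estimate recovers the planted fold of 5
up to well noise (mean over 10 seeds: 5.08).

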