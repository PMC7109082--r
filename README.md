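# panelTMB

In silico comparison of **gene-panel tumour mutational burden (TMB)**
against **exome-based TMB** in cancer cohorts.

Targeted sequencing panels report TMB from a ~1 Mb footprint of cancer
genes, while the exome reference spans ~30 Mb. Because panels are built
from recurrently mutated driver genes, the mutation density they see is
systematically inflated — panels *over-call* TMB-high at low cut-offs —
and each panel needs its own calibrated cut-point to match an
exome-based dichotomisation. `panelTMB` provides the full pipeline to
quantify this on any cohort of somatic variant calls, plus a synthetic
metastatic-cohort generator so everything is testable without
access-controlled patient data.

What it computes, per sample and panel:

* **Panel TMB** = variants (SNV + MNV + indel) with any reference-base
  overlap of the panel footprint, divided by the footprint size in Mb.
  The footprint is the merged longest-ORF coding sequence of the
  panel's genes (vendors' exact capture designs are proprietary).
* **Exome TMB** = variants in the CDS union / 30 Mb (denominator
  overridable).
* **Mutational load (ML)** = genome-wide non-synonymous variant count.

and, per panel over the cohort:

* confusion matrices (TP/FP/TN/FN, misclassification % = FP% + FN%)
  across high-TMB cut-offs 5, 10, 20, 40 mutations/Mb;
* ROC curves against exome TMB dichotomised at 10/Mb, with AUC equal to
  the Mann–Whitney ranking statistic, pan-cancer and per tumour type;
* an accuracy-optimal **calibrated cut-point** (lowest-threshold
  tie-break, midpoint reporting);
* per-tumour-type OLS fits of ML against exome TMB (slope, intercept,
  R², predicted ML at 10/Mb).

## Worked example

```r
library(panelTMB)

cfg    <- sim_config(seed = 42L, n_samples = 200L)   # driver_enrichment = 2
cohort <- simulate_cohort(cfg)                       # add dir = "..." to write VCFs etc.
cp     <- cohort_profiles(cohort)                    # footprints + per-sample TMB/ML

footprint_summary(cp$panels)
#>                       panel n_genes_matched n_genes_unmatched footprint_mb
#> FoundationOne FoundationOne             324                 0     0.635091
#> MSK-IMPACT       MSK-IMPACT             468                 0     0.910621
#> ...
#> TempusXT           TempusXT             596                 0     1.175227

subset(cutoff_sweep(cp$profiles), panel == "FoundationOne")
#>           panel cutoff tp fp  tn fn tp_pct fp_pct tn_pct fn_pct misclassified_pct
#> 1 FoundationOne      5 85 40  74  1   42.5   20.0   37.0    0.5              20.5
#> 2 FoundationOne     10 41 34 124  1   20.5   17.0   62.0    0.5              17.5
#> 3 FoundationOne     20 12 21 167  0    6.0   10.5   83.5    0.0              10.5
#> 4 FoundationOne     40  7  4 189  0    3.5    2.0   94.5    0.0               2.0
```

Misclassification is dominated by false positives (over-calling) and
declines as the cut-off rises — the smallest panel here misclassifies
20.5% of samples at 5/Mb but 2% at 40/Mb. Calibration shows what
threshold each panel should use instead of the nominal 10/Mb:

```r
calibrate_cutpoints(cp$profiles, strata = "pan-cancer")[, c("panel", "auc", "optimal_cutpoint", "optimal_accuracy")]
#>           panel       auc optimal_cutpoint optimal_accuracy
#> 1 FoundationOne 0.9795057         16.53306            0.955
#> 2    MSK-IMPACT 0.9888487         14.82505            0.960
#> 3         Caris 0.9908831         11.54201            0.960
#> 4      TempusXT 0.9909584         11.48714            0.960
#> ...

regression_summary(cp$profiles)
#>   tumour_type  n    slope    intercept r_squared ml_at_tmb10
#> 1      breast 57 2.720929  0.253135655 0.9432297    27.46243
#> 2  colorectal 48 2.809151 -0.074129276 0.9994637    28.01738
#> 3        lung 63 2.868284  0.009761372 0.9943497    28.69261
#> 4        skin 32 2.845981 -0.393334243 0.9914419    28.06648
```

All panels rank samples almost perfectly (AUC ≈ 0.98–0.99) yet their
accuracy-optimal cut-points sit well above 10/Mb — larger footprints
calibrate closer to the reference. ML and TMB are tightly linear within
each tumour type; on this synthetic cohort the slope is the
non-synonymous fraction times the exome denominator (≈ 2.84 ML per
mutation/Mb at the miniature 4 Mb scale).

For file-based cohorts (a GTF, panel gene lists, one VCF per sample and
a metadata TSV), `run_full_analysis()` — or the `inst/cli/panel-tmb`
script's `simulate | footprint | tmb | classify | roc | regress |
report` subcommands — writes the full report bundle (`table1.tsv`,
`calibrated_cutpoints.tsv`, `auc_summary.tsv`, `roc_points.tsv`,
`regression_summary.tsv`, `summary.json`, `run.log`).

## Vignette

`vignettes/panel-tmb-methods.Rmd` documents the model, the longest-ORF
footprint assumption, the tie/midpoint conventions of the cut-point
search, the synthetic cohort generator's design (and what it
deliberately does not emulate), and known calibration behaviours under
shot noise.
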