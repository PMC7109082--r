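---
title: "Methods: in silico panel TMB versus exome TMB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico panel TMB versus exome TMB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tumour mutational burden (TMB) — somatic mutations per megabase of
interrogated sequence — is reported by many commercial targeted gene
panels, but each panel interrogates a different set of genes over a
different footprint. Because panels concentrate on recurrently mutated
cancer driver genes, the mutation density inside a panel is not the
mutation density of the exome, and a sample classified "TMB-high" by one
assay need not be classified high by another, or by exome sequencing.
`panelTMB` implements the in silico machinery to quantify this: it
simulates what each panel *would have reported* on a cohort with known
exome-wide somatic calls, compares the resulting high/non-high calls
against the exome standard across cut-offs, and calibrates
panel-specific cut-points by ROC analysis.

# Model and procedure

## Footprints

A panel design is a set of gene symbols. Since vendors do not publish
exact capture designs, the footprint of a panel is approximated by the
coding sequence of the **longest open reading frame** of each gene:
for every gene the transcript with maximal summed CDS length is chosen
(ties broken by the lexicographically smallest transcript id, C-locale
order), and the chosen intervals are merged — overlapping and
book-ended intervals are fused so each base counts once. Coordinates
are 0-based half-open internally (BED arithmetic); GTF input is
converted on read. Panel genes with no annotated CDS (promoter-only
content such as TERT) are excluded with a warning. The true capture
design is generally *smaller* than this footprint, which is a known
limitation of the approximation, not of the implementation.

## TMB, mutational load, membership

* **Panel TMB** = (somatic SNVs + MNVs + indels whose reference span
  overlaps the footprint) / footprint Mb. Membership uses the
  any-overlap rule on the reference span `[pos, pos + len(ref) - 1]`:
  a capture design observes an event if any interrogated base is
  touched. Each VCF ALT allele counts once, regardless of class.
* **Exome TMB** = (variants in the CDS-union regions) / 30 Mb. The
  30 Mb denominator is the conventional exome size and is deliberately
  fixed independent of the annotation's true CDS length; it can be
  overridden (we override it with the miniature genome's own CDS union
  in simulations, so panel and exome TMB are on the same scale).
* **Mutational load (ML)** = the genome-wide count of non-synonymous
  SNVs/MNVs/indels. The non-synonymous flag is consumed from a VCF
  INFO key (default `NS`); the package does not re-derive coding
  consequence — that belongs to an annotation pipeline, not here.
* Classification: equal ref/alt length 1 → SNV, equal length > 1 →
  MNV, unequal → INDEL. Inputs are assumed VCF-normalized; no
  re-left-alignment is attempted.

## Concordance and calibration

A sample is TMB-high when TMB ≥ cut-off; the same rule is applied to
panel and exome values (ties count as high — common TMB-high reporting
practice). With the exome call as reference, the confusion grid is
swept over cut-offs 5, 10, 20 and 40 mutations/Mb, and the
misclassification rate is FP% + FN% of the cohort.

ROC analysis dichotomises exome TMB at 10/Mb (the cut-off most used in
trials) and sweeps thresholds over the distinct panel TMB values. AUC
is computed by trapezoidal integration, which under this sweep equals
the Mann–Whitney probability-of-correct-ranking statistic with ties
counted one half — the suite asserts the equality to 1e-12 against an
independent pair-counting oracle.

The **calibrated cut-point** of a panel maximizes classification
*accuracy* (fraction of samples in the right category) rather than
Youden's J, because matching the reference category for as many
patients as possible is the decision problem panels face. Ties are
broken toward the lowest threshold; the reported threshold is the
midpoint between the two adjacent distinct panel TMB values realizing
the optimum, so calibrated cut-points do not depend on sample
granularity. The boundary rules (all-positive / all-negative) are
reported as min(score) − 1 and max(score) + 1. Strata (tumour types)
in which the exome dichotomisation yields a single class are skipped
with a warning: a ROC curve is undefined there.

## ML–TMB regression

Within each tumour type, ML is regressed on exome TMB by ordinary
least squares (`stats::lm`), reporting slope, intercept, R² and the
predicted ML at 10/Mb. Plain OLS is used deliberately — the relation
in both real and simulated data is strongly linear and the fitted line
is descriptive, not inferential.

# The synthetic cohort generator

There is no public cohort at metastatic-WGS scale, so the generator is
a first-class module: every pipeline stage is exercised on data whose
ground truth is known exactly.

**Genome.** 2000 non-overlapping genes on 2 chromosomes, CDS lengths
log-normal with mean 2 kb (sdlog 0.6), 1–4 exons, 1–3 transcripts per
gene; extra transcripts are 5' exon subsets of the first, so a gene's
CDS union equals its longest ORF and footprint arithmetic is exactly
checkable. The CDS union is ≈ 4 Mb. 17.5% of genes are flagged as
drivers.

**Panels.** Seven nested, driver-biased gene subsets using the real
products' gene counts (324–596 genes). With 2 kb mean CDS this gives
footprints of ≈ 0.66–1.2 Mb — deliberately close to the 0.78–1.48 Mb
range of the real assays, with a largest-to-smallest ratio of ≈ 1.8.
We chose near-real panel footprints rather than scaling panels down
with the genome: the binomial shot noise of a panel TMB measurement at
a 10/Mb boundary is `sqrt(TMB / panel_Mb)`-scale, and shrinking panels
to a few hundred kb would make every calibration result a statement
about shot noise instead of about the method. The miniature part of
the design is the *exome* (4 Mb instead of 30), which only rescales
the exome denominator, overridden in simulations anyway.

**Samples.** Per tumour type, target exome TMB is log-normal with an
explicit hypermutator mixture (fraction × multiplier) producing the
heavy right tail that makes 20–40/Mb cut-offs meaningful. Defaults
(colorectal: median 3/Mb, 7% hypermutators ×12, the MSI-like tail;
skin: median 8/Mb, wide spread; lung: median 7/Mb; breast: median
2.5/Mb) are desk-scale caricatures of metastatic cohorts, chosen once
for realism and not revisited. The coding mutation count is Poisson
with mean TMB × CDS-union-Mb; positions are placed over coding bases
with per-gene rates multiplied by `driver_enrichment` (default 2) for
driver genes — the mechanism by which driver-gene panels over-call at
low TMB. Classes follow a 90/3/7 SNV/MNV/indel mix; non-synonymous
status is Bernoulli per class (0.70/0.75/0.90). Every sample has its
own RNG stream derived from (seed, sample index), so generation is
byte-identical under a fixed seed and stable under parallel layouts.

**Truth.** The generator records per-sample coding counts, per-panel
counts (via gene membership, which coincides with positional footprint
membership by construction) and non-synonymous counts; the suite
asserts that pipeline recounts from the emitted VCFs equal these
integers exactly.

**What the generator does not emulate** — and what passing tests
therefore do not establish about real data: trinucleotide signatures
and regional mutation-rate covariates, copy number, purity/ploidy,
FFPE artefacts, germline contamination, and vendor-specific capture
chemistry. The generator validates the *computational* pipeline and
the *mechanism* of panel over-calling, not clinical performance.

# Numerical choices and known behaviours

* **Derived quantities.** With the class mix `p` and per-class NS
  probabilities `f`, the marginal NS status of an event is
  Bernoulli(`nsbar = sum(p * f)` = 0.7155), so E[ML | TMB] =
  `nsbar × D × TMB` where `D` is the exome denominator. The
  slope-recovery test checks the fitted slope against this analytic
  truth using the exact conditional sampling SE
  `sqrt(sum(w_i^2 N_i nsbar (1 - nsbar)))` — the OLS standard error
  would understate the slope's sampling variability several-fold here,
  because Var(ML | N) grows with N and hypermutators are high-leverage
  points.
* **Calibration under no enrichment.** With `driver_enrichment = 1`,
  panel TMB is an exactly unbiased subsample estimate of exome TMB,
  and the suite verifies the mean panel-minus-exome difference is zero
  within Monte-Carlo error. The accuracy-optimal *threshold*, however,
  systematically calibrates ~1–2/Mb above the 10/Mb reference even
  without enrichment: panel-scale footprints see ~10 mutations at the
  boundary (shot noise SD ≈ 2.4/Mb) and the TMB density declines
  through 10/Mb, so near-boundary negatives outnumber positives and
  the optimal threshold moves up to avoid false positives. This is a
  property of threshold calibration from noisy unbiased scores — worth
  knowing when interpreting published calibrated cut-points — and it
  applies equally to the real assays' 0.78–1.48 Mb footprints.
* **Problem sizes.** Unit tests run on an 80-gene genome with three
  small panels; study-scale checks use the default genome with
  cohorts of 200–500 samples, sizes at which every qualitative claim
  (monotone FP% in enrichment, misclassification declining with the
  cut-off, slope recovery) is resolved well beyond its Monte-Carlo
  error.
* **Degenerate inputs.** Zero-footprint panels, empty cohorts,
  single-class strata, < 3 regression samples and zero-variance
  predictors are all hard, named errors; a constant response reports
  R² = 0.

# Limitations

The footprint approximation (longest ORF) overstates real capture
designs; gene matching is exact and case-sensitive by symbol; no
germline subtraction, normalization or consequence annotation is
performed — inputs are assumed to be somatic, normalized and (for ML)
annotated. The calibrated cut-points produced on synthetic cohorts
characterize the method, not any vendor's assay.
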