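Package: panelTMB
Title: In Silico Assessment of Gene-Panel Tumour Mutational Burden
    Against Exome-Based TMB
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the in silico comparison of targeted gene-panel
    tumour mutational burden (TMB) with exome-based TMB in cancer
    cohorts. Builds panel genomic footprints from a gene annotation
    under a longest-open-reading-frame assumption, computes per-sample
    panel and exome TMB and mutational load from somatic variant calls,
    sweeps high-TMB cut-offs to produce confusion matrices, calibrates
    panel-specific cut-points by ROC analysis (pan-cancer and per
    tumour type), fits the per-tumour-type linear relation between
    mutational load and TMB, and ships a fully synthetic metastatic
    cohort generator (miniature genome, driver-gene enrichment,
    hypermutator tails) so the whole pipeline is testable without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    VariantAnnotation,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
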