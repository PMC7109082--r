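#' Profiles for an in-memory simulated cohort
#'
#' Convenience wrapper chaining footprint construction and TMB
#' computation on a [simulate_cohort()] result: builds one
#' `panel_design` per generated panel from the generated annotation,
#' an exome model, and the per-sample profile table.
#'
#' @param cohort a `sim_cohort`.
#' @param exome_denominator_mb reporting denominator; default the
#'   cohort's own CDS union in Mb (so panel and exome TMB are directly
#'   comparable at miniature genome scale). Pass 30 for the exome
#'   reporting convention.
#' @param compute_ml compute mutational load.
#' @return list: `profiles`, `panels` (panel_design list), `exome`.
#' @export
cohort_profiles <- function(cohort, exome_denominator_mb = NULL,
                            compute_ml = TRUE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  ann <- cohort$sim_ann$annotation
  panels <- lapply(names(cohort$panels), function(nm)
    build_panel_footprint(cohort$panels[[nm]], ann, name = nm))
  names(panels) <- names(cohort$panels)
  if (is.null(exome_denominator_mb)) {
    exome_denominator_mb <- cohort$sim_ann$union_mb
  }
  exome <- exome_model(ann, denominator_mb = exome_denominator_mb)
  profiles <- build_sample_profiles(cohort$variants, cohort$metadata,
                                    panels, exome, compute_ml = compute_ml)
  list(profiles = profiles, panels = panels, exome = exome)
}

#' Run the full panel-vs-exome TMB analysis from files
#'
#' Orchestrates every stage on a cohort directory: read the annotation
#' (GTF) and panel gene lists, build footprints, read one VCF per
#' sample, compute per-sample profiles, sweep the high-TMB cut-offs into
#' a confusion grid, run ROC calibration pan-cancer and per tumour
#' type, and fit the per-type ML-TMB regression. All machine-readable
#' outputs are written to `out_dir` together with a JSON summary and a
#' run log (versions, seed, input digests).
#'
#' @param config list (or path to a YAML file) with elements:
#'   `annotation` (GTF path), `panels_dir` (directory of `*.txt` gene
#'   lists), `vcf_dir` (directory of `<sample_id>.vcf`), `metadata`
#'   (TSV with sample_id, tumour_type), `out_dir`; optional `cutoffs`
#'   (default 5,10,20,40), `exome_cutoff` (default 10),
#'   `exome_denominator_mb` (default 30), `stratify_types` (default all
#'   types present), `ns_key` (default "NS"), `nonsynonymous_only`
#'   (default FALSE).
#' @return invisibly, a list with profiles, table1, calibration,
#'   regression and the panel designs.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("annotation", "panels_dir", "vcf_dir", "metadata", "out_dir")) {
    if (is.null(config[[f]])) stop("config error: missing '", f, "'",
                                   call. = FALSE)
  }
  cutoffs <- config$cutoffs %||% c(5, 10, 20, 40)
  exome_cutoff <- config$exome_cutoff %||% 10
  denom <- config$exome_denominator_mb %||% 30
  ns_key <- config$ns_key %||% "NS"
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("panelTMB %s | R %s",
                         as.character(utils::packageVersion("panelTMB")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %s", config$seed %||% "none"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ann <- stage("annotation", read_gene_models(config$annotation))
  panel_files <- list.files(config$panels_dir, pattern = "\\.txt$",
                            full.names = TRUE)
  if (!length(panel_files)) stop("stage 'footprint' failed: no panel lists in ",
                                 config$panels_dir, call. = FALSE)
  panels <- stage("footprint", {
    ps <- lapply(panel_files, function(f)
      build_panel_footprint(read_panel_genes(f), ann,
                            name = sub("\\.txt$", "", basename(f))))
    stats::setNames(ps, vapply(ps, `[[`, "", "name"))
  })
  exome <- exome_model(ann, denominator_mb = denom)
  fs <- footprint_summary(panels)
  utils::write.table(fs, file.path(out_dir, "footprint_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("panel %s: %d matched / %d unmatched genes, %.4f Mb",
                         fs$panel, fs$n_genes_matched, fs$n_genes_unmatched,
                         fs$footprint_mb),
                 sprintf("exome: %.4f Mb CDS union, denominator %g Mb",
                         exome$regions_mb, exome$denominator_mb))

  metadata <- stage("metadata", {
    md <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
    miss <- setdiff(c("sample_id", "tumour_type"), names(md))
    if (length(miss)) stop("metadata lacks column(s): ",
                           paste(miss, collapse = ", "))
    md
  })
  variants <- stage("variants", {
    do.call(rbind, lapply(metadata$sample_id, function(sid) {
      f <- file.path(config$vcf_dir, paste0(sid, ".vcf"))
      if (!file.exists(f)) stop("no VCF for sample ", sid)
      read_somatic_vcf(f, sample_id = sid, ns_key = ns_key)
    }))
  })
  if (isTRUE(config$nonsynonymous_only)) {
    if (anyNA(variants$non_synonymous)) {
      stop("nonsynonymous_only requested but annotation flag missing",
           call. = FALSE)
    }
    variants <- variants[variants$non_synonymous, , drop = FALSE]
  }
  profiles <- stage("tmb", build_sample_profiles(
    variants, metadata, panels, exome,
    compute_ml = !anyNA(variants$non_synonymous)))
  utils::write.table(profiles, file.path(out_dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  table1 <- stage("classify", cutoff_sweep(profiles, cutoffs = cutoffs))
  utils::write.table(table1, file.path(out_dir, "table1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  strata <- c("pan-cancer",
              config$stratify_types %||% sort(unique(profiles$tumour_type)))
  calibration <- stage("roc", calibrate_cutpoints(
    profiles, strata = strata, exome_cutoff = exome_cutoff))
  utils::write.table(calibration,
                     file.path(out_dir, "calibrated_cutpoints.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calibration[, c("panel", "stratum", "auc")],
                     file.path(out_dir, "auc_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(stage("roc", roc_points(profiles,
                                             exome_cutoff = exome_cutoff)),
                     file.path(out_dir, "roc_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  regression <- if ("mutational_load" %in% names(profiles)) {
    stage("regress", regression_summary(profiles))
  }
  if (!is.null(regression)) {
    utils::write.table(regression,
                       file.path(out_dir, "regression_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_samples = nrow(profiles),
    n_variants = nrow(variants),
    panels = fs,
    exome_denominator_mb = exome$denominator_mb,
    cutoffs = cutoffs,
    exome_cutoff = exome_cutoff,
    misclassified_pct = stats::setNames(
      lapply(split(table1, table1$cutoff), function(d)
        stats::setNames(as.list(d$misclassified_pct), d$panel)),
      paste0("cutoff_", sort(unique(table1$cutoff)))),
    pan_cancer = calibration[calibration$stratum == "pan-cancer",
                             c("panel", "auc", "optimal_cutpoint",
                               "optimal_accuracy")],
    regression = regression)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  digests <- tools::md5sum(c(config$annotation, config$metadata))
  log_lines <- c(log_lines,
                 sprintf("input %s md5 %s", names(digests), digests),
                 sprintf("samples: %d, variants: %d", nrow(profiles),
                         nrow(variants)))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(profiles = profiles, table1 = table1,
                 calibration = calibration, regression = regression,
                 panels = panels, exome = exome))
}
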