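#' Panel-based tumour mutational burden
#'
#' Counts the variants whose reference span overlaps the panel footprint
#' and divides by the footprint size in Mb. Every ALT event counts once,
#' regardless of class (SNV/MNV/INDEL).
#'
#' @param variants variant data frame for one sample.
#' @param panel a `panel_design` from [build_panel_footprint()].
#' @return mutations per Mb (numeric scalar).
#' @export
panel_tmb <- function(variants, panel) {
  stopifnot(inherits(panel, "panel_design"))
  if (!isTRUE(panel$footprint_mb > 0)) {
    stop("panel '", panel$name, "' has zero-size footprint", call. = FALSE)
  }
  sum(in_footprint(variants, panel$footprint)) / panel$footprint_mb
}

#' Exome-based tumour mutational burden
#'
#' Counts the variants overlapping the exome (CDS-union) regions and
#' divides by the model's reporting denominator — by convention 30 Mb,
#' independent of the regions' true length.
#'
#' @param variants variant data frame for one sample.
#' @param exome an `exome_model` from [exome_model()].
#' @return mutations per Mb (numeric scalar).
#' @export
exome_tmb <- function(variants, exome) {
  stopifnot(inherits(exome, "exome_model"))
  sum(in_footprint(variants, exome$regions)) / exome$denominator_mb
}

#' Mutational load: count of non-synonymous somatic events
#'
#' The total number of non-synonymous SNVs, MNVs and indels in the
#' tumour, genome-wide (not restricted to any footprint). Requires every
#' variant to carry a non-synonymous flag.
#'
#' @param variants variant data frame with a logical `non_synonymous`
#'   column.
#' @return non-negative integer count.
#' @export
mutational_load <- function(variants) {
  if (nrow(variants) == 0L) return(0L)
  if (anyNA(variants$non_synonymous)) {
    bad <- unique(variants$sample_id[is.na(variants$non_synonymous)])
    stop("mutational load requested but non-synonymous annotation is ",
         "missing for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sum(variants$non_synonymous)
}

#' Per-sample TMB profiles for a cohort
#'
#' Assembles the per-sample quantities every downstream analysis
#' consumes: exome TMB, one TMB per panel, and (optionally) mutational
#' load. Samples listed in `metadata` but absent from `variants` get
#' zero counts.
#'
#' @param variants variant data frame for the whole cohort (column
#'   `sample_id`).
#' @param metadata data frame with columns `sample_id`, `tumour_type`.
#' @param panels named list of `panel_design` objects.
#' @param exome an `exome_model`.
#' @param compute_ml compute mutational load (requires non-synonymous
#'   flags on all variants).
#' @return data frame with one row per metadata sample: `sample_id`,
#'   `tumour_type`, `exome_tmb`, one column per panel (panel name),
#'   and `mutational_load` when requested.
#' @export
build_sample_profiles <- function(variants, metadata, panels, exome,
                                  compute_ml = TRUE) {
  stopifnot(is.data.frame(metadata),
            all(c("sample_id", "tumour_type") %in% names(metadata)))
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    names(panels) <- vapply(panels, `[[`, "", "name")
  }
  ids <- as.character(metadata$sample_id)
  count_by_sample <- function(mask) {
    cnt <- rowsum(as.numeric(mask), variants$sample_id)
    out <- stats::setNames(rep(0, length(ids)), ids)
    hit <- intersect(rownames(cnt), ids)
    out[hit] <- cnt[hit, 1L]
    out
  }
  prof <- data.frame(sample_id = ids,
                     tumour_type = as.character(metadata$tumour_type),
                     stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(variants)) {
    prof$exome_tmb <- count_by_sample(in_footprint(variants, exome$regions)) /
      exome$denominator_mb
    for (nm in names(panels)) {
      p <- panels[[nm]]
      if (!isTRUE(p$footprint_mb > 0)) {
        stop("panel '", nm, "' has zero-size footprint", call. = FALSE)
      }
      prof[[nm]] <- count_by_sample(in_footprint(variants, p$footprint)) /
        p$footprint_mb
    }
    if (compute_ml) {
      if (anyNA(variants$non_synonymous)) {
        bad <- unique(variants$sample_id[is.na(variants$non_synonymous)])
        stop("non-synonymous annotation missing for sample(s): ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
      }
      prof$mutational_load <-
        as.integer(count_by_sample(variants$non_synonymous))
    }
  } else {
    prof$exome_tmb <- 0
    for (nm in names(panels)) prof[[nm]] <- 0
    if (compute_ml) prof$mutational_load <- 0L
  }
  rownames(prof) <- NULL
  prof
}

#' Names of the panel TMB columns in a profile table
#' @param profiles profile data frame from [build_sample_profiles()].
#' @return character vector of panel column names.
#' @export
panel_columns <- function(profiles) {
  setdiff(names(profiles),
          c("sample_id", "tumour_type", "exome_tmb", "mutational_load"))
}
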