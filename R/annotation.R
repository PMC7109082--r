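#' Gene annotation container
#'
#' A `gene_annotation` holds the coding (CDS) structure of a genome as a
#' flat table: one row per CDS interval with its gene and transcript.
#' It is the input to footprint construction. Coordinates are stored
#' 0-based half-open; GTF input (1-based inclusive) is converted on read.
#'
#' @param cds data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, `gene_name`, `transcript_id`.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(cds) {
  req <- c("chrom", "start", "end", "gene_id", "gene_name", "transcript_id")
  stopifnot(is.data.frame(cds), all(req %in% names(cds)))
  validate_intervals(cds)
  cds <- cds[order(cds$chrom, cds$start), req, drop = FALSE]
  rownames(cds) <- NULL
  structure(list(cds = cds), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", length(unique(x$cds$gene_name)), "genes,",
      length(unique(x$cds$transcript_id)), "transcripts,",
      nrow(x$cds), "CDS intervals\n")
  invisible(x)
}

#' Read a gene annotation from GTF/GFF3
#'
#' Only `CDS` features are retained; `gene_id`, `gene_name` and
#' `transcript_id` attributes are required on them (GFF3 files using
#' `Name`/`Parent` are mapped when possible by rtracklayer).
#'
#' @param path GTF or GFF3 file.
#' @return a [gene_annotation()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features found in ", path, call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  need <- c("gene_id", "transcript_id")
  miss <- setdiff(need, names(mc))
  if (length(miss)) {
    stop("annotation lacks attribute(s) on CDS features: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  gene_name <- if ("gene_name" %in% names(mc)) mc$gene_name else mc$gene_id
  gene_annotation(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    gene_id = as.character(mc$gene_id),
    gene_name = as.character(gene_name),
    transcript_id = as.character(mc$transcript_id),
    stringsAsFactors = FALSE))
}

#' Longest-ORF coding intervals per gene
#'
#' For each gene, selects the transcript whose summed CDS length is
#' maximal (the "longest open reading frame" proxy for a panel's target
#' region) and returns that transcript's CDS intervals. Ties on coding
#' length are broken by the lexicographically smallest transcript id
#' (C-locale ordering, so "T10" sorts before "T2").
#'
#' @param annotation a [gene_annotation()].
#' @return interval data frame with columns `chrom`, `start`, `end`,
#'   `gene_name`, `transcript_id`.
#' @export
longest_orf_cds <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  cds <- annotation$cds
  key <- paste(cds$gene_name, cds$transcript_id, sep = "\r")
  len <- rowsum(cds$end - cds$start, key, reorder = FALSE)
  parts <- strsplit(rownames(len), "\r", fixed = TRUE)
  tx <- data.frame(gene_name = vapply(parts, `[`, "", 1L),
                   transcript_id = vapply(parts, `[`, "", 2L),
                   cds_bp = as.numeric(len),
                   stringsAsFactors = FALSE)
  # per gene: max cds_bp, ties to the smallest transcript_id (C locale)
  pick <- unlist(lapply(split(seq_len(nrow(tx)), tx$gene_name), function(i) {
    best <- i[tx$cds_bp[i] == max(tx$cds_bp[i])]
    best[order(tx$transcript_id[best], method = "radix")[1L]]
  }), use.names = FALSE)
  chosen <- tx[pick, c("gene_name", "transcript_id")]
  keep <- paste(cds$gene_name, cds$transcript_id, sep = "\r") %in%
    paste(chosen$gene_name, chosen$transcript_id, sep = "\r")
  out <- cds[keep, c("chrom", "start", "end", "gene_name", "transcript_id")]
  rownames(out) <- NULL
  out
}

#' Build a panel design footprint from a gene list
#'
#' The footprint is the merged union of the longest-ORF coding intervals
#' of the panel's genes; its size in Mb is the denominator for panel TMB.
#' Gene matching is case-sensitive on `gene_name`. Panel genes absent
#' from the annotation (e.g. promoter-only content with no annotated
#' CDS) are excluded with a warning.
#'
#' @param panel_genes character vector of gene symbols.
#' @param annotation a [gene_annotation()].
#' @param name panel name.
#' @return an object of class `panel_design` with elements `name`,
#'   `genes`, `matched`, `unmatched`, `footprint` (merged intervals) and
#'   `footprint_mb`.
#' @export
build_panel_footprint <- function(panel_genes, annotation, name = "panel") {
  stopifnot(inherits(annotation, "gene_annotation"))
  panel_genes <- unique(as.character(panel_genes))
  if (length(panel_genes) == 0L) stop("empty panel gene list", call. = FALSE)
  lorf <- longest_orf_cds(annotation)
  matched <- intersect(panel_genes, unique(lorf$gene_name))
  unmatched <- setdiff(panel_genes, matched)
  if (length(matched) == 0L) {
    stop("panel '", name, "': no panel gene matches the annotation",
         call. = FALSE)
  }
  if (length(unmatched)) {
    warning("panel '", name, "': ", length(unmatched),
            " gene(s) not matched in annotation (no CDS): ",
            paste(utils::head(unmatched, 5L), collapse = ", "),
            if (length(unmatched) > 5L) ", ..." else "",
            call. = FALSE)
  }
  fp <- merge_intervals(lorf[lorf$gene_name %in% matched,
                             c("chrom", "start", "end")])
  structure(list(name = name,
                 genes = panel_genes,
                 matched = matched,
                 unmatched = unmatched,
                 footprint = fp,
                 footprint_mb = sum(fp$end - fp$start) / 1e6),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("panel_design '%s': %d/%d genes matched, footprint %.3f Mb (%d intervals)\n",
              x$name, length(x$matched), length(x$genes),
              x$footprint_mb, nrow(x$footprint)))
  invisible(x)
}

#' Exome model: union of all CDS with a fixed reporting denominator
#'
#' The numerator regions are the merged union of every CDS interval in
#' the annotation; the denominator defaults to the 30 Mb exome
#' convention regardless of the regions' true length. Override
#' `denominator_mb` (e.g. with the regions' own size) for sensitivity
#' analyses or miniature simulated genomes.
#'
#' @param annotation a [gene_annotation()].
#' @param denominator_mb reporting denominator in Mb; default 30.
#' @return object of class `exome_model` with `regions`, `regions_mb`,
#'   `denominator_mb`.
#' @export
exome_model <- function(annotation, denominator_mb = 30) {
  stopifnot(inherits(annotation, "gene_annotation"), denominator_mb > 0)
  regions <- merge_intervals(annotation$cds[, c("chrom", "start", "end")])
  structure(list(regions = regions,
                 regions_mb = sum(regions$end - regions$start) / 1e6,
                 denominator_mb = denominator_mb),
            class = "exome_model")
}

#' @export
print.exome_model <- function(x, ...) {
  cat(sprintf("exome_model: %.3f Mb CDS union, reporting denominator %g Mb\n",
              x$regions_mb, x$denominator_mb))
  invisible(x)
}

#' Read a panel gene list (one symbol per line, '#' comments)
#' @param path text file.
#' @return character vector of gene symbols.
#' @export
read_panel_genes <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Footprint summary table for a set of panels
#' @param panels list of `panel_design` objects.
#' @return data frame: panel, n_genes_matched, n_genes_unmatched,
#'   footprint_mb.
#' @export
footprint_summary <- function(panels) {
  do.call(rbind, lapply(panels, function(p) {
    data.frame(panel = p$name,
               n_genes_matched = length(p$matched),
               n_genes_unmatched = length(p$unmatched),
               footprint_mb = p$footprint_mb,
               stringsAsFactors = FALSE)
  }))
}
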