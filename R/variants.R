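#' Classify a somatic variant as SNV, MNV or INDEL
#'
#' Classification uses allele lengths only: equal length 1 is an SNV,
#' equal length above 1 an MNV (multi-nucleotide substitution), unequal
#' lengths an INDEL. Alleles are assumed VCF-normalized (indels carry an
#' anchor base; no redundant shared prefix beyond it).
#'
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return character vector in `c("SNV", "MNV", "INDEL")`.
#' @examples
#' classify_variant(c("A", "AT", "A"), c("T", "GC", "AT"))
#' @export
classify_variant <- function(ref, alt) {
  ref <- as.character(ref); alt <- as.character(alt)
  stopifnot(length(ref) == length(alt))
  if (length(ref) == 0L) return(character())
  if (anyNA(ref) || anyNA(alt) || any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("empty or missing allele", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt alleles must differ", call. = FALSE)
  nr <- nchar(ref); na <- nchar(alt)
  ifelse(nr != na, "INDEL", ifelse(nr == 1L, "SNV", "MNV"))
}

#' Read somatic variant calls from a VCF file
#'
#' Produces one row per ALT allele of each record passing FILTER
#' (`PASS` or `.`). The non-synonymous status is taken from an INFO key
#' (0/1; default `NS`) when the header declares it, otherwise left `NA`.
#' For a multi-sample VCF, supply `sample` to keep only records with a
#' non-reference genotype for that sample.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param sample_id sample label attached to the returned variants;
#'   defaults to the file name without extension.
#' @param ns_key INFO key holding the non-synonymous flag.
#' @param sample optional genotype column name used to subset a cohort
#'   VCF.
#' @return data frame: sample_id, chrom, pos (1-based), ref, alt,
#'   vclass, non_synonymous (logical, may be NA).
#' @export
read_somatic_vcf <- function(path, sample_id = NULL, ns_key = "NS",
                             sample = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(path))
  }
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop("malformed or unreadable VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  vcf <- VariantAnnotation::expand(vcf)
  filt <- VariantAnnotation::filt(vcf)
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  if (!is.null(sample)) {
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt) || !sample %in% colnames(gt)) {
      stop("sample '", sample, "' not found in VCF genotypes", call. = FALSE)
    }
    keep <- keep & !gt[, sample] %in% c("0/0", "0|0", "./.", ".")
  }
  vcf <- vcf[keep]
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ns <- rep(NA, n)
  inf <- VariantAnnotation::info(vcf)
  if (ns_key %in% names(inf)) ns <- as.logical(as.integer(inf[[ns_key]]))
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  data.frame(sample_id = rep(sample_id, n),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = ref,
             alt = alt,
             vclass = if (n) classify_variant(ref, alt) else character(),
             non_synonymous = ns,
             stringsAsFactors = FALSE)
}

variant_spans <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(variants$pos,
                                          variants$pos + nchar(variants$ref) - 1L))
}

#' Test footprint membership of somatic variants
#'
#' A variant belongs to a footprint when any base of its reference span
#' (`[pos, pos + len(ref) - 1]` in 1-based coordinates) overlaps a
#' footprint interval — the any-overlap rule under which a capture
#' design would observe the event.
#'
#' @param variants variant data frame (see [read_somatic_vcf()]).
#' @param footprint interval data frame (0-based half-open).
#' @return logical vector, one element per variant row.
#' @export
in_footprint <- function(variants, footprint) {
  if (nrow(variants) == 0L) return(logical())
  validate_intervals(footprint)
  if (nrow(footprint) == 0L) return(rep(FALSE, nrow(variants)))
  # suppressed warning: disjoint seqlevels between query and footprint
  # simply mean no overlap on those chromosomes
  suppressWarnings(IRanges::overlapsAny(variant_spans(variants),
                                        intervals_to_granges(footprint)))
}

#' Write variants as a normalized TSV
#' @param variants variant data frame.
#' @param path output file.
#' @export
write_variant_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
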