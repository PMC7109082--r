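# Independent brute-force oracles used across the suite. These stay
# deliberately naive (per-base loops, pair counting) so they share no
# code path with the implementation they check.

# per-base union: returns total bp and a membership test closure
bf_union <- function(intervals) {
  by_chrom <- split(intervals, intervals$chrom)
  sets <- lapply(by_chrom, function(d) {
    bases <- logical(max(d$end))
    for (i in seq_len(nrow(d))) {
      bases[(d$start[i] + 1):d$end[i]] <- TRUE  # 1-based base index
    }
    bases
  })
  list(
    bp = sum(vapply(sets, sum, 0L)),
    member = function(chrom, pos1) {
      s <- sets[[chrom]]
      !is.null(s) && pos1 <= length(s) && s[pos1]
    })
}

# linear per-base scan membership for a variant reference span
bf_in_footprint <- function(variants, footprint) {
  u <- bf_union(footprint)
  vapply(seq_len(nrow(variants)), function(i) {
    span <- variants$pos[i]:(variants$pos[i] + nchar(variants$ref[i]) - 1L)
    any(vapply(span, function(p) u$member(variants$chrom[i], p), TRUE))
  }, TRUE)
}

# Mann-Whitney pair-count AUC: (concordant + 0.5 * ties) / (pos * neg)
bf_pair_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive accuracy scan over all achievable ">= t" rules
bf_best_accuracy <- function(scores, labels) {
  max(vapply(c(sort(unique(scores)), Inf), function(t)
    mean((scores >= t) == labels), numeric(1L)))
}

random_intervals <- function(n, chroms = c("chrA", "chrB"), span = 1000L) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(50L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# toy annotation: one gene per row, single transcript, single CDS exon
toy_annotation <- function(gene_name, chrom, start, end) {
  gene_annotation(data.frame(
    chrom = chrom, start = start, end = end,
    gene_id = gene_name, gene_name = gene_name,
    transcript_id = paste0(gene_name, ".T1"),
    stringsAsFactors = FALSE))
}

toy_variants <- function(chrom, pos, ref = "A", alt = "T",
                         sample_id = "S1", non_synonymous = TRUE) {
  n <- max(length(chrom), length(pos))
  data.frame(sample_id = rep_len(sample_id, n),
             chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             vclass = classify_variant(rep_len(ref, n), rep_len(alt, n)),
             non_synonymous = rep_len(non_synonymous, n),
             stringsAsFactors = FALSE)
}
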