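#' Simulation configuration for a synthetic metastatic cohort
#'
#' Bundles every knob of the cohort generator. Defaults emulate a
#' metastatic pan-cancer cohort at miniature genome scale: per-type
#' log-normal TMB with an explicit hypermutator mixture (the heavy right
#' tail that makes 20-40/Mb cut-offs meaningful), a multiplicative
#' mutation-rate enrichment in designated driver genes (the mechanism
#' behind panel over-calling, since panels are built from driver genes),
#' an SNV/MNV/indel mixture dominated by SNVs, and per-class
#' non-synonymous probabilities.
#'
#' @param seed integer master seed; every sample derives its own RNG
#'   stream from (seed, sample index).
#' @param n_samples cohort size.
#' @param tumour_type_mix named proportions over tumour types (sum 1).
#' @param tmb_distribution per-type list: `meanlog`, `sdlog` (log-normal
#'   on mutations/Mb), `hyper_fraction`, `hyper_multiplier`.
#' @param driver_enrichment mutation-rate multiplier for driver genes
#'   (>= 1; 1 disables enrichment).
#' @param variant_mix named proportions for SNV/MNV/INDEL (sum 1).
#' @param nonsynonymous_fraction named per-class probability that a
#'   coding variant is non-synonymous.
#' @param genome_spec list: `n_genes`, `n_chromosomes`, `cds_mean_bp`,
#'   `cds_sdlog`, `driver_fraction`, optional `chrom_length_bp` cap.
#' @param panel_sizes named integer vector of panel gene counts; `NULL`
#'   uses the [generate_panels()] defaults (the seven commercial
#'   products' counts).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 200L,
                       tumour_type_mix = c(colorectal = 0.25, skin = 0.20,
                                           lung = 0.30, breast = 0.25),
                       tmb_distribution = list(
                         colorectal = list(meanlog = log(3.0), sdlog = 0.55,
                                           hyper_fraction = 0.07,
                                           hyper_multiplier = 12),
                         skin = list(meanlog = log(8.0), sdlog = 0.90,
                                     hyper_fraction = 0.02,
                                     hyper_multiplier = 5),
                         lung = list(meanlog = log(7.0), sdlog = 0.70,
                                     hyper_fraction = 0.02,
                                     hyper_multiplier = 5),
                         breast = list(meanlog = log(2.5), sdlog = 0.60,
                                       hyper_fraction = 0.03,
                                       hyper_multiplier = 8)),
                       driver_enrichment = 2,
                       variant_mix = c(SNV = 0.90, MNV = 0.03, INDEL = 0.07),
                       nonsynonymous_fraction = c(SNV = 0.70, MNV = 0.75,
                                                  INDEL = 0.90),
                       genome_spec = list(n_genes = 2000L,
                                          n_chromosomes = 2L,
                                          cds_mean_bp = 2000,
                                          cds_sdlog = 0.60,
                                          driver_fraction = 0.175),
                       panel_sizes = NULL) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              tumour_type_mix = tumour_type_mix,
              tmb_distribution = tmb_distribution,
              driver_enrichment = driver_enrichment,
              variant_mix = variant_mix,
              nonsynonymous_fraction = nonsynonymous_fraction,
              genome_spec = genome_spec,
              panel_sizes = panel_sizes)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$tumour_type_mix) == 0L) {
    stop("tumour_type_mix is empty", call. = FALSE)
  }
  if (abs(sum(cfg$tumour_type_mix) - 1) > 1e-9) {
    stop("tumour_type_mix proportions must sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$variant_mix) - 1) > 1e-9) {
    stop("variant_mix proportions must sum to 1", call. = FALSE)
  }
  miss <- setdiff(names(cfg$tumour_type_mix), names(cfg$tmb_distribution))
  if (length(miss)) {
    stop("tmb_distribution missing for type(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!isTRUE(cfg$driver_enrichment >= 1)) {
    stop("driver_enrichment must be >= 1", call. = FALSE)
  }
  if (any(cfg$variant_mix < 0) || any(cfg$nonsynonymous_fraction < 0) ||
      any(cfg$nonsynonymous_fraction > 1)) {
    stop("invalid rate in variant_mix / nonsynonymous_fraction",
         call. = FALSE)
  }
  invisible(cfg)
}

# deterministic per-sample stream: exact in double precision below 2^53
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65011 * 33013 + i) %% 2147483629)
}

#' Generate a miniature genome annotation
#'
#' Non-overlapping genes on a small number of chromosomes, each with
#' 1-3 transcripts. The first transcript of a gene carries all of its
#' exons; additional transcripts are 5' exon subsets, so the union of a
#' gene's CDS equals its longest ORF — a deliberate simplification that
#' keeps footprint arithmetic exactly checkable. A configured fraction
#' of genes is flagged as drivers (the pool panels are built from).
#'
#' @param genome_spec see [sim_config()].
#' @param seed integer seed; fixed seed gives byte-identical GTF output.
#' @param gtf optional path; when given the annotation is written as GTF.
#' @return list of class `sim_annotation`: `annotation`
#'   ([gene_annotation()]), `genes` (gene table with `cds_bp`, `driver`),
#'   `exons` (per-gene exon layout), `union_mb`, `contigs`, `gtf`.
#' @export
generate_annotation <- function(genome_spec, seed, gtf = NULL) {
  gs <- genome_spec
  n <- as.integer(gs$n_genes)
  if (is.na(n) || n < 10L) stop("n_genes must be >= 10", call. = FALSE)
  n_chrom <- as.integer(gs$n_chromosomes %||% 2L)
  set.seed(as.integer(seed))
  cds_bp <- pmax(150, round(stats::rlnorm(
    n, log(gs$cds_mean_bp) - gs$cds_sdlog^2 / 2, gs$cds_sdlog)))
  n_ex <- pmin(sample(1:4, n, replace = TRUE), pmax(1L, cds_bp %/% 120L))
  n_tx <- sample(1:3, n, replace = TRUE)
  chrom_of <- rep_len(seq_len(n_chrom), n)
  cursor <- numeric(n_chrom)
  genes <- vector("list", n)
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    e <- n_ex[i]
    w <- stats::runif(e, 0.5, 1.5)
    lens <- floor(cds_bp[i] * w / sum(w))
    lens[1L] <- lens[1L] + cds_bp[i] - sum(lens)
    introns <- if (e > 1L) sample(100:400, e - 1L, replace = TRUE) else integer()
    ch <- chrom_of[i]
    g_start <- cursor[ch] + sample(500:1500, 1L)
    ex_start <- g_start + cumsum(c(0, lens[-e] + introns))
    ex_end <- ex_start + lens
    cursor[ch] <- ex_end[e]
    genes[[i]] <- c(chrom = ch, start = g_start, end = ex_end[e],
                    n_exons = e, n_tx = n_tx[i])
    exons[[i]] <- cbind(start = ex_start, end = ex_end)
  }
  if (!is.null(gs$chrom_length_bp) && any(cursor > gs$chrom_length_bp)) {
    stop("infeasible packing: genes exceed chromosome length ",
         gs$chrom_length_bp, call. = FALSE)
  }
  gt <- as.data.frame(do.call(rbind, genes))
  gene_id <- sprintf("G%05d", seq_len(n))
  gene_name <- sprintf("GENE%05d", seq_len(n))
  chrom_name <- paste0("chr", gt$chrom)
  n_drivers <- max(1L, round((gs$driver_fraction %||% 0.15) * n))
  driver <- logical(n)
  driver[sample(n, n_drivers)] <- TRUE

  # extra transcripts: 5' exon-subset truncations of transcript 1
  ks_list <- lapply(seq_len(n), function(i) {
    c(gt$n_exons[i],
      if (gt$n_tx[i] > 1L) sample(seq_len(gt$n_exons[i]),
                                  gt$n_tx[i] - 1L, replace = TRUE))
  })
  gene_rep <- rep(seq_len(n), vapply(ks_list, function(k) as.integer(sum(k)), 0L))
  exon_idx <- unlist(lapply(ks_list, function(ks)
    unlist(lapply(ks, seq_len))), use.names = FALSE)
  tx_num <- unlist(lapply(ks_list, function(ks)
    rep(seq_along(ks), ks)), use.names = FALSE)
  ex_starts <- lapply(exons, function(m) m[, "start"])
  ex_ends <- lapply(exons, function(m) m[, "end"])
  flat_idx <- function(xs) {
    off <- cumsum(c(0L, vapply(xs, length, 0L)))[gene_rep]
    unlist(xs, use.names = FALSE)[off + exon_idx]
  }
  cds <- data.frame(
    chrom = chrom_name[gene_rep],
    start = flat_idx(ex_starts),
    end = flat_idx(ex_ends),
    gene_id = gene_id[gene_rep],
    gene_name = gene_name[gene_rep],
    transcript_id = sprintf("%s.T%d", gene_id[gene_rep], tx_num),
    stringsAsFactors = FALSE)
  ann <- gene_annotation(cds)
  contigs <- stats::setNames(
    vapply(seq_len(n_chrom), function(ch)
      max(gt$end[gt$chrom == ch]) + 10000, numeric(1L)),
    paste0("chr", seq_len(n_chrom)))
  gi_rep <- rep(seq_len(n), vapply(exons, nrow, 0L))
  exon_tab <- data.frame(gene_idx = gi_rep, chrom = chrom_name[gi_rep],
                         start = unlist(ex_starts, use.names = FALSE),
                         end = unlist(ex_ends, use.names = FALSE),
                         stringsAsFactors = FALSE)
  exon_tab$len <- exon_tab$end - exon_tab$start
  # exome-wide cumulative coding coordinate used to map draws to bases
  # (rows are already in gene order, exons ascending within gene)
  exon_tab$cum_start <- cumsum(c(0, exon_tab$len[-nrow(exon_tab)]))
  genes_df <- data.frame(gene_id = gene_id, gene_name = gene_name,
                         chrom = chrom_name, start = gt$start, end = gt$end,
                         cds_bp = as.numeric(cds_bp), driver = driver,
                         cds_cum_start = exon_tab$cum_start[
                           !duplicated(exon_tab$gene_idx)],
                         stringsAsFactors = FALSE)
  out <- structure(list(annotation = ann, genes = genes_df,
                        exons = exon_tab,
                        union_mb = sum(cds_bp) / 1e6,
                        contigs = contigs, gtf = gtf),
                   class = "sim_annotation")
  if (!is.null(gtf)) write_sim_gtf(out, gtf)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_sim_gtf <- function(sim_ann, path) {
  cds <- sim_ann$annotation$cds
  g <- sim_ann$genes
  attr_gene <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
  gene_lines <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\t%s",
                        g$chrom, g$start + 1, g$end, attr_gene)
  tx_key <- !duplicated(cds$transcript_id)
  tx <- cds[tx_key, ]
  tx_end <- tapply(cds$end, cds$transcript_id, max)[tx$transcript_id]
  tx_start <- tapply(cds$start, cds$transcript_id, min)[tx$transcript_id]
  attr_tx <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                     tx$gene_id, tx$gene_name, tx$transcript_id)
  tx_lines <- sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t+\t.\t%s",
                      tx$chrom, as.integer(tx_start) + 1, as.integer(tx_end),
                      attr_tx)
  attr_cds <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                      cds$gene_id, cds$gene_name, cds$transcript_id)
  cds_lines <- sprintf("%s\tsim\tCDS\t%d\t%d\t.\t+\t0\t%s",
                       cds$chrom, cds$start + 1, cds$end, attr_cds)
  writeLines(c("##gff-version 2", gene_lines, tx_lines, cds_lines), path)
  invisible(path)
}

#' Generate panel gene lists from a simulated annotation
#'
#' Emulates commercial panel designs as nested, driver-biased gene
#' subsets: each panel takes as many genes as possible from a shuffled
#' driver pool, topped up from a shuffled non-driver pool. Default panel
#' gene counts follow the seven commercial products, spanning a
#' largest-to-smallest footprint ratio of about 1.9.
#'
#' @param sim_ann a `sim_annotation` from [generate_annotation()].
#' @param seed integer seed for the pool shuffles.
#' @param sizes named integer vector of panel gene counts.
#' @param dir optional directory; when given each panel is written as
#'   `<dir>/<name>.txt` (one symbol per line).
#' @return named list of gene-name character vectors.
#' @export
generate_panels <- function(sim_ann, seed,
                            sizes = c(FoundationOne = 324L,
                                      `MSK-IMPACT` = 468L,
                                      Caris = 592L,
                                      TempusXT = 596L,
                                      ThermoFisher = 409L,
                                      NeoGenomics = 340L,
                                      Cancerplex = 435L),
                            dir = NULL) {
  g <- sim_ann$genes
  if (any(sizes > nrow(g))) {
    stop("requested panel larger than the gene pool (", nrow(g), " genes)",
         call. = FALSE)
  }
  set.seed(derive_seed(seed, 999983L))
  drv <- sample(g$gene_name[g$driver])
  oth <- sample(g$gene_name[!g$driver])
  panels <- lapply(sizes, function(s) {
    nd <- min(s, length(drv))
    c(drv[seq_len(nd)], if (s > nd) oth[seq_len(s - nd)])
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(panels)) {
      writeLines(c(sprintf("# panel %s (%d genes, simulated)", nm,
                           length(panels[[nm]])),
                   panels[[nm]]),
                 file.path(dir, paste0(nm, ".txt")))
    }
  }
  panels
}

random_bases <- function(n) {
  vapply(n, function(k)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1L))
}

mutate_bases <- function(x) {
  # substitute every base with a different one
  vapply(strsplit(x, ""), function(b) {
    paste(vapply(b, function(bb)
      sample(setdiff(c("A", "C", "G", "T"), bb), 1L), character(1L)),
      collapse = "")
  }, character(1L))
}

#' Simulate the somatic variants of one sample
#'
#' Draws the sample's target exome TMB from its tumour type's
#' (possibly hypermutator-inflated) log-normal, a Poisson coding
#' mutation count with expectation TMB x CDS-union-Mb, and places
#' mutations over coding bases with per-gene rates multiplied by the
#' driver enrichment for driver genes. Classes follow the configured
#' SNV/MNV/indel mixture; non-synonymous status is Bernoulli with the
#' per-class probability.
#'
#' @param config a [sim_config()].
#' @param sim_ann a `sim_annotation`.
#' @param sample_id sample label.
#' @param tumour_type one of the configured tumour types.
#' @param vcf optional path for the sorted VCF (INFO keys `NS`, `CLASS`).
#' @param rng_seed integer stream seed; by default derived from
#'   `config$seed` and the sample id's digits.
#' @return list: `variants` (data frame with an extra `gene_name`
#'   bookkeeping column), `truth` (one-row data frame: sample_id,
#'   tumour_type, target_tmb, exome_count, ns_count).
#' @export
simulate_sample <- function(config, sim_ann, sample_id, tumour_type,
                            vcf = NULL, rng_seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            tumour_type %in% names(config$tmb_distribution))
  if (is.null(rng_seed)) {
    digits <- as.numeric(gsub("\\D", "", sample_id))
    rng_seed <- derive_seed(config$seed,
                            if (is.na(digits)) 0 else digits %% 1e6)
  }
  set.seed(rng_seed)
  d <- config$tmb_distribution[[tumour_type]]
  tmb <- stats::rlnorm(1L, d$meanlog, d$sdlog)
  if (stats::runif(1L) < d$hyper_fraction) tmb <- tmb * d$hyper_multiplier
  n_mut <- stats::rpois(1L, tmb * sim_ann$union_mb)
  g <- sim_ann$genes
  w <- g$cds_bp * ifelse(g$driver, config$driver_enrichment, 1)
  if (n_mut > 0L) {
    gi <- sample.int(nrow(g), n_mut, replace = TRUE, prob = w)
    off <- floor(stats::runif(n_mut) * g$cds_bp[gi])
    # redraw colliding coding positions (cosmetic; collisions are rare)
    for (iter in 1:20) {
      dup <- duplicated(g$cds_cum_start[gi] + off)
      if (!any(dup)) break
      gi[dup] <- sample.int(nrow(g), sum(dup), replace = TRUE, prob = w)
      off[dup] <- floor(stats::runif(sum(dup)) * g$cds_bp[gi[dup]])
    }
    glob <- g$cds_cum_start[gi] + off
    ex <- sim_ann$exons
    row <- findInterval(glob, ex$cum_start)
    pos0 <- ex$start[row] + (glob - ex$cum_start[row])
    vclass <- sample(names(config$variant_mix), n_mut, replace = TRUE,
                     prob = config$variant_mix)
    ns <- stats::runif(n_mut) < config$nonsynonymous_fraction[vclass]
    ref <- alt <- character(n_mut)
    for (k in seq_len(n_mut)) {
      switch(vclass[k],
        SNV = {
          ref[k] <- random_bases(1L)
          alt[k] <- mutate_bases(ref[k])
        },
        MNV = {
          ref[k] <- random_bases(2L)
          alt[k] <- mutate_bases(ref[k])
        },
        INDEL = {
          anchor <- random_bases(1L)
          len <- sample(1:6, 1L)
          if (stats::runif(1L) < 0.5) {           # insertion
            ref[k] <- anchor
            alt[k] <- paste0(anchor, random_bases(len))
          } else {                                 # deletion
            ref[k] <- paste0(anchor, random_bases(len))
            alt[k] <- anchor
          }
        })
    }
    variants <- data.frame(sample_id = sample_id,
                           chrom = ex$chrom[row],
                           pos = pos0 + 1,
                           ref = ref, alt = alt, vclass = vclass,
                           non_synonymous = ns,
                           gene_name = g$gene_name[gi],
                           stringsAsFactors = FALSE)
    variants <- variants[order(variants$chrom, variants$pos), ]
    rownames(variants) <- NULL
  } else {
    variants <- data.frame(sample_id = character(), chrom = character(),
                           pos = numeric(), ref = character(),
                           alt = character(), vclass = character(),
                           non_synonymous = logical(),
                           gene_name = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(vcf)) write_sample_vcf(variants, vcf, sim_ann$contigs)
  list(variants = variants,
       truth = data.frame(sample_id = sample_id, tumour_type = tumour_type,
                          target_tmb = tmb,
                          exome_count = n_mut,
                          ns_count = sum(variants$non_synonymous),
                          stringsAsFactors = FALSE))
}

write_sample_vcf <- function(variants, path, contigs) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelTMBsim",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           '##INFO=<ID=NS,Number=1,Type=Integer,Description="Non-synonymous (1) or synonymous (0) coding variant">',
           '##INFO=<ID=CLASS,Number=1,Type=String,Description="Variant class: SNV, MNV or INDEL">',
           '##FILTER=<ID=PASS,Description="All filters passed">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tNS=%d;CLASS=%s",
            variants$chrom, as.integer(variants$pos), variants$ref,
            variants$alt, as.integer(variants$non_synonymous),
            variants$vclass)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a full synthetic cohort
#'
#' Generates the miniature annotation, the seven panel gene lists, and
#' one somatic variant set per sample, together with exact bookkeeping
#' truth (per-sample coding mutation count, per-panel count,
#' non-synonymous count). With `dir` set, the on-disk layout is
#' `annotation.gtf`, `panels/*.txt`, `vcf/<sample>.vcf`, `metadata.tsv`,
#' `truth.tsv` and a `config.yaml` echo — everything the file-based
#' pipeline consumes.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return object of class `sim_cohort`: config, sim_ann, panels,
#'   variants (cohort data frame with `gene_name` bookkeeping), truth,
#'   metadata, dir.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  }
  sim_ann <- generate_annotation(config$genome_spec, config$seed,
                                 gtf = if (!is.null(dir))
                                   file.path(dir, "annotation.gtf"))
  panels <- if (is.null(config$panel_sizes)) {
    generate_panels(sim_ann, config$seed,
                    dir = if (!is.null(dir)) file.path(dir, "panels"))
  } else {
    generate_panels(sim_ann, config$seed, sizes = config$panel_sizes,
                    dir = if (!is.null(dir)) file.path(dir, "panels"))
  }
  set.seed(derive_seed(config$seed, 424243L))
  types <- sample(names(config$tumour_type_mix), config$n_samples,
                  replace = TRUE, prob = config$tumour_type_mix)
  ids <- sprintf("S%04d", seq_len(config$n_samples))
  res <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    res[[i]] <- simulate_sample(
      config, sim_ann, ids[i], types[i],
      vcf = if (!is.null(dir)) file.path(dir, "vcf", paste0(ids[i], ".vcf")),
      rng_seed = derive_seed(config$seed, i))
  }
  variants <- do.call(rbind, lapply(res, `[[`, "variants"))
  truth <- do.call(rbind, lapply(res, `[[`, "truth"))
  for (nm in names(panels)) {
    cnt <- rowsum(as.numeric(variants$gene_name %in% panels[[nm]]),
                  variants$sample_id)
    col <- stats::setNames(rep(0, length(ids)), ids)
    col[rownames(cnt)] <- cnt[, 1L]
    truth[[paste0("count_", nm)]] <- as.integer(col[truth$sample_id])
  }
  metadata <- data.frame(sample_id = ids, tumour_type = types,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  structure(list(config = config, sim_ann = sim_ann, panels = panels,
                 variants = variants, truth = truth, metadata = metadata,
                 dir = dir),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples, %d variants, %d panels, CDS union %.2f Mb%s\n",
              nrow(x$metadata), nrow(x$variants), length(x$panels),
              x$sim_ann$union_mb,
              if (is.null(x$dir)) "" else paste0(" [", x$dir, "]")))
  invisible(x)
}
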