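test_that("configuration validation catches inconsistent settings", {
  expect_error(sim_config(tumour_type_mix = c()), "empty")
  expect_error(sim_config(tumour_type_mix = c(colorectal = 0.6, skin = 0.6)),
               "sum to 1")
  expect_error(sim_config(variant_mix = c(SNV = 0.5, MNV = 0.2, INDEL = 0.2)),
               "sum to 1")
  expect_error(sim_config(driver_enrichment = 0.5), ">= 1")
  expect_error(sim_config(tumour_type_mix = c(brain = 1)),
               "tmb_distribution missing")
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- list(n_genes = 20L, n_chromosomes = 2L, cds_mean_bp = 500,
               cds_sdlog = 0.3, driver_fraction = 0.2)
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  generate_annotation(spec, seed = 9L, gtf = f1)
  sa <- generate_annotation(spec, seed = 9L, gtf = f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg <- small_config()
  v1 <- withr::local_tempfile(fileext = ".vcf")
  v2 <- withr::local_tempfile(fileext = ".vcf")
  simulate_sample(cfg, sa, "S0001", "skin", vcf = v1, rng_seed = 123L)
  simulate_sample(cfg, sa, "S0001", "skin", vcf = v2, rng_seed = 123L)
  expect_identical(readLines(v1), readLines(v2))
})

test_that("a minimal 10-gene annotation is generated and parseable", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  sa <- generate_annotation(list(n_genes = 10L, n_chromosomes = 1L,
                                 cds_mean_bp = 300, cds_sdlog = 0.2,
                                 driver_fraction = 0.2), seed = 2L, gtf = gtf)
  ann <- read_gene_models(gtf)
  expect_equal(length(unique(ann$cds$gene_id)), 10L)
  expect_error(generate_annotation(list(n_genes = 5L), seed = 1L), ">= 10")
  expect_error(
    generate_annotation(list(n_genes = 50L, n_chromosomes = 1L,
                             cds_mean_bp = 5000, cds_sdlog = 0.3,
                             driver_fraction = 0.1,
                             chrom_length_bp = 1e4), seed = 1L),
    "infeasible packing")
})

test_that("the CDS union tracks n_genes times the mean CDS length", {
  sa <- generate_annotation(list(n_genes = 500L, n_chromosomes = 2L,
                                 cds_mean_bp = 1500, cds_sdlog = 0.5,
                                 driver_fraction = 0.1), seed = 4L)
  expected <- 500 * 1500 / 1e6
  se <- expected * 0.5 / sqrt(500)  # lognormal mean SE, first order
  expect_lt(abs(sa$union_mb - expected), 4 * se + 0.02)
  # union equals the merged length of all CDS (transcripts are nested)
  expect_equal(sa$union_mb,
               interval_bp(sa$annotation$cds[, c("chrom", "start", "end")]) / 1e6)
})

test_that("default panels are nested driver-biased subsets with ~1.9 footprint span", {
  co <- default_cohort()
  panels <- co$panels
  expect_length(panels, 7L)
  expect_true(all(unlist(panels) %in% co$sim_ann$genes$gene_name))
  fs <- footprint_summary(lapply(names(panels), function(nm)
    build_panel_footprint(panels[[nm]], co$sim_ann$annotation, name = nm)))
  ratio <- max(fs$footprint_mb) / min(fs$footprint_mb)
  expect_gt(ratio, 1.9 * 0.85)
  expect_lt(ratio, 1.9 * 1.15)
  # driver genes shared across panels: smallest panel inside the driver pool
  drivers <- co$sim_ann$genes$gene_name[co$sim_ann$genes$driver]
  smallest <- panels[[which.min(fs$footprint_mb)]]
  expect_true(all(smallest %in% drivers))
  expect_error(generate_panels(co$sim_ann, 1L, sizes = c(huge = 10000L)),
               "larger than the gene pool")
})

test_that("tumour type assignment follows the configured mix", {
  co <- default_cohort()
  mix <- co$config$tumour_type_mix
  n <- nrow(co$metadata)
  counts <- table(factor(co$metadata$tumour_type, names(mix)))
  for (tt in names(mix)) {
    lo <- qbinom(0.005, n, mix[[tt]])
    hi <- qbinom(0.995, n, mix[[tt]])
    expect_gte(counts[[tt]], lo)
    expect_lte(counts[[tt]], hi)
  }
})

test_that("generator truth matches a pipeline recount exactly", {
  co <- small_cohort()
  cp <- cached("small_profiles", cohort_profiles(small_cohort()))
  pr <- cp$profiles
  m <- match(pr$sample_id, co$truth$sample_id)
  expect_identical(round(pr$exome_tmb * cp$exome$denominator_mb),
                   as.numeric(co$truth$exome_count[m]))
  for (nm in names(cp$panels)) {
    expect_identical(round(pr[[nm]] * cp$panels[[nm]]$footprint_mb),
                     as.numeric(co$truth[[paste0("count_", nm)]][m]))
  }
  expect_identical(pr$mutational_load, co$truth$ns_count[m])
})

test_that("driver enrichment inflates panel TMB relative to exome density", {
  # enrichment-free generation is unbiased: panel TMB ~ exome density
  co1 <- cached("enrich1", simulate_cohort(
    small_config(seed = 19L, n = 120L, enrichment = 1)))
  cp1 <- cohort_profiles(co1)
  d1 <- unlist(lapply(panel_columns(cp1$profiles), function(nm)
    cp1$profiles[[nm]] - cp1$profiles$exome_tmb))
  expect_lt(abs(mean(d1)), 3 * sd(d1) / sqrt(length(d1)))

  # strong enrichment shifts panel TMB up
  co4 <- cached("enrich4", simulate_cohort(
    small_config(seed = 19L, n = 120L, enrichment = 4)))
  cp4 <- cohort_profiles(co4)
  d4 <- unlist(lapply(panel_columns(cp4$profiles), function(nm)
    cp4$profiles[[nm]] - cp4$profiles$exome_tmb))
  expect_lt(t.test(d4, alternative = "greater")$p.value, 0.001)
  expect_gt(mean(d4), mean(d1))
})
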