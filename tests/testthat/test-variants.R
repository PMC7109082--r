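test_that("variant classification partitions alleles into SNV/MNV/INDEL", {
  expect_equal(classify_variant("A", "T"), "SNV")
  expect_equal(classify_variant("AT", "GC"), "MNV")
  expect_equal(classify_variant("A", "AT"), "INDEL")
  expect_equal(classify_variant("ATG", "A"), "INDEL")
  expect_equal(classify_variant(c("A", "AT", "A"), c("T", "GC", "AT")),
               c("SNV", "MNV", "INDEL"))
  expect_error(classify_variant("A", "A"), "differ")
  expect_error(classify_variant("", "T"), "empty")
})

write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##INFO=<ID=NS,Number=1,Type=Integer,Description="Non-synonymous flag">',
    '##FILTER=<ID=PASS,Description="ok">',
    '##FILTER=<ID=germline_filter,Description="germline evidence">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\tNS=1",
    "chr1\t200\t.\tG\tGTT\t.\tPASS\tNS=0",
    "chr1\t300\t.\tAT\tGC\t.\tPASS\tNS=1",
    "chr1\t400\t.\tC\tA\t.\tgermline_filter\tNS=1",
    "chr1\t500\t.\tA\tT,AT\t.\tPASS\tNS=1"), path)
  path
}

test_that("VCF reading filters records, splits ALT alleles and reads the NS flag", {
  path <- write_fixture_vcf(withr::local_tempfile(fileext = ".vcf"))
  v <- read_somatic_vcf(path, sample_id = "s1")
  # germline_filter record excluded; multi-allelic record split in two
  expect_equal(nrow(v), 5L)
  expect_equal(v$vclass[v$pos == 100], "SNV")
  expect_equal(v$vclass[v$pos == 200], "INDEL")
  expect_equal(v$vclass[v$pos == 300], "MNV")
  expect_false(400 %in% v$pos)
  expect_equal(sort(v$vclass[v$pos == 500]), c("INDEL", "SNV"))
  expect_equal(v$non_synonymous[v$pos == 200], FALSE)
  expect_true(all(v$sample_id == "s1"))
  expect_error(read_somatic_vcf(withr::local_tempfile(lines = "not a vcf")),
               "malformed|unreadable")
})

test_that("NS flag is left unset when the INFO key is absent", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    "chr1\t10\t.\tA\tG\t.\tPASS\t."), path)
  v <- read_somatic_vcf(path)
  expect_true(is.na(v$non_synonymous))
  expect_error(mutational_load(v), "non-synonymous")
})

test_that("footprint membership uses the any-overlap rule on the reference span", {
  fp <- data.frame(chrom = "chr1", start = 50, end = 150)
  expect_true(in_footprint(toy_variants("chr1", 100), fp))
  expect_false(in_footprint(toy_variants("chr1", 151), fp))
  # 10 bp deletion straddling the right footprint boundary
  del <- toy_variants("chr1", 145, ref = "ACGTACGTAC", alt = "A")
  expect_true(in_footprint(del, fp))
  # anchored just past the end: no overlap
  del2 <- toy_variants("chr1", 151, ref = "ACGTACGTAC", alt = "A")
  expect_false(in_footprint(del2, fp))
  expect_false(in_footprint(toy_variants("chr2", 100), fp))
})

test_that("membership agrees with a per-base linear scan and is invariant to interval layout", {
  set.seed(99)
  fp <- merge_intervals(random_intervals(20, span = 2000L))
  n <- 300
  v <- toy_variants(sample(c("chrA", "chrB"), n, TRUE),
                    sample.int(2100L, n, TRUE),
                    ref = replicate(n, paste(rep("A", sample(1:10, 1)),
                                             collapse = "")),
                    alt = "C")
  v$vclass <- NULL  # classification irrelevant here
  got <- in_footprint(v, fp)
  expect_equal(got, bf_in_footprint(v, fp))

  # order invariance
  expect_equal(in_footprint(v, fp[sample(nrow(fp)), ]), got)
  # splitting an interval into adjacent halves changes nothing
  split_fp <- do.call(rbind, lapply(seq_len(nrow(fp)), function(i) {
    mid <- floor((fp$start[i] + fp$end[i]) / 2)
    if (mid > fp$start[i] && mid < fp$end[i]) {
      data.frame(chrom = fp$chrom[i], start = c(fp$start[i], mid),
                 end = c(mid, fp$end[i]))
    } else fp[i, ]
  }))
  expect_equal(in_footprint(v, split_fp), got)
})
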