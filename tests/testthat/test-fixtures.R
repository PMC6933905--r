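# The synthetic-fixture generator and its ground-truth manifest.

test_that("the same spec and seed reproduce byte-identical files", {
  spec <- mixed_fixture_spec(seed = 9L)
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture(spec, d1)
  generate_fixture(spec, d2)
  for (f in c("ref.fa", "target.bed", "snps.vcf", "reads.bam")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = paste("bytes of", f))
  }
})

test_that("a variant planted outside every region is rejected", {
  expect_error(fixture_spec(
    regions = data.frame(chrom = "chr1", start = 100L, end = 200L,
                         depth = 10L, regime = "exact",
                         stringsAsFactors = FALSE),
    variants = data.frame(chrom = "chr1", pos = 50L, alt = "G", vaf = 0.5,
                          stringsAsFactors = FALSE)),
    "outside every region")
})

test_that("depth-exact regions have the planted depth at every position", {
  spec <- fixture_spec(seed = 21L, contigs = c(chr1 = 400L),
                       regions = data.frame(chrom = "chr1", start = 80L,
                                            end = 150L, depth = 25L,
                                            regime = "exact",
                                            stringsAsFactors = FALSE))
  fx <- generate_fixture(spec, tempfile())
  res <- pileup_target(fx$bam, fx$bed, fx$fasta, min_base_quality = 0L,
                       min_mapping_quality = 0L)
  expect_equal(res$pileup$depth, rep(25, 70))
})

test_that("the manifest agrees with the brute-force oracle on both sides of dedup", {
  fx <- mixed_fixture()
  tgt <- read_target(fx$bed)
  m <- fx$manifest
  exact_pos <- paste(m$chrom, m$pos)
  # the two chr1 regions overlap; the manifest carries one row per
  # region-position, the oracle one per position: align on first occurrence
  first <- !duplicated(exact_pos)
  for (dd in c(FALSE, TRUE)) {
    orc <- oracle_pileup(fx$bam, tgt, filter_config(0L, 0L, dd))
    rows <- match(exact_pos[first], paste(orc$chrom, orc$pos))
    side <- if (dd) "post_" else "pre_"
    expect_identical(
      unname(as.matrix(m[first, paste0(side, count_cols)])),
      count_matrix(orc[rows, ]),
      label = paste("manifest", side, "counts"))
  }
})

test_that("a duplicate group of size 5 collapses to one fragment", {
  spec <- fixture_spec(seed = 33L, contigs = c(chr1 = 400L),
                       regions = data.frame(chrom = "chr1", start = 100L,
                                            end = 160L, depth = 8L,
                                            regime = "exact",
                                            stringsAsFactors = FALSE),
                       dup_groups = list(list(region = 1L, size = 5L,
                                              type = "single", strand = "F",
                                              clips = rep(0L, 5))))
  fx <- generate_fixture(spec, tempfile())
  pre <- pileup_target(fx$bam, fx$bed, fx$fasta, min_base_quality = 0L,
                       min_mapping_quality = 0L)
  post <- pileup_target(fx$bam, fx$bed, fx$fasta, min_base_quality = 0L,
                        min_mapping_quality = 0L, duplicates_filter = TRUE)
  expect_equal(pre$pileup$depth, rep(8 + 5, 60))
  expect_equal(post$pileup$depth, rep(8 + 1, 60))
  expect_equal(post$log$n_duplicate_reads, 4L)
})

test_that("planted allele fractions surface in the pileup", {
  spec <- fixture_spec(seed = 55L, contigs = c(chr1 = 400L),
                       regions = data.frame(chrom = "chr1", start = 100L,
                                            end = 160L, depth = 40L,
                                            regime = "exact",
                                            stringsAsFactors = FALSE),
                       variants = data.frame(chrom = "chr1", pos = 130L,
                                             alt = "T", vaf = 0.25,
                                             stringsAsFactors = FALSE))
  fx <- generate_fixture(spec, tempfile())
  res <- pileup_target(fx$bam, fx$bed, fx$fasta, fx$vcf,
                       min_base_quality = 0L, min_mapping_quality = 0L)
  sn <- res$snps
  expect_equal(nrow(sn), 1L)
  expect_equal(sn$af, 0.25)          # deterministic planting: exact fraction
  expect_equal(sn$genotype, "0/1")
})

test_that("a fixture spec file round-trips through the text format", {
  spec_text <- c("seed 13",
                 "contig chr1 400",
                 "region chr1 100 160 10 exact",
                 "variant chr1 120 G 0.5",
                 "dupgroup 1 single 3 0,2,0 R",
                 "qual 20,30,40",
                 "mapq 0,60")
  p <- tempfile()
  writeLines(spec_text, p)
  spec <- read_fixture_spec(p)
  expect_s3_class(spec, "fixture_spec")
  expect_equal(spec$seed, 13L)
  expect_equal(spec$regions$end, 160L)
  expect_equal(spec$dup_groups[[1]]$clips, c(0L, 2L, 0L))
  expect_equal(spec$dup_groups[[1]]$strand, "R")
  fx <- generate_fixture(spec, tempfile())
  expect_true(file.exists(fx$bam))
  expect_error(read_fixture_spec(tempfile()), "not found")
})
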