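# Accumulator semantics, region partitioning and engine/oracle agreement.

test_that("aligned bases increment the matching strand counter", {
  region <- region_row(start = 100L, end = 110L)
  reads <- mk_read("r1", 100L, "10M", seq = strrep("A", 10))
  pp <- pileup_region(reads, region, strrep("C", 10),
                      filter_config(0L, 0L))
  expect_equal(pp$A_fwd, rep(1L, 10))
  expect_equal(rowSums(count_matrix(pp)), rep(1, 10))
  # reverse strand goes to the reverse counters
  rev <- mk_read("r2", 100L, "10M", seq = strrep("G", 10), reverse = TRUE)
  pp2 <- pileup_region(rev, region, strrep("C", 10), filter_config(0L, 0L))
  expect_equal(pp2$G_rev, rep(1L, 10))
  expect_equal(pp2$G_fwd, rep(0L, 10))
})

test_that("deletions leave the spanned positions untouched", {
  region <- region_row(start = 100L, end = 112L)
  reads <- mk_read("r1", 100L, "5M2D5M", seq = strrep("T", 10))
  pp <- pileup_region(reads, region, strrep("A", 12), filter_config(0L, 0L))
  expect_equal(pp$T_fwd, c(rep(1L, 5), 0L, 0L, rep(1L, 5)))
  # insertions and clips contribute nothing anywhere
  ins <- mk_read("r2", 100L, "3S4M2I4M3S", seq = strrep("C", 16))
  pp2 <- pileup_region(ins, region, strrep("A", 12), filter_config(0L, 0L))
  expect_equal(sum(pp2$C_fwd), 8L)
})

test_that("the base-quality filter is per base, not per read", {
  region <- region_row(start = 0L, end = 10L)
  qual <- rep(30L, 10); qual[4] <- 5L
  reads <- mk_read("r1", 0L, "10M", seq = strrep("A", 10), qual = qual)
  pp <- pileup_region(reads, region, strrep("C", 10),
                      filter_config(min_base_quality = 20L))
  expect_equal(pp$A_fwd, c(1L, 1L, 1L, 0L, rep(1L, 6)))
})

test_that("N read bases are never counted", {
  region <- region_row(start = 0L, end = 4L)
  reads <- mk_read("r1", 0L, "4M", seq = "ANGT")
  pp <- pileup_region(reads, region, "ACGT", filter_config(0L, 0L))
  expect_equal(rowSums(count_matrix(pp)), c(1, 0, 1, 1))
})

test_that("empty input yields all-zero rows for every position", {
  region <- region_row(start = 50L, end = 60L)
  pp <- pileup_region(mk_read("x", 0L, "5M")[0, ], region, strrep("A", 10))
  expect_equal(nrow(pp), 10L)
  expect_true(all(count_matrix(pp) == 0L))
  expect_equal(pp$pos, 50:59)
})

test_that("reference window length mismatches are a hard error", {
  region <- region_row(start = 0L, end = 10L)
  expect_error(pileup_region(mk_read("r", 0L, "5M"), region, "ACGT"),
               "length")
})

test_that("partition_target balances contiguous chunks", {
  tgt <- data.frame(chrom = "chr1", start = 0:9 * 100L, end = 0:9 * 100L + 50L,
                    index = 1:10, stringsAsFactors = FALSE)
  expect_equal(partition_target(tgt, 1L), list(1:10))
  p3 <- partition_target(tgt, 3L)
  expect_equal(lengths(p3), c(4L, 3L, 3L))
  expect_equal(unlist(p3), 1:10)
  p12 <- partition_target(tgt, 12L)
  expect_equal(sum(lengths(p12) == 0L), 2L)
  expect_equal(sort(unlist(p12)), 1:10)
})

test_that("engine counts match the brute-force oracle on a mixed fixture", {
  fx <- mixed_fixture()
  tgt <- read_target(fx$bed)
  pre <- oracle_load_reads(fx$bam)
  for (dd in c(FALSE, TRUE)) {
    res <- pileup_target(fx$bam, fx$bed, fx$fasta,
                         min_base_quality = 20L, min_mapping_quality = 1L,
                         duplicates_filter = dd)
    orc <- oracle_pileup(pre, tgt, filter_config(20L, 1L, dd))
    expect_same_counts(res$pileup, orc)
  }
})

test_that("raising quality thresholds never increases any count", {
  fx <- mixed_fixture()
  base <- pileup_target(fx$bam, fx$bed, fx$fasta, min_base_quality = 0L,
                        min_mapping_quality = 0L)
  for (cfg in list(c(13L, 0L), c(30L, 0L), c(0L, 20L), c(30L, 40L))) {
    res <- pileup_target(fx$bam, fx$bed, fx$fasta,
                         min_base_quality = cfg[1],
                         min_mapping_quality = cfg[2])
    expect_true(all(count_matrix(res$pileup) <= count_matrix(base$pileup)))
  }
})

test_that("per-position depth equals the sum of the base counts", {
  fx <- mixed_fixture()
  res <- pileup_target(fx$bam, fx$bed, fx$fasta)
  expect_equal(res$pileup$depth, unname(rowSums(count_matrix(res$pileup))))
  expect_equal(res$pileup$A + res$pileup$C + res$pileup$G + res$pileup$T,
               res$pileup$depth)
})

test_that("overlapping regions appear once per position in the pileup", {
  fx <- mixed_fixture()   # regions 1 and 2 overlap on chr1 [140,160)
  res <- pileup_target(fx$bam, fx$bed, fx$fasta)
  key <- paste(res$pileup$chrom, res$pileup$pos)
  expect_false(any(duplicated(key)))
  tgt <- read_target(fx$bed)
  n_distinct <- length(unique(unlist(lapply(seq_len(nrow(tgt)), function(i)
    paste(tgt$chrom[i], tgt$start[i]:(tgt$end[i] - 1L))))))
  expect_equal(nrow(res$pileup), n_distinct)
  # but both regions get their own statistics row
  expect_equal(nrow(res$regions), nrow(tgt))
})

test_that("merged worker output reproduces the single-worker result", {
  fx <- mixed_fixture()
  one <- pileup_target(fx$bam, fx$bed, fx$fasta, fx$vcf, threads = 1L)
  for (th in c(2L, 4L)) {
    multi <- pileup_target(fx$bam, fx$bed, fx$fasta, fx$vcf, threads = th)
    expect_identical(multi$pileup, one$pileup)
    expect_identical(multi$regions, one$regions)
    expect_identical(multi$snps, one$snps)
  }
})

test_that("chromosome naming mismatches between BED and BAM fail loudly", {
  fx <- mixed_fixture()
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t100\t160", bed)
  expect_error(pileup_target(fx$bam, bed, fx$fasta), "naming must match")
})
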