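# Output dialects, golden files and the CLI surface.

empty_result <- function() {
  structure(list(
    target = read_target(local({
      p <- tempfile(); writeLines(character(0), p); p
    })),
    regions = pilecov:::region_stats(
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 index = integer(0), stringsAsFactors = FALSE),
      list(), 0.5),
    pileup = NULL, snps = NULL,
    params = list(), log = list()), class = "pileup_result")
}

test_that("an empty target produces header-only files", {
  res <- empty_result()
  p <- tempfile()
  write_region_file(res$regions, p)
  expect_equal(length(readLines(p)), 1L)
  write_pileup_file(res$pileup, p, "full")
  expect_equal(length(readLines(p)), 1L)
})

test_that("the region file has one data row per region", {
  fx <- mixed_fixture()
  res <- pileup_target(fx$bam, fx$bed, fx$fasta)
  p <- tempfile()
  write_region_file(res$regions, p)
  lines <- readLines(p)
  expect_equal(length(lines), nrow(res$regions) + 1L)
  # 1-based start in text output
  first <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(first[2]), res$regions$start[1] + 1L)
  expect_equal(as.integer(first[3]), res$regions$end[1])
})

test_that("full pileup row count equals the distinct target positions", {
  fx <- mixed_fixture()
  res <- pileup_target(fx$bam, fx$bed, fx$fasta)
  p <- tempfile()
  write_pileup_file(res$pileup, p, "full")
  tgt <- read_target(fx$bed)
  n_distinct <- length(unique(unlist(lapply(seq_len(nrow(tgt)), function(i)
    paste(tgt$chrom[i], tgt$start[i]:(tgt$end[i] - 1L))))))
  expect_equal(length(readLines(p)) - 1L, n_distinct)
})

test_that("alt-support output is a row-subset of the full pileup", {
  fx <- mixed_fixture()
  res <- pileup_target(fx$bam, fx$bed, fx$fasta)
  full_p <- tempfile(); pabs_p <- tempfile()
  write_pileup_file(res$pileup, full_p, "full")
  write_pileup_file(res$pileup, pabs_p, "pabs")
  full <- readLines(full_p)[-1]
  pabs <- readLines(pabs_p)[-1]
  expect_gt(length(pabs), 0L)
  expect_true(all(pabs %in% full))
  # pabs rows are exactly the rows with a positive VAF
  af <- as.numeric(vapply(strsplit(full, "\t"), `[[`, character(1), 8L))
  expect_equal(length(pabs), sum(af > 0))
})

test_that("engine outputs are byte-identical to the committed goldens", {
  fx <- mixed_fixture()
  res <- pileup_target(fx$bam, fx$bed, fx$fasta, fx$vcf,
                       min_base_quality = 20L, min_mapping_quality = 1L)
  prefix <- tempfile()
  write_outputs(res, prefix, "abcd")
  for (suffix in c("regions", "pileup", "pabs", "snps")) {
    got <- readBin(paste0(prefix, ".", suffix, ".txt"), "raw", n = 1e7)
    want <- readBin(test_path("goldens", paste0("mixed.", suffix, ".txt")),
                    "raw", n = 1e7)
    expect_identical(got, want,
                     label = paste0("bytes of .", suffix, ".txt"))
  }
})

test_that("mode selection accepts letters and digits and validates", {
  fx <- mixed_fixture()
  res <- pileup_target(fx$bam, fx$bed, fx$fasta)
  prefix <- tempfile()
  files <- write_outputs(res, prefix, "13")
  expect_equal(length(files), 2L)
  expect_true(file.exists(paste0(prefix, ".regions.txt")))
  expect_true(file.exists(paste0(prefix, ".pabs.txt")))
  expect_error(write_outputs(res, prefix, "z"), "invalid output mode")
  expect_error(write_outputs(res, prefix, "d"), "no VCF")
})

test_that("the CLI runs end to end and reports errors with nonzero status", {
  fx <- mixed_fixture()
  prefix <- tempfile()
  status <- suppressMessages(run_cli(c(
    "pileup", "--bam", fx$bam, "--bed", fx$bed, "--fasta", fx$fasta,
    "--vcf", fx$vcf, "--mode", "abcd", "--out-prefix", prefix)))
  expect_equal(status, 0L)
  expect_true(all(file.exists(paste0(prefix, c(".regions.txt", ".pileup.txt",
                                               ".pabs.txt", ".snps.txt")))))
  # --help succeeds
  expect_equal(suppressMessages(run_cli("--help")), 0L)
  # missing required flag
  st <- suppressMessages(run_cli(c("pileup", "--bed", fx$bed,
                                   "--fasta", fx$fasta)))
  expect_gt(st, 0L)
  # SNP mode without a VCF
  st2 <- suppressMessages(run_cli(c("pileup", "--bam", fx$bam, "--bed",
                                    fx$bed, "--fasta", fx$fasta,
                                    "--mode", "d")))
  expect_gt(st2, 0L)
  # unknown subcommand
  expect_equal(suppressMessages(run_cli("frobnicate")), 2L)
})

test_that("repeated runs write byte-identical files", {
  fx <- mixed_fixture()
  p1 <- tempfile(); p2 <- tempfile()
  for (p in c(p1, p2)) {
    res <- pileup_target(fx$bam, fx$bed, fx$fasta, fx$vcf)
    write_outputs(res, p, "abcd")
  }
  for (suffix in c(".regions.txt", ".pileup.txt", ".pabs.txt", ".snps.txt")) {
    expect_identical(readBin(paste0(p1, suffix), "raw", 1e7),
                     readBin(paste0(p2, suffix), "raw", 1e7))
  }
})
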