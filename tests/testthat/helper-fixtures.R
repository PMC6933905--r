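# Shared builders for in-memory read tables and on-disk fixtures.

# query length of a CIGAR (test-side arithmetic, kept deliberately simple)
cigar_qlen <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  sum(as.integer(sub(".$", "", toks[grepl("[MIS=X]$", toks)])))
}

# one row of the engine's read-table representation
mk_read <- function(qname, pos, cigar, reverse = FALSE, chrom = "chr1",
                    seq = NULL, qual = NULL, mapq = 60L, paired = FALSE,
                    mate_unmapped = FALSE) {
  qlen <- cigar_qlen(cigar)
  if (is.null(seq)) seq <- strrep("A", qlen)
  if (is.null(qual)) qual <- rep(30L, qlen)
  stopifnot(nchar(seq) == qlen, length(qual) == qlen)
  df <- data.frame(qname = qname, chrom = chrom, pos = as.integer(pos),
                   mapq = as.integer(mapq), cigar = cigar, reverse = reverse,
                   paired = paired, mate_unmapped = mate_unmapped,
                   stringsAsFactors = FALSE)
  df$seq <- seq
  df$qual <- list(as.integer(qual))
  df
}

mk_reads <- function(...) do.call(rbind, list(...))

region_row <- function(chrom = "chr1", start = 0L, end = 10L) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             index = 1L, stringsAsFactors = FALSE)
}

# standard mixed fixture used by several test files
mixed_fixture_spec <- function(seed = 42L) {
  fixture_spec(
    seed = seed,
    contigs = c(chr1 = 700L, chr2 = 500L),
    regions = data.frame(
      chrom = c("chr1", "chr1", "chr2"),
      start = c(100L, 140L, 150L),     # first two overlap on [140,160)
      end = c(160L, 200L, 230L),
      depth = c(12L, 10L, 15L),
      regime = c("exact", "exact", "random"),
      stringsAsFactors = FALSE),
    variants = data.frame(chrom = c("chr1", "chr2"), pos = c(130L, 180L),
                          alt = c("G", "T"), vaf = c(0.5, 0.3),
                          stringsAsFactors = FALSE),
    dup_groups = list(list(region = 1L, size = 3L, type = "single",
                           strand = "F", clips = c(0L, 2L, 0L))),
    qual_values = c(10L, 20L, 30L, 40L),
    mapq_values = c(0L, 30L, 60L))
}

mixed_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "pilecov-mixed-fixture")
      cache <<- generate_fixture(mixed_fixture_spec(), dir)
    }
    cache
  }
})

count_cols <- c("A_fwd", "C_fwd", "G_fwd", "T_fwd",
                "A_rev", "C_rev", "G_rev", "T_rev")

count_matrix <- function(pileup) {
  unname(as.matrix(pileup[, count_cols]))
}

expect_same_counts <- function(engine_pileup, oracle_pileup) {
  eng <- engine_pileup[, c("chrom", "pos", count_cols)]
  orc <- oracle_pileup[, c("chrom", "pos", count_cols)]
  expect_equal(eng$chrom, orc$chrom)
  expect_equal(eng$pos, orc$pos)
  expect_identical(count_matrix(eng), count_matrix(orc))
}
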