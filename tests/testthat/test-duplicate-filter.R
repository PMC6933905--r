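# Clip-corrected duplicate keying and the streaming filter.

test_that("unclipped 5' position corrects for soft clips on both strands", {
  expect_equal(unclipped_five_prime(100L, "5S95M", FALSE), 95L)
  expect_equal(unclipped_five_prime(100L, "100M", FALSE), 100L)
  # reverse strand: 5' end is the last aligned base plus the trailing clip
  expect_equal(unclipped_five_prime(100L, "95M5S", TRUE), 199L)
  expect_equal(unclipped_five_prime(100L, "95M", TRUE), 194L)
  # deletions extend the reference span, insertions do not
  expect_equal(unclipped_five_prime(100L, "40M5D40M10S", TRUE),
               100L + 85L - 1L + 10L)
  expect_equal(unclipped_five_prime(100L, "40M5I40M", FALSE), 100L)
  expect_error(unclipped_five_prime(100L, "*", FALSE), "unmapped")
})

test_that("identical single-end reads share a key; differing spans do not", {
  r1 <- mk_read("a", 100L, "50M")
  r2 <- mk_read("b", 100L, "50M")
  r3 <- mk_read("c", 100L, "30M")   # same 5', different span
  keys <- duplicate_key(mk_reads(r1, r2, r3))
  expect_identical(keys[1], keys[2])
  expect_false(keys[3] == keys[1])
})

test_that("clip-shifted copies share the uncorrected read's key", {
  plain <- mk_read("a", 100L, "50M")
  clipped <- mk_read("b", 105L, "5S45M")   # same unclipped start and span
  keys <- duplicate_key(mk_reads(plain, clipped))
  expect_identical(keys[1], keys[2])
  # reverse-strand counterpart: trailing clip
  plain_r <- mk_read("c", 100L, "50M", reverse = TRUE)
  clip_r <- mk_read("d", 100L, "45M5S", reverse = TRUE)
  keys_r <- duplicate_key(mk_reads(plain_r, clip_r))
  expect_identical(keys_r[1], keys_r[2])
  # strand is part of the key
  expect_false(keys[1] == keys_r[1])
})

pair_of <- function(qname, fwd_pos, fwd_cigar, rev_pos, rev_cigar,
                    qual_f = NULL, qual_r = NULL) {
  mk_reads(
    mk_read(qname, fwd_pos, fwd_cigar, reverse = FALSE, paired = TRUE,
            qual = qual_f),
    mk_read(qname, rev_pos, rev_cigar, reverse = TRUE, paired = TRUE,
            qual = qual_r))
}

test_that("both mates of a pair get one key, and PCR copies collide", {
  pp <- rbind(pair_of("p1", 100L, "5S45M", 180L, "50M"),
              pair_of("p2", 105L, "10S40M", 180L, "48M2S"))
  keys <- duplicate_key(pp)
  expect_identical(keys[1], keys[2])     # mates agree
  expect_identical(keys[1], keys[3])     # clip-corrected copy collides
  expect_identical(keys[3], keys[4])
})

test_that("pairs with equal 5' ends but different template extents differ", {
  pp <- rbind(pair_of("p1", 100L, "50M", 250L, "50M"),
              pair_of("p2", 100L, "50M", 230L, "50M"))
  keys <- duplicate_key(pp)
  expect_false(keys[1] == keys[3])
})

test_that("filter keeps one representative per key and is idempotent", {
  reads <- mk_reads(
    mk_read("a", 100L, "50M"),
    mk_read("b", 100L, "50M"),
    mk_read("c", 100L, "50M"),
    mk_read("d", 100L, "50M"),
    mk_read("e", 100L, "50M"),
    mk_read("f", 300L, "50M"))
  out <- filter_duplicates(reads)
  expect_equal(nrow(out$reads), 2L)
  expect_equal(out$n_fragments, 2L)
  expect_equal(out$n_suppressed_reads, 4L)
  again <- filter_duplicates(out$reads)
  expect_identical(again$reads, out$reads)
  expect_equal(again$n_suppressed_reads, 0L)
  # degenerate input
  empty <- filter_duplicates(reads[0, , drop = FALSE])
  expect_equal(nrow(empty$reads), 0L)
  single <- filter_duplicates(mk_read("z", 5L, "10M"))
  expect_equal(nrow(single$reads), 1L)
})

test_that("the highest-total-base-quality fragment is the representative", {
  reads <- mk_reads(
    mk_read("lo", 100L, "10M", qual = rep(10L, 10)),
    mk_read("hi", 100L, "10M", qual = rep(40L, 10)),
    mk_read("mid", 100L, "10M", qual = rep(20L, 10)))
  out <- filter_duplicates(reads)
  expect_equal(out$reads$qname, "hi")
  # ties fall back to first occurrence in coordinate order
  tied <- mk_reads(
    mk_read("first", 100L, "10M"),
    mk_read("second", 100L, "10M"))
  expect_equal(filter_duplicates(tied)$reads$qname, "first")
})

test_that("mates are kept or suppressed together", {
  pp <- rbind(pair_of("keep", 100L, "50M", 200L, "50M",
                      qual_f = rep(40L, 50), qual_r = rep(40L, 50)),
              pair_of("drop", 100L, "50M", 200L, "50M",
                      qual_f = rep(10L, 50), qual_r = rep(10L, 50)))
  out <- filter_duplicates(pp)
  expect_setequal(out$reads$qname, "keep")
  expect_equal(nrow(out$reads), 2L)
})

test_that("emitted fragment count equals the number of distinct keys", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 40L
    rows <- lapply(seq_len(n), function(i) {
      pos <- sample(c(100L, 150L, 200L), 1)
      clip <- sample(c(0L, 3L), 1)
      cigar <- if (clip > 0) paste0(clip, "S", 30L - clip, "M") else "30M"
      mk_read(paste0("r", rep, "_", i),
              if (clip > 0) pos + clip else pos, cigar,
              reverse = runif(1) < 0.5,
              qual = sample(10:40, 30L, replace = TRUE))
    })
    reads <- do.call(rbind, rows)
    out <- filter_duplicates(reads)
    expect_equal(nrow(out$reads), length(unique(duplicate_key(reads))))
  }
})
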