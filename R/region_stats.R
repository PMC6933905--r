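# Region-level summary statistics: mean depth of coverage, GC content of
# the reference, and the maximal-coverage sub-region ("peak") statistic
# compensating for read fall-off at capture-region edges.

#' Mean depth of coverage of a region
#'
#' @param depths Per-position total depths (post-filter).
#' @return Arithmetic mean.
#' @export
mean_coverage <- function(depths) {
  stopifnot(length(depths) > 0)
  mean(depths)
}

#' GC content of a reference window
#'
#' Fraction of G/C bases among unambiguous bases; N is excluded from both
#' numerator and denominator. A window of only N returns 0 with a warning.
#'
#' @param bases Uppercase reference sequence (string).
#' @return Real in [0, 1].
#' @export
gc_content <- function(bases) {
  stopifnot(nchar(bases) > 0)
  freq <- Biostrings::letterFrequency(Biostrings::DNAString(bases),
                                      letters = c("A", "C", "G", "T"))
  denom <- sum(freq)
  if (denom == 0) {
    warning("window contains no unambiguous bases; GC content set to 0")
    return(0)
  }
  unname((freq[["C"]] + freq[["G"]]) / denom)
}

# round-half-up; base round() is round-half-even, which would make window
# lengths depend on parity
round_half_up <- function(x) floor(x + 0.5)

#' Maximal-coverage sub-region of a depth profile
#'
#' Finds the contiguous window of length \code{max(1, round(fraction *
#' length))} (round half up) with the highest mean depth, via a single
#' sliding-sum pass. Ties are broken by the leftmost window.
#'
#' @param depths Per-position total depths of one region.
#' @param fraction Window length as a fraction of the region length, in
#'   (0, 1].
#' @return A list with \code{sub_start}, \code{sub_end} (0-based half-open
#'   offsets within the region) and \code{sub_mean_cov}.
#' @export
peak_subregion <- function(depths, fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single value in (0, 1]")
  }
  n <- length(depths)
  stopifnot(n > 0)
  w <- max(1L, as.integer(round_half_up(fraction * n)))
  cs <- c(0, cumsum(as.numeric(depths)))
  sums <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  best <- which.max(sums)  # leftmost maximum
  list(sub_start = best - 1L, sub_end = best - 1L + w,
       sub_mean_cov = sums[best] / w)
}

# Assemble the region statistics table from per-region pileups.
region_stats <- function(target, pileups, fraction) {
  rows <- lapply(seq_len(nrow(target)), function(i) {
    pp <- pileups[[i]]
    depths <- pileup_depth(pp)
    peak <- peak_subregion(depths, fraction)
    gc <- gc_content(paste(pp$ref, collapse = ""))
    data.frame(
      chrom = target$chrom[i],
      start = target$start[i],
      end = target$end[i],
      sub_start = target$start[i] + peak$sub_start,
      sub_end = target$start[i] + peak$sub_end,
      mean_cov = mean(depths),
      sub_mean_cov = peak$sub_mean_cov,
      gc_content = gc,
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sub_start = integer(0),
                      sub_end = integer(0), mean_cov = numeric(0),
                      sub_mean_cov = numeric(0), gc_content = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
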