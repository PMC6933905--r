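# CIGAR arithmetic used by the pileup accumulator and the duplicate filter.
# All positions are 0-based internally; text outputs convert to 1-based.

#' Parse a CIGAR string into operation/length vectors
#'
#' @param cigar A single CIGAR string (e.g. \code{"5S95M"}).
#' @return A list with integer vector \code{len} and character vector
#'   \code{op}, in order of appearance.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(list(len = integer(0), op = character(0)))
  }
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar)
  }
  list(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op  = sub("^\\d+", "", toks)
  )
}

# reference bases consumed by each op class
.ops_ref   <- c("M", "D", "N", "=", "X")
.ops_query <- c("M", "I", "S", "=", "X")
.ops_align <- c("M", "=", "X")

cigar_reference_span <- function(cig) sum(cig$len[cig$op %in% .ops_ref])
cigar_query_length   <- function(cig) sum(cig$len[cig$op %in% .ops_query])

leading_softclip <- function(cig) {
  # soft clip at the query start; may follow a hard clip
  i <- which(cig$op != "H")[1]
  if (!is.na(i) && cig$op[i] == "S") cig$len[i] else 0L
}

trailing_softclip <- function(cig) {
  n <- length(cig$op)
  i <- rev(which(cig$op != "H"))[1]
  if (!is.na(i) && cig$op[i] == "S") cig$len[i] else 0L
}

#' Soft-clip-corrected 5' alignment position
#'
#' Returns the coordinate the read's 5' end would have had without
#' soft-clipping: for a forward-strand read, the leftmost aligned position
#' minus the leading soft-clip length; for a reverse-strand read, the last
#' aligned reference position plus the trailing soft-clip length (the 5' end
#' of a reverse read is its right end). This is the coordinate signature
#' PCR duplicates share even when their clipping differs.
#'
#' @param pos 0-based leftmost aligned reference position.
#' @param cigar CIGAR string of the alignment.
#' @param reverse Logical; \code{TRUE} for a reverse-strand alignment.
#' @return 0-based clip-corrected 5' position (integer).
#' @examples
#' unclipped_five_prime(100L, "5S95M", FALSE)  # 95
#' unclipped_five_prime(100L, "95M5S", TRUE)   # 199
#' @export
unclipped_five_prime <- function(pos, cigar, reverse) {
  stopifnot(length(pos) == 1L, !is.na(pos))
  cig <- parse_cigar(cigar)
  if (length(cig$op) == 0L) stop("unmapped read has no 5' position")
  if (reverse) {
    pos + cigar_reference_span(cig) - 1L + trailing_softclip(cig)
  } else {
    pos - leading_softclip(cig)
  }
}

# Clip-corrected extent [ustart, uend] (0-based inclusive) of one alignment.
unclipped_extent <- function(pos, cig) {
  c(
    pos - leading_softclip(cig),
    pos + cigar_reference_span(cig) - 1L + trailing_softclip(cig)
  )
}

# Expand the aligned (M/=/X) part of one alignment into parallel vectors of
# reference positions and 1-based query indices. D/N consume reference only,
# I/S consume query only, H/P consume nothing.
cigar_aligned_pairs <- function(pos, cig) {
  refpos <- integer(0)
  qidx <- integer(0)
  r <- pos
  q <- 1L
  for (k in seq_along(cig$op)) {
    op <- cig$op[k]
    len <- cig$len[k]
    if (op %in% .ops_align) {
      refpos <- c(refpos, seq.int(r, length.out = len))
      qidx <- c(qidx, seq.int(q, length.out = len))
      r <- r + len
      q <- q + len
    } else if (op %in% c("D", "N")) {
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    }
  }
  list(refpos = refpos, qidx = qidx)
}
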