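# On-the-fly PCR-duplicate filter. Fragments (read pairs or single-end
# reads) are clustered by a clip-corrected coordinate signature and one
# representative per cluster is kept, during traversal, without writing a
# duplicate-marked alignment file.

#' Duplicate signature of each fragment in a read table
#'
#' Computes the duplicate-cluster key for every read: for paired reads whose
#' mate is present in the table, a canonically ordered pair of
#' (chromosome, clip-corrected 5' position, strand) signatures plus the
#' total mapping size (absolute distance between the two mates' clip-corrected
#' 5' coordinates); for single-end reads, or paired reads whose mate is
#' unmapped or absent, the read's own (chromosome, clip-corrected 5' position,
#' strand) plus its clip-corrected reference span. Both mates of one pair
#' receive the identical key.
#'
#' @param reads A read table as built by the engine (one row per alignment
#'   record), with columns \code{qname}, \code{chrom}, \code{pos},
#'   \code{cigar}, \code{reverse}, \code{paired}, \code{mate_unmapped}.
#' @return Character vector of keys, one per row of \code{reads}.
#' @export
duplicate_key <- function(reads) {
  n <- nrow(reads)
  if (n == 0L) return(character(0))
  u5 <- integer(n)
  span <- integer(n)
  for (i in seq_len(n)) {
    cig <- parse_cigar(reads$cigar[i])
    ext <- unclipped_extent(reads$pos[i], cig)
    span[i] <- ext[2] - ext[1] + 1L
    u5[i] <- if (reads$reverse[i]) ext[2] else ext[1]
  }
  strand <- ifelse(reads$reverse, "R", "F")
  sig <- paste(reads$chrom, u5, strand, sep = ":")
  single_key <- paste("S", sig, span, sep = "|")

  key <- single_key
  pairable <- reads$paired & !reads$mate_unmapped
  if (any(pairable)) {
    groups <- split(which(pairable), reads$qname[pairable])
    for (idx in groups) {
      if (length(idx) != 2L) next  # mate outside window: single-end fallback
      a <- idx[1]; b <- idx[2]
      ord <- order(c(sig[a], sig[b]))
      two <- c(sig[a], sig[b])[ord]
      size <- if (reads$chrom[a] == reads$chrom[b]) abs(u5[a] - u5[b]) else 0L
      key[idx] <- paste("P", two[1], two[2], size, sep = "|")
    }
  }
  key
}

#' Filter duplicate fragments from a read table
#'
#' Clusters fragments by \code{\link{duplicate_key}} and keeps exactly one
#' representative per cluster: the fragment with the highest total base
#' quality (summed over both mates for pairs), ties broken by first
#' occurrence in coordinate order. Both mates of a kept pair are kept;
#' both mates of a suppressed pair are suppressed. Existing duplicate flags
#' in the input are ignored — the filter is self-contained.
#'
#' @param reads Read table (see \code{\link{duplicate_key}}) with an
#'   additional list column \code{qual} of integer base-quality vectors.
#' @return A list with \code{reads} (the surviving rows, input order
#'   preserved), \code{n_fragments} (distinct keys seen) and
#'   \code{n_suppressed_reads}.
#' @export
filter_duplicates <- function(reads) {
  n <- nrow(reads)
  if (n == 0L) {
    return(list(reads = reads, n_fragments = 0L, n_suppressed_reads = 0L))
  }
  key <- duplicate_key(reads)

  # fragment = both mates of a pair when present, else the single read
  pairable <- reads$paired & !reads$mate_unmapped
  frag_id <- ifelse(pairable, paste0("q:", reads$qname), paste0("r:", seq_len(n)))
  frag_rows <- split(seq_len(n), frag_id)
  frag_key <- vapply(frag_rows, function(idx) key[idx[1]], character(1))
  frag_sumq <- vapply(frag_rows, function(idx) {
    sum(vapply(reads$qual[idx], function(q) sum(as.numeric(q)), numeric(1)))
  }, numeric(1))
  frag_minpos <- vapply(frag_rows, function(idx) min(reads$pos[idx]), numeric(1))
  frag_first <- vapply(frag_rows, function(idx) min(idx), numeric(1))

  keep_rows <- logical(n)
  for (idx in split(seq_along(frag_rows), frag_key)) {
    best <- idx[order(-frag_sumq[idx], frag_minpos[idx], frag_first[idx])[1]]
    keep_rows[frag_rows[[best]]] <- TRUE
  }
  list(
    reads = reads[keep_rows, , drop = FALSE],
    n_fragments = length(unique(frag_key)),
    n_suppressed_reads = sum(!keep_rows)
  )
}
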