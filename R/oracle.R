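# Naive brute-force pileup used only for validation: independent
# character-by-character CIGAR walking, offline global duplicate grouping,
# and a per-position double loop over reads. Deliberately the simplest
# possible implementation; shares only the filter *definitions* with the
# engine, not code.

# walk one CIGAR string one character at a time
oracle_walk_cigar <- function(pos, cigar) {
  refpos <- integer(0); qidx <- integer(0)
  r <- pos; q <- 1L; num <- 0L
  lead_clip <- NA_integer_; trail_clip <- 0L
  seen_align <- FALSE
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch >= "0" && ch <= "9") {
      num <- num * 10L + as.integer(ch)
      next
    }
    if (ch %in% c("M", "=", "X")) {
      for (k in seq_len(num)) {
        refpos <- c(refpos, r); qidx <- c(qidx, q)
        r <- r + 1L; q <- q + 1L
      }
      seen_align <- TRUE
      trail_clip <- 0L
    } else if (ch %in% c("D", "N")) {
      r <- r + num
      trail_clip <- 0L
    } else if (ch == "I") {
      q <- q + num
      trail_clip <- 0L
    } else if (ch == "S") {
      if (!seen_align && is.na(lead_clip)) lead_clip <- num
      trail_clip <- num
      q <- q + num
    }
    num <- 0L
  }
  if (is.na(lead_clip)) lead_clip <- 0L
  list(refpos = refpos, qidx = qidx, lead_clip = lead_clip,
       trail_clip = trail_clip)
}

#' Load and pre-walk all reads of a BAM for the brute-force oracle
#'
#' Reads the whole file once, decodes flags, and walks each CIGAR with the
#' oracle's own character-by-character walker. The result can be passed to
#' \code{\link{oracle_pileup}} in place of the path to avoid re-reading the
#' file when sweeping filter configurations.
#'
#' @param bam_path BAM file path.
#' @return A list of per-read records (class \code{oracle_reads}).
#' @export
oracle_load_reads <- function(bam_path) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq", "qual"))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  quals <- lapply(as.character(res$qual), function(q) utf8ToInt(q) - 33L)
  out <- list()
  for (i in seq_along(res$flag)) {
    f <- res$flag[i]
    if (bitwAnd(f, 0x4) > 0 || bitwAnd(f, 0x100) > 0 ||
        bitwAnd(f, 0x800) > 0 || bitwAnd(f, 0x200) > 0 || is.na(res$pos[i])) {
      next
    }
    walk <- oracle_walk_cigar(res$pos[i] - 1L, res$cigar[i])
    out[[length(out) + 1L]] <- list(
      qname = res$qname[i],
      chrom = as.character(res$rname[i]),
      pos = res$pos[i] - 1L,
      mapq = res$mapq[i],
      reverse = as.character(res$strand[i]) == "-",
      paired = bitwAnd(f, 0x1) > 0,
      mate_unmapped = bitwAnd(f, 0x8) > 0,
      bases = strsplit(as.character(res$seq[i]), "")[[1]],
      qual = quals[[i]],
      walk = walk)
  }
  structure(out, class = "oracle_reads")
}

# independent clip-corrected signature (same stated definition as the
# engine's duplicate key, recomputed from the oracle's own CIGAR walk)
oracle_signature <- function(rd) {
  if (length(rd$walk$refpos) == 0L) return(NULL)
  ustart <- rd$pos - rd$walk$lead_clip
  uend <- max(rd$walk$refpos) + rd$walk$trail_clip
  u5 <- if (rd$reverse) uend else ustart
  list(sig = paste(rd$chrom, u5, if (rd$reverse) "R" else "F", sep = ":"),
       u5 = u5, span = uend - ustart + 1L)
}

oracle_dedup <- function(reads) {
  n <- length(reads)
  if (n == 0L) return(reads)
  sig <- lapply(reads, oracle_signature)
  qn <- vapply(reads, `[[`, character(1), "qname")
  pairable <- vapply(reads, function(rd) rd$paired && !rd$mate_unmapped,
                     logical(1))
  key <- character(n)
  frag <- character(n)
  for (i in seq_len(n)) {
    key[i] <- paste("S", sig[[i]]$sig, sig[[i]]$span, sep = "|")
    frag[i] <- paste0("r:", i)
  }
  for (q in unique(qn[pairable])) {
    idx <- which(pairable & qn == q)
    if (length(idx) != 2L) next
    two <- sort(c(sig[[idx[1]]]$sig, sig[[idx[2]]]$sig))
    same_chrom <- reads[[idx[1]]]$chrom == reads[[idx[2]]]$chrom
    size <- if (same_chrom) abs(sig[[idx[1]]]$u5 - sig[[idx[2]]]$u5) else 0L
    key[idx] <- paste("P", two[1], two[2], size, sep = "|")
    frag[idx] <- paste0("q:", q)
  }
  keep <- logical(n)
  frag_ids <- unique(frag)
  frag_key <- vapply(frag_ids, function(fid) key[frag == fid][1], character(1))
  frag_sumq <- vapply(frag_ids, function(fid)
    sum(unlist(lapply(which(frag == fid), function(i)
      as.numeric(reads[[i]]$qual)))), numeric(1))
  frag_minpos <- vapply(frag_ids, function(fid)
    min(vapply(which(frag == fid), function(i) reads[[i]]$pos, numeric(1))),
    numeric(1))
  frag_first <- vapply(frag_ids, function(fid) min(which(frag == fid)),
                       numeric(1))
  for (k in unique(frag_key)) {
    cand <- which(frag_key == k)
    best <- cand[order(-frag_sumq[cand], frag_minpos[cand],
                       frag_first[cand])[1]]
    keep[frag == frag_ids[best]] <- TRUE
  }
  reads[keep]
}

#' Brute-force pileup oracle
#'
#' Recomputes per-position strand-specific counts by the simplest possible
#' double loop over reads and positions, with its own CIGAR walking and an
#' offline, global duplicate grouping. Intended for validating the engine
#' on small synthetic inputs; not for production use.
#'
#' @param bam_path BAM file (read in full), or the preloaded result of
#'   \code{\link{oracle_load_reads}}.
#' @param target Target regions data.frame (\code{chrom}, \code{start},
#'   \code{end}).
#' @param config A \code{\link{filter_config}}.
#' @return A data.frame with one row per target position (positions in
#'   overlapping regions deduplicated, first region wins) and the eight
#'   strand-specific count columns.
#' @export
oracle_pileup <- function(bam_path, target, config = filter_config()) {
  reads <- if (inherits(bam_path, "oracle_reads")) bam_path
           else oracle_load_reads(bam_path)
  reads <- Filter(function(rd) rd$mapq >= config$min_mapping_quality, reads)
  if (config$duplicates_filter) reads <- oracle_dedup(reads)

  out <- NULL
  for (i in seq_len(nrow(target))) {
    chrom <- target$chrom[i]
    positions <- seq.int(target$start[i], target$end[i] - 1L)
    counts <- matrix(0L, nrow = length(positions), ncol = 8L,
                     dimnames = list(NULL, COUNT_COLS))
    for (rd in reads) {
      if (rd$chrom != chrom) next
      for (j in seq_along(rd$walk$refpos)) {
        p <- rd$walk$refpos[j]
        row <- p - target$start[i] + 1L
        if (row < 1L || row > length(positions)) next
        base <- rd$bases[rd$walk$qidx[j]]
        if (!base %in% BASES) next
        if (rd$qual[rd$walk$qidx[j]] < config$min_base_quality) next
        col <- match(base, BASES) + 4L * as.integer(rd$reverse)
        counts[row, col] <- counts[row, col] + 1L
      }
    }
    out <- rbind(out, cbind(data.frame(chrom = chrom, pos = positions,
                                       stringsAsFactors = FALSE),
                            as.data.frame(counts)))
  }
  if (!is.null(out)) {
    out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
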