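# The pileup engine: traverses reads over the target, applies mapping/base
# quality filters and (optionally) the on-the-fly duplicate filter, and
# accumulates per-position, per-base, per-strand counts.

BASES <- c("A", "C", "G", "T")
COUNT_COLS <- c(paste0(BASES, "_fwd"), paste0(BASES, "_rev"))

#' Filter configuration for the pileup engine
#'
#' @param min_base_quality Minimum Phred base quality for a base to be
#'   counted (applied per base, not per read).
#' @param min_mapping_quality Minimum mapping quality for a read to enter
#'   the pileup.
#' @param duplicates_filter Apply the on-the-fly duplicate filter?
#' @return A list of class \code{filter_config}.
#' @export
filter_config <- function(min_base_quality = 20L, min_mapping_quality = 1L,
                          duplicates_filter = FALSE) {
  stopifnot(min_base_quality >= 0, min_mapping_quality >= 0)
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 duplicates_filter = isTRUE(duplicates_filter)),
            class = "filter_config")
}

# Convert one scanBam window result into the engine's read table.
# Unmapped, secondary, supplementary and QC-fail records are excluded always;
# records flagged as duplicates in the input are NOT excluded (the engine's
# own filter is self-contained). Returns the read table plus exclusion counts.
bam_records_to_reads <- function(res) {
  flag <- res$flag
  excl <- bitwAnd(flag, 0x4) > 0 |    # unmapped
    bitwAnd(flag, 0x100) > 0 |        # secondary
    bitwAnd(flag, 0x800) > 0 |        # supplementary
    bitwAnd(flag, 0x200) > 0          # qc fail
  keep <- !excl & !is.na(res$pos)
  quals <- lapply(as.character(res$qual), function(q) utf8ToInt(q) - 33L)
  reads <- data.frame(
    qname = res$qname[keep],
    chrom = as.character(res$rname)[keep],
    pos = res$pos[keep] - 1L,
    mapq = res$mapq[keep],
    cigar = res$cigar[keep],
    reverse = as.character(res$strand)[keep] == "-",
    paired = bitwAnd(flag[keep], 0x1) > 0,
    mate_unmapped = bitwAnd(flag[keep], 0x8) > 0,
    stringsAsFactors = FALSE)
  reads$seq <- as.character(res$seq)[keep]
  reads$qual <- quals[keep]
  list(reads = reads, n_records = length(flag), n_excluded = sum(excl))
}

# Fetch primary mapped alignments overlapping [start, end) on one chromosome.
read_bam_window <- function(bam_path, chrom, start, end) {
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq", "qual"),
    which = which)
  bam_records_to_reads(Rsamtools::scanBam(bam_path, param = param)[[1]])
}

# Expand the aligned bases of every read into one long table:
# refpos (0-based), base index 1..4 (NA for non-ACGT), qual, reverse.
# Works per CIGAR operation, not per base, so cost scales with the number
# of operations rather than R-level per-base iteration.
expand_alignments <- function(reads) {
  n <- nrow(reads)
  empty <- data.frame(refpos = integer(0), base = integer(0),
                      qual = integer(0), reverse = logical(0))
  if (n == 0L) return(empty)
  op_read <- integer(0); op_refstart <- integer(0)
  op_qstart <- integer(0); op_len <- integer(0)
  for (i in seq_len(n)) {
    cig <- parse_cigar(reads$cigar[i])
    ref_consumed <- ifelse(cig$op %in% .ops_ref, cig$len, 0L)
    q_consumed <- ifelse(cig$op %in% .ops_query, cig$len, 0L)
    aligned <- cig$op %in% .ops_align
    if (!any(aligned)) next
    ref_before <- cumsum(c(0L, ref_consumed))[seq_along(cig$op)]
    q_before <- cumsum(c(0L, q_consumed))[seq_along(cig$op)]
    op_read <- c(op_read, rep.int(i, sum(aligned)))
    op_refstart <- c(op_refstart, reads$pos[i] + ref_before[aligned])
    op_qstart <- c(op_qstart, 1L + q_before[aligned])
    op_len <- c(op_len, cig$len[aligned])
  }
  if (length(op_len) == 0L) return(empty)
  within <- sequence(op_len) - 1L
  refpos <- rep.int(op_refstart, op_len) + within
  qidx <- rep.int(op_qstart, op_len) + within
  ridx <- rep.int(op_read, op_len)
  # global query offsets into the concatenated sequence/quality vectors
  seqlen <- nchar(reads$seq)
  offset <- cumsum(c(0L, seqlen))[ridx]
  chars <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
  quals <- unlist(reads$qual, use.names = FALSE)
  data.frame(refpos = refpos,
             base = match(chars[offset + qidx], BASES),
             qual = quals[offset + qidx],
             reverse = reads$reverse[ridx])
}

# Count aligned bases over [start, end) into a length x 8 matrix
# (A,C,G,T forward then A,C,G,T reverse), applying the per-base quality
# threshold. Bases outside ACGT never count.
count_window <- function(expanded, start, end, min_base_quality) {
  len <- end - start
  keep <- !is.na(expanded$base) &
    expanded$refpos >= start & expanded$refpos < end &
    expanded$qual >= min_base_quality
  slot <- (expanded$base[keep] - 1L) + 4L * as.integer(expanded$reverse[keep])
  li <- 1L + (expanded$refpos[keep] - start) + len * slot
  counts <- matrix(tabulate(li, nbins = len * 8L), nrow = len, ncol = 8L)
  colnames(counts) <- COUNT_COLS
  counts
}

#' Per-position pileup of one target region
#'
#' Accumulates strand-specific A/C/G/T counts for every position of a
#' region from a set of alignments. The alignments are assumed to have
#' already passed the read-level filters (mapping quality, duplicate
#' filter); the base-quality filter is applied here, per base. Deletions,
#' skips, insertions and clips contribute to no position.
#'
#' @param reads Read table overlapping the region (engine representation).
#' @param region One-row data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param ref_bases Reference sequence of the region (uppercase string of
#'   length \code{end - start}).
#' @param config A \code{\link{filter_config}}.
#' @return Data.frame with one row per position: \code{chrom}, \code{pos}
#'   (0-based), \code{ref}, and the eight strand-specific counts.
#' @export
pileup_region <- function(reads, region, ref_bases, config = filter_config()) {
  len <- region$end - region$start
  if (nchar(ref_bases) != len) {
    stop("reference window length ", nchar(ref_bases),
         " does not match region length ", len)
  }
  expanded <- expand_alignments(reads)
  counts <- count_window(expanded, region$start, region$end,
                         config$min_base_quality)
  out <- data.frame(
    chrom = rep(region$chrom, len),
    pos = seq.int(region$start, length.out = len),
    ref = strsplit(ref_bases, "", fixed = TRUE)[[1]],
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts))
}

#' Partition the target into contiguous balanced chunks
#'
#' Splits the ordered region list into \code{n_workers} contiguous chunks
#' whose sizes differ by at most one (earlier chunks take the remainder).
#' Concatenating per-chunk results in order reproduces the single-worker
#' result exactly.
#'
#' @param target Target regions data.frame.
#' @param n_workers Number of chunks (>= 1).
#' @return A list of \code{n_workers} integer vectors of row indices (some
#'   possibly empty).
#' @export
partition_target <- function(target, n_workers) {
  stopifnot(n_workers >= 1)
  n <- nrow(target)
  sizes <- rep(n %/% n_workers, n_workers) +
    as.integer(seq_len(n_workers) <= n %% n_workers)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_workers), function(i) {
    if (sizes[i] == 0L) integer(0) else seq.int(starts[i], ends[i])
  })
}

# The traversal windows of one chunk: one contiguous window per chromosome
# block, spanning the chunk's regions on that chromosome.
chunk_windows <- function(regions) {
  if (nrow(regions) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, lapply(unique(regions$chrom), function(chrom) {
    sel <- regions$chrom == chrom
    data.frame(chrom = chrom, start = min(regions$start[sel]),
               end = max(regions$end[sel]), stringsAsFactors = FALSE)
  }))
}

# Process one chunk of regions. `window_reads` holds the reads of each of
# the chunk's traversal windows (one per chromosome block); the mapping
# quality and duplicate filters are applied over the whole window, so
# duplicate groups straddling a region boundary within the chunk are still
# collapsed.
process_chunk <- function(window_reads, regions, config, ref_seqs) {
  pileups <- vector("list", nrow(regions))
  stats <- list(n_records = 0L, n_excluded = 0L, n_mapq_filtered = 0L,
                n_duplicate_reads = 0L)
  if (nrow(regions) == 0L) {
    return(list(pileups = pileups, order = integer(0), stats = stats))
  }
  for (w in seq_along(window_reads)) {
    win <- window_reads[[w]]
    chrom <- win$chrom
    sel <- which(regions$chrom == chrom)
    reads <- win$reads
    stats$n_records <- stats$n_records + win$n_records
    stats$n_excluded <- stats$n_excluded + win$n_excluded
    low_mapq <- reads$mapq < config$min_mapping_quality
    stats$n_mapq_filtered <- stats$n_mapq_filtered + sum(low_mapq)
    reads <- reads[!low_mapq, , drop = FALSE]
    if (config$duplicates_filter) {
      dd <- filter_duplicates(reads)
      reads <- dd$reads
      stats$n_duplicate_reads <- stats$n_duplicate_reads + dd$n_suppressed_reads
    }
    expanded <- expand_alignments(reads)
    for (i in sel) {
      len <- regions$end[i] - regions$start[i]
      counts <- count_window(expanded, regions$start[i], regions$end[i],
                             config$min_base_quality)
      ref <- substring(ref_seqs[[chrom]], regions$start[i] + 1L,
                       regions$end[i])
      pp <- data.frame(
        chrom = rep(chrom, len),
        pos = seq.int(regions$start[i], length.out = len),
        ref = strsplit(ref, "", fixed = TRUE)[[1]],
        stringsAsFactors = FALSE)
      pileups[[i]] <- cbind(pp, as.data.frame(counts))
    }
  }
  list(pileups = pileups, order = regions$index, stats = stats)
}

#' Run the full pileup engine over a target
#'
#' Reads the four input artifacts, traverses the alignments region by
#' region (optionally in parallel over contiguous region chunks), applies
#' the configured filters, and returns region-level statistics, the
#' per-base pileup, and (when a VCF is supplied) SNP pileups with genotype
#' calls. Output is deterministic and identical for any number of workers.
#'
#' @param bam_path Coordinate-sorted, indexed BAM file.
#' @param bed_path Sorted BED file of target regions.
#' @param fasta_path Reference FASTA (indexed, or an index is created).
#' @param vcf_path Optional VCF of SNPs of interest within the target.
#' @param min_base_quality,min_mapping_quality,duplicates_filter See
#'   \code{\link{filter_config}}.
#' @param threads Number of region chunks processed in parallel (forked
#'   workers; results merged in target order).
#' @param region_fraction Fraction of each region's length used for the
#'   maximal-coverage sub-region statistic (default 0.5).
#' @param het_low,het_high,min_genotype_depth Genotyping thresholds, see
#'   \code{\link{genotype_call}}.
#' @return An object of class \code{pileup_result}: a list with
#'   \code{target}, \code{regions} (region statistics), \code{pileup}
#'   (per-position table, positions deduplicated across overlapping
#'   regions), \code{snps} (or \code{NULL}), \code{params} and \code{log}.
#' @export
pileup_target <- function(bam_path, bed_path, fasta_path, vcf_path = NULL,
                          min_base_quality = 20L, min_mapping_quality = 1L,
                          duplicates_filter = FALSE, threads = 1L,
                          region_fraction = 0.5,
                          het_low = 0.2, het_high = 0.8,
                          min_genotype_depth = 10L) {
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  config <- filter_config(min_base_quality, min_mapping_quality,
                          duplicates_filter)
  hdr <- bam_header_chroms(bam_path)
  target <- read_target(bed_path, chrom_order = hdr$chrom)
  snps <- if (!is.null(vcf_path)) read_snps(vcf_path, target) else NULL

  # reference: whole-contig cache for the chromosomes in the target
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  fa_info <- Rsamtools::seqinfo(fa)
  fa_chroms <- GenomeInfoDb::seqnames(fa_info)
  for (chrom in unique(target$chrom)) {
    if (!chrom %in% fa_chroms) stop("chromosome not present in FASTA: ", chrom)
    too_far <- target$end[target$chrom == chrom] >
      GenomeInfoDb::seqlengths(fa_info)[[chrom]]
    if (any(too_far)) {
      stop("target region beyond length of ", chrom, " in the FASTA")
    }
  }
  ref_seqs <- list()
  for (chrom in unique(target$chrom)) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      1L, GenomeInfoDb::seqlengths(fa_info)[[chrom]]))
    ref_seqs[[chrom]] <- toupper(as.character(Rsamtools::scanFa(fa, param = gr)[[1]]))
  }

  # one BAM pass over every chunk's traversal windows
  chunks <- partition_target(target, threads)
  chunk_regions <- lapply(chunks, function(rows) target[rows, , drop = FALSE])
  windows <- lapply(chunk_regions, chunk_windows)
  all_win <- do.call(rbind, windows)
  win_reads <- list()
  if (!is.null(all_win) && nrow(all_win) > 0L) {
    gr <- GenomicRanges::GRanges(all_win$chrom,
                                 IRanges::IRanges(all_win$start + 1L,
                                                  all_win$end))
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
               "mrnm", "mpos", "isize", "seq", "qual"),
      which = gr)
    scan <- Rsamtools::scanBam(bam_path, param = param)
    win_reads <- lapply(seq_len(nrow(all_win)), function(i) {
      c(bam_records_to_reads(scan[[i]]), list(chrom = all_win$chrom[i]))
    })
  }
  win_of_chunk <- split(
    seq_len(if (is.null(all_win)) 0L else nrow(all_win)),
    rep(seq_along(windows), vapply(windows, nrow, integer(1))))

  run_one <- function(k) {
    idx <- win_of_chunk[[as.character(k)]]
    process_chunk(win_reads[idx], chunk_regions[[k]], config, ref_seqs)
  }
  results <- if (threads > 1L) {
    parallel::mclapply(seq_along(chunks), run_one, mc.cores = threads)
  } else {
    lapply(seq_along(chunks), run_one)
  }

  pileups <- vector("list", nrow(target))
  stats <- list(n_records = 0L, n_excluded = 0L, n_mapq_filtered = 0L,
                n_duplicate_reads = 0L)
  for (res in results) {
    if (inherits(res, "try-error")) stop(res)
    for (i in seq_along(res$order)) {
      pileups[[res$order[i]]] <- res$pileups[[i]]
    }
    for (nm in names(stats)) stats[[nm]] <- stats[[nm]] + res$stats[[nm]]
  }

  regions <- region_stats(target, pileups, region_fraction)

  merged <- if (nrow(target)) do.call(rbind, pileups) else NULL
  if (!is.null(merged) && nrow(merged)) {
    # positions covered by overlapping regions appear once (first region wins)
    merged <- merged[!duplicated(paste(merged$chrom, merged$pos)), , drop = FALSE]
    rownames(merged) <- NULL
    merged <- derive_pileup(merged)
  }

  snp_calls <- if (!is.null(snps)) {
    call_snps(snps, merged, het_low, het_high, min_genotype_depth)
  } else NULL

  structure(list(
    target = target,
    regions = regions,
    pileup = merged,
    snps = snp_calls,
    params = list(min_base_quality = config$min_base_quality,
                  min_mapping_quality = config$min_mapping_quality,
                  duplicates_filter = config$duplicates_filter,
                  threads = as.integer(threads),
                  region_fraction = region_fraction,
                  het_low = het_low, het_high = het_high,
                  min_genotype_depth = as.integer(min_genotype_depth)),
    log = c(list(n_regions = nrow(target),
                 n_snps = if (is.null(snps)) NA_integer_ else nrow(snps)),
            stats)
  ), class = "pileup_result")
}

#' @export
print.pileup_result <- function(x, ...) {
  cat("Targeted pileup result\n")
  cat("  regions:           ", x$log$n_regions, "\n")
  cat("  target positions:  ", if (is.null(x$pileup)) 0L else nrow(x$pileup), "\n")
  if (!is.na(x$log$n_snps)) cat("  SNPs in target:    ", x$log$n_snps, "\n")
  cat("  filters: mbq >=", x$params$min_base_quality,
      "| mrq >=", x$params$min_mapping_quality,
      "| duplicates filter", if (x$params$duplicates_filter) "on" else "off", "\n")
  cat("  reads: ", x$log$n_records, "records,", x$log$n_excluded,
      "excluded,", x$log$n_mapq_filtered, "below mapq,",
      x$log$n_duplicate_reads, "duplicates suppressed\n")
  invisible(x)
}

#' @export
summary.pileup_result <- function(object, ...) {
  depth <- if (is.null(object$pileup)) numeric(0) else pileup_depth(object$pileup)
  out <- list(
    n_regions = object$log$n_regions,
    n_positions = length(depth),
    mean_coverage = if (length(depth)) mean(depth) else NA_real_,
    mean_region_coverage = if (nrow(object$regions)) mean(object$regions$mean_cov) else NA_real_,
    n_alt_positions = if (length(depth)) sum(!is.na(object$pileup$alt)) else 0L,
    log = object$log)
  class(out) <- "summary.pileup_result"
  out
}

#' @export
print.summary.pileup_result <- function(x, ...) {
  cat("Regions:", x$n_regions, " positions:", x$n_positions, "\n")
  cat("Mean per-base coverage:", format(x$mean_coverage, digits = 6), "\n")
  cat("Mean region coverage:  ", format(x$mean_region_coverage, digits = 6), "\n")
  cat("Positions with alternative support:", x$n_alt_positions, "\n")
  invisible(x)
}

# total depth per pileup row
pileup_depth <- function(pileup) {
  rowSums(as.matrix(pileup[, COUNT_COLS]))
}
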