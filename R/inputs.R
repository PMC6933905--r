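# Readers for the four input artifacts: BED target, VCF SNP list, reference
# FASTA, BAM header. Coordinates are BED-style 0-based half-open everywhere
# inside the engine; VCF positions are converted on read.

#' Read a sorted BED target file
#'
#' Reads a 3+ column tab-separated BED file into the engine's target
#' representation. Regions are kept exactly as given (overlapping or adjacent
#' intervals are not merged) and must arrive sorted: within a chromosome by
#' ascending start, chromosomes in contiguous blocks (optionally checked
#' against a supplied chromosome order, e.g. the BAM header order).
#'
#' @param bed_path Path to the BED file.
#' @param chrom_order Optional character vector giving the required
#'   chromosome order (typically from the BAM header). When \code{NULL},
#'   any block order is accepted but interleaved chromosomes are rejected.
#' @return A data.frame with columns \code{chrom}, \code{start} (0-based
#'   inclusive), \code{end} (0-based exclusive), \code{index} (ordinal in
#'   the target).
#' @export
read_target <- function(bed_path, chrom_order = NULL) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), index = integer(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 3L)) {
    stop("malformed BED line ", which(n_col < 3L)[1],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad)) {
    stop("invalid BED line ", bad[1], ": start (", start[bad[1]],
         ") must be < end (", end[bad[1]], ")")
  }
  bad <- which(start < 0L)
  if (length(bad)) stop("invalid BED line ", bad[1], ": negative start")

  # sortedness: ascending start within each chromosome block
  same_chrom <- chrom[-1] == chrom[-length(chrom)]
  decreasing <- c(FALSE, same_chrom & start[-1] < start[-length(start)])
  if (any(decreasing)) {
    stop("unsorted BED input at line ", which(decreasing)[1],
         ": start positions must be non-decreasing within a chromosome")
  }
  # chromosomes must form contiguous blocks
  blocks <- rle(chrom)$values
  if (anyDuplicated(blocks)) {
    dup <- blocks[duplicated(blocks)][1]
    first_bad <- which(chrom == dup & c(FALSE, !same_chrom))[1]
    stop("unsorted BED input at line ", first_bad,
         ": chromosome ", dup, " appears in non-contiguous blocks")
  }
  if (!is.null(chrom_order)) {
    missing <- setdiff(blocks, chrom_order)
    if (length(missing)) {
      stop("BED chromosome not present in BAM header: ",
           paste(missing, collapse = ", "),
           " (chromosome naming must match exactly)")
    }
    if (is.unsorted(match(blocks, chrom_order))) {
      off <- blocks[which(diff(match(blocks, chrom_order)) < 0)[1] + 1L]
      stop("unsorted BED input: chromosome ", off,
           " out of order relative to the BAM header")
    }
  }
  data.frame(chrom = chrom, start = start, end = end,
             index = seq_along(chrom), stringsAsFactors = FALSE)
}

#' Write target regions back to BED text
#'
#' @param target Data.frame as returned by \code{\link{read_target}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_target <- function(target, path) {
  writeLines(paste(target$chrom, target$start, target$end, sep = "\t"), path)
  invisible(path)
}

#' Read SNPs of interest from a VCF file
#'
#' Keeps only biallelic single-nucleotide records whose position falls inside
#' a target region. Indels, multi-allelic rows and rows with a missing REF or
#' ALT are skipped with a warning; records outside the target are dropped
#' with a logged count.
#'
#' @param vcf_path Path to a VCF file (only CHROM/POS/ID/REF/ALT are used).
#' @param target Target regions from \code{\link{read_target}}.
#' @return A data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{id}, \code{ref}, \code{alt}.
#' @export
read_snps <- function(vcf_path, target) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0), id = character(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  }
  chrom <- fix[, "CHROM"]
  pos1 <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  missing_allele <- is.na(ref) | is.na(alt) | ref == "." | alt == "" | alt == "."
  if (any(missing_allele)) {
    warning(sum(missing_allele), " VCF record(s) with missing REF/ALT skipped")
  }
  keep <- !missing_allele
  snv <- keep & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_non_snv <- sum(keep & !snv)
  if (n_non_snv > 0L) {
    warning(n_non_snv, " non-biallelic-SNV VCF record(s) skipped")
  }
  same <- snv & ref == alt
  if (any(same)) {
    warning(sum(same), " VCF record(s) with REF == ALT skipped")
    snv <- snv & !same
  }
  chrom <- chrom[snv]; pos0 <- pos1[snv] - 1L
  id <- id[snv]; ref <- ref[snv]; alt <- alt[snv]

  in_target <- vapply(seq_along(pos0), function(i) {
    any(target$chrom == chrom[i] & target$start <= pos0[i] & pos0[i] < target$end)
  }, logical(1))
  n_off <- sum(!in_target)
  if (n_off > 0L) {
    message(n_off, " SNP(s) outside the target dropped")
  }
  ids <- ifelse(is.na(id[in_target]) | id[in_target] == "", ".", id[in_target])
  data.frame(chrom = chrom[in_target], pos = pos0[in_target], id = ids,
             ref = ref[in_target], alt = alt[in_target],
             stringsAsFactors = FALSE)
}

#' Fetch a reference window from an indexed FASTA
#'
#' Returns the reference bases over a target region, uppercased so that
#' soft-masked (lowercase) sequence is treated identically to uppercase.
#'
#' @param fasta_path Path to a FASTA file; a \code{.fai} index is created if
#'   absent.
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @return A single uppercase character string of length \code{end - start}.
#' @export
fetch_reference <- function(fasta_path, chrom, start, end) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  info <- Rsamtools::seqinfo(fa)
  if (!chrom %in% GenomeInfoDb::seqnames(info)) {
    stop("chromosome not present in FASTA: ", chrom)
  }
  clen <- GenomeInfoDb::seqlengths(info)[[chrom]]
  if (end > clen) {
    stop("region [", start, ",", end, ") beyond length of ", chrom, " (", clen, ")")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  seq <- Rsamtools::scanFa(fa, param = gr)
  toupper(as.character(seq[[1]]))
}

# Chromosome names and lengths from the BAM header, in header order.
bam_header_chroms <- function(bam_path) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  data.frame(chrom = names(hdr), length = unname(hdr), stringsAsFactors = FALSE)
}
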