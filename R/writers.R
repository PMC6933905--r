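# Tab-delimited writers for the four output modes. Number formatting is
# frozen (4-decimal floats, bare integer counts, "NA" for missing values)
# so that outputs are byte-reproducible across runs and worker counts.
# Text outputs report 1-based positions; internal coordinates are 0-based.

fmt_float <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
fmt_int <- function(x) format(as.integer(x), scientific = FALSE, trim = TRUE)

write_tsv_lines <- function(header, lines, path) {
  con <- file(path, open = "wb")  # binary keeps LF endings on any platform
  on.exit(close(con))
  writeLines(c(header, lines), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write the region statistics file
#'
#' One row per target region: coordinates (1-based start, inclusive end),
#' the maximal-coverage sub-region window, mean coverage, sub-region mean
#' coverage and reference GC content.
#'
#' @param regions Region statistics table from \code{\link{pileup_target}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_region_file <- function(regions, path) {
  header <- paste(c("chrom", "start", "end", "sub_start", "sub_end",
                    "mean_cov", "sub_mean_cov", "gc_content"),
                  collapse = "\t")
  lines <- if (nrow(regions) == 0L) character(0) else paste(
    regions$chrom, fmt_int(regions$start + 1L), fmt_int(regions$end),
    fmt_int(regions$sub_start + 1L), fmt_int(regions$sub_end),
    fmt_float(regions$mean_cov), fmt_float(regions$sub_mean_cov),
    fmt_float(regions$gc_content), sep = "\t")
  write_tsv_lines(header, lines, path)
}

pileup_header <- paste(c("chrom", "pos", "ref", "A", "C", "G", "T", "af",
                         "cov", "A_fwd", "C_fwd", "G_fwd", "T_fwd",
                         "A_sb", "C_sb", "G_sb", "T_sb"), collapse = "\t")

format_pileup_rows <- function(pp) {
  paste(pp$chrom, fmt_int(pp$pos + 1L), pp$ref,
        fmt_int(pp$A), fmt_int(pp$C), fmt_int(pp$G), fmt_int(pp$T),
        fmt_float(pp$af), fmt_int(pp$depth),
        fmt_int(pp$A_fwd), fmt_int(pp$C_fwd), fmt_int(pp$G_fwd),
        fmt_int(pp$T_fwd),
        fmt_float(pp$A_sb), fmt_float(pp$C_sb), fmt_float(pp$G_sb),
        fmt_float(pp$T_sb), sep = "\t")
}

#' Write a per-base pileup file
#'
#' In \code{"full"} mode every distinct target position is written
#' (including zero-coverage positions); in \code{"pabs"} mode only
#' positions with alternative base support (positive VAF) are written, as
#' a row-subset of the full output.
#'
#' @param pileup Per-position pileup table from \code{\link{pileup_target}}.
#' @param path Output path.
#' @param mode Either \code{"full"} or \code{"pabs"}.
#' @return The path, invisibly.
#' @export
write_pileup_file <- function(pileup, path, mode = c("full", "pabs")) {
  mode <- match.arg(mode)
  pp <- if (is.null(pileup)) NULL else pileup
  if (!is.null(pp) && mode == "pabs") pp <- pp[!is.na(pp$alt), , drop = FALSE]
  lines <- if (is.null(pp) || nrow(pp) == 0L) character(0) else
    format_pileup_rows(pp)
  write_tsv_lines(pileup_header, lines, path)
}

#' Write the SNP pileup file
#'
#' One row per SNP of the input VCF falling inside the target; VAF is
#' computed against the VCF alternative allele, and the genotype call uses
#' the VAF thresholds. Zero-coverage SNPs are included with VAF 0.
#'
#' @param snps SNP call table from \code{\link{pileup_target}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_snp_file <- function(snps, path) {
  header <- paste(c("chrom", "pos", "id", "ref", "alt", "A", "C", "G", "T",
                    "af", "cov", "genotype"), collapse = "\t")
  lines <- if (is.null(snps) || nrow(snps) == 0L) character(0) else paste(
    snps$chrom, fmt_int(snps$pos + 1L), snps$id, snps$ref, snps$alt,
    fmt_int(snps$A), fmt_int(snps$C), fmt_int(snps$G), fmt_int(snps$T),
    fmt_float(snps$af), fmt_int(snps$depth), snps$genotype, sep = "\t")
  write_tsv_lines(header, lines, path)
}

#' Write the selected output modes of a pileup result
#'
#' Mode letters select the files: \code{"a"} region statistics
#' (\code{<prefix>.regions.txt}), \code{"b"} full per-base pileup
#' (\code{.pileup.txt}), \code{"c"} positions with alternative support
#' (\code{.pabs.txt}), \code{"d"} SNP pileup (\code{.snps.txt}). Digits
#' 1-4 are accepted as synonyms.
#'
#' @param result A \code{pileup_result}.
#' @param out_prefix Path prefix for the output files.
#' @param modes Character scalar of mode letters/digits, e.g. \code{"abcd"}.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, out_prefix, modes = "a") {
  sel <- strsplit(as.character(modes), "")[[1]]
  sel <- chartr("1234", "abcd", sel)
  bad <- setdiff(sel, c("a", "b", "c", "d"))
  if (length(bad) || length(sel) == 0L) {
    stop("invalid output mode: ", modes, " (use letters a-d or digits 1-4)")
  }
  written <- character(0)
  if ("a" %in% sel) {
    written <- c(written, write_region_file(result$regions,
                                            paste0(out_prefix, ".regions.txt")))
  }
  if ("b" %in% sel) {
    written <- c(written, write_pileup_file(result$pileup,
                                            paste0(out_prefix, ".pileup.txt"),
                                            mode = "full"))
  }
  if ("c" %in% sel) {
    written <- c(written, write_pileup_file(result$pileup,
                                            paste0(out_prefix, ".pabs.txt"),
                                            mode = "pabs"))
  }
  if ("d" %in% sel) {
    if (is.null(result$snps)) {
      stop("SNP output requested but no VCF was supplied")
    }
    written <- c(written, write_snp_file(result$snps,
                                         paste0(out_prefix, ".snps.txt")))
  }
  invisible(written)
}
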