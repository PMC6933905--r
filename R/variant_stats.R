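# Allele-level quantities derived from the pileup: alternative-base
# selection, variant allelic fraction (VAF), per-base strand bias, and
# VAF-threshold genotype assignment at SNP sites.

#' Alternative base with highest coverage at a position
#'
#' Among the three non-reference bases, returns the one with the highest
#' total (forward + reverse) depth, provided that depth is positive; ties
#' are broken in fixed base order A < C < G < T.
#'
#' @param counts Named numeric vector of total depths for A, C, G, T.
#' @param ref Reference base at the position.
#' @return A single base, or \code{NA_character_} when no non-reference
#'   base has support.
#' @export
select_alt_base <- function(counts, ref) {
  alt_bases <- setdiff(BASES, ref)
  d <- counts[alt_bases]
  if (all(d == 0)) return(NA_character_)
  alt_bases[which.max(d)]   # which.max takes the first (lexicographic) tie
}

#' Variant allelic fraction
#'
#' @param depth_alt Depth supporting the alternative allele.
#' @param total_depth Total depth at the position.
#' @return \code{depth_alt / total_depth}, or 0 when the position has no
#'   coverage.
#' @export
compute_vaf <- function(depth_alt, total_depth) {
  if (depth_alt > total_depth) {
    stop("alternative depth ", depth_alt, " exceeds total depth ",
         total_depth, " (corrupt accumulator)")
  }
  if (total_depth == 0) 0 else depth_alt / total_depth
}

#' Per-base strand bias
#'
#' Forward-strand fraction of the depth supporting one base:
#' \code{fwd / (fwd + rev)}. Undefined (NA) when the base has no depth.
#'
#' @param fwd,rev Forward- and reverse-strand depths of the base.
#' @return Real in [0, 1], or \code{NA}.
#' @export
strand_bias <- function(fwd, rev) {
  ifelse(fwd + rev == 0, NA_real_, fwd / (fwd + rev))
}

#' Genotype assignment from VAF
#'
#' Assigns 0/0, 0/1 or 1/1 by comparing the VAF (computed against the VCF
#' alternative allele) to two thresholds; positions with depth below the
#' genotyping gate are reported as "./.".
#'
#' @param vaf Variant allelic fraction in [0, 1].
#' @param depth Total depth at the position.
#' @param het_low,het_high Heterozygous VAF band: \code{vaf < het_low} is
#'   0/0, \code{het_low <= vaf <= het_high} is 0/1, \code{vaf > het_high}
#'   is 1/1.
#' @param min_depth Minimum depth for any genotype call.
#' @return One of "0/0", "0/1", "1/1", "./.".
#' @export
genotype_call <- function(vaf, depth, het_low = 0.2, het_high = 0.8,
                          min_depth = 10L) {
  stopifnot(het_low <= het_high)
  if (depth < min_depth) return("./.")
  if (vaf < het_low) "0/0" else if (vaf <= het_high) "0/1" else "1/1"
}

# Add derived columns to a raw counts pileup table: per-base totals, total
# depth, alternative base, VAF (vs the max-coverage alternative) and
# per-base strand bias.
derive_pileup <- function(pileup) {
  for (b in BASES) {
    pileup[[b]] <- pileup[[paste0(b, "_fwd")]] + pileup[[paste0(b, "_rev")]]
  }
  pileup$depth <- pileup$A + pileup$C + pileup$G + pileup$T
  totals <- as.matrix(pileup[, BASES])
  n <- nrow(pileup)
  alt <- character(n)
  vaf <- numeric(n)
  for (i in seq_len(n)) {
    alt[i] <- select_alt_base(totals[i, ], pileup$ref[i])
    vaf[i] <- if (is.na(alt[i])) 0 else
      compute_vaf(totals[i, alt[i]], pileup$depth[i])
  }
  pileup$alt <- alt
  pileup$af <- vaf
  for (b in BASES) {
    pileup[[paste0(b, "_sb")]] <- strand_bias(pileup[[paste0(b, "_fwd")]],
                                              pileup[[paste0(b, "_rev")]])
  }
  pileup
}

# SNP pileup: VAF against the VCF alternative allele, plus genotype.
call_snps <- function(snps, pileup, het_low, het_high, min_depth) {
  if (nrow(snps) == 0L) {
    out <- snps
    for (col in c(BASES, "depth")) out[[col]] <- integer(0)
    out$af <- numeric(0)
    out$genotype <- character(0)
    return(out)
  }
  key <- paste(pileup$chrom, pileup$pos)
  idx <- match(paste(snps$chrom, snps$pos), key)
  stopifnot(!anyNA(idx))  # SNPs are inside the target, hence in the pileup
  out <- snps
  for (b in BASES) out[[b]] <- pileup[[b]][idx]
  out$depth <- pileup$depth[idx]
  alt_depth <- vapply(seq_len(nrow(out)), function(i) out[[out$alt[i]]][i],
                      numeric(1))
  out$af <- vapply(seq_len(nrow(out)), function(i)
    compute_vaf(alt_depth[i], out$depth[i]), numeric(1))
  out$genotype <- vapply(seq_len(nrow(out)), function(i)
    genotype_call(out$af[i], out$depth[i], het_low, het_high, min_depth),
    character(1))
  rownames(out) <- NULL
  out
}
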