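# Visual QC report built from the four output files. Every plotted
# quantity is also emitted as a tab-delimited numeric table; tests assert
# on the tables, images are existence-checked only.

#' Cumulative coverage distribution table
#'
#' For each integer threshold from 0 to the maximum observed depth, the
#' fraction of target positions with depth >= threshold. The fraction at
#' threshold 0 is 1 and the curve is non-increasing.
#'
#' @param depths Per-position total depths.
#' @return Data.frame with columns \code{threshold}, \code{fraction}.
#' @export
cumulative_coverage_table <- function(depths) {
  if (length(depths) == 0L) stop("no positions")
  thresholds <- 0:max(depths)
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds, function(t) mean(depths >= t),
                               numeric(1)))
}

#' Histogram table of VAF-like values on [0, 1]
#'
#' Fixed bin width (default 0.02); the final bin is closed so a value of
#' exactly 1 is counted.
#'
#' @param values Numeric values in [0, 1].
#' @param bin Bin width.
#' @return Data.frame with \code{bin_low}, \code{bin_high}, \code{count};
#'   counts sum to \code{length(values)}.
#' @export
vaf_histogram <- function(values, bin = 0.02) {
  n_bins <- as.integer(round(1 / bin))
  idx <- pmin(floor(values / bin) + 1L, n_bins)
  data.frame(bin_low = (seq_len(n_bins) - 1L) * bin,
             bin_high = seq_len(n_bins) * bin,
             count = tabulate(idx, nbins = n_bins))
}

#' Substitution spectrum of alternative-support positions
#'
#' Counts the 12 ordered reference-to-alternative substitutions.
#'
#' @param ref,alt Character vectors of reference and alternative bases.
#' @return Data.frame with \code{ref}, \code{alt}, \code{count} (12 rows,
#'   counts summing to \code{length(ref)}).
#' @export
substitution_spectrum <- function(ref, alt) {
  combos <- expand.grid(alt = BASES, ref = BASES,
                        stringsAsFactors = FALSE)[, c("ref", "alt")]
  combos <- combos[combos$ref != combos$alt, ]
  rownames(combos) <- NULL
  key <- paste(ref, alt, sep = ">")
  combos$count <- as.integer(table(factor(key, levels = paste(
    combos$ref, combos$alt, sep = ">")))[paste(combos$ref, combos$alt,
                                               sep = ">")])
  combos$count[is.na(combos$count)] <- 0L
  combos
}

hist_table <- function(values, breaks) {
  idx <- pmin(pmax(findInterval(values, breaks, left.open = FALSE), 1L),
              length(breaks) - 1L)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             count = tabulate(idx, nbins = length(breaks) - 1L))
}

report_write <- function(tab, out_dir, name, format, plot_fun) {
  utils::write.table(tab, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  img <- file.path(out_dir, paste0(name, ".", format))
  if (format == "pdf") grDevices::pdf(img, width = 7, height = 5)
  else grDevices::png(img, width = 900, height = 640)
  ok <- try(plot_fun(), silent = TRUE)
  grDevices::dev.off()
  invisible(img)
}

#' Render the visual QC report
#'
#' Builds the report tables and images from the output files written under
#' \code{in_prefix} (\code{.regions.txt}, \code{.pileup.txt},
#' \code{.pabs.txt}, \code{.snps.txt}): cumulative per-base coverage,
#' per-base VAF distribution, SNP VAF distribution split by genotype,
#' substitution spectrum, strand-bias distribution, region coverage
#' distribution and region GC content distribution. Sections whose input
#' file is missing are skipped with a warning.
#'
#' @param in_prefix Prefix of the engine's output files.
#' @param out_dir Output directory for tables and images.
#' @param format Image format, \code{"png"} or \code{"pdf"}.
#' @return Number of skipped sections, invisibly usable as an exit status.
#' @export
render_report <- function(in_prefix, out_dir, format = c("png", "pdf")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(regions = paste0(in_prefix, ".regions.txt"),
                pileup = paste0(in_prefix, ".pileup.txt"),
                pabs = paste0(in_prefix, ".pabs.txt"),
                snps = paste0(in_prefix, ".snps.txt"))
  have <- vapply(paths, file.exists, logical(1))
  read_tab <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
  n_skipped <- 0L

  if (have[["pileup"]]) {
    pp <- read_tab(paths$pileup)
    cum <- cumulative_coverage_table(pp$cov)
    report_write(cum, out_dir, "cumulative_coverage", format, function()
      graphics::plot(cum$threshold, cum$fraction, type = "s",
                     xlab = "depth of coverage threshold",
                     ylab = "fraction of positions >= threshold",
                     main = "Cumulative coverage distribution"))
    sb <- unlist(pp[, c("A_sb", "C_sb", "G_sb", "T_sb")])
    sb <- sb[!is.na(sb)]
    sbt <- vaf_histogram(sb, 0.02)
    report_write(sbt, out_dir, "strand_bias_distribution", format, function()
      graphics::barplot(sbt$count, names.arg = sprintf("%.2f", sbt$bin_low),
                        xlab = "forward-strand fraction", ylab = "bases",
                        main = "Strand bias distribution"))
  } else {
    warning("per-base pileup file missing; coverage and strand-bias ",
            "sections skipped")
    n_skipped <- n_skipped + 2L
  }

  if (have[["pabs"]]) {
    pa <- read_tab(paths$pabs)
    vt <- vaf_histogram(pa$af, 0.02)
    report_write(vt, out_dir, "vaf_distribution", format, function()
      graphics::barplot(vt$count, names.arg = sprintf("%.2f", vt$bin_low),
                        xlab = "VAF", ylab = "positions",
                        main = "VAF distribution (alternative support)"))
    # pabs rows always have an alternative base: highest-coverage non-ref
    alt <- vapply(seq_len(nrow(pa)), function(i) {
      cnt <- as.numeric(pa[i, BASES])
      names(cnt) <- BASES
      select_alt_base(cnt, pa$ref[i])
    }, character(1))
    st <- substitution_spectrum(pa$ref, alt)
    report_write(st, out_dir, "substitution_spectrum", format, function()
      graphics::barplot(st$count, names.arg = paste0(st$ref, ">", st$alt),
                        las = 2, ylab = "positions",
                        main = "Substitution spectrum"))
  } else {
    warning("alternative-support file missing; VAF and substitution ",
            "sections skipped")
    n_skipped <- n_skipped + 2L
  }

  if (have[["snps"]]) {
    sn <- read_tab(paths$snps)
    bins <- vaf_histogram(sn$af, 0.02)[, c("bin_low", "bin_high")]
    for (g in c("0/0", "0/1", "1/1", "./.")) {
      sub <- sn$af[sn$genotype == g]
      bins[[paste0("count_", chartr("/.", "_m", g))]] <-
        vaf_histogram(sub, 0.02)$count
    }
    report_write(bins, out_dir, "snp_vaf_genotypes", format, function() {
      m <- t(as.matrix(bins[, -(1:2)]))
      graphics::barplot(m, names.arg = sprintf("%.2f", bins$bin_low),
                        col = c("grey70", "orange", "firebrick", "grey30"),
                        xlab = "VAF", ylab = "SNPs",
                        main = "SNP VAF distribution by genotype")
    })
  } else {
    warning("SNP file missing; SNP VAF section skipped")
    n_skipped <- n_skipped + 1L
  }

  if (have[["regions"]]) {
    rg <- read_tab(paths$regions)
    breaks <- seq(0, max(rg$mean_cov, 1) * 1.0001, length.out = 21)
    ct <- hist_table(rg$mean_cov, breaks)
    report_write(ct, out_dir, "region_coverage_distribution", format,
                 function()
      graphics::barplot(ct$count, names.arg = sprintf("%.1f", ct$bin_low),
                        las = 2, xlab = "mean depth of coverage",
                        ylab = "regions",
                        main = "Region coverage distribution"))
    gt <- hist_table(rg$gc_content, seq(0, 1, 0.02))
    report_write(gt, out_dir, "region_gc_distribution", format, function()
      graphics::barplot(gt$count, names.arg = sprintf("%.2f", gt$bin_low),
                        las = 2, xlab = "GC content", ylab = "regions",
                        main = "Region GC content distribution"))
  } else {
    warning("region statistics file missing; region sections skipped")
    n_skipped <- n_skipped + 2L
  }

  invisible(n_skipped)
}
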