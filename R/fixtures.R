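# Synthetic fixture generator: builds a fully self-contained input set
# (reference FASTA + index, BED target, VCF of planted SNPs, sorted and
# indexed BAM) with planted ground truth, plus a per-position manifest of
# expected counts for deterministically placed regions.
#
# Region regimes:
#   exact   - depth-exact placement: read i spans the whole region plus a
#             left flank of i bases and a small right flank, so every
#             in-region position has exactly `depth` aligned bases and every
#             fragment has a distinct duplicate key. Variant alleles are
#             assigned deterministically (round(vaf * depth) reads).
#   sampled - same depth-exact placement, but each covering read carries the
#             alternative allele with probability `vaf` (seeded sampling),
#             for statistical parameter-recovery tests.
#   random  - seeded random placement, lengths, soft-clips, indels and
#             sequencing mismatches; no manifest (the brute-force oracle is
#             the truth source).

#' Construct a fixture specification
#'
#' @param seed Integer seed; the same spec and seed yield byte-identical
#'   files.
#' @param contigs Named integer vector of contig lengths.
#' @param regions Data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{depth}, \code{regime}
#'   (\code{"exact"}, \code{"sampled"} or \code{"random"}).
#' @param variants Data.frame with columns \code{chrom}, \code{pos}
#'   (0-based), \code{alt}, \code{vaf}; every variant must fall inside a
#'   region.
#' @param dup_groups List of lists with fields \code{region} (region row
#'   index), \code{size}, \code{type} (\code{"single"} or \code{"paired"}),
#'   \code{strand} (\code{"F"}/\code{"R"}, single-end only) and
#'   \code{clips} (integer vector, one 5' soft-clip length per member; 0
#'   means an exact copy).
#' @param qual_values,qual_probs Base-quality alphabet and sampling weights.
#' @param mapq_values,mapq_probs Mapping-quality alphabet and weights.
#' @param read_len Read length for the random regime.
#' @param paired_fraction Fraction of random-regime fragments that are
#'   proper pairs.
#' @param mismatch_rate,clip_rate,indel_rate Per-read structural rates for
#'   the random regime.
#' @return A list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L,
                         contigs = c(chr1 = 600L),
                         regions = data.frame(chrom = "chr1", start = 100L,
                                              end = 200L, depth = 30L,
                                              regime = "exact",
                                              stringsAsFactors = FALSE),
                         variants = NULL,
                         dup_groups = list(),
                         qual_values = 35L, qual_probs = NULL,
                         mapq_values = 60L, mapq_probs = NULL,
                         read_len = 50L, paired_fraction = 0.3,
                         mismatch_rate = 0.01, clip_rate = 0.2,
                         indel_rate = 0.15) {
  stopifnot(is.numeric(contigs), !is.null(names(contigs)))
  stopifnot(all(regions$start < regions$end))
  stopifnot(all(regions$regime %in% c("exact", "sampled", "random")))
  if (!is.null(variants)) {
    stopifnot(all(variants$vaf >= 0 & variants$vaf <= 1))
    ok <- vapply(seq_len(nrow(variants)), function(i) {
      any(regions$chrom == variants$chrom[i] &
            regions$start <= variants$pos[i] & variants$pos[i] < regions$end)
    }, logical(1))
    if (!all(ok)) stop("planted variant outside every region: row ",
                       which(!ok)[1])
  }
  structure(list(seed = as.integer(seed), contigs = contigs,
                 regions = regions, variants = variants,
                 dup_groups = dup_groups,
                 qual_values = as.integer(qual_values),
                 qual_probs = qual_probs,
                 mapq_values = as.integer(mapq_values),
                 mapq_probs = mapq_probs,
                 read_len = as.integer(read_len),
                 paired_fraction = paired_fraction,
                 mismatch_rate = mismatch_rate, clip_rate = clip_rate,
                 indel_rate = indel_rate),
            class = "fixture_spec")
}

sample_quals <- function(spec, n) {
  if (length(spec$qual_values) == 1L) rep(spec$qual_values, n)
  else sample(spec$qual_values, n, replace = TRUE, prob = spec$qual_probs)
}

sample_mapq <- function(spec, n = 1L) {
  if (length(spec$mapq_values) == 1L) rep(spec$mapq_values, n)
  else sample(spec$mapq_values, n, replace = TRUE, prob = spec$mapq_probs)
}

# One alignment record under construction. Segments are built jointly with
# their aligned reference positions, so manifest bookkeeping never parses a
# CIGAR string.
new_read <- function(chrom, pos, cigar, aligned_ref, aligned_q, seqlen,
                     reverse, refseq, spec, group = NA_character_) {
  bases <- rep("N", seqlen)
  bases[aligned_q] <- substring(refseq, aligned_ref + 1L, aligned_ref + 1L)
  # unaligned (clipped/inserted) bases: deterministic filler
  bases[bases == "N"] <- "A"
  list(chrom = chrom, pos = pos, cigar = cigar, seq = bases,
       qual = sample_quals(spec, seqlen), mapq = sample_mapq(spec),
       reverse = reverse, aligned_ref = aligned_ref, aligned_q = aligned_q,
       group = group, mate = NA_integer_)
}

# Depth-exact read set for one region: read i spans [start - i, end + b_i)
# as a single M run. Distinct flank offsets give every fragment a distinct
# duplicate key.
build_exact_reads <- function(spec, region, refseq) {
  D <- region$depth
  reads <- vector("list", D)
  if (D == 0L) return(reads[0])
  for (i in seq_len(D)) {
    a <- i - 1L
    b <- 1L + ((i - 1L) %% 5L)
    pos <- region$start - a
    len <- (region$end - region$start) + a + b
    reads[[i]] <- new_read(region$chrom, pos, paste0(len, "M"),
                           aligned_ref = seq.int(pos, length.out = len),
                           aligned_q = seq_len(len), seqlen = len,
                           reverse = (i %% 2L == 0L), refseq = refseq,
                           spec = spec)
  }
  reads
}

# Random-regime reads: seeded random placement and structure.
build_random_reads <- function(spec, region, refseq, contig_len) {
  rl <- spec$read_len
  n <- max(1L, as.integer(round(region$depth * (region$end - region$start + rl) / rl)))
  reads <- vector("list", 0)
  for (i in seq_len(n)) {
    pos <- sample(max(0L, region$start - rl + 1L):(region$end - 1L), 1L)
    len <- rl + sample(-5L:5L, 1L)
    # structural decoration
    lead_clip <- if (stats::runif(1) < spec$clip_rate) sample(1:8, 1L) else 0L
    trail_clip <- if (stats::runif(1) < spec$clip_rate) sample(1:8, 1L) else 0L
    mid <- len - lead_clip - trail_clip
    if (mid < 10L) { lead_clip <- 0L; trail_clip <- 0L; mid <- len }
    ops <- list()
    aligned_ref <- integer(0)
    aligned_q <- integer(0)
    q <- lead_clip + 1L
    r <- pos
    if (lead_clip > 0L) ops <- c(ops, list(c(lead_clip, "S")))
    remaining <- mid
    while (remaining > 0L) {
      mlen <- if (stats::runif(1) < spec$indel_rate && remaining > 6L) {
        sample(3:(remaining - 3L), 1L)
      } else remaining
      ops <- c(ops, list(c(mlen, "M")))
      aligned_ref <- c(aligned_ref, seq.int(r, length.out = mlen))
      aligned_q <- c(aligned_q, seq.int(q, length.out = mlen))
      r <- r + mlen
      q <- q + mlen
      remaining <- remaining - mlen
      if (remaining > 0L) {
        if (stats::runif(1) < 0.5) {           # deletion
          dlen <- sample(1:3, 1L)
          ops <- c(ops, list(c(dlen, "D")))
          r <- r + dlen
        } else {                                # insertion
          ilen <- min(sample(1:3, 1L), remaining - 1L)
          ops <- c(ops, list(c(ilen, "I")))
          q <- q + ilen
          remaining <- remaining - ilen
        }
      }
    }
    if (trail_clip > 0L) ops <- c(ops, list(c(trail_clip, "S")))
    if (max(aligned_ref) >= contig_len || min(aligned_ref) < 0L) next
    seqlen <- lead_clip + trail_clip +
      sum(vapply(ops, function(o) if (o[2] %in% c("M", "I")) as.integer(o[1]) else 0L,
                 integer(1))) - lead_clip - trail_clip
    seqlen <- seqlen + lead_clip + trail_clip
    cigar <- paste0(vapply(ops, function(o) paste0(o[1], o[2]), character(1)),
                    collapse = "")
    rd <- new_read(region$chrom, pos, cigar, aligned_ref, aligned_q,
                   seqlen, reverse = stats::runif(1) < 0.5, refseq = refseq,
                   spec = spec)
    # sequencing mismatches and occasional N calls on aligned bases
    nb <- length(rd$aligned_q)
    mm <- which(stats::runif(nb) < spec$mismatch_rate)
    for (j in mm) {
      cur <- rd$seq[rd$aligned_q[j]]
      rd$seq[rd$aligned_q[j]] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    nn <- which(stats::runif(nb) < 0.005)
    rd$seq[rd$aligned_q[nn]] <- "N"
    reads <- c(reads, list(rd))
  }
  reads
}

# A duplicate group: one template fragment plus size-1 clip-shifted copies
# that share the template's clip-corrected signature.
build_dup_group <- function(spec, region, refseq, group_idx) {
  g <- spec$dup_groups[[group_idx]]
  stopifnot(g$size >= 2L, length(g$clips) == g$size)
  gid <- paste0("dup", group_idx)
  L <- region$end - region$start
  a <- region$depth + 2L + 3L * group_idx   # flank keeps keys off the tiling
  pos0 <- region$start - a
  len0 <- L + a + 2L
  reads <- list()
  if (identical(g$type, "paired")) {
    for (m in seq_len(g$size)) {
      s <- g$clips[m]
      stopifnot(s < len0 - 1L)
      # forward mate, 5' (left) clip-shifted: unclipped start stays pos0
      f_pos <- pos0 + s
      f_cig <- if (s > 0L) paste0(s, "S", len0 - s, "M") else paste0(len0, "M")
      fwd <- new_read(region$chrom, f_pos, f_cig,
                      aligned_ref = seq.int(f_pos, length.out = len0 - s),
                      aligned_q = seq.int(s + 1L, length.out = len0 - s),
                      seqlen = len0, reverse = FALSE, refseq = refseq,
                      spec = spec, group = gid)
      # reverse mate fully overlapping, exact copy across members
      rev <- new_read(region$chrom, pos0, paste0(len0, "M"),
                      aligned_ref = seq.int(pos0, length.out = len0),
                      aligned_q = seq_len(len0), seqlen = len0,
                      reverse = TRUE, refseq = refseq, spec = spec,
                      group = gid)
      fwd$mate <- 2L; rev$mate <- 1L
      reads <- c(reads, list(fwd, rev))
    }
  } else {
    reverse <- identical(g$strand, "R")
    for (m in seq_len(g$size)) {
      s <- g$clips[m]
      stopifnot(s < len0 - 1L)
      if (reverse) {
        # 5' of a reverse read is its right end: trailing clip, same pos
        cig <- if (s > 0L) paste0(len0 - s, "M", s, "S") else paste0(len0, "M")
        rd <- new_read(region$chrom, pos0, cig,
                       aligned_ref = seq.int(pos0, length.out = len0 - s),
                       aligned_q = seq_len(len0 - s), seqlen = len0,
                       reverse = TRUE, refseq = refseq, spec = spec,
                       group = gid)
      } else {
        cig <- if (s > 0L) paste0(s, "S", len0 - s, "M") else paste0(len0, "M")
        rd <- new_read(region$chrom, pos0 + s, cig,
                       aligned_ref = seq.int(pos0 + s, length.out = len0 - s),
                       aligned_q = seq.int(s + 1L, length.out = len0 - s),
                       seqlen = len0, reverse = FALSE, refseq = refseq,
                       spec = spec, group = gid)
      }
      reads <- c(reads, list(rd))
    }
  }
  reads
}

plant_variant <- function(reads, variant, regime, depth) {
  carriers <- which(vapply(reads, function(rd) {
    is.na(rd$group) && variant$pos %in% rd$aligned_ref
  }, logical(1)))
  if (length(carriers) == 0L) return(list(reads = reads, n_alt = 0L))
  if (regime == "sampled") {
    take <- carriers[stats::runif(length(carriers)) < variant$vaf]
  } else {
    take <- carriers[seq_len(min(length(carriers),
                                 round_half_up(variant$vaf * length(carriers))))]
  }
  for (i in take) {
    qi <- reads[[i]]$aligned_q[match(variant$pos, reads[[i]]$aligned_ref)]
    reads[[i]]$seq[qi] <- variant$alt
  }
  list(reads = reads, n_alt = length(take))
}

# Manifest bookkeeping: accumulate the generator's own aligned-pair records
# (pre-dedup, and post-dedup keeping one representative per planted group by
# the stated rule: max total base quality, then leftmost, then first built).
manifest_counts <- function(reads, region) {
  len <- region$end - region$start
  pre <- matrix(0L, nrow = len, ncol = 8L, dimnames = list(NULL, COUNT_COLS))
  post <- matrix(0L, nrow = len, ncol = 8L, dimnames = list(NULL, COUNT_COLS))
  groups <- vapply(reads, function(rd) rd$group, character(1))
  keep_post <- rep(TRUE, length(reads))
  for (gid in unique(groups[!is.na(groups)])) {
    # members: consecutive fragments; paired groups keep both mates of one
    idx <- which(groups == gid)
    paired <- any(vapply(reads[idx], function(rd) !is.na(rd$mate), logical(1)))
    frag <- if (paired) split(idx, rep(seq_len(length(idx) / 2L), each = 2L))
            else as.list(idx)
    sumq <- vapply(frag, function(ii)
      sum(vapply(reads[ii], function(rd) sum(as.numeric(rd$qual)), numeric(1))),
      numeric(1))
    minpos <- vapply(frag, function(ii)
      min(vapply(reads[ii], function(rd) rd$pos, numeric(1))), numeric(1))
    best <- order(-sumq, minpos, vapply(frag, min, numeric(1)))[1]
    keep_post[setdiff(idx, frag[[best]])] <- FALSE
  }
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    if (rd$chrom != region$chrom) next
    inside <- rd$aligned_ref >= region$start & rd$aligned_ref < region$end
    if (!any(inside)) next
    b <- match(rd$seq[rd$aligned_q[inside]], BASES)
    off <- rd$aligned_ref[inside] - region$start
    ok <- !is.na(b)
    col <- b[ok] + 4L * as.integer(rd$reverse)
    for (j in seq_along(col)) {
      pre[off[ok][j] + 1L, col[j]] <- pre[off[ok][j] + 1L, col[j]] + 1L
      if (keep_post[i]) {
        post[off[ok][j] + 1L, col[j]] <- post[off[ok][j] + 1L, col[j]] + 1L
      }
    }
  }
  list(pre = pre, post = post)
}

phred_to_ascii <- function(q) intToUtf8(q + 33L)

revcomp <- function(bases) {
  rev(chartr("ACGTN", "TGCAN", bases))
}

# Serialize reads as SAM records (SEQ/QUAL stored in sequencing order for
# reverse-strand reads, per the SAM convention the record is already in
# reference orientation, so no flip is needed here).
reads_to_sam <- function(reads, contigs) {
  n <- length(reads)
  qname <- character(n)
  frag <- 0L
  i <- 1L
  while (i <= n) {
    frag <- frag + 1L
    if (!is.na(reads[[i]]$mate)) {
      qname[i] <- qname[i + 1L] <- sprintf("frag%06d", frag)
      i <- i + 2L
    } else {
      qname[i] <- sprintf("frag%06d", frag)
      i <- i + 1L
    }
  }
  recs <- character(n)
  for (i in seq_len(n)) {
    rd <- reads[[i]]
    if (!is.na(rd$mate)) {
      mate <- reads[[i + ifelse(rd$mate == 2L, 1L, -1L)]]
      flag <- 0x1 + 0x2 +
        ifelse(rd$reverse, 0x10, 0) + ifelse(mate$reverse, 0x20, 0) +
        ifelse(rd$mate == 2L, 0x40, 0x80)
      rnext <- "="
      pnext <- mate$pos + 1L
      outer_l <- min(rd$pos, mate$pos)
      outer_r <- max(max(rd$aligned_ref), max(mate$aligned_ref)) + 1L
      tlen <- (outer_r - outer_l) * ifelse(rd$pos <= mate$pos, 1L, -1L)
    } else {
      flag <- ifelse(rd$reverse, 0x10, 0x0)
      rnext <- "*"; pnext <- 0L; tlen <- 0L
    }
    recs[i] <- paste(qname[i], flag, rd$chrom, rd$pos + 1L, rd$mapq, rd$cigar,
                     rnext, pnext, tlen, paste(rd$seq, collapse = ""),
                     phred_to_ascii(rd$qual), sep = "\t")
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(contigs), "\tLN:", contigs))
  ord <- order(match(vapply(reads, `[[`, character(1), "chrom"), names(contigs)),
               vapply(reads, `[[`, numeric(1), "pos"))
  c(hdr, recs[ord])
}

#' Generate a synthetic fixture
#'
#' Writes \code{ref.fa} (+ \code{.fai}), \code{target.bed},
#' \code{snps.vcf} (when variants are planted), a coordinate-sorted indexed
#' \code{reads.bam}, and \code{manifest.tsv} with the expected per-position
#' strand-specific counts (before and after duplicate collapsing, at zero
#' quality thresholds) for every depth-exact region.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the file paths plus the planted-truth
#'   manifest as a data.frame.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  # feasibility: exact-regime flanks must stay inside the contig
  for (i in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[i, ]
    margin <- rg$depth + 2L + 3L * length(spec$dup_groups) + 8L
    if (rg$regime %in% c("exact", "sampled") &&
        (rg$start < margin ||
         rg$end + 8L > spec$contigs[[rg$chrom]])) {
      stop("region ", i, " too close to a contig edge for depth-exact ",
           "placement (needs ", margin, " bp of flank)")
    }
  }

  refseq <- vapply(spec$contigs, function(len)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))

  # a planted variant needs a reference base different from its alt allele
  if (!is.null(spec$variants)) {
    for (v in seq_len(nrow(spec$variants))) {
      ch <- spec$variants$chrom[v]
      p1 <- spec$variants$pos[v] + 1L
      if (substring(refseq[[ch]], p1, p1) == spec$variants$alt[v]) {
        substring(refseq[[ch]], p1, p1) <-
          setdiff(BASES, spec$variants$alt[v])[1]
      }
    }
  }

  fa_path <- file.path(out_dir, "ref.fa")
  writeLines(unlist(lapply(names(spec$contigs), function(nm) {
    c(paste0(">", nm), substring(refseq[[nm]],
                                 seq(1, nchar(refseq[[nm]]), 70),
                                 pmin(seq(1, nchar(refseq[[nm]]), 70) + 69,
                                      nchar(refseq[[nm]]))))
  })), fa_path)
  if (file.exists(paste0(fa_path, ".fai"))) unlink(paste0(fa_path, ".fai"))
  Rsamtools::indexFa(fa_path)

  bed_path <- file.path(out_dir, "target.bed")
  write_target(spec$regions, bed_path)

  all_reads <- list()
  region_reads <- vector("list", nrow(spec$regions))
  for (i in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[i, ]
    rds <- if (rg$regime == "random") {
      build_random_reads(spec, rg, refseq[[rg$chrom]], spec$contigs[[rg$chrom]])
    } else {
      build_exact_reads(spec, rg, refseq[[rg$chrom]])
    }
    for (gi in seq_along(spec$dup_groups)) {
      if (spec$dup_groups[[gi]]$region == i) {
        rds <- c(rds, build_dup_group(spec, rg, refseq[[rg$chrom]], gi))
      }
    }
    if (!is.null(spec$variants)) {
      for (v in seq_len(nrow(spec$variants))) {
        vr <- spec$variants[v, ]
        if (vr$chrom == rg$chrom && vr$pos >= rg$start && vr$pos < rg$end) {
          pv <- plant_variant(rds, vr, rg$regime, rg$depth)
          rds <- pv$reads
        }
      }
    }
    region_reads[[i]] <- rds
    all_reads <- c(all_reads, rds)
  }

  vcf_path <- NULL
  if (!is.null(spec$variants) && nrow(spec$variants) > 0L) {
    vcf_path <- file.path(out_dir, "snps.vcf")
    ref_at <- vapply(seq_len(nrow(spec$variants)), function(v)
      substring(refseq[[spec$variants$chrom[v]]],
                spec$variants$pos[v] + 1L, spec$variants$pos[v] + 1L),
      character(1))
    writeLines(c(
      "##fileformat=VCFv4.2",
      paste0("##contig=<ID=", names(spec$contigs), ",length=",
             spec$contigs, ">"),
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      paste(spec$variants$chrom, spec$variants$pos + 1L,
            sprintf("snp%03d", seq_len(nrow(spec$variants))),
            ref_at, spec$variants$alt, ".", ".", ".", sep = "\t")), vcf_path)
  }

  sam_path <- file.path(out_dir, "reads.sam")
  writeLines(reads_to_sam(all_reads, spec$contigs), sam_path)
  bam_path <- suppressMessages(
    Rsamtools::asBam(sam_path, file.path(out_dir, "reads"),
                     overwrite = TRUE, indexDestination = TRUE))
  unlink(sam_path)

  # manifest for depth-exact regions
  manifest <- NULL
  for (i in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[i, ]
    if (rg$regime == "random") next
    # counts accumulate over ALL reads: a neighbouring region's reads (or
    # their flanks) overlapping this region must be included
    mc <- manifest_counts(all_reads, rg)
    rows <- data.frame(chrom = rg$chrom,
                       pos = seq.int(rg$start, rg$end - 1L),
                       stringsAsFactors = FALSE)
    colnames(mc$pre) <- paste0("pre_", COUNT_COLS)
    colnames(mc$post) <- paste0("post_", COUNT_COLS)
    manifest <- rbind(manifest, cbind(rows, as.data.frame(mc$pre),
                                      as.data.frame(mc$post)))
  }
  manifest_path <- file.path(out_dir, "manifest.tsv")
  if (!is.null(manifest)) {
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  invisible(list(fasta = fa_path, bed = bed_path, vcf = vcf_path,
                 bam = bam_path, manifest = manifest,
                 manifest_path = if (is.null(manifest)) NULL else manifest_path))
}

#' Read a fixture specification from a key-value text file
#'
#' Line format (whitespace-separated): \code{seed N};
#' \code{contig NAME LEN}; \code{region CHROM START END DEPTH REGIME};
#' \code{variant CHROM POS ALT VAF}; \code{dupgroup REGION TYPE SIZE
#' CLIPS[,CLIPS...] [STRAND]}; \code{qual V1,V2,...}; \code{mapq V1,V2,...}.
#'
#' @param path Path to the spec file.
#' @return A \code{\link{fixture_spec}}.
#' @export
read_fixture_spec <- function(path) {
  if (!file.exists(path)) stop("fixture spec not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  args <- list(contigs = c(), regions = NULL, variants = NULL,
               dup_groups = list())
  for (tk in toks) {
    switch(tk[1],
      seed = { args$seed <- as.integer(tk[2]) },
      contig = {
        v <- as.integer(tk[3]); names(v) <- tk[2]
        args$contigs <- c(args$contigs, v)
      },
      region = {
        args$regions <- rbind(args$regions, data.frame(
          chrom = tk[2], start = as.integer(tk[3]), end = as.integer(tk[4]),
          depth = as.integer(tk[5]), regime = tk[6], stringsAsFactors = FALSE))
      },
      variant = {
        args$variants <- rbind(args$variants, data.frame(
          chrom = tk[2], pos = as.integer(tk[3]), alt = tk[4],
          vaf = as.numeric(tk[5]), stringsAsFactors = FALSE))
      },
      dupgroup = {
        args$dup_groups <- c(args$dup_groups, list(list(
          region = as.integer(tk[2]), type = tk[3], size = as.integer(tk[4]),
          clips = as.integer(strsplit(tk[5], ",")[[1]]),
          strand = if (length(tk) >= 6) tk[6] else "F")))
      },
      qual = { args$qual_values <- as.integer(strsplit(tk[2], ",")[[1]]) },
      mapq = { args$mapq_values <- as.integer(strsplit(tk[2], ",")[[1]]) },
      stop("unknown fixture spec directive: ", tk[1]))
  }
  if (length(args$contigs) == 0L) args$contigs <- NULL
  do.call(fixture_spec, args[!vapply(args, is.null, logical(1))])
}
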