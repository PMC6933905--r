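---
title: "Region and single-base pileup statistics for targeted sequencing"
author: "pilecov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region and single-base pileup statistics for targeted sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`pilecov` characterizes whole-exome and targeted sequencing alignments at two
resolutions. At the region level it computes, for every interval of a capture
target, the mean depth of coverage, the GC content of the reference sequence,
and the mean coverage of the contiguous sub-interval that maximizes the
coverage signal. At single-base resolution it accumulates, for every position
of the target, strand-specific counts of A, C, G and T read bases, from which
total depth, variant allelic fraction (VAF) and per-base strand bias are
derived; at user-supplied SNP positions the VAF against the VCF alternative
allele yields a threshold genotype call. A PCR-duplicate filter can be applied
*during* traversal, so no intermediate duplicate-marked BAM is ever written.

The engine is deliberately model-free: every reported number is a count or a
ratio of counts over filtered alignments. There is no error model, prior, or
recalibration; the package is a measurement instrument for downstream copy
number, variant-calling and quality-control analyses, not a variant caller.

## Coordinates and inputs

Internally every position is 0-based with half-open intervals, the BED
convention. VCF positions (1-based) are converted on input; all text outputs
print 1-based positions, the convention of pileup-style files. The four
inputs are a coordinate-sorted indexed BAM, a sorted BED target, an optional
VCF restricted to biallelic SNVs (indels and multi-allelic rows are skipped
with a warning, off-target SNPs dropped with a logged count), and an indexed
FASTA reference. Chromosome naming must agree exactly between BED and BAM
header; a mismatch (`chr1` vs `1`) is a hard error rather than silent zero
coverage. Overlapping BED intervals are processed independently — each gets
its own region statistics — while the per-base output deduplicates positions
(the first covering region wins; counts are identical by construction).

## Filters

Four read classes are always excluded: unmapped, secondary, supplementary
and QC-fail records. Two thresholds are user-tunable: the minimum read
mapping quality (`--mrq`, Phred, default 1, i.e. only mapping quality 0 is
dropped) applied per read, and the minimum base quality (`--mbq`, Phred,
default 20) applied per base — a read with one low-quality base still
contributes its other bases. Filter order is fixed: always-on exclusions,
then mapping quality, then the duplicate filter, then per-base base quality.
Bases other than A/C/G/T (ambiguity codes, N) never count. Deletions, skips,
insertions and clips contribute to no position, so per-position depth counts
aligned bases only. Existing duplicate flags in the BAM are ignored: the
engine's own filter is self-contained, making results independent of
whatever upstream marking was or was not done.

## The duplicate filter

Fragments are clustered by a coordinate signature that is robust to
soft-clipping: the 5' alignment position corrected for soft-clips (for a
forward read, `pos - leading clip`; for a reverse read, the last aligned
reference base `+ trailing clip`, because the 5' end of a reverse read is
its right end), the strand, and the *total mapping size*. Two alignments of
the same original molecule that were clipped differently still collide, which
is the point of the correction.

Total mapping size needs a concrete definition, which we fix as:

* single-end fragment — the clip-corrected reference span of the read
  (unclipped end − unclipped start + 1);
* paired fragment — the absolute distance between the two mates'
  clip-corrected 5' coordinates, with both mates' (chromosome, unclipped 5',
  strand) signatures ordered canonically so the two mates of a pair always
  produce the identical key. Orientation is part of the key through the
  per-segment strand, so FR and RF fragments with coincident ends do not
  collide.

Within a duplicate cluster exactly one representative survives: the fragment
with the highest total base quality (summed over both mates for pairs), ties
broken by leftmost position and then first occurrence. This makes the output
deterministic. A paired read whose mate is unmapped or outside the traversal
window falls back to single-end keying.

The filter operates over one contiguous traversal window per worker chunk
and chromosome, so duplicate clusters straddling a region boundary *within*
a chunk are still collapsed. Clusters split across worker boundaries are a
documented approximation of the region-partitioned design: the partitioner
places boundaries only between regions, so the approximation can only matter
for fragments spanning the gap between two regions assigned to different
workers. The synthetic test fixtures never plant such straddling clusters;
the equivalence tests therefore validate the filter under the same windowing
contract the engine promises.

## Region statistics

Mean coverage is the arithmetic mean of the post-filter per-position depths,
so region and per-base outputs are mutually consistent. GC content is
computed on the reference sequence (the standard for capture QC, and
independent of coverage); N bases are excluded from numerator and
denominator, and an all-N window reports 0 with a warning.

The *peak sub-region* statistic compensates for the coverage fall-off at
capture-region edges caused by reads only partially matching the captured
interval: for a window fraction `f` (default 0.5) it reports the contiguous
window of length `w = max(1, round_half_up(f × length))` with maximal mean
depth, found in a single sliding-sum pass, ties broken by the leftmost
window. Round-half-up (rather than R's round-half-even) keeps window lengths
reproducible across region-length parities. One property worth stating
precisely: the peak mean dominates every window of the same length, and at
`f = 1` it equals the region mean exactly — but it is *not* in general at
least the overall region mean, because windows of length `w` cannot always
tile the region (depths `[10, 0, 10]` at `f = 0.5` give a peak mean of 5
versus an overall mean of 6.67). Tests assert the true invariant.

## Allele-level statistics

Two VAF definitions coexist deliberately. In the per-base pileup, the
alternative base is the non-reference base with the highest total depth
(ties broken in A &lt; C &lt; G &lt; T order) and the VAF is its fraction of
total depth — zero when no non-reference base has support. The
alternative-support output (`pabs`) is exactly the rows with positive VAF.
In the SNP output, the VAF is computed against the VCF alternative allele,
whatever its rank in the pileup; the two values agree only when the VCF
allele happens to be the max-coverage alternative. Strand bias per base is
the forward-strand fraction `fwd/(fwd+rev)`, undefined (printed `NA`) at
zero depth for that base; cross-strand test statistics are out of scope.

Genotypes are assigned from the SNP VAF with a depth gate: fewer than
`--min-genotype-depth` (default 10) reads gives `./.`; otherwise
`vaf < het_low` (default 0.2) is `0/0`, `vaf ≤ het_high` (default 0.8) is
`0/1`, and above that `1/1`, with the boundaries belonging to the
heterozygous band. The three thresholds are exposed as flags because
different assays justify different bands; the 0.2 default matches the
allelic-fraction cutoff conventionally used to declare a position
informative in concordance analyses of this kind of pileup output.

## Parallel execution

The target is split into contiguous chunks of near-equal region counts
(earlier chunks take the remainder: 10 regions over 3 workers gives 4/3/3).
Workers share nothing mutable — each owns its regions' accumulators — and
the merge is ordered concatenation, so output files are byte-identical for
any worker count; tests assert this at 1/2/4 workers. More workers than
regions simply leaves some idle.

## Output dialects

Four tab-delimited files, selected by mode letters `a`–`d` (digits 1–4 are
synonyms): region statistics, full per-base pileup, alternative-support
pileup (a row-subset of the full pileup) and SNP pileup (one row per
in-target VCF SNP, zero-depth SNPs included with VAF 0 and the depth gate
deciding `./.`). Number formatting is frozen — four-decimal floats, bare
integer counts, `NA` for undefined strand bias, LF line endings — so golden
tests can assert byte equality. The per-base file carries both per-base
forward-strand counts and per-base strand-bias ratios, making strand
information usable without recomputation.

## The synthetic-data generator and what it shows

Test inputs are fully synthetic and generated from a seed (same spec + seed
gives byte-identical files). Three regimes are used:

* *exact* — depth-exact placement: the i-th read spans the whole region plus
  an i-base left flank, so every in-region position has exactly the planted
  depth and every fragment has a distinct duplicate key. Variant alleles are
  assigned to a deterministic `round(vaf × depth)` subset of reads. Used for
  exact-count assertions against the generator's own bookkeeping manifest.
* *sampled* — the same placement, but each read carries the alternative
  allele with probability `vaf`; used for parameter-recovery tests (VAF
  within the binomial interval of the planted fraction at the realized
  depth). The recovery tests use depth 200, a realistic deep-coverage value
  for targeted panels at which the three genotype classes are comfortably
  separated by the 0.2/0.8 band.
* *random* — seeded random placement, lengths, soft-clips, insertions,
  deletions, N calls and ~1% mismatches; here the brute-force oracle, an
  independent naive implementation with its own CIGAR walker and offline
  global duplicate grouping, is the truth source.

Duplicate clusters are planted as clip-shifted copies (leading clips on
forward members, trailing clips on reverse members) so that only
clip-corrected keying collapses them — uncorrected positions would not.

The generator emulates the structural features the engine must handle, not
sequencing physics: there is no quality-dependent error model, no optical
duplicates, no realistic insert-size distribution, no reference bias.
Passing tests therefore demonstrate *counting correctness* under the stated
filter semantics — that the engine agrees exactly with an independent naive
recount and with offline duplicate grouping — not calling accuracy on real
data, which is not a claim this package makes.

Validation problem sizes were chosen to keep the whole suite fast while
exercising every code path: 50 randomized fixtures of 2–3 regions of 40–70
bp at depth 4–8, swept over base-quality thresholds {0, 13, 20, 30} ×
mapping-quality thresholds {0, 1, 20}, with and without duplicate filtering;
planted duplicate clusters of sizes 2–10; 200 random depth vectors (length
up to 300) for the peak-window enumeration check.

## Known limitations

CRAM, remote inputs, liftover, UMI-aware deduplication, optical-duplicate
distinction, indel pileup records and statistical variant calling are out of
scope. Duplicate clusters split across worker-chunk boundaries are not
merged (see above). The VCF reader consumes only CHROM/POS/ID/REF/ALT and
skips multi-allelic rows rather than splitting them.
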