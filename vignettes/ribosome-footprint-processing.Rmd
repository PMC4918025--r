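---
title: "Processing ribosome footprints: offset calibration, counting and pause scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing ribosome footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ribosome profiling captures the ~20–40 nt mRNA fragments a translating
ribosome protects from nuclease digestion. A footprint's mapped
coordinates do not directly name the codon being decoded: depending on
the digestion chemistry, the ribosomal P-site sits at a fixed,
read-length-dependent distance from the read's 5' end (typical for
eukaryotic protocols, often ~12–13 nt) or from its 3' end (common for
bacterial data, ~15 nt). `ribopipe` makes that recalibration step
explicit and automatic, and builds the standard quantifications on top
of it: per-region counts, codon-resolution coverage, motif tables and
pause scores.

The package assumes its BAM input has already been cleaned upstream:
rRNA/tRNA contamination and PCR duplicates should be removed before the
analysis starts. Alignment, trimming and deduplication are deliberately
out of scope.

# Coordinate model

All internal coordinates are 0-based and half-open; GTF input (1-based
inclusive, Ensembl dialect with `exon`/`CDS` features) is converted at
the parsing boundary only. A transcript model stores exons in 5'→3'
transcript order and the CDS as a transcript-coordinate interval
`[cds_start, cds_end)`; the 5'UTR and 3'UTR are the flanking intervals,
either possibly empty, and their lengths always sum to the transcript
length. `genome_to_transcript()` and `transcript_to_genome()` are exact
inverses on exonic positions, on both strands and across splice
junctions; intronic or flanking positions map to `NA` rather than
erroring. The CDS span is taken exactly as annotated — GTF dialects
differ on whether the stop codon is inside the CDS, and no correction is
applied. All isoforms are kept; a read compatible with several isoforms
contributes to each, and this double counting is accepted rather than
resolved by a canonical-transcript heuristic.

# Offset calibration

Calibration uses the transcripts most likely to give a clean initiation
signal: transcripts are ranked by the raw count of reads overlapping
their exons (length normalization is deliberately not applied — the
selection only needs "highly expressed", not comparability across
lengths) and the top fraction (default 3%) is kept, with ties broken by
transcript id so the selection is deterministic. For each read length,
the chosen read end (5' or 3') is histogrammed at positions relative to
the first CDS nucleotide within a ±`window` (default 50 nt; 30 nt is
plenty for typical offsets and is what the test suite uses).

Because initiating ribosomes accumulate on the start codon, the profile
shows a peak at `-offset` (5'-end mode) or `+offset` (3'-end mode). The
estimator is a windowed argmax restricted to the expected side, guarded
two ways: the peak must hold at least `min_fraction_at_peak` (default
10%) of the window total, and a tied maximum is never broken. Either
failure reports the length as ambiguous (`NA`) instead of guessing —
read lengths with erratic TSS distributions are thereby surfaced to the
analyst rather than silently mis-calibrated. Published pipelines
typically quantify this peak by eye; the contribution here is making the
rule explicit, deterministic and refusable.

# Counting

P-sites are computed per read as `tx(end5) + offset` or
`tx(end3) - offset`, using each length's calibrated offset (a single
global offset is also accepted for protocols where all lengths share
one). Reads whose length has no unambiguous offset, whose end does not
map into any transcript, or whose shifted position falls outside the
transcript are dropped and tallied by reason in a drop log.

Region assignment uses half-open boundaries: positions before
`cds_start` are 5'UTR, positions in `[cds_start, cds_end)` are CDS —
so the start codon's first nucleotide counts as CDS, consistent with
reading the ATG occupancy peak as coding signal — and the rest is
3'UTR. Counts are raw; normalization by region length or library size is
left to downstream tools. Codon coverage bins CDS events by
`floor((tx_pos - cds_start)/3)`; transcripts whose annotated CDS length
is not a multiple of 3 cannot be framed and are skipped with a warning.

# Motifs, PCA and pause scores

Motif tables slide a 1–3-codon window along each CDS, keyed by the
concatenated codons or the translated residues (stops translate to `*`;
windows never extend past the annotated CDS). Two footprint
attributions are provided because ribosome stalling is driven largely by
the incoming A-site codon: `window` sums coverage over all codons of the
window, `last` takes only the final codon. Under exactly uniform
coverage these give scores equal to the motif length and to 1,
respectively — useful analytic nulls that the test suite asserts
exactly.

The pause score of a motif in one ORF is its footprint density relative
to its uniform share,
`(Reads_motif / Reads_ORF) / (N_motif / Length_ORF)`, computed as a
single ratio of products so the integer-input identities above hold
without floating-point drift. ORF length is measured in codons; the
score is a ratio of densities, so any consistent unit choice rescales
all motifs of an ORF by the same constant and leaves their ranking
unchanged. Only ORFs with strictly more than 20 footprints enter the
analysis (an ORF with exactly 20 is excluded), and per-motif summaries
are unweighted means over contributing ORFs, so a single highly
expressed gene cannot dominate the average.

PCA of the transcripts-by-64-codons occupancy matrix is a centered
(optionally scaled) `prcomp`, with zero-variance columns dropped and
component signs canonicalized so each loading vector's
largest-magnitude entry is positive — making scores and loadings
reproducible across platforms. Rows are transcripts by default; when
several samples are processed the same function applies to a
samples-by-codons matrix.

# The synthetic-data generator

The generator exists so that every stage can be validated against known
truth without external data. Its defaults describe a small but
realistic experiment, chosen once:

- 20 transcripts on alternating strands of one chromosome, every third
  one spliced; UTRs of 40–90 nt and CDSs of 120–240 codons.
- Log-normal expression (sdlog 1.5), enough heterogeneity that a
  "top 3%" selection is meaningful.
- An initiation peak: the start codon carries 30× the occupancy of a
  background codon. This is what makes the TSS metagene peak — and with
  it offset recovery and the ATG dominance in the codon PCA — *emerge*
  from the simulated reads rather than being wired in downstream.
- CDS P-sites sit on the first nucleotide of their codon (frame 0),
  reproducing the triplet periodicity of real libraries; UTR P-sites
  (5% of reads in the 5'UTR, mimicking uORF-like signal; 0.5% in the
  3'UTR) are uniform.
- Per-length 5'-end offsets of 12–14 nt by default; any map of lengths
  to offsets, for either end, can be planted.
- One copy of each Pro-Pro-X tripeptide is written into every CDS (with
  random synonymous codons), so pause analyses always have all 20
  motifs represented; stall multipliers scale the occupancy of every
  codon of each matching window.
- Reads are perfect-match (CIGAR `M`, or `M..N..M` across a junction),
  placed so the chosen end sits exactly at the planted offset from the
  P-site, and written through a SAM text rendering to a
  coordinate-sorted, indexed BAM. A single RNG stream keyed by the seed
  makes FASTA, GTF, BAM and truth table byte-reproducible.

What the generator does *not* emulate — sequencing errors, indels,
ligation and digestion sequence bias, multi-mapping, incomplete
annotation — bounds what passing tests show: they validate the
pipeline's bookkeeping (coordinates, offsets, conservation, scoring)
exactly, not its robustness to real-library artifacts.

The test suite and the acceptance script run simulations of 1,000 to
30,000 reads on this 20-transcript reference; these sizes give
unambiguous calibration peaks and tight stall-recovery ratios while
keeping a full run in the minutes range.

# Numerical and design choices

- Match length is the number of query bases consumed by M/=/X/I CIGAR
  operations: soft/hard clips are adapter remnants, insertions are
  sequenced bases. The footprint window is inclusive, `[20, 40]` nt by
  default.
- "Uniquely mapped" is approximated portably as: not flagged secondary,
  and MAPQ ≠ 0 where MAPQ is recorded.
- Expression ranking counts reads on exon overlap (not CDS-only): the
  selection feeds a TSS-anchored profile, where 5'UTR reads carry
  signal too.
- Ambiguity in offset estimation is always propagated, never resolved
  by a tie-break; downstream stages drop ambiguous lengths and log the
  count.
- Whether a motif's footprints are counted over its whole window or its
  last codon is not a settled convention; both are first-class options
  (`attribution`), with `window` the default.

# Limitations

Differential translation between conditions, dwell-time/bias-model
normalization, periodicity-based frame refinement, and stop-codon
metagenes are out of scope. Isoform double counting (above) means
region and codon counts are per-transcript evidence, not gene-level
estimates. The pause analysis reports descriptive scores; it performs
no significance testing.
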