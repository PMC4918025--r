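# ribopipe

A ribosome-profiling (Ribo-seq) processing pipeline for R: from aligned
footprints (BAM) to P-site-calibrated quantification.

Ribo-seq sequences the ~20–40 nt mRNA fragments protected from RNase
digestion by translating ribosomes. Before footprints can be counted on
codons or features, each read must be recalibrated: there is a fixed,
read-length-dependent distance (the *offset*) between a read's 5' or 3'
end and the ribosomal P-site. `ribopipe` covers the full standard
workflow for analysts working with such data:

- **Quality assessment** — histogram of read match lengths (which should
  be enriched in the footprint range).
- **Offset calibration** — per-read-length metagene profiles of read
  ends anchored at the translation start site (TSS) of the most
  expressed transcripts (top 3% by default), with an explicit,
  deterministic peak rule: for a 5'-end profile the offset is
  `-argmax` of the frequency over positions `[-window, -1]`,
  for a 3'-end profile `+argmax` over `[1, window]`; tied or weak peaks
  are flagged ambiguous rather than guessed.
- **Footprint counting** — P-site assignment
  (`tx(end5) + offset` or `tx(end3) - offset`) and per-transcript counts
  on 5'UTR / CDS / 3'UTR, plus codon-resolution coverage.
- **Motif analysis** — occurrence and footprint tables for 1–3-codon
  motifs (codon or amino-acid alphabet), PCA of codon occupancy, and
  per-ORF **pause scores** for stalling motifs such as Pro-Pro-X:

  ```
  score(motif | ORF) = (Reads_motif / Reads_ORF) / (N_motif / Length_ORF)
  ```

  the motif's footprint density relative to its uniform-coverage share
  (1 = no pausing), averaged per motif over all ORFs with more than 20
  footprints.
- **Synthetic data** — a generator that emits a genome FASTA, GTF and
  an aligned, sorted, indexed BAM with planted per-length offsets,
  log-normal expression, an initiation peak and stall multipliers, so
  every stage can be validated against known ground truth.

## Worked example

Simulate an experiment with known truth (offsets 12–14 nt from the 5'
end, a 10× stall multiplier planted on Pro-Pro-Trp), then run each stage:

```r
library(ribopipe)

cfg <- sim_config(seed = 1L, n_reads = 10000L, stall_multipliers = c(PPW = 10))
ref <- make_reference(cfg, "sim")
sim <- simulate_reads(cfg, ref$catalog, "sim")

reads <- stream_reads(sim$bam)                      # 20-40 nt, per strand ends
length_histogram(sim$bam)
#>   26   27   28   30
#> 2425 2568 2499 2508

ids <- select_top_transcripts(ref$catalog, reads, 0.03)
profiles <- metagene_profile(reads, ref$catalog, ids, "5prime", window = 30)
calibrate_offsets(profiles)
#>   read_length offset ambiguous
#> 1          26     12     FALSE
#> 2          27     13     FALSE
#> 3          28     13     FALSE
#> 4          30     14     FALSE

psites <- assign_psites(reads, ref$catalog, calibrate_offsets(profiles), "5prime")
colSums(count_regions(psites, ref$catalog)[c("utr5", "cds", "utr3")])
#> utr5  cds utr3
#>  390 9567   43

motif_pause_analysis(psites, ref$catalog, "PP?", 20, "window")
#> pause_table: 380 ORF x motif scores, 20 motifs
#>  motif mean_score n_orfs
#>    PPW  22.769150     19
#>    PPP   3.430127     19
#>    PPD   3.303044     19
#>    ...
```

The calibration recovers every planted offset exactly; footprints are
CDS-dominant with a small 5'UTR signal and a near-empty 3'UTR, as in
real libraries; and the planted PPW stall stands far above the other
PP(X) motifs (background window scores sit near 3, the exact
uniform-coverage value for a 3-codon window).

The same workflow runs in one call over one or more BAMs —
`run_pipeline(bams, gtf, fasta, outdir)` — writing per-sample TSVs
(histogram, metagene profiles, offset table, region counts, codon
coverage, motif counts, pause scores, PCA) plus a JSON run log, or from
a shell via `inst/scripts/ribopipe`.

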