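# Synthetic Ribo-seq data with known ground truth: a small multi-transcript
# reference (both strands, some spliced), reads whose chosen end sits at a
# planted per-length offset from the P-site, log-normal expression
# heterogeneity, an initiation peak at the start codon, and optional
# planted stall multipliers on amino-acid motifs.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# codons per amino acid (sense codons only)
.aa_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Configuration for the synthetic Ribo-seq generator
#'
#' Defaults emulate a small but realistic footprint experiment: 20
#' transcripts on both strands (every third one spliced), log-normal
#' expression so a "top few percent" selection is meaningful, a strong
#' ribosome peak on the initiation codon, mostly-CDS footprints with a
#' small 5'UTR fraction (uORF-like signal) and a near-empty 3'UTR, and a
#' per-read-length offset between the 5' read end and the P-site in the
#' 12-14 nt range typical of eukaryotic footprints. One copy of each of
#' the twenty Pro-Pro-X tripeptides is planted per CDS so that stalling
#' analyses have every motif represented.
#'
#' @param n_transcripts Number of transcripts.
#' @param utr5_range,utr3_range UTR length ranges in nt.
#' @param cds_codons_range CDS length range in codons (incl. start/stop).
#' @param offset_map Named integer vector: read length -> planted offset
#'   (distance from the chosen read end to the P-site).
#' @param end_mode `"5prime"` or `"3prime"`: which read end carries the
#'   planted offset.
#' @param expression_sdlog sdlog of the log-normal per-transcript
#'   abundance.
#' @param start_peak_weight Occupancy multiplier of the initiation codon
#'   relative to a background CDS codon.
#' @param stall_multipliers Named numeric: amino-acid motif (`"?"` matches
#'   any residue) -> occupancy multiplier applied to every codon of each
#'   occurrence.
#' @param insert_motifs Amino-acid motifs written into each CDS (one copy
#'   each, random synonymous codons) so they are guaranteed to occur.
#' @param utr5_read_fraction,utr3_read_fraction Fraction of P-sites drawn
#'   uniformly from the UTRs instead of the CDS.
#' @param n_reads Number of reads to simulate.
#' @param multi_exon_every Every k-th transcript receives one intron.
#' @param intron_range Intron length range in nt.
#' @param intergenic Intergenic gap in nt between transcript loci.
#' @param chrom_name Name of the single synthetic chromosome.
#' @param seed Integer seed; all outputs are bit-reproducible given the
#'   configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 20L,
                       utr5_range = c(40L, 90L),
                       cds_codons_range = c(120L, 240L),
                       utr3_range = c(40L, 90L),
                       offset_map = c("26" = 12L, "27" = 13L,
                                      "28" = 13L, "30" = 14L),
                       end_mode = c("5prime", "3prime"),
                       expression_sdlog = 1.5,
                       start_peak_weight = 30,
                       stall_multipliers = NULL,
                       insert_motifs = paste0("PP", .AA20),
                       utr5_read_fraction = 0.05,
                       utr3_read_fraction = 0.005,
                       n_reads = 10000L,
                       multi_exon_every = 3L,
                       intron_range = c(60L, 200L),
                       intergenic = 200L,
                       chrom_name = "chrS",
                       seed = 1L) {
  end_mode <- match.arg(end_mode)
  if (is.null(names(offset_map)) || any(offset_map < 0))
    stop("offset_map must be named (read length -> offset >= 0)")
  need <- 3L * length(insert_motifs) + 2L
  if (cds_codons_range[1L] < need)
    stop("cds_codons_range too small for the motifs to insert (need >= ",
         need, " codons)")
  if (utr5_range[1L] < max(offset_map) + 5L ||
      utr3_range[1L] < max(offset_map) + 5L)
    stop("UTR ranges too short for the largest planted offset")
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    utr5_range = as.integer(utr5_range),
    cds_codons_range = as.integer(cds_codons_range),
    utr3_range = as.integer(utr3_range),
    offset_map = offset_map, end_mode = end_mode,
    expression_sdlog = expression_sdlog,
    start_peak_weight = start_peak_weight,
    stall_multipliers = stall_multipliers,
    insert_motifs = insert_motifs,
    utr5_read_fraction = utr5_read_fraction,
    utr3_read_fraction = utr3_read_fraction,
    n_reads = as.integer(n_reads),
    multi_exon_every = as.integer(multi_exon_every),
    intron_range = as.integer(intron_range),
    intergenic = as.integer(intergenic),
    chrom_name = chrom_name, seed = as.integer(seed)),
    class = "sim_config")
}

.random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random CDS of n_codons: ATG + random sense codons + stop, with the
# configured amino-acid motifs written in at non-overlapping interior
# positions (random synonymous codons per residue).
.random_cds_codons <- function(n_codons, insert_motifs) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE), .STOP_CODONS)
  codons <- c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
              sample(.STOP_CODONS, 1L))
  if (length(insert_motifs)) {
    taken <- rep(FALSE, n_codons)
    taken[c(1L, n_codons)] <- TRUE
    for (motif in insert_motifs) {
      res <- strsplit(motif, "")[[1L]]
      m <- length(res)
      cand <- sample(which(!taken)[which(!taken) <= n_codons - m])
      placed <- FALSE
      for (s in cand) {
        if (any(taken[s:(s + m - 1L)])) next
        codons[s:(s + m - 1L)] <- vapply(res, function(a)
          sample(.aa_codons[[a]], 1L), "")
        taken[s:(s + m - 1L)] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place motif ", motif)
    }
  }
  codons
}

#' Generate a synthetic reference (genome FASTA + GTF + catalog)
#'
#' Builds the transcripts described by the configuration, places them on
#' alternating strands of one synthetic chromosome with intergenic gaps
#' (every `multi_exon_every`-th transcript gets one intron), and writes
#' the genome FASTA and an Ensembl-dialect GTF. The returned catalog is
#' identical to what [load_annotation()] reconstructs from those files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with `fasta`, `gtf` (paths) and `catalog`
#'   (a `transcript_catalog` with sequences).
#' @export
make_reference <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  nt <- cfg$n_transcripts
  ids <- sprintf("t%03d", seq_len(nt))
  gids <- sprintf("g%03d", seq_len(nt))
  chrom_parts <- character(0)
  pos <- 0L                       # running chromosome length (0-based)
  models <- list()
  seqs <- character(0)
  for (i in seq_len(nt)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    u5 <- sample(seq(cfg$utr5_range[1L], cfg$utr5_range[2L]), 1L)
    ncod <- sample(seq(cfg$cds_codons_range[1L], cfg$cds_codons_range[2L]), 1L)
    u3 <- sample(seq(cfg$utr3_range[1L], cfg$utr3_range[2L]), 1L)
    cds <- paste(.random_cds_codons(ncod, cfg$insert_motifs), collapse = "")
    txseq <- paste0(.random_nt(u5), cds, .random_nt(u3))
    txlen <- nchar(txseq)

    gap <- .random_nt(cfg$intergenic)
    chrom_parts <- c(chrom_parts, gap)
    pos <- pos + cfg$intergenic
    locus_start <- pos

    spliced <- cfg$multi_exon_every > 0L && i %% cfg$multi_exon_every == 0L
    if (spliced) {
      sp <- sample(seq(20L, txlen - 20L), 1L)
      ilen <- sample(seq(cfg$intron_range[1L], cfg$intron_range[2L]), 1L)
      gseq_tx <- paste0(substr(txseq, 1L, sp), .random_nt(ilen),
                        substr(txseq, sp + 1L, txlen))
      # exon offsets within the locus, in transcript orientation
      ex_off <- data.frame(start = c(0L, sp + ilen),
                           end = c(sp, txlen + ilen))
    } else {
      gseq_tx <- txseq
      ex_off <- data.frame(start = 0L, end = txlen)
    }
    glen <- nchar(gseq_tx)
    if (strand == "+") {
      gseq <- gseq_tx
      exons <- data.frame(start = locus_start + ex_off$start,
                          end = locus_start + ex_off$end)
    } else {
      gseq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gseq_tx)))
      # mirror: tx-oriented offset [a,b) -> plus-strand [glen-b, glen-a)
      exons <- data.frame(start = locus_start + glen - ex_off$end,
                          end = locus_start + glen - ex_off$start)
    }
    chrom_parts <- c(chrom_parts, gseq)
    pos <- pos + glen
    models[[ids[i]]] <- transcript_model(
      ids[i], gids[i], cfg$chrom_name, strand, exons,
      u5, u5 + nchar(cds))
    seqs[[ids[i]]] <- txseq
  }
  chrom_parts <- c(chrom_parts, .random_nt(cfg$intergenic))
  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- cfg$chrom_name

  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta)
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(.emit_gtf(models), gtf)
  list(fasta = fasta, gtf = gtf,
       catalog = transcript_catalog(models, Biostrings::DNAStringSet(seqs)))
}

# Ensembl-dialect GTF lines (1-based inclusive) for exon and CDS features.
.emit_gtf <- function(models) {
  lines <- character(0)
  for (model in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     model$gene_id, model$transcript_id)
    ex <- model$exons[order(model$exons$start), , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, paste(model$chrom, "sim", "exon",
                              ex$start[j] + 1L, ex$end[j], ".",
                              model$strand, ".", attrs, sep = "\t"))
    cb <- tx_interval_to_genomic_blocks(model, model$cds_start_tx,
                                        model$cds_end_tx)
    for (j in seq_len(nrow(cb)))
      lines <- c(lines, paste(model$chrom, "sim", "CDS",
                              cb$start[j] + 1L, cb$end[j], ".",
                              model$strand, ".", attrs, sep = "\t"))
  }
  lines
}

#' Simulate Ribo-seq reads with known P-sites
#'
#' Draws P-sites per transcript proportional to log-normal expression and,
#' within the CDS, per codon proportional to the stall multipliers (the
#' initiation codon carries `start_peak_weight`); CDS P-sites sit on the
#' first nucleotide of their codon (frame 0), UTR P-sites are uniform.
#' Each read is then laid out so that its chosen end (5' or 3' per
#' `end_mode`) lies exactly `offset_map[length]` nt from the P-site in
#' transcript space, spliced across exon junctions when required, and
#' written to a coordinate-sorted, indexed BAM. Draws that would place a
#' read end outside the transcript are rejected and redrawn.
#'
#' @param cfg A [sim_config()].
#' @param catalog Catalog from [make_reference()] (sequences required).
#' @param dir Output directory.
#' @return List with `bam` (path), `truth` (data.frame: `qname`,
#'   `transcript_id`, `psite_tx`, `read_length`, `region`), `truth_path`
#'   (TSV) and `expression` (named weights).
#' @export
simulate_reads <- function(cfg, catalog, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(catalog$sequences)) stop("catalog has no sequences")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 1L)
  ids <- names(catalog$models)
  w <- stats::rlnorm(length(ids), meanlog = 0, sdlog = cfg$expression_sdlog)
  w <- stats::setNames(w / sum(w), ids)

  codon_weights <- lapply(ids, function(tid) {
    model <- catalog$models[[tid]]
    aa <- .translate_codons(.codons(cds_seq(catalog, tid)))
    cw <- rep(1, length(aa))
    cw[1L] <- cfg$start_peak_weight
    for (motif in names(cfg$stall_multipliers)) {
      m <- nchar(motif)
      n <- length(aa) - m + 1L
      if (n < 1L) next
      win <- vapply(seq_len(n), function(i)
        paste(aa[i:(i + m - 1L)], collapse = ""), "")
      for (s in which(.motif_matcher(motif)(win)))
        cw[s:(s + m - 1L)] <- cw[s:(s + m - 1L)] * cfg$stall_multipliers[motif]
    }
    cw
  })
  names(codon_weights) <- ids

  lens <- as.integer(names(cfg$offset_map))
  tx_id <- character(0); psite <- integer(0)
  rlen <- integer(0); region <- character(0)
  need <- cfg$n_reads
  while (need > 0L) {
    ti <- sample(ids, need, replace = TRUE, prob = w)
    L <- sample(lens, need, replace = TRUE)
    off <- as.integer(cfg$offset_map[as.character(L)])
    u <- stats::runif(need)
    p <- integer(need); reg <- character(need)
    for (tid in unique(ti)) {
      sel <- which(ti == tid)
      model <- catalog$models[[tid]]
      cs <- model$cds_start_tx; ce <- model$cds_end_tx
      r <- ifelse(u[sel] < cfg$utr5_read_fraction & cs > 0L, "utr5",
                  ifelse(u[sel] < cfg$utr5_read_fraction +
                           cfg$utr3_read_fraction & ce < model$tx_length,
                         "utr3", "cds"))
      pp <- integer(length(sel))
      i5 <- r == "utr5"; i3 <- r == "utr3"; ic <- r == "cds"
      if (any(i5)) pp[i5] <- sample(seq(0L, cs - 1L), sum(i5), replace = TRUE)
      if (any(i3)) pp[i3] <- sample(seq(ce, model$tx_length - 1L),
                                    sum(i3), replace = TRUE)
      if (any(ic)) {
        cod <- sample(seq_along(codon_weights[[tid]]), sum(ic),
                      replace = TRUE, prob = codon_weights[[tid]])
        pp[ic] <- cs + 3L * (cod - 1L)
      }
      p[sel] <- pp; reg[sel] <- r
    }
    # read span in transcript coordinates given end mode and offset
    s <- if (cfg$end_mode == "5prime") p - off else p + off - L + 1L
    e <- s + L - 1L
    txlen <- vapply(catalog$models[ti], `[[`, 0L, "tx_length")
    ok <- s >= 0L & e < txlen
    tx_id <- c(tx_id, ti[ok]); psite <- c(psite, p[ok])
    rlen <- c(rlen, L[ok]); region <- c(region, reg[ok])
    need <- cfg$n_reads - length(tx_id)
  }
  truth <- data.frame(qname = sprintf("r%06d", seq_len(cfg$n_reads)),
                      transcript_id = tx_id, psite_tx = psite,
                      read_length = rlen, region = region,
                      stringsAsFactors = FALSE)

  sam <- file.path(dir, "reads.sam")
  .write_sam(truth, cfg, catalog, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(bam = bam, truth = truth, truth_path = truth_path, expression = w)
}

# Emit one SAM line per truth row: perfect-match alignments (M blocks
# separated by N gaps at exon junctions), strand of the transcript.
.write_sam <- function(truth, cfg, catalog, sam_path) {
  # chromosome length = max exon end + intergenic tail
  chrom_len <- max(vapply(catalog$models, function(m) max(m$exons$end), 0L)) +
    cfg$intergenic
  off <- as.integer(cfg$offset_map[as.character(truth$read_length)])
  lines <- character(nrow(truth) + 2L)
  lines[1L] <- "@HD\tVN:1.6"
  lines[2L] <- paste0("@SQ\tSN:", cfg$chrom_name, "\tLN:", chrom_len)
  for (k in seq_len(nrow(truth))) {
    tid <- truth$transcript_id[k]
    model <- catalog$models[[tid]]
    L <- truth$read_length[k]
    s <- if (cfg$end_mode == "5prime") truth$psite_tx[k] - off[k]
         else truth$psite_tx[k] + off[k] - L + 1L
    blocks <- tx_interval_to_genomic_blocks(model, s, s + L)
    widths <- blocks$end - blocks$start
    cigar <- if (nrow(blocks) == 1L) paste0(L, "M") else
      paste(paste0(widths, "M"),
            collapse = paste0(blocks$start[-1L] -
                                blocks$end[-nrow(blocks)], "N"))
    seqstr <- substr(as.character(catalog$sequences[[tid]]), s + 1L, s + L)
    flag <- 0L
    if (model$strand == "-") {
      flag <- 16L
      seqstr <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqstr)))
    }
    lines[k + 2L] <- paste(truth$qname[k], flag, model$chrom,
                           blocks$start[1L] + 1L, 50L, cigar, "*", 0L, 0L,
                           seqstr, "*", sep = "\t")
  }
  writeLines(lines, sam_path)
}
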