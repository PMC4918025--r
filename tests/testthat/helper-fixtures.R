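# Fixtures built in code: toy transcript models, tiny GTF/FASTA/BAM
# writers, and small constructed catalogs with sequences.

# The canonical toy transcript: + strand, one exon at genomic 100-399
# (1-based GTF coordinates), CDS 150-329. In 0-based terms: exon
# [99, 399), tx_length 300, CDS transcript span [50, 230).
toy_model_plus <- function() {
  transcript_model("tx_plus", "gene1", "chr1", "+",
                   data.frame(start = 99L, end = 399L), 50L, 230L)
}

# Minus-strand two-exon toy: exons 1000-1100 and 1200-1300 (1-based).
toy_model_minus <- function(cds_start_tx = 20L, cds_end_tx = 182L) {
  transcript_model("tx_minus", "gene2", "chr1", "-",
                   data.frame(start = c(1199L, 999L),
                              end = c(1300L, 1100L)),
                   cds_start_tx, cds_end_tx)
}

toy_gtf_lines <- function() {
  a1 <- 'gene_id "gene1"; transcript_id "tx_plus";'
  a2 <- 'gene_id "gene2"; transcript_id "tx_minus";'
  c(paste("chr1", "toy", "exon", 100, 399, ".", "+", ".", a1, sep = "\t"),
    paste("chr1", "toy", "CDS", 150, 329, ".", "+", ".", a1, sep = "\t"),
    paste("chr1", "toy", "exon", 1000, 1100, ".", "-", ".", a2, sep = "\t"),
    paste("chr1", "toy", "exon", 1200, 1300, ".", "-", ".", a2, sep = "\t"),
    paste("chr1", "toy", "CDS", 1020, 1100, ".", "-", ".", a2, sep = "\t"),
    paste("chr1", "toy", "CDS", 1200, 1280, ".", "-", ".", a2, sep = "\t"))
}

write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(toy_gtf_lines(), path)
  path
}

# Deterministic chr1 sequence long enough for the toy models.
write_toy_fasta <- function(path = tempfile(fileext = ".fa"), len = 1500L) {
  set.seed(424242)
  seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  writeLines(c(">chr1", seq), path)
  path
}

# Write a BAM from alignment tuples (qname, flag, pos1, cigar, mapq).
write_test_bam <- function(aln, chrom = "chr1", chrom_len = 2000L,
                           dest = tempfile()) {
  hdr <- c("@HD\tVN:1.6", paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  body <- vapply(seq_len(nrow(aln)), function(i) {
    n_m <- sum(as.integer(
      regmatches(aln$cigar[i],
                 gregexpr("[0-9]+(?=[MIX=])", aln$cigar[i], perl = TRUE))[[1]]))
    paste(aln$qname[i], aln$flag[i], chrom, aln$pos1[i],
          if (is.null(aln$mapq)) 50L else aln$mapq[i],
          aln$cigar[i], "*", 0L, 0L,
          strrep("A", n_m + sum(as.integer(regmatches(
            aln$cigar[i], gregexpr("[0-9]+(?=S)", aln$cigar[i],
                                   perl = TRUE))[[1]]))),
          "*", sep = "\t")
  }, "")
  sam <- paste0(dest, ".sam")
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# Single-exon plus-strand transcript with an attached sequence; genomic
# span [origin, origin + nchar(seq)).
seq_catalog <- function(seqs, cds_start, cds_end, chrom = "c1") {
  origin <- 0L
  models <- list()
  for (tid in names(seqs)) {
    len <- nchar(seqs[[tid]])
    models[[tid]] <- transcript_model(
      tid, paste0("g_", tid), chrom, "+",
      data.frame(start = origin, end = origin + len),
      cds_start[[tid]], cds_end[[tid]])
    origin <- origin + len + 100L
  }
  transcript_catalog(models, Biostrings::DNAStringSet(unlist(seqs)))
}

# A read data.frame row as stream_reads() would produce it.
make_read <- function(chrom, strand, left, match_length,
                      right = left + match_length) {
  data.frame(qname = "r", chrom = chrom, strand = strand,
             left = left, right = right, match_length = match_length,
             end5 = if (strand == "+") left else right - 1L,
             end3 = if (strand == "+") right - 1L else left,
             stringsAsFactors = FALSE)
}

# Metagene profile object built directly from a named frequency vector.
make_profile <- function(freq_at, window, end_used, read_length = 28L) {
  positions <- seq.int(-window, window)
  freq <- stats::setNames(integer(length(positions)), positions)
  for (p in names(freq_at)) freq[p] <- freq_at[[p]]
  structure(list(read_length = read_length, end_used = end_used,
                 window = as.integer(window), freq = freq,
                 n_transcripts = 1L),
            class = "metagene_profile")
}
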