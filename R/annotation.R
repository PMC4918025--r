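# Transcript models and genome <-> transcript coordinate maps.
#
# Internal coordinates are 0-based, half-open throughout; GTF input is
# converted from its 1-based inclusive convention at the parsing boundary
# and nowhere else.

#' Construct a transcript model
#'
#' A transcript model holds the exon structure of one transcript together
#' with the transcript-coordinate span of its coding sequence, from which
#' the 5'UTR and 3'UTR fall out as the flanking intervals. Exons are given
#' in transcript (5' to 3') orientation: ascending genomic coordinates on
#' the plus strand, descending on the minus strand.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons A data.frame with integer columns `start` and `end`
#'   (0-based half-open genomic coordinates), one row per exon, ordered
#'   5' to 3' along the transcript.
#' @param cds_start_tx,cds_end_tx CDS span in 0-based half-open transcript
#'   coordinates. The CDS is taken exactly as annotated; whether the stop
#'   codon is inside it follows the annotation's own convention.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start_tx, cds_end_tx) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1L)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exons$start >= exons$end)) stop("empty or inverted exon interval")
  # exons must be disjoint and ordered 5'->3' for the strand
  gs <- if (strand == "+") exons$start else rev(exons$start)
  ge <- if (strand == "+") exons$end else rev(exons$end)
  if (nrow(exons) > 1L && any(gs[-1L] < ge[-length(ge)]))
    stop("exons overlap or are out of transcript order")
  widths <- exons$end - exons$start
  tx_length <- sum(widths)
  cds_start_tx <- as.integer(cds_start_tx)
  cds_end_tx <- as.integer(cds_end_tx)
  if (!(cds_start_tx >= 0L && cds_start_tx < cds_end_tx &&
        cds_end_tx <= tx_length))
    stop("CDS span outside [0, tx_length) for ", transcript_id)
  structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exons = exons[, c("start", "end")],
    cds_start_tx = cds_start_tx,
    cds_end_tx = cds_end_tx,
    tx_length = as.integer(tx_length),
    # cumulative transcript offset at the 5' edge of each exon
    .cum = as.integer(c(0L, cumsum(widths))[seq_len(nrow(exons))])
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s  %d exon(s), tx_length=%d\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$tx_length))
  cat(sprintf("  5'UTR [0,%d)  CDS [%d,%d)  3'UTR [%d,%d)\n",
              x$cds_start_tx, x$cds_start_tx, x$cds_end_tx,
              x$cds_end_tx, x$tx_length))
  invisible(x)
}

#' Region lengths of a transcript model
#'
#' @param model A `transcript_model`.
#' @return Named integer vector with elements `utr5`, `cds`, `utr3`.
#' @export
region_lengths <- function(model) {
  c(utr5 = model$cds_start_tx,
    cds = model$cds_end_tx - model$cds_start_tx,
    utr3 = model$tx_length - model$cds_end_tx)
}

#' Map transcript positions to genomic positions
#'
#' @param model A `transcript_model`.
#' @param tpos Integer vector of 0-based transcript positions.
#' @return Integer vector of 0-based genomic positions; `NA` for positions
#'   outside `[0, tx_length)`.
#' @export
transcript_to_genome <- function(model, tpos) {
  tpos <- as.integer(tpos)
  out <- rep(NA_integer_, length(tpos))
  ok <- !is.na(tpos) & tpos >= 0L & tpos < model$tx_length
  if (!any(ok)) return(out)
  i <- findInterval(tpos[ok], model$.cum)          # exon index, 1-based
  off <- tpos[ok] - model$.cum[i]
  out[ok] <- if (model$strand == "+")
    model$exons$start[i] + off
  else
    model$exons$end[i] - 1L - off
  out
}

#' Map genomic positions to transcript positions
#'
#' The inverse of [transcript_to_genome()] on exonic positions; intronic or
#' flanking positions map to `NA` ("outside"). Total function: never errors
#' on any input position.
#'
#' @param model A `transcript_model`.
#' @param gpos Integer vector of 0-based genomic positions.
#' @return Integer vector of 0-based transcript positions, `NA` outside.
#' @export
genome_to_transcript <- function(model, gpos) {
  gpos <- as.integer(gpos)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons$start[i]; e <- model$exons$end[i]
    hit <- !is.na(gpos) & gpos >= s & gpos < e
    if (any(hit)) {
      out[hit] <- if (model$strand == "+")
        model$.cum[i] + (gpos[hit] - s)
      else
        model$.cum[i] + (e - 1L - gpos[hit])
    }
  }
  out
}

#' Build a transcript catalog from a GTF annotation
#'
#' Parses `exon` and `CDS` features (Ensembl GTF dialect,
#' `transcript_id "X"` attributes) into one [transcript_model()] per
#' transcript carrying at least one CDS record. When a genome FASTA is
#' supplied, transcript-oriented sequences are extracted (reverse
#' complemented on the minus strand).
#'
#' Transcripts whose CDS does not fall inside their exon union are rejected
#' with a warning rather than an error. All isoforms of a gene are kept;
#' no canonical-transcript selection is performed, so downstream counts may
#' double-count reads shared between isoforms.
#'
#' @param gtf_path Path to a GTF file.
#' @param fasta_path Optional path to the genome FASTA.
#' @param protein_coding_only Keep only transcripts with CDS records
#'   (transcripts without CDS cannot be modelled and are always skipped;
#'   with the flag unset a note reports how many were skipped).
#' @return A `transcript_catalog`: list with `models` (named list of
#'   `transcript_model`) and `sequences` (named `DNAStringSet` or `NULL`).
#' @export
load_annotation <- function(gtf_path, fasta_path = NULL,
                            protein_coding_only = TRUE) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  feat <- as.character(gr$type)
  if (is.null(gr$transcript_id))
    stop("GTF has no transcript_id attributes: ", gtf_path)
  keep <- feat %in% c("exon", "CDS")
  gr <- gr[keep]; feat <- feat[keep]
  bad <- which(is.na(gr$transcript_id))
  if (length(bad))
    stop("missing transcript_id attribute on GTF record(s) ",
         paste(head(bad, 5L), collapse = ", "), " of ", gtf_path)

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,      # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = feat,
    transcript_id = as.character(gr$transcript_id),
    gene_id = if (is.null(gr$gene_id)) NA_character_
              else as.character(gr$gene_id),
    stringsAsFactors = FALSE)

  genome <- NULL
  if (!is.null(fasta_path)) {
    genome <- Biostrings::readDNAStringSet(fasta_path)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }

  tx_ids <- sort(unique(df$transcript_id))
  has_cds <- unique(df$transcript_id[df$type == "CDS"])
  skipped_nc <- setdiff(tx_ids, has_cds)
  if (length(skipped_nc) && !protein_coding_only)
    message(length(skipped_nc),
            " transcript(s) without CDS skipped (no coding span to model)")
  tx_ids <- intersect(tx_ids, has_cds)

  models <- list()
  seqs <- character(0)
  for (tid in tx_ids) {
    sub <- df[df$transcript_id == tid, ]
    ex <- sub[sub$type == "exon", ]
    cds <- sub[sub$type == "CDS", ]
    if (nrow(ex) == 0L) {
      warning("transcript ", tid, " has CDS but no exons; skipped")
      next
    }
    strand <- ex$strand[1L]
    if (length(unique(ex$chrom)) > 1L || length(unique(ex$strand)) > 1L) {
      warning("transcript ", tid, " spans chromosomes/strands; skipped")
      next
    }
    ex <- ex[order(ex$start), ]
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
    gid <- sub$gene_id[1L]
    if (is.na(gid)) gid <- tid
    model0 <- tryCatch(
      transcript_model(tid, gid, ex$chrom[1L], strand,
                       data.frame(start = ex$start, end = ex$end),
                       0L, 1L),  # placeholder CDS, fixed below
      error = function(e) {
        warning("transcript ", tid, ": ", conditionMessage(e), "; skipped")
        NULL
      })
    if (is.null(model0)) next
    # CDS genomic span -> transcript coordinates through the exon map
    cds_first <- genome_to_transcript(model0, cds$start)
    cds_last <- genome_to_transcript(model0, cds$end - 1L)
    if (anyNA(cds_first) || anyNA(cds_last)) {
      warning("transcript ", tid, ": CDS outside exon union; model rejected")
      next
    }
    cs <- min(c(cds_first, cds_last))
    ce <- max(c(cds_first, cds_last)) + 1L
    if (ce - cs != sum(cds$end - cds$start)) {
      warning("transcript ", tid,
              ": CDS blocks not contiguous in transcript space; rejected")
      next
    }
    model <- transcript_model(tid, gid, ex$chrom[1L], strand,
                              data.frame(start = ex$start, end = ex$end),
                              cs, ce)
    models[[tid]] <- model
    if (!is.null(genome)) {
      if (!model$chrom %in% names(genome))
        stop("FASTA lacks chromosome ", model$chrom,
             " referenced by transcript ", tid)
      seqs[[tid]] <- extract_transcript_seq(model, genome)
    }
  }
  transcript_catalog(models,
                     if (is.null(genome)) NULL
                     else Biostrings::DNAStringSet(seqs))
}

#' Assemble a transcript catalog
#'
#' @param models Named list of `transcript_model` (names = transcript ids).
#' @param sequences Optional `DNAStringSet` of transcript-oriented
#'   sequences keyed by transcript id; lengths must match `tx_length`.
#' @return A `transcript_catalog`.
#' @export
transcript_catalog <- function(models, sequences = NULL) {
  if (is.null(names(models)) && length(models))
    names(models) <- vapply(models, `[[`, "", "transcript_id")
  if (anyDuplicated(names(models))) stop("duplicate transcript ids")
  if (!is.null(sequences)) {
    for (tid in names(sequences)) {
      if (!tid %in% names(models)) stop("sequence for unknown transcript ", tid)
      if (length(sequences[[tid]]) != models[[tid]]$tx_length)
        stop("sequence length != tx_length for ", tid)
    }
  }
  structure(list(models = models, sequences = sequences),
            class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("transcript_catalog: %d transcript(s)%s\n", length(x$models),
              if (is.null(x$sequences)) "" else " with sequences"))
  invisible(x)
}

#' @export
length.transcript_catalog <- function(x) length(x$models)

# Extract the transcript-oriented sequence of one model from a genome
# DNAStringSet. Exons are read in transcript order; minus-strand pieces
# are reverse complemented.
extract_transcript_seq <- function(model, genome) {
  chromseq <- genome[[model$chrom]]
  pieces <- vapply(seq_len(nrow(model$exons)), function(i) {
    p <- Biostrings::subseq(chromseq, model$exons$start[i] + 1L,
                            model$exons$end[i])
    if (model$strand == "-") p <- Biostrings::reverseComplement(p)
    as.character(p)
  }, character(1))
  paste(pieces, collapse = "")
}

#' CDS sequence of a transcript
#'
#' @param catalog A `transcript_catalog` with sequences.
#' @param transcript_id Transcript id.
#' @return Character scalar: the CDS nucleotide sequence.
#' @export
cds_seq <- function(catalog, transcript_id) {
  if (is.null(catalog$sequences)) stop("catalog has no sequences")
  model <- catalog$models[[transcript_id]]
  if (is.null(model)) stop("unknown transcript ", transcript_id)
  substr(as.character(catalog$sequences[[transcript_id]]),
         model$cds_start_tx + 1L, model$cds_end_tx)
}

# GRanges of all exons of a catalog, with transcript_id metadata; used by
# the overlap machinery in the offset and counting stages.
catalog_exon_ranges <- function(catalog) {
  ml <- catalog$models
  n <- vapply(ml, function(m) nrow(m$exons), 0L)
  GenomicRanges::GRanges(
    seqnames = rep(vapply(ml, `[[`, "", "chrom"), n),
    ranges = IRanges::IRanges(
      start = unlist(lapply(ml, function(m) m$exons$start)) + 1L,
      end = unlist(lapply(ml, function(m) m$exons$end))),
    strand = rep(vapply(ml, `[[`, "", "strand"), n),
    transcript_id = rep(names(ml), n))
}

# Map a transcript-coordinate interval [s, e) to its genomic blocks.
# Returns a data.frame(start, end) of 0-based half-open genomic intervals
# in ascending genomic order (possibly >1 row when the interval crosses an
# exon junction). Internal: used by the GTF emitter and read placement.
tx_interval_to_genomic_blocks <- function(model, s, e) {
  stopifnot(s >= 0L, e > s, e <= model$tx_length)
  starts <- integer(0); ends <- integer(0)
  cum <- model$.cum
  w <- model$exons$end - model$exons$start
  for (i in seq_len(nrow(model$exons))) {
    a <- max(s, cum[i]); b <- min(e, cum[i] + w[i])
    if (a >= b) next
    if (model$strand == "+") {
      gs <- model$exons$start[i] + (a - cum[i]); ge <- gs + (b - a)
    } else {
      ge <- model$exons$end[i] - (a - cum[i]); gs <- ge - (b - a)
    }
    starts <- c(starts, gs); ends <- c(ends, ge)
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}
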