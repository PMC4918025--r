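# Shift reads to P-sites with the calibrated per-length offsets and count
# footprints on 5'UTR / CDS / 3'UTR per transcript.

# Normalize the accepted offset representations (a calibrate_offsets()
# data.frame, a named vector keyed by read length, or one global scalar)
# into a named numeric map length -> offset; NA marks ambiguous lengths.
.as_offset_map <- function(offsets, lengths) {
  if (is.data.frame(offsets)) {
    stopifnot(all(c("read_length", "offset") %in% names(offsets)))
    return(stats::setNames(as.integer(offsets$offset),
                           as.character(offsets$read_length)))
  }
  if (is.numeric(offsets) && length(offsets) == 1L && is.null(names(offsets)))
    return(stats::setNames(rep(as.integer(offsets), length(lengths)),
                           as.character(lengths)))
  if (is.numeric(offsets) && !is.null(names(offsets)))
    return(stats::setNames(as.integer(offsets), names(offsets)))
  stop("offsets must be a calibration data.frame, a named vector, ",
       "or a single global value")
}

#' Assign reads to P-site transcript positions
#'
#' Shifts each read's chosen end by the offset calibrated for its length:
#' P-site = transcript position of the 5' end + offset (5' mode), or of the
#' 3' end - offset (3' mode). A read whose end lies in an exon of several
#' transcripts yields one event per transcript. Reads whose end does not
#' map to any transcript, whose length has no (or an ambiguous) offset, or
#' whose shifted position falls outside the transcript are dropped and
#' tallied in the `drops` attribute.
#'
#' @param reads data.frame from [stream_reads()].
#' @param catalog A `transcript_catalog`.
#' @param offsets Offset table from [calibrate_offsets()], a named vector
#'   (names = read lengths), or a single global offset applied to all
#'   lengths.
#' @param end_used `"5prime"` or `"3prime"`.
#' @param strict Error (rather than skip and log) when a streamed read
#'   length has no offset.
#' @return data.frame of P-site events (`transcript_id`, `tx_pos`,
#'   `read_length`) with attribute `drops`: named counts of dropped reads
#'   per reason (`no_offset`, `end_unmapped`, `out_of_range`).
#' @export
assign_psites <- function(reads, catalog, offsets,
                          end_used = c("5prime", "3prime"), strict = FALSE) {
  end_used <- match.arg(end_used)
  lens <- sort(unique(reads$match_length))
  omap <- .as_offset_map(offsets, lens)
  missing_len <- setdiff(as.character(lens), names(omap)[!is.na(omap)])
  if (strict && length(missing_len))
    stop("no offset for read length(s): ", paste(missing_len, collapse = ", "))

  drops <- c(no_offset = 0L, end_unmapped = 0L, out_of_range = 0L)
  has_off <- as.character(reads$match_length) %in%
    names(omap)[!is.na(omap)]
  drops["no_offset"] <- sum(!has_off)
  reads <- reads[has_off, , drop = FALSE]

  empty <- data.frame(transcript_id = character(0), tx_pos = integer(0),
                      read_length = integer(0))
  if (nrow(reads) == 0L || length(catalog$models) == 0L) {
    attr(empty, "drops") <- drops
    return(empty)
  }

  endpos <- if (end_used == "5prime") reads$end5 else reads$end3
  pts <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = endpos + 1L, width = 1L),
    strand = reads$strand)
  ex <- catalog_exon_ranges(catalog)
  hits <- GenomicRanges::findOverlaps(pts, ex)
  ri <- S4Vectors::queryHits(hits)
  tx <- ex$transcript_id[S4Vectors::subjectHits(hits)]
  pairs <- unique(data.frame(ri = ri, tx = tx, stringsAsFactors = FALSE))
  drops["end_unmapped"] <- sum(!seq_len(nrow(reads)) %in% pairs$ri)
  if (nrow(pairs) == 0L) {
    attr(empty, "drops") <- drops
    return(empty)
  }

  res_tx <- character(0); res_pos <- integer(0); res_len <- integer(0)
  for (tid in unique(pairs$tx)) {
    model <- catalog$models[[tid]]
    idx <- pairs$ri[pairs$tx == tid]
    tpos <- genome_to_transcript(model, endpos[idx])
    off <- omap[as.character(reads$match_length[idx])]
    p <- if (end_used == "5prime") tpos + off else tpos - off
    ok <- !is.na(p) & p >= 0L & p < model$tx_length
    drops["out_of_range"] <- drops["out_of_range"] + sum(!ok)
    if (any(ok)) {
      res_tx <- c(res_tx, rep(tid, sum(ok)))
      res_pos <- c(res_pos, as.integer(p[ok]))
      res_len <- c(res_len, reads$match_length[idx][ok])
    }
  }
  events <- data.frame(transcript_id = res_tx, tx_pos = res_pos,
                       read_length = res_len, stringsAsFactors = FALSE)
  attr(events, "drops") <- drops
  events
}

#' Count P-site events per transcript region
#'
#' Partitions each transcript's events into 5'UTR, CDS and 3'UTR by the
#' half-open region boundaries: `tx_pos < cds_start` is 5'UTR,
#' `cds_start <= tx_pos < cds_end` is CDS (so the start codon's first
#' nucleotide counts as CDS signal), the rest 3'UTR. Every catalog
#' transcript appears, with zeros when it received no events.
#'
#' @param psites data.frame from [assign_psites()].
#' @param catalog A `transcript_catalog`.
#' @return data.frame with columns `transcript_id`, `gene_id`, `utr5`,
#'   `cds`, `utr3`, `total`.
#' @export
count_regions <- function(psites, catalog) {
  ids <- names(catalog$models)
  out <- data.frame(
    transcript_id = ids,
    gene_id = vapply(catalog$models, `[[`, "", "gene_id"),
    utr5 = 0L, cds = 0L, utr3 = 0L, total = 0L,
    row.names = NULL, stringsAsFactors = FALSE)
  if (nrow(psites) == 0L) return(out)
  sp <- split(psites$tx_pos, psites$transcript_id)
  for (tid in names(sp)) {
    model <- catalog$models[[tid]]
    if (is.null(model)) stop("event for unknown transcript ", tid)
    p <- sp[[tid]]
    i <- match(tid, out$transcript_id)
    out$utr5[i] <- sum(p < model$cds_start_tx)
    out$cds[i] <- sum(p >= model$cds_start_tx & p < model$cds_end_tx)
    out$utr3[i] <- sum(p >= model$cds_end_tx)
    out$total[i] <- length(p)
  }
  out
}
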