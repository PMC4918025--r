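# BAM input: footprint records, match lengths, length histogram.

# Read mapped alignments from a BAM into the internal record layout.
# match_length counts query bases consumed by M/=/X/I CIGAR operations,
# i.e. aligned query length with soft/hard clips excluded — the closest
# portable reading of a read's "match size" across aligners.
.read_bam_records <- function(bam_path, sample_limit = NULL) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = c("mapq", "flag", "qname"))
  gal <- GenomicAlignments::readGAlignments(bam_path, param = param)
  if (!is.null(sample_limit) && length(gal) > sample_limit)
    gal <- gal[seq_len(sample_limit)]
  cig <- GenomicAlignments::cigar(gal)
  mlen <- vapply(
    GenomicAlignments::explodeCigarOpLengths(cig, ops = c("M", "=", "X", "I")),
    sum, 0L)
  left <- GenomicRanges::start(gal) - 1L            # 0-based
  right <- GenomicRanges::end(gal)                  # 0-based exclusive
  strand <- as.character(GenomicRanges::strand(gal))
  data.frame(
    qname = S4Vectors::mcols(gal)$qname,
    chrom = as.character(GenomicRanges::seqnames(gal)),
    strand = strand,
    left = left,
    right = right,
    match_length = mlen,
    end5 = ifelse(strand == "+", left, right - 1L),
    end3 = ifelse(strand == "+", right - 1L, left),
    mapq = S4Vectors::mcols(gal)$mapq,
    flag = S4Vectors::mcols(gal)$flag,
    stringsAsFactors = FALSE)
}

#' Histogram of read match lengths
#'
#' Tabulates the aligned query length (CIGAR M/=/X/I bases; soft and hard
#' clips excluded) of every mapped read. Visual inspection of this
#' distribution is the first quality check of a footprint library, which
#' should be enriched in the 20-40 nt range protected by the ribosome.
#'
#' @param bam_path Path to a BAM file.
#' @param sample_limit Optional cap on the number of records surveyed.
#' @return Named integer vector: `counts[length]` = number of reads;
#'   empty for an empty BAM.
#' @export
length_histogram <- function(bam_path, sample_limit = NULL) {
  rec <- .read_bam_records(bam_path, sample_limit)
  if (nrow(rec) == 0L) return(integer(0))
  tab <- table(rec$match_length)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Stream footprint-compatible reads from a BAM
#'
#' Yields mapped reads whose match length lies in `[min_len, max_len]`
#' (bounds inclusive), with the biological 5' and 3' end of each alignment
#' resolved per strand. Spliced (`N`-containing) alignments are kept; their
#' ends are taken from the full reference span and later resolved through
#' the transcript coordinate map.
#'
#' @param bam_path Path to a BAM file.
#' @param min_len,max_len Inclusive match-length window (defaults 20-40 nt,
#'   the standard ribosome-footprint enrichment range).
#' @param unique_only Drop reads flagged as secondary alignments and, when
#'   mapping quality is recorded, reads with MAPQ 0 — an aligner-portable
#'   approximation of "uniquely mapped".
#' @return data.frame with columns `qname`, `chrom`, `strand`, `left`,
#'   `right` (0-based half-open genomic span), `match_length`, `end5`,
#'   `end3` (0-based genomic positions of the read ends).
#' @export
stream_reads <- function(bam_path, min_len = 20L, max_len = 40L,
                         unique_only = FALSE) {
  if (min_len > max_len) stop("min_len > max_len")
  rec <- .read_bam_records(bam_path)
  keep <- rec$match_length >= min_len & rec$match_length <= max_len
  if (unique_only) {
    keep <- keep & bitwAnd(rec$flag, 256L) == 0L
    keep <- keep & !(!is.na(rec$mapq) & rec$mapq == 0L)
  }
  rec <- rec[keep, c("qname", "chrom", "strand", "left", "right",
                     "match_length", "end5", "end3")]
  rownames(rec) <- NULL
  rec
}
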