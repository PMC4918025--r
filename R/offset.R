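# P-site offset calibration: metagene profiles of read ends around the
# translation start site (TSS = first nt of the CDS) of the most expressed
# transcripts, and a deterministic peak-based offset estimate per read
# length.

# GRanges of the full read spans (1-based for GRanges arithmetic).
.read_span_ranges <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$left + 1L, end = reads$right),
    strand = reads$strand)
}

#' Select the most expressed transcripts
#'
#' Ranks transcripts by the number of reads overlapping their exons (raw
#' counts, strand-aware; any overlap counts once per read and transcript)
#' and returns the top fraction. These highly expressed transcripts anchor
#' the metagene profiles used for offset calibration; the conventional
#' default keeps the top 3%.
#'
#' @param catalog A `transcript_catalog`.
#' @param reads data.frame from [stream_reads()].
#' @param top_fraction Proportion of transcripts to keep (0 < f <= 1);
#'   `ceiling(f * N)` ids are returned. Ties at the cutoff are broken by
#'   transcript id, lexically, for determinism.
#' @return Character vector of transcript ids.
#' @export
select_top_transcripts <- function(catalog, reads, top_fraction = 0.03) {
  if (length(catalog$models) == 0L) stop("empty catalog")
  if (!(top_fraction > 0 && top_fraction <= 1))
    stop("top_fraction must be in (0, 1]")
  ids <- names(catalog$models)
  counts <- stats::setNames(integer(length(ids)), ids)
  if (nrow(reads) > 0L) {
    ex <- catalog_exon_ranges(catalog)
    hits <- GenomicRanges::findOverlaps(.read_span_ranges(reads), ex)
    pairs <- unique(data.frame(
      read = S4Vectors::queryHits(hits),
      tx = ex$transcript_id[S4Vectors::subjectHits(hits)]))
    if (nrow(pairs)) {
      tab <- table(pairs$tx)
      counts[names(tab)] <- as.integer(tab)
    }
  }
  n_keep <- ceiling(top_fraction * length(ids))
  ids[order(-counts, ids)][seq_len(n_keep)]
}

#' Metagene profiles of read ends around the translation start site
#'
#' For each selected transcript, each read whose chosen end (5' or 3')
#' maps within `window` nt of the first CDS nucleotide contributes one
#' count at its relative position, binned by its match length. A read
#' overlapping several selected isoforms contributes to each of their
#' profiles (isoform ambiguity is accepted rather than resolved).
#'
#' @param reads data.frame from [stream_reads()].
#' @param catalog A `transcript_catalog`.
#' @param ids Transcript ids to profile (typically from
#'   [select_top_transcripts()]).
#' @param end_used `"5prime"` or `"3prime"`: which read end is profiled.
#' @param window Half-width of the profile in nt (positions -window..window
#'   relative to the TSS; 0 = first CDS nt).
#' @param lengths Read lengths to profile; default: all observed.
#' @return Named list (one element per read length) of `metagene_profile`
#'   objects: lists with `read_length`, `end_used`, `window`, `freq` (named
#'   integer vector over relative positions) and `n_transcripts`.
#' @export
metagene_profile <- function(reads, catalog, ids,
                             end_used = c("5prime", "3prime"),
                             window = 50L, lengths = NULL) {
  end_used <- match.arg(end_used)
  if (length(ids) == 0L) stop("ids must be nonempty")
  if (window < 1L) stop("window must be >= 1")
  if (is.null(lengths)) lengths <- sort(unique(reads$match_length))
  positions <- seq.int(-window, window)
  empty <- stats::setNames(integer(length(positions)), positions)
  mats <- lapply(lengths, function(L) empty)
  names(mats) <- as.character(lengths)

  endpos <- if (end_used == "5prime") reads$end5 else reads$end3
  for (tid in ids) {
    model <- catalog$models[[tid]]
    if (is.null(model)) stop("unknown transcript ", tid)
    cand <- which(reads$chrom == model$chrom & reads$strand == model$strand &
                    reads$match_length %in% lengths)
    if (!length(cand)) next
    tpos <- genome_to_transcript(model, endpos[cand])
    rel <- tpos - model$cds_start_tx
    ok <- !is.na(rel) & rel >= -window & rel <= window
    if (!any(ok)) next
    inc <- table(L = reads$match_length[cand][ok], pos = rel[ok])
    pos_names <- colnames(inc)
    for (L in rownames(inc))
      mats[[L]][pos_names] <- mats[[L]][pos_names] +
        as.integer(inc[L, , drop = TRUE])
  }
  lapply(stats::setNames(names(mats), names(mats)), function(L)
    structure(list(read_length = as.integer(L), end_used = end_used,
                   window = as.integer(window), freq = mats[[L]],
                   n_transcripts = length(ids)),
              class = "metagene_profile"))
}

#' Sum metagene profiles across read lengths
#'
#' Groups lengths that share an offset into a single summary profile.
#'
#' @param profiles List of `metagene_profile` (same end mode and window).
#' @return A `metagene_profile` with `read_length = NA`.
#' @export
sum_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  w <- unique(vapply(profiles, `[[`, 0L, "window"))
  em <- unique(vapply(profiles, `[[`, "", "end_used"))
  if (length(w) != 1L || length(em) != 1L)
    stop("profiles differ in window or end mode")
  freq <- Reduce(`+`, lapply(profiles, `[[`, "freq"))
  structure(list(read_length = NA_integer_, end_used = em, window = w,
                 freq = freq, n_transcripts = profiles[[1L]]$n_transcripts),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile (%s end) length=%s window=%d total=%d\n",
              x$end_used, ifelse(is.na(x$read_length), "all", x$read_length),
              x$window, sum(x$freq)))
  invisible(x)
}

#' Tabulate metagene profiles for export
#'
#' @param profiles List of `metagene_profile`.
#' @return data.frame with columns `read_length`, `rel_pos`, `count`,
#'   `percent` (percentage of the profile's window total; 0 when empty).
#' @export
profile_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    tot <- sum(p$freq)
    data.frame(read_length = p$read_length,
               rel_pos = as.integer(names(p$freq)),
               count = as.integer(p$freq),
               percent = if (tot > 0) 100 * p$freq / tot else 0 * p$freq,
               row.names = NULL)
  }))
}

#' Estimate the P-site offset from one metagene profile
#'
#' The offset is read off as the position of the dominant read-end peak on
#' the expected side of the start codon: upstream (`[-window, -1]`) for 5'
#' ends, downstream (`[1, window]`) for 3' ends. Published pipelines
#' quantify this peak visually; here the argmax rule is made explicit and
#' guarded: a profile whose peak holds less than `min_fraction_at_peak` of
#' the window total, or whose maximum is tied, is reported as ambiguous
#' (`NA`) rather than guessed — surfacing read lengths with erratic TSS
#' distributions.
#'
#' @param profile A `metagene_profile`.
#' @param min_fraction_at_peak Minimum share of the window total the peak
#'   must hold for an unambiguous call.
#' @return Integer offset in nt (>= 0, measured from the chosen read end
#'   toward the read interior), or `NA_integer_` if ambiguous.
#' @export
estimate_offset <- function(profile, min_fraction_at_peak = 0.1) {
  pos <- as.integer(names(profile$freq))
  side <- if (profile$end_used == "5prime") pos <= -1L else pos >= 1L
  f <- profile$freq[side]
  p <- pos[side]
  tot <- sum(profile$freq)
  if (tot == 0L || sum(f) == 0L) return(NA_integer_)
  mx <- max(f)
  if (mx / tot < min_fraction_at_peak) return(NA_integer_)
  at <- p[f == mx]
  if (length(at) != 1L) return(NA_integer_)
  as.integer(abs(at))
}

#' Calibrate offsets for a set of read lengths
#'
#' Runs [estimate_offset()] on each per-length profile and collects the
#' result into an offset table.
#'
#' @param profiles Named list from [metagene_profile()].
#' @param min_fraction_at_peak Passed to [estimate_offset()].
#' @return data.frame with columns `read_length`, `offset` (`NA` when
#'   ambiguous) and `ambiguous` (logical flag).
#' @export
calibrate_offsets <- function(profiles, min_fraction_at_peak = 0.1) {
  off <- vapply(profiles, estimate_offset, integer(1),
                min_fraction_at_peak = min_fraction_at_peak)
  data.frame(read_length = vapply(profiles, `[[`, 0L, "read_length"),
             offset = off,
             ambiguous = is.na(off),
             row.names = NULL)
}
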