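# Per-ORF motif pause scores and per-motif averages: the readout for
# stalling motifs such as Pro-Pro-X, whose translation requires EF-P and
# which accumulate footprints in efp-knockout cells.

#' Pause score of a motif within one ORF
#'
#' The motif's footprint density relative to its expected share under
#' uniform coverage of the ORF:
#' \deqn{score = (Reads_{motif} / Reads_{ORF}) / (N_{motif} / Length_{ORF})}
#' A motif carrying exactly its uniform share scores 1; scores above 1
#' indicate footprint accumulation (pausing). ORF length is measured in
#' codons; because the score is a ratio of densities, any consistent unit
#' rescales all motifs of an ORF identically and leaves their ranking
#' unchanged. The score is invariant to scaling all coverage by a
#' constant.
#'
#' @param reads_motif Footprints attributed to the motif's occurrences in
#'   the ORF.
#' @param reads_orf Total footprints on the ORF (> 0).
#' @param n_motif Number of occurrences of the motif in the ORF (>= 1).
#' @param length_orf ORF length in codons (>= 1).
#' @return Numeric score (vectorized over the inputs).
#' @export
pause_score <- function(reads_motif, reads_orf, n_motif, length_orf) {
  if (any(reads_orf <= 0)) stop("reads_orf must be > 0")
  if (any(n_motif < 1)) stop("n_motif must be >= 1")
  if (any(length_orf < 1)) stop("length_orf must be >= 1")
  if (any(reads_motif > reads_orf))
    stop("reads_motif cannot exceed reads_orf")
  # single ratio of products: exact for integer inputs (no intermediate
  # rounding), identical algebraically to (density_motif / density_uniform)
  (reads_motif * length_orf) / (reads_orf * n_motif)
}

# Expand a motif pattern over the amino-acid alphabet ('?' = any residue)
# into a fixed-position character matrix check. Returns a function
# matching window strings.
.motif_matcher <- function(motif_spec) {
  chars <- strsplit(motif_spec, "")[[1L]]
  fixed <- which(chars != "?")
  function(windows) {
    if (!length(fixed)) return(rep(TRUE, length(windows)))
    ok <- rep(TRUE, length(windows))
    for (i in fixed)
      ok <- ok & substr(windows, i, i) == chars[i]
    ok
  }
}

#' Pause-score analysis of a motif family across ORFs
#'
#' For every ORF (annotated CDS) with more than `min_orf_footprints`
#' P-site footprints — strictly more, so an ORF with exactly the threshold
#' is excluded — each concrete amino-acid motif matching `motif_spec`
#' (e.g. `"PP?"` expands to the twenty Pro-Pro-X tripeptides present)
#' receives one pause score, computed from the ORF's codon coverage. The
#' summary averages scores per motif over ORFs, unweighted by expression.
#'
#' Footprint attribution per occurrence: `"window"` sums coverage over all
#' codons of the motif; `"last"` takes only the final codon (A-site
#' style). Under exactly uniform coverage, `"window"` scores equal the
#' motif length and `"last"` scores equal 1, for every motif.
#'
#' @param psites data.frame from [assign_psites()].
#' @param catalog A `transcript_catalog` with sequences.
#' @param motif_spec Pattern over the amino-acid alphabet; `"?"` matches
#'   any residue (including `*` for stop).
#' @param min_orf_footprints Strict lower bound on ORF footprints
#'   (default 20: ORFs must have more than this many).
#' @param attribution `"window"` or `"last"`.
#' @return A `pause_table`: list with `scores` (per-ORF rows: `orf_id`,
#'   `motif`, `reads_motif`, `reads_orf`, `n_motif`, `length_orf`,
#'   `pause_score`) and `summary` (`motif`, `mean_score`, `n_orfs`).
#' @export
motif_pause_analysis <- function(psites, catalog, motif_spec = "PP?",
                                 min_orf_footprints = 20L,
                                 attribution = c("window", "last")) {
  attribution <- match.arg(attribution)
  if (is.null(catalog$sequences)) stop("catalog has no sequences")
  coverage <- codon_coverage(psites, catalog)
  m <- nchar(motif_spec)
  if (!m %in% 1:3) stop("motif_spec must cover 1-3 codons")
  matches <- .motif_matcher(motif_spec)

  rows <- list()
  for (tid in names(coverage)) {
    cov <- coverage[[tid]]
    reads_orf <- sum(cov)
    if (reads_orf <= min_orf_footprints) next
    aa <- .translate_codons(.codons(cds_seq(catalog, tid)))
    n <- length(aa) - m + 1L
    if (n < 1L) next
    win <- vapply(seq_len(n), function(i)
      paste(aa[i:(i + m - 1L)], collapse = ""), "")
    sel <- which(matches(win))
    if (!length(sel)) next
    fp <- if (attribution == "window")
      vapply(sel, function(i) sum(cov[i:(i + m - 1L)]), 0L)
    else cov[sel + m - 1L]
    agg <- stats::aggregate(cbind(reads_motif = fp, n_motif = rep(1L,
                                                                  length(sel))),
                            by = list(motif = win[sel]), FUN = sum)
    agg$orf_id <- tid
    agg$reads_orf <- reads_orf
    agg$length_orf <- length(cov)
    rows[[tid]] <- agg
  }
  if (!length(rows)) {
    warning("no ORF passed the footprint filter or matched '",
            motif_spec, "'")
    scores <- data.frame(orf_id = character(0), motif = character(0),
                         reads_motif = numeric(0), reads_orf = numeric(0),
                         n_motif = integer(0), length_orf = integer(0),
                         pause_score = numeric(0))
    summary <- data.frame(motif = character(0), mean_score = numeric(0),
                          n_orfs = integer(0))
    return(structure(list(scores = scores, summary = summary),
                     class = "pause_table"))
  }
  scores <- do.call(rbind, rows)
  scores$pause_score <- pause_score(scores$reads_motif, scores$reads_orf,
                                    scores$n_motif, scores$length_orf)
  scores <- scores[order(scores$orf_id, scores$motif),
                   c("orf_id", "motif", "reads_motif", "reads_orf",
                     "n_motif", "length_orf", "pause_score")]
  rownames(scores) <- NULL
  summary <- stats::aggregate(scores$pause_score,
                              by = list(motif = scores$motif),
                              FUN = mean)
  names(summary)[2L] <- "mean_score"
  summary$n_orfs <- as.integer(table(scores$motif)[summary$motif])
  summary <- summary[order(summary$motif), ]
  rownames(summary) <- NULL
  structure(list(scores = scores, summary = summary), class = "pause_table")
}

#' @export
print.pause_table <- function(x, ...) {
  cat("pause_table:", nrow(x$scores), "ORF x motif scores,",
      nrow(x$summary), "motifs\n")
  if (nrow(x$summary)) {
    top <- x$summary[order(-x$summary$mean_score), ]
    print(utils::head(top, 10L), row.names = FALSE)
  }
  invisible(x)
}
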