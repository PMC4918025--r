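# Codon-resolution coverage, 1-3 codon motif quantification over CDS
# sequences, and PCA of codon occupancy.

# Split a CDS string into codons. Length must be a multiple of 3.
.codons <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Translate codon strings; stops become '*', unknowns 'X'.
.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Codon-resolution footprint coverage
#'
#' Bins CDS P-site events of each transcript into codons:
#' `codon = floor((tx_pos - cds_start) / 3)`. UTR events are ignored here.
#' Transcripts whose CDS length is not a multiple of 3 cannot be framed
#' into codons and are skipped with a warning.
#'
#' @param psites data.frame from [assign_psites()].
#' @param catalog A `transcript_catalog`.
#' @return Named list: per transcript, an integer vector of per-codon
#'   counts (length = CDS length / 3).
#' @export
codon_coverage <- function(psites, catalog) {
  out <- list()
  skipped <- character(0)
  for (tid in names(catalog$models)) {
    model <- catalog$models[[tid]]
    clen <- model$cds_end_tx - model$cds_start_tx
    if (clen %% 3L != 0L) {
      skipped <- c(skipped, tid)
      next
    }
    n_codon <- clen %/% 3L
    cov <- integer(n_codon)
    p <- psites$tx_pos[psites$transcript_id == tid]
    p <- p[p >= model$cds_start_tx & p < model$cds_end_tx]
    if (length(p)) {
      idx <- (p - model$cds_start_tx) %/% 3L
      tab <- table(idx)
      cov[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    out[[tid]] <- cov
  }
  if (length(skipped))
    warning("CDS length not a multiple of 3; skipped: ",
            paste(skipped, collapse = ", "))
  out
}

#' Long-format codon coverage table
#'
#' @param coverage List from [codon_coverage()].
#' @param catalog A `transcript_catalog` with sequences (for the codon
#'   column; omitted when sequences are absent).
#' @return data.frame `transcript_id`, `codon_index` (0-based), `codon`,
#'   `count`.
#' @export
codon_coverage_table <- function(coverage, catalog) {
  do.call(rbind, lapply(names(coverage), function(tid) {
    cov <- coverage[[tid]]
    codon <- if (!is.null(catalog$sequences) &&
                 tid %in% names(catalog$sequences))
      .codons(cds_seq(catalog, tid)) else NA_character_
    data.frame(transcript_id = tid,
               codon_index = seq_along(cov) - 1L,
               codon = codon, count = cov,
               stringsAsFactors = FALSE)
  }))
}

#' Quantify footprints on 1-3 codon motifs
#'
#' Slides a window of `motif_length` consecutive codons (step 1) along each
#' CDS and accumulates, per motif key (concatenated codons, or translated
#' residues with `*` for stops), the number of occurrences and the summed
#' footprint coverage. With `attribution = "window"` a window's footprints
#' are the coverage summed over all its codons; with `"last"` only the
#' final codon of the window counts — an A-site-style attribution for
#' stalling analyses, where the incoming codon drives the pause.
#'
#' For the amino-acid alphabet, ORFs with an internal stop codon are
#' skipped with a warning (their frame is suspect).
#'
#' @param coverage List from [codon_coverage()].
#' @param catalog A `transcript_catalog` with sequences.
#' @param motif_length 1, 2 or 3 codons.
#' @param alphabet `"amino_acid"` or `"codon"`.
#' @param attribution `"window"` or `"last"`.
#' @param by_transcript Keep one row per (transcript, motif) instead of
#'   aggregating over transcripts.
#' @return data.frame `motif`, `occurrences`, `footprints` (plus
#'   `transcript_id` when `by_transcript`), sorted by motif.
#' @export
motif_table <- function(coverage, catalog, motif_length = 3L,
                        alphabet = c("amino_acid", "codon"),
                        attribution = c("window", "last"),
                        by_transcript = FALSE) {
  alphabet <- match.arg(alphabet)
  attribution <- match.arg(attribution)
  if (!motif_length %in% 1:3) stop("motif_length must be 1, 2 or 3")
  if (is.null(catalog$sequences)) stop("catalog has no sequences")
  rows <- list()
  skipped <- character(0)
  for (tid in names(coverage)) {
    if (!tid %in% names(catalog$sequences))
      stop("no sequence for transcript ", tid)
    cov <- coverage[[tid]]
    codons <- .codons(cds_seq(catalog, tid))
    stopifnot(length(codons) == length(cov))
    keys <- codons
    if (alphabet == "amino_acid") {
      keys <- .translate_codons(codons)
      if (any(keys[-length(keys)] == "*")) {
        skipped <- c(skipped, tid)
        next
      }
    }
    n <- length(keys) - motif_length + 1L
    if (n < 1L) next
    motif <- vapply(seq_len(n), function(i)
      paste(keys[i:(i + motif_length - 1L)], collapse = ""), "")
    fp <- if (attribution == "window") {
      if (motif_length == 1L) cov[seq_len(n)]
      else vapply(seq_len(n), function(i)
        sum(cov[i:(i + motif_length - 1L)]), 0L)
    } else cov[seq_len(n) + motif_length - 1L]
    agg <- stats::aggregate(
      cbind(occurrences = rep(1L, n), footprints = fp),
      by = list(motif = motif), FUN = sum)
    agg$transcript_id <- tid
    rows[[tid]] <- agg
  }
  if (length(skipped))
    warning("internal stop codon; skipped: ", paste(skipped, collapse = ", "))
  if (!length(rows)) {
    out <- data.frame(motif = character(0), occurrences = integer(0),
                      footprints = integer(0))
    if (by_transcript) out$transcript_id <- character(0)
    return(out)
  }
  all <- do.call(rbind, rows)
  if (by_transcript) {
    out <- all[order(all$transcript_id, all$motif),
               c("transcript_id", "motif", "occurrences", "footprints")]
  } else {
    out <- stats::aggregate(all[c("occurrences", "footprints")],
                            by = list(motif = all$motif), FUN = sum)
    out <- out[order(out$motif), ]
  }
  rownames(out) <- NULL
  out
}

#' Per-transcript codon-occupancy matrix
#'
#' Aggregates codon coverage by codon identity: one row per transcript,
#' one column per codon (all 64), entries = summed footprints on that
#' codon in that transcript. The standard input for [codon_pca()].
#'
#' @param coverage List from [codon_coverage()].
#' @param catalog A `transcript_catalog` with sequences.
#' @return Numeric matrix, transcripts x 64 codons.
#' @export
codon_occupancy_matrix <- function(coverage, catalog) {
  if (is.null(catalog$sequences)) stop("catalog has no sequences")
  all_codons <- sort(names(Biostrings::GENETIC_CODE))
  m <- matrix(0, nrow = length(coverage), ncol = length(all_codons),
              dimnames = list(names(coverage), all_codons))
  for (tid in names(coverage)) {
    codons <- .codons(cds_seq(catalog, tid))
    s <- tapply(coverage[[tid]], codons, sum)
    m[tid, names(s)] <- s
  }
  m
}

#' PCA of codon occupancy
#'
#' Centered (optionally unit-variance scaled) principal component analysis
#' of a transcripts-by-codons occupancy matrix. Zero-variance columns are
#' dropped before the decomposition. Component signs are canonicalized so
#' that each loading vector's largest-magnitude entry is positive, making
#' results deterministic across platforms.
#'
#' @param mat Numeric matrix (rows = transcripts or samples, columns =
#'   codons).
#' @param scale Scale columns to unit variance.
#' @return A `codon_pca` object: list with `scores`, `loadings`,
#'   `explained_variance` (proportions, non-increasing) and `center`.
#' @export
codon_pca <- function(mat, scale = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 rows")
  v <- apply(mat, 2L, stats::var)
  keep <- v > 0
  if (sum(keep) < 2L) stop("no variance: need >= 2 columns with variance")
  mat <- mat[, keep, drop = FALSE]
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    l[which.max(abs(l))] < 0
  }, TRUE)
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance = ev, center = pc$center,
                 scale = if (scale) pc$scale else NULL),
            class = "codon_pca")
}

#' @export
print.codon_pca <- function(x, ...) {
  cat("codon_pca:", nrow(x$scores), "rows,", ncol(x$loadings),
      "components\n  explained variance:",
      paste(sprintf("%.1f%%", 100 * head(x$explained_variance, 5L)),
            collapse = " "), "\n")
  invisible(x)
}
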