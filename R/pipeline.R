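# One-call workflow over one or more BAMs: histogram, offset calibration,
# region counting, codon coverage, motif and pause tables, PCA, run log.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full footprint-processing workflow
#'
#' For each BAM: length histogram; metagene profiles of the chosen read
#' end around the TSS of the most expressed transcripts; per-length offset
#' calibration (skipped when explicit offsets are given); P-site
#' assignment; region counts (5'UTR/CDS/3'UTR); codon coverage; and, when
#' the catalog carries sequences, motif quantification, codon-occupancy
#' PCA and pause-score analysis. Results are written as TSV files plus a
#' JSON run log (parameters, drop statistics) into one subdirectory per
#' BAM. Samples are independent; with `workers > 1` they are processed
#' concurrently with results identical to a serial run. A failing sample
#' is reported in its `error.txt` and does not abort the others.
#'
#' @param bam_paths One or more BAM paths.
#' @param gtf_path GTF annotation.
#' @param fasta_path Optional genome FASTA (enables sequence-level
#'   analyses).
#' @param outdir Output directory.
#' @param min_len,max_len Footprint length window (inclusive).
#' @param unique_only Keep only uniquely mapped reads.
#' @param end_used `"5prime"` or `"3prime"`.
#' @param window Metagene half-width in nt.
#' @param top_fraction Fraction of transcripts used for calibration.
#' @param offsets Explicit offsets (named vector length -> offset, or one
#'   global value); `NULL` calibrates automatically.
#' @param motif_length,motif_alphabet,attribution Motif-table settings.
#' @param pause_motif Motif pattern for the pause analysis (`"?"` = any
#'   residue); `NULL` disables it.
#' @param min_orf_footprints Strict ORF footprint filter for pause scores.
#' @param workers Number of concurrent sample processes.
#' @param plots Also write summary plots (PDF).
#' @return Invisibly, a named list per sample: output directory or a
#'   condition object on failure.
#' @export
run_pipeline <- function(bam_paths, gtf_path, fasta_path = NULL,
                         outdir, min_len = 20L, max_len = 40L,
                         unique_only = FALSE,
                         end_used = c("5prime", "3prime"),
                         window = 50L, top_fraction = 0.03,
                         offsets = NULL, motif_length = 3L,
                         motif_alphabet = "amino_acid",
                         attribution = "window",
                         pause_motif = "PP?", min_orf_footprints = 20L,
                         workers = 1L, plots = FALSE) {
  end_used <- match.arg(end_used)
  for (p in c(bam_paths, gtf_path, fasta_path))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  catalog <- load_annotation(gtf_path, fasta_path)

  one <- function(bam) {
    name <- sub("\\.bam$", "", basename(bam))
    dir <- file.path(outdir, name)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tryCatch({
      hist <- length_histogram(bam)
      .write_tsv(data.frame(read_length = as.integer(names(hist)),
                            count = hist, row.names = NULL),
                 file.path(dir, "length_histogram.tsv"))
      reads <- stream_reads(bam, min_len, max_len, unique_only)

      ids <- select_top_transcripts(catalog, reads, top_fraction)
      profiles <- metagene_profile(reads, catalog, ids, end_used, window)
      .write_tsv(profile_table(profiles),
                 file.path(dir, "metagene_profiles.tsv"))
      offtab <- if (is.null(offsets)) calibrate_offsets(profiles) else {
        omap <- .as_offset_map(offsets, sort(unique(reads$match_length)))
        data.frame(read_length = as.integer(names(omap)),
                   offset = unname(omap), ambiguous = is.na(omap))
      }
      .write_tsv(offtab, file.path(dir, "offset_table.tsv"))

      psites <- assign_psites(reads, catalog, offtab, end_used)
      regions <- count_regions(psites, catalog)
      .write_tsv(regions, file.path(dir, "region_counts.tsv"))
      coverage <- codon_coverage(psites, catalog)

      have_seq <- !is.null(catalog$sequences)
      if (have_seq) {
        .write_tsv(codon_coverage_table(coverage, catalog),
                   file.path(dir, "codon_coverage.tsv"))
        .write_tsv(motif_table(coverage, catalog, motif_length,
                               motif_alphabet, attribution),
                   file.path(dir, "motif_counts.tsv"))
        occ <- codon_occupancy_matrix(coverage, catalog)
        pca_note <- NULL
        pca <- tryCatch(codon_pca(occ), error = function(e) {
          pca_note <<- conditionMessage(e); NULL
        })
        if (!is.null(pca)) {
          .write_tsv(data.frame(transcript_id = rownames(pca$scores),
                                pca$scores, row.names = NULL),
                     file.path(dir, "pca_scores.tsv"))
          .write_tsv(data.frame(codon = rownames(pca$loadings),
                                pca$loadings, row.names = NULL),
                     file.path(dir, "pca_loadings.tsv"))
        }
        if (!is.null(pause_motif)) {
          pt <- motif_pause_analysis(psites, catalog, pause_motif,
                                     min_orf_footprints, attribution)
          .write_tsv(pt$scores, file.path(dir, "pause_scores.tsv"))
          .write_tsv(pt$summary, file.path(dir, "pause_summary.tsv"))
        }
      }
      if (plots) .write_plots(dir, hist, profiles,
                              if (have_seq && !is.null(pause_motif)) pt
                              else NULL)
      log <- list(
        package = "ribopipe",
        version = as.character(utils::packageVersion("ribopipe")),
        bam = bam, gtf = gtf_path, fasta = fasta_path,
        parameters = list(min_len = min_len, max_len = max_len,
                          unique_only = unique_only, end_used = end_used,
                          window = window, top_fraction = top_fraction,
                          explicit_offsets = !is.null(offsets),
                          offsets = stats::setNames(
                            as.list(offtab$offset),
                            offtab$read_length),
                          motif_length = motif_length,
                          attribution = attribution,
                          pause_motif = pause_motif,
                          min_orf_footprints = min_orf_footprints),
        n_reads = nrow(reads),
        calibration_transcripts = ids,
        drops = as.list(attr(psites, "drops")))
      writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE,
                                  null = "null"),
                 file.path(dir, "run_log.json"))
      dir
    }, error = function(e) {
      writeLines(conditionMessage(e), file.path(dir, "error.txt"))
      e
    })
  }

  res <- if (workers > 1L)
    parallel::mclapply(bam_paths, one, mc.cores = workers)
  else lapply(bam_paths, one)
  names(res) <- basename(bam_paths)
  failed <- vapply(res, inherits, TRUE, "condition")
  if (any(failed))
    warning("sample(s) failed: ", paste(names(res)[failed], collapse = ", "))
  invisible(res)
}

# Summary plots: length histogram, per-length metagene panels with a line
# at the TSS, and the mean pause score per motif.
.write_plots <- function(dir, hist, profiles, pause_table) {
  grDevices::pdf(file.path(dir, "report.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off())
  if (length(hist))
    graphics::barplot(hist, xlab = "match length (nt)", ylab = "reads",
                      main = "Read length distribution")
  for (p in profiles) {
    graphics::plot(as.integer(names(p$freq)), p$freq, type = "h",
                   xlab = "position relative to TSS (nt)", ylab = "read ends",
                   main = sprintf("%s-end metagene, length %s",
                                  sub("prime", "'", p$end_used),
                                  p$read_length))
    graphics::abline(v = 0, col = "red", lty = 2)
  }
  if (length(profiles) > 1L) {
    s <- sum_profiles(profiles)
    graphics::plot(as.integer(names(s$freq)), s$freq, type = "h",
                   xlab = "position relative to TSS (nt)", ylab = "read ends",
                   main = "All lengths summed")
    graphics::abline(v = 0, col = "red", lty = 2)
  }
  if (!is.null(pause_table) && nrow(pause_table$summary)) {
    s <- pause_table$summary[order(pause_table$summary$motif), ]
    graphics::barplot(s$mean_score, names.arg = s$motif, las = 2,
                      ylab = "mean pause score",
                      main = "Average ribosome occupancy per motif")
    graphics::abline(h = 1, lty = 2)
  }
}
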