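# Build a single-exon coding catalog and a P-site event table giving each
# codon of each CDS a chosen coverage. Used throughout the pause tests.
psites_from_coverage <- function(catalog, coverage) {
  rows <- lapply(names(coverage), function(tid) {
    m <- catalog$models[[tid]]
    cov <- coverage[[tid]]
    pos <- rep(m$cds_start_tx + 3L * (seq_along(cov) - 1L), cov)
    if (!length(pos)) return(NULL)
    data.frame(transcript_id = tid, tx_pos = pos, read_length = 28L)
  })
  do.call(rbind, rows)
}

# 100-codon ORF: ATG + 98 sense codons with one PPN at codons 10-12
# (0-based indices) + TAA stop.
ppn_orf <- function() {
  body <- rep("GCT", 98L)                 # alanine background
  body[c(10L, 11L)] <- "CCA"              # Pro Pro
  body[12L] <- "AAT"                      # Asn
  paste(c("ATG", body, "TAA"), collapse = "")
}

test_that("pause score follows the density-ratio identity", {
  expect_equal(pause_score(1, 100, 1, 100), 1.0)       # uniform share -> 1
  expect_equal(pause_score(0, 100, 1, 100), 0)
  expect_equal(pause_score(30, 100, 2, 100), 15.0)
  expect_error(pause_score(1, 0, 1, 100), "reads_orf")
  expect_error(pause_score(5, 4, 1, 100), "exceed")
  # scale invariance: multiplying all coverage by c changes nothing
  expect_equal(pause_score(30 * 7, 100 * 7, 2, 100), 15.0)
})

test_that("single planted PPN in a uniform ORF scores the worked value", {
  catalog <- seq_catalog(list(orf1 = ppn_orf()), c(orf1 = 0L),
                         c(orf1 = 300L))
  psites <- psites_from_coverage(catalog, list(orf1 = rep(1L, 100L)))
  pt <- motif_pause_analysis(psites, catalog, "PPN", 20L, "window")
  expect_equal(pt$scores$reads_motif, 3)
  expect_equal(pt$scores$reads_orf, 100)
  expect_equal(pt$scores$n_motif, 1L)
  expect_equal(pt$scores$length_orf, 100L)
  expect_equal(pt$scores$pause_score, 3.0)
})

test_that("the ORF footprint filter is strictly greater-than", {
  catalog <- seq_catalog(list(orf1 = ppn_orf()), c(orf1 = 0L),
                         c(orf1 = 300L))
  cov20 <- c(rep(1L, 20L), rep(0L, 80L))
  expect_warning(
    pt20 <- motif_pause_analysis(psites_from_coverage(catalog,
                                                      list(orf1 = cov20)),
                                 catalog, "PP?", 20L),
    "no ORF")
  expect_equal(nrow(pt20$scores), 0L)
  cov21 <- c(rep(1L, 21L), rep(0L, 79L))
  pt21 <- motif_pause_analysis(psites_from_coverage(catalog,
                                                    list(orf1 = cov21)),
                               catalog, "PP?", 20L)
  expect_equal(nrow(pt21$scores), 1L)
})

test_that("uniform coverage gives exact null scores in both attributions", {
  set.seed(55)
  # several ORFs with assorted PP(X) motifs planted
  mk <- function(extra) {
    body <- rep("GCT", 120L)
    i <- 5L
    for (aa in extra) {
      body[c(i, i + 1L)] <- "CCG"
      body[i + 2L] <- switch(aa, N = "AAC", W = "TGG", D = "GAT",
                             G = "GGC", K = "AAA")
      i <- i + 10L
    }
    paste(c("ATG", body, "TAA"), collapse = "")
  }
  seqs <- list(o1 = mk(c("N", "W")), o2 = mk(c("D", "G", "K")),
               o3 = mk("N"))
  catalog <- seq_catalog(seqs, stats::setNames(rep(0L, 3), names(seqs)),
                         stats::setNames(rep(366L, 3), names(seqs)))
  coverage <- stats::setNames(rep(list(rep(2L, 122L)), 3), names(seqs))
  psites <- psites_from_coverage(catalog, coverage)
  # window attribution: every motif scores exactly its length in codons
  ptw <- motif_pause_analysis(psites, catalog, "PP?", 20L, "window")
  expect_true(all(ptw$scores$pause_score == 3.0))
  # last-codon attribution: every motif scores exactly 1
  ptl <- motif_pause_analysis(psites, catalog, "PP?", 20L, "last")
  expect_true(all(ptl$scores$pause_score == 1.0))
})

test_that("summary means agree with an independent group-by", {
  set.seed(56)
  body <- function() {
    b <- rep("GCT", 80L)
    b[c(10L, 11L)] <- "CCA"; b[12L] <- "AAT"
    b[c(40L, 41L)] <- "CCG"; b[42L] <- "TGG"
    paste(c("ATG", b, "TAA"), collapse = "")
  }
  seqs <- list(a = body(), b = body(), c = body())
  catalog <- seq_catalog(seqs, stats::setNames(rep(0L, 3), names(seqs)),
                         stats::setNames(rep(246L, 3), names(seqs)))
  coverage <- lapply(stats::setNames(names(seqs), names(seqs)), function(i)
    as.integer(stats::rpois(82L, 3)) + 1L)
  pt <- motif_pause_analysis(psites_from_coverage(catalog, coverage),
                             catalog, "PP?", 20L)
  oracle <- tapply(pt$scores$pause_score, pt$scores$motif, mean)
  expect_equal(pt$summary$mean_score,
               as.vector(oracle[pt$summary$motif]))
  oracle_n <- tapply(pt$scores$pause_score, pt$scores$motif, length)
  expect_equal(pt$summary$n_orfs,
               as.vector(as.integer(oracle_n[pt$summary$motif])))
})

test_that("planted stall multipliers raise the motif's mean pause score", {
  cfg <- sim_config(seed = 61L, n_reads = 10000L,
                    stall_multipliers = c(PPW = 10))
  ref <- make_reference(cfg, file.path(tempdir(), "pause_sim"))
  sim <- simulate_reads(cfg, ref$catalog, file.path(tempdir(), "pause_sim"))
  ps <- assign_psites(stream_reads(sim$bam), ref$catalog, cfg$offset_map,
                      "5prime")
  pt <- motif_pause_analysis(ps, ref$catalog, "PP?", 20L, "window")
  s <- stats::setNames(pt$summary$mean_score, pt$summary$motif)
  expect_gt(s[["PPW"]], max(s[names(s) != "PPW"]))
  expect_gt(s[["PPW"]] / max(s[names(s) != "PPW"]), 3)
})
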