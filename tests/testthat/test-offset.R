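test_that("top-transcript selection ranks by overlapping read count", {
  # 100 single-exon transcripts, 300 nt apart; read counts 1..100
  models <- lapply(1:100, function(i)
    transcript_model(sprintf("t%03d", i), sprintf("g%03d", i), "c1", "+",
                     data.frame(start = (i - 1L) * 300L,
                                end = (i - 1L) * 300L + 200L),
                     50L, 150L))
  catalog <- transcript_catalog(models)
  reads <- do.call(rbind, lapply(1:100, function(i)
    do.call(rbind, replicate(i, make_read("c1", "+", (i - 1L) * 300L + 60L,
                                          28L), simplify = FALSE))))
  top <- select_top_transcripts(catalog, reads, 0.03)
  expect_equal(top, c("t100", "t099", "t098"))
  expect_equal(length(select_top_transcripts(catalog, reads, 1.0)), 100L)
  expect_error(select_top_transcripts(transcript_catalog(list()), reads),
               "empty")
})

test_that("rank-boundary ties go to the lexically smaller id", {
  models <- lapply(c("aa", "bb", "cc", "dd"), function(id)
    transcript_model(id, id, "c1", "+",
                     data.frame(start = 0L, end = 100L), 10L, 70L))
  catalog <- transcript_catalog(models)
  # aa: 2 reads; bb, cc, dd: 1 each -> keep 2, tie between bb/cc/dd
  reads <- do.call(rbind, list(make_read("c1", "+", 20L, 28L),
                               make_read("c1", "+", 30L, 28L)))
  top <- select_top_transcripts(catalog, reads, 0.5)
  expect_equal(top, c("aa", "bb"))
})

test_that("a single read lands at its relative position in the profile", {
  model <- toy_model_plus()
  catalog <- transcript_catalog(list(model))
  # 5' end 13 nt upstream of the CDS start: transcript position 37
  g5 <- transcript_to_genome(model, 37L)
  reads <- make_read("chr1", "+", g5, 28L)
  prof <- metagene_profile(reads, catalog, "tx_plus", "5prime", 50L)
  expect_equal(sum(prof[["28"]]$freq), 1L)
  expect_equal(unname(prof[["28"]]$freq["-13"]), 1L)

  # an end outside the window contributes nothing
  far <- make_read("chr1", "+", transcript_to_genome(model, 150L), 28L)
  prof2 <- metagene_profile(far, catalog, "tx_plus", "5prime", 50L)
  expect_equal(sum(prof2[["28"]]$freq), 0L)
})

test_that("mirrored minus-strand geometry gives the identical profile", {
  plus <- toy_model_plus()
  minus <- transcript_model("tx_m", "g", "chr1", "-",
                            data.frame(start = 999L, end = 1300L),
                            50L, 230L)
  catalog <- transcript_catalog(list(plus, minus))
  rel <- -13L
  r_plus <- make_read("chr1", "+",
                      transcript_to_genome(plus, plus$cds_start_tx + rel),
                      28L)
  g_m <- transcript_to_genome(minus, minus$cds_start_tx + rel)
  r_minus <- make_read("chr1", "-", g_m - 27L, 28L)  # end5 = right - 1 = g_m
  p1 <- metagene_profile(r_plus, catalog, "tx_plus", "5prime", 50L)
  p2 <- metagene_profile(r_minus, catalog, "tx_m", "5prime", 50L)
  expect_identical(p1[["28"]]$freq, p2[["28"]]$freq)
})

test_that("offset estimation reads the peak on the expected side", {
  expect_equal(estimate_offset(make_profile(list("-13" = 100L), 50L,
                                            "5prime")), 13L)
  expect_equal(estimate_offset(make_profile(list("15" = 100L), 50L,
                                            "3prime")), 15L)
  # uniform profile: every position tied -> ambiguous
  uni <- make_profile(as.list(stats::setNames(rep(1L, 101), -50:50)),
                      50L, "5prime")
  expect_true(is.na(estimate_offset(uni)))
  # tie between two peaks -> ambiguous, never guessed
  tie <- make_profile(list("-13" = 50L, "-12" = 50L), 50L, "5prime")
  expect_true(is.na(estimate_offset(tie)))
  # peak below the required share of the window total -> ambiguous
  weak <- make_profile(c(list("-13" = 5L),
                         as.list(stats::setNames(rep(3L, 50), 1:50))),
                       50L, "5prime")
  expect_true(is.na(estimate_offset(weak)))
  # all-zero profile -> ambiguous
  expect_true(is.na(estimate_offset(make_profile(list(), 50L, "5prime"))))
})

test_that("profile counts are conserved and selection order is irrelevant", {
  cfg <- sim_config(seed = 21L, n_reads = 2000L)
  ref <- make_reference(cfg, file.path(tempdir(), "off_prop"))
  sim <- simulate_reads(cfg, ref$catalog, file.path(tempdir(), "off_prop"))
  reads <- stream_reads(sim$bam)
  ids <- names(ref$catalog$models)[1:5]
  prof <- metagene_profile(reads, ref$catalog, ids, "5prime", 40L)
  prof_rev <- metagene_profile(reads, ref$catalog, rev(ids), "5prime", 40L)
  for (L in names(prof))
    expect_identical(prof[[L]]$freq, prof_rev[[L]]$freq)
  # conservation: window totals count exactly the contributing read ends
  endpos <- reads$end5
  expected <- 0L
  for (tid in ids) {
    m <- ref$catalog$models[[tid]]
    sel <- reads$chrom == m$chrom & reads$strand == m$strand
    tpos <- genome_to_transcript(m, endpos[sel])
    rel <- tpos - m$cds_start_tx
    expected <- expected + sum(!is.na(rel) & abs(rel) <= 40L)
  }
  expect_equal(sum(vapply(prof, function(p) sum(p$freq), 0L)), expected)
})

test_that("planted offsets are recovered per length on simulated data", {
  cfg <- sim_config(seed = 22L, n_reads = 8000L,
                    offset_map = c("26" = 12L, "28" = 13L, "30" = 14L))
  ref <- make_reference(cfg, file.path(tempdir(), "off_rec"))
  sim <- simulate_reads(cfg, ref$catalog, file.path(tempdir(), "off_rec"))
  reads <- stream_reads(sim$bam)
  ids <- select_top_transcripts(ref$catalog, reads, 0.2)
  prof <- metagene_profile(reads, ref$catalog, ids, "5prime", 30L)
  got <- calibrate_offsets(prof)
  expect_equal(stats::setNames(got$offset, got$read_length),
               c("26" = 12L, "28" = 13L, "30" = 14L))
})
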