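test_that("codon coverage bins CDS events by frame-0 triplets", {
  model <- toy_model_plus()
  catalog <- transcript_catalog(list(model))
  cs <- model$cds_start_tx
  psites <- data.frame(transcript_id = "tx_plus",
                       tx_pos = c(cs, cs + 3L, cs + 4L, cs + 5L, 10L),
                       read_length = 28L)
  cov <- codon_coverage(psites, catalog)[["tx_plus"]]
  expect_length(cov, 60L)                 # 180 nt CDS
  expect_equal(cov[1L], 1L)               # event at the CDS start: codon 0
  expect_equal(cov[2L], 3L)               # +3, +4, +5 all in codon 1
  expect_equal(sum(cov), 4L)              # the UTR event is ignored
})

test_that("codon coverage equals an independent brute-force binning", {
  set.seed(88)
  model <- toy_model_plus()
  catalog <- transcript_catalog(list(model))
  psites <- data.frame(transcript_id = "tx_plus",
                       tx_pos = sample.int(model$tx_length, 500L,
                                           replace = TRUE) - 1L,
                       read_length = 28L)
  cov <- codon_coverage(psites, catalog)[["tx_plus"]]
  naive <- integer(60L)
  for (p in psites$tx_pos)
    if (p >= 50L && p < 230L) {
      i <- (p - 50L) %/% 3L + 1L
      naive[i] <- naive[i] + 1L
    }
  expect_equal(cov, naive)
  # conservation against the region counter on identical input
  rc <- count_regions(psites, catalog)
  expect_equal(sum(cov), rc$cds)
})

test_that("a CDS whose length is not a multiple of 3 is skipped", {
  model <- transcript_model("bad", "g", "c1", "+",
                            data.frame(start = 0L, end = 100L), 10L, 30L)
  model2 <- transcript_model("ok", "g2", "c1", "+",
                             data.frame(start = 200L, end = 300L), 10L, 31L)
  catalog <- transcript_catalog(list(model2, model))
  ps <- data.frame(transcript_id = "ok", tx_pos = 10L, read_length = 28L)
  expect_warning(cov <- codon_coverage(ps, catalog), "multiple of 3")
  expect_named(cov, "ok")   # 30-10 = 20 nt is not framable; 31-10 = 21 is
})

test_that("motif windows are translated and counted as in a hand scan", {
  catalog <- seq_catalog(list(t1 = "ATGCCACCGAATTAA"),
                         c(t1 = 0L), c(t1 = 15L))
  cov <- list(t1 = c(1L, 2L, 4L, 8L, 16L))
  mt <- motif_table(cov, catalog, motif_length = 3L, alphabet = "amino_acid")
  expect_equal(mt$motif, c("MPP", "PN*", "PPN"))
  expect_equal(mt$occurrences, c(1L, 1L, 1L))
  # window attribution sums coverage over all codons of the window
  expect_equal(mt$footprints[mt$motif == "PPN"], 2L + 4L + 8L)
  # A-site-style attribution takes the final codon only
  ml <- motif_table(cov, catalog, 3L, "amino_acid", attribution = "last")
  expect_equal(ml$footprints[ml$motif == "PPN"], 8L)
  # all-zero coverage leaves occurrences intact, footprints zero
  m0 <- motif_table(list(t1 = integer(5L)), catalog, 3L, "amino_acid")
  expect_equal(m0$occurrences, c(1L, 1L, 1L))
  expect_equal(sum(m0$footprints), 0L)
})

test_that("single-codon motif table aggregates coverage by codon identity", {
  catalog <- seq_catalog(list(t1 = "ATGCCACCGCCATAA"),
                         c(t1 = 0L), c(t1 = 15L))
  cov <- list(t1 = c(5L, 1L, 2L, 4L, 9L))
  mt <- motif_table(cov, catalog, motif_length = 1L, alphabet = "codon")
  expect_equal(sum(mt$footprints), sum(cov$t1))
  expect_equal(mt$footprints[mt$motif == "CCA"], 1L + 4L)
  expect_equal(mt$occurrences[mt$motif == "CCA"], 2L)
  # occurrences agree with an independent substring scan of the CDS
  for (k in mt$motif) {
    hits <- gregexpr(k, "ATGCCACCGCCATAA", fixed = TRUE)[[1L]]
    in_frame <- sum(hits > 0 & (hits - 1L) %% 3L == 0L)
    expect_equal(mt$occurrences[mt$motif == k], in_frame)
  }
})

test_that("internal-stop ORFs are skipped for the amino-acid alphabet", {
  catalog <- seq_catalog(list(t1 = "ATGTAACCGTAA"), c(t1 = 0L), c(t1 = 12L))
  expect_warning(mt <- motif_table(list(t1 = integer(4L)), catalog, 2L,
                                   "amino_acid"), "internal stop")
  expect_equal(nrow(mt), 0L)
})

test_that("PCA matches the closed-form eigendecomposition on a 2x2 toy", {
  m <- matrix(c(1, 3, 2, 8), nrow = 2)   # rows = observations
  pc <- codon_pca(m)
  ev <- eigen(stats::cov(m))$values
  expect_equal(pc$explained_variance, ev / sum(ev))
  # reconstruction with all components retained
  rec <- pc$scores %*% t(pc$loadings) +
    matrix(pc$center, nrow = 2, ncol = 2, byrow = TRUE)
  expect_equal(unname(rec), unname(m))
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)
})

test_that("the dominant-variance codon carries the largest PC1 loading", {
  set.seed(99)
  n <- 30L
  codons <- sort(names(Biostrings::GENETIC_CODE))
  m <- matrix(stats::rnorm(n * 64, sd = 0.5), nrow = n,
              dimnames = list(NULL, codons))
  m[, "ATG"] <- stats::rnorm(n, sd = 10)   # start-codon occupancy dominates
  pc <- codon_pca(m)
  l1 <- abs(pc$loadings[, 1L])
  expect_equal(names(which.max(l1)), "ATG")
  # canonical sign: the largest-magnitude loading entry is positive
  for (j in seq_len(ncol(pc$loadings))) {
    lj <- pc$loadings[, j]
    expect_gt(lj[which.max(abs(lj))], 0)
  }
})

test_that("degenerate PCA inputs are handled as specified", {
  expect_error(codon_pca(matrix(1, 4, 5)), "no variance")
  # duplicated rows: zero-variance directions fall out of the top
  m <- matrix(c(1, 1, 5, 5, 2, 2, 9, 9), nrow = 4)
  pc <- codon_pca(m)
  expect_lt(pc$explained_variance[2L], 1e-12)
})
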