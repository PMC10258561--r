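test_that("overlap matrix uses half-open intersection and matches brute force", {
  peaks <- data.frame(chrom = "chr1", start = c(19L, 20L, 100L),
                      end = c(30L, 30L, 120L))
  peaks$name <- peak_id(peaks$chrom, peaks$start, peaks$end)
  tfbs <- list(TFA = data.frame(chrom = "chr1", start = 10L, end = 20L),
               TFB = data.frame(chrom = "chr2", start = 10L, end = 200L))
  ov <- suppressWarnings(build_overlap_matrix(tfbs, peaks))
  # TFBS [10,20) touches peak [19,30) but not [20,30)
  expect_identical(unname(ov["TFA", ]), c(1L, 0L, 0L))
  # TF with sites on another chromosome only: all-zero row
  expect_identical(unname(ov["TFB", ]), c(0L, 0L, 0L))

  set.seed(5)
  for (i in 1:10) {
    p <- data.frame(chrom = sample(c("chr1", "chr2"), 8, TRUE),
                    start = sample(0:50, 8))
    p$end <- p$start + sample(1:20, 8, TRUE)
    p$name <- sprintf("p%d", 1:8)
    sites <- data.frame(chrom = sample(c("chr1", "chr2"), 5, TRUE),
                        start = sample(0:60, 5))
    sites$end <- sites$start + sample(1:10, 5, TRUE)
    tf2 <- list(T1 = sites[1:3, ], T2 = sites[4:5, ])
    got <- build_overlap_matrix(tf2, p)
    want <- rbind(T1 = as.integer(colSums(oracle_overlaps(sites[1:3, ], p)) > 0),
                  T2 = as.integer(colSums(oracle_overlaps(sites[4:5, ], p)) > 0))
    colnames(want) <- p$name
    expect_identical(got, want)
  }
})

test_that("TF-peak correlation matches the definitional computation", {
  tf <- matrix(c(1, 3, 2, 5, 4), 1, dimnames = list("TFA", paste0("s", 1:5)))
  pk <- rbind(lin = 2 * tf[1, ] + 1, neg = 10 - tf[1, ],
              rnd = c(0.3, 2.2, 1.1, 0.9, 1.8))
  rownames(pk) <- c("chr1:0-10", "chr1:20-30", "chr1:40-50")
  corr <- correlate_tf_peak(count_matrix(tf, "user"),
                            count_matrix(pk, "user"), "TFA")
  expect_equal(unname(corr$r[1, 1:2]), c(1, -1))
  expect_equal(corr$r["TFA", 3],
               cov(tf[1, ], pk[3, ]) / (sd(tf[1, ]) * sd(pk[3, ])),
               ignore_attr = TRUE)
  expect_identical(corr$n_samples, 5L)

  # zero-variance peaks are flagged and excluded
  pk2 <- rbind(pk, flat = rep(2, 5))
  rownames(pk2)[4] <- "chr1:60-70"
  expect_message(c2 <- correlate_tf_peak(count_matrix(tf, "user"),
                                         count_matrix(pk2, "user"), "TFA"),
                 "zero variance")
  expect_identical(c2$dropped_peaks, "chr1:60-70")
  # sample mismatch is an error
  pk3 <- pk
  colnames(pk3) <- paste0("x", 1:5)
  expect_error(correlate_tf_peak(count_matrix(tf, "user"),
                                 count_matrix(pk3, "user"), "TFA"),
               "samples")
})

test_that("empirical FDR reproduces the hand-computed worked example", {
  r <- matrix(c(0.9, 0.8, -0.2, 0.9, -0.5, 0.1, -0.9), nrow = 1,
              dimnames = list("TFA", paste0("p", 1:7)))
  overlap <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L), nrow = 1,
                    dimnames = dimnames(r))
  tab <- empirical_fdr(as_tf_peak_correlation(r), overlap, "TFA")
  expect_identical(attr(tab, "ntp"), 3L)
  expect_identical(attr(tab, "nfp"), 4L)
  row <- tab[tab$direction == "positive" & tab$bin_lo == 0.80, ]
  # fg r >= 0.8: {0.9, 0.8}; bg r >= 0.8: {0.9}; scaled by 3/4
  expect_identical(row$ntp_k, 2L)
  expect_identical(row$nfp_k_raw, 1L)
  expect_equal(row$nfp_k_norm, 0.75)
  expect_equal(row$efdr, 0.75 / 2.75)
  # 40 bins per direction spanning [-1, 1] in steps of 0.05
  expect_identical(nrow(tab), 80L)
  expect_equal(min(tab$bin_lo), -1)
  expect_equal(max(tab$bin_hi), 1)
  # no background above k > 0.9: efdr 0 where foreground remains
  hi <- tab[tab$direction == "positive" & tab$bin_lo > 0.9, ]
  expect_true(all(hi$efdr[hi$ntp_k > 0] == 0))
})

test_that("empirical FDR matches the brute-force oracle on random instances", {
  set.seed(13)
  for (i in 1:30) {
    n_pk <- sample(20:60, 1)
    r <- matrix(round(runif(n_pk, -1, 1), 3), nrow = 1,
                dimnames = list("TFA", sprintf("p%d", seq_len(n_pk))))
    ov <- matrix(rbinom(n_pk, 1, 0.3), nrow = 1, dimnames = dimnames(r))
    if (sum(ov) == 0 || sum(ov) == n_pk) next
    got <- empirical_fdr(as_tf_peak_correlation(r), ov, "TFA")
    want <- oracle_efdr(r[1, ov[1, ] == 1], r[1, ov[1, ] == 0])
    expect_identical(got$ntp_k, want$ntp_k)
    expect_identical(got$nfp_k_raw, want$nfp_k_raw)
    expect_equal(got$efdr, want$efdr)
    # cumulative monotonicity in the positive direction
    pos <- got[got$direction == "positive", ]
    expect_true(all(diff(pos$ntp_k) <= 0))
    expect_true(all(diff(pos$nfp_k_raw) <= 0))
  }
  # degenerate stratifications are errors
  r <- matrix(0.5, 1, 2, dimnames = list("TFA", c("p1", "p2")))
  ov_all <- matrix(1L, 1, 2, dimnames = dimnames(r))
  expect_error(empirical_fdr(as_tf_peak_correlation(r), ov_all, "TFA"),
               "empty foreground or background")
})

test_that("matched same-distribution strata give efdr near 0.5", {
  set.seed(19)
  r <- matrix(runif(4000, -1, 1), nrow = 1,
              dimnames = list("TFA", sprintf("p%d", 1:4000)))
  ov <- matrix(rep(c(1L, 0L), 2000), nrow = 1, dimnames = dimnames(r))
  tab <- empirical_fdr(as_tf_peak_correlation(r), ov, "TFA")
  mid <- tab[tab$ntp_k >= 200, ] # well-populated cumulative sets
  expect_true(all(abs(mid$efdr - 0.5) < 0.1))
})

test_that("link calling assigns bin efdr, respects motifs, defaults to 0.2", {
  expect_identical(formals(call_tf_peak_links)$threshold, 0.2)
  r <- matrix(c(0.92, 0.52, -0.97, 0.91, 0.2, -0.1, 0.05, -0.2, 0.3, 0.1),
              nrow = 1, dimnames = list("TFA", sprintf("p%d", 1:10)))
  ov <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), nrow = 1,
               dimnames = dimnames(r))
  tabs <- empirical_fdr_all(as_tf_peak_correlation(r), ov)
  links <- call_tf_peak_links(as_tf_peak_correlation(r), ov, tabs,
                              threshold = 0.2)
  # motif-absent p4 has r = 0.91 but can never be a link
  expect_false("p4" %in% links$peak_id)
  expect_true(all(links$peak_id %in% colnames(ov)[ov[1, ] == 1]))
  # brute-force check: each motif pair's bin efdr against the oracle table
  want <- oracle_efdr(r[1, ov[1, ] == 1], r[1, ov[1, ] == 0])
  for (k in seq_len(nrow(links))) {
    rv <- links$r[k]
    bin <- want[want$bin_lo <= rv + 1e-9 & rv < want$bin_hi + 1e-9, ]
    pos <- bin$efdr[bin$direction == "positive"]
    neg <- bin$efdr[bin$direction == "negative"]
    expect_equal(links$efdr[k], min(pos, neg, na.rm = TRUE))
  }
  # p2 (r=0.52) and p3 (r=-0.97) are clear calls in opposite directions;
  # p1 (r=0.92) is rejected because the matched background peak at r=0.91
  # pushes its own bin's efdr above the threshold
  expect_identical(links$direction[links$peak_id == "p2"], "positive")
  expect_identical(links$direction[links$peak_id == "p3"], "negative")
  expect_false("p1" %in% links$peak_id)
})

test_that("TF classification separates shifted foregrounds from the null", {
  set.seed(23)
  n <- 200
  bg_r <- runif(n, -0.5, 0.5)
  mk <- function(fg_r, bg_r) {
    r <- matrix(c(fg_r, bg_r), nrow = 1)
    dimnames(r) <- list("TFA", sprintf("p%d", seq_len(ncol(r))))
    ov <- matrix(c(rep(1L, length(fg_r)), rep(0L, length(bg_r))), nrow = 1,
                 dimnames = dimnames(r))
    classify_tf(as_tf_peak_correlation(r), ov, "TFA")
  }
  expect_identical(mk(bg_r, bg_r)$class, "undetermined")
  expect_identical(mk(bg_r + 0.5, bg_r)$class, "activator")
  expect_identical(mk(bg_r - 0.5, bg_r)$class, "repressor")
  expect_warning(few <- mk(bg_r[1:3], bg_r), "fewer than 5")
  expect_identical(few$class, "undetermined")
  expect_identical(formals(classify_tf)$stringency, 0.1)
})

test_that("randomized background is seeded and far sparser than real links", {
  sim <- small_sim()
  res <- suppressMessages(suppressWarnings(run_egrn_pipeline(
    sim$cohort$rna, sim$cohort$atac, sim$cohort$tfbs, sim$cohort$genes,
    background_seed = 7)))
  bg1 <- res$background$tf_peak
  bg2 <- background_tf_peak(res$rna, res$atac, res$overlap, seed = 7)
  expect_identical(bg1, bg2) # determinism under the same seed
  bg3 <- background_tf_peak(res$rna, res$atac, res$overlap, seed = 8)
  expect_false(identical(bg1, bg3))
  expect_lt(nrow(bg1), 0.5 * nrow(res$tf_peak_links))
  if (nrow(bg1)) expect_identical(unique(bg1$provenance), "background")
})
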