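test_that("parameter validation rejects impossible cohorts", {
  expect_error(simulation_params(n_samples = 0), "positive")
  expect_error(simulation_params(frac_true_tf_peak = 1), "\\[0, 1\\)")
  expect_error(simulation_params(feature_spacing = 3e5, window = 2.5e5),
               "spacing")
  p <- simulation_params()
  expect_identical(p$n_samples, 30)
  expect_identical(p$window, 250000)
})

test_that("the planted truth is seeded and geometrically consistent", {
  params <- simulation_params(n_tfs = 5, n_peaks = 60, n_genes = 40,
                              features_per_chrom = 50, seed = 3)
  t1 <- simulate_truth(params)
  t2 <- simulate_truth(params)
  expect_identical(t1$tf_peak, t2$tf_peak)
  expect_identical(t1$peak_gene, t2$peak_gene)

  # every true peak-gene pair lies within the window
  pk <- t1$peaks[match(t1$peak_gene$peak_id, t1$peaks$name), ]
  gn <- t1$genes[match(t1$peak_gene$gene_id, t1$genes$gene_id), ]
  expect_true(all(pk$chrom == gn$chrom))
  dist <- pmin(abs(gn$tss - pk$start), abs(gn$tss - (pk$end - 1)))
  expect_true(all(dist <= params$window))

  # repressor slopes are negative, activator slopes positive
  cls <- setNames(t1$tf_classes$class, t1$tf_classes$tf_id)
  expect_true(all(t1$tf_peak$slope[cls[t1$tf_peak$tf_id] == "activator"] > 0))
  expect_true(all(t1$tf_peak$slope[cls[t1$tf_peak$tf_id] == "repressor"] < 0))
  expect_true(all(t1$peak_gene$beta > 0))

  # every true TF-peak edge has a planted binding site inside the peak
  ov <- suppressWarnings(build_overlap_matrix(t1$tfbs, t1$peaks))
  expect_true(all(ov[cbind(t1$tf_peak$tf_id, t1$tf_peak$peak_id)] == 1L))

  # a zero-fraction truth is a pure null
  null <- simulate_truth(simulation_params(n_tfs = 5, n_peaks = 60,
                                           n_genes = 40,
                                           features_per_chrom = 50,
                                           frac_true_tf_peak = 0, seed = 3))
  expect_identical(nrow(null$tf_peak), 0L)
  expect_identical(nrow(null$peak_gene), 0L)
})

test_that("cohorts are integer counts with the planted covariation", {
  sim <- small_sim()
  cohort <- sim$cohort
  expect_true(all(cohort$rna$values == floor(cohort$rna$values)))
  expect_true(all(cohort$rna$values >= 0))
  expect_identical(simulate_cohort(sim$truth)$rna$values,
                   cohort$rna$values)

  # latent signal: a true TF-peak edge correlates strongly; a TF with no
  # edge to a peak shows a null-scale correlation on average
  e <- sim$truth$tf_peak[1, ]
  lat <- cohort$latent
  expect_gt(abs(cor(lat$activities[e$tf_id, ], lat$peaks[e$peak_id, ])), 0.6)
  other <- setdiff(sim$truth$tf_classes$tf_id, sim$truth$tf_peak$tf_id[
    sim$truth$tf_peak$peak_id == e$peak_id])
  r_null <- vapply(other, function(tf)
    cor(lat$activities[tf, ], lat$peaks[e$peak_id, ]), numeric(1))
  expect_lt(mean(abs(r_null)), 0.35)

  # overdispersion roughly matches the requested NB dispersion
  # (method of moments on replicate draws of a flat latent)
  p <- sim$params
  set.seed(99)
  mu <- exp(p$base_log_mean)
  draws <- rnbinom(20000, mu = mu, size = 1 / p$nb_dispersion)
  disp_hat <- (var(draws) - mean(draws)) / mean(draws)^2
  expect_lt(abs(disp_hat - p$nb_dispersion), 0.03)
})

test_that("knockout-style DE reflects pathway weights", {
  sim <- small_sim()
  truth <- sim$truth
  pert <- head(unique(truth$tf_peak$tf_id), 2)
  de <- simulate_de(truth, pert, seed = 5)
  expect_identical(de, simulate_de(truth, pert, seed = 5))
  expect_error(simulate_de(truth, "NOPE"), "unknown TF")

  affected <- de$pathway_weight != 0
  expect_gt(mean(abs(de$log2fc[affected])), mean(abs(de$log2fc[!affected])))
  expect_lt(median(de$p_adj[affected]), 0.01)
  # null effect: pure noise
  de0 <- simulate_de(truth, pert, effect = 0, seed = 5)
  expect_lt(mean(abs(de0$log2fc)), 1)
  # genes fed by two perturbed pathways move more than single-pathway genes
  n_paths <- with(merge(truth$tf_peak[truth$tf_peak$tf_id %in% pert, ],
                        truth$peak_gene, by = "peak_id"),
                  tapply(peak_id, gene_id, length))
  if (any(n_paths >= 2) && any(n_paths == 1)) {
    multi <- names(n_paths)[n_paths >= 2]
    single <- names(n_paths)[n_paths == 1]
    expect_gt(mean(abs(de$pathway_weight[de$gene_id %in% multi])),
              mean(abs(de$pathway_weight[de$gene_id %in% single])))
  }
})

test_that("recovery scoring handles perfect, empty and mixed calls", {
  sim <- small_sim()
  truth <- sim$truth
  perfect_tp <- data.frame(tf_id = truth$tf_peak$tf_id,
                           peak_id = truth$tf_peak$peak_id)
  perfect_pg <- data.frame(peak_id = truth$peak_gene$peak_id,
                           gene_id = truth$peak_gene$gene_id)
  sc <- score_recovery(perfect_tp, perfect_pg, truth)
  expect_equal(sc$tf_peak$precision, 1)
  expect_equal(sc$tf_peak$recall, 1)
  expect_equal(sc$peak_gene$recall, 1)

  empty <- data.frame(tf_id = character(), peak_id = character(),
                      gene_id = character())
  sc0 <- score_recovery(empty, empty, truth)
  expect_equal(sc0$tf_peak$recall, 0)
  expect_equal(sc0$tf_peak$precision, 1)
  expect_true(sc0$tf_peak$empty)

  # half true, half false calls: precision = recall = 0.5 when the call
  # count equals the truth count
  n <- nrow(truth$tf_peak)
  half <- truth$tf_peak[seq_len(n %/% 2), c("tf_id", "peak_id")]
  fake <- data.frame(tf_id = rep("TF01", n - n %/% 2),
                     peak_id = sprintf("fake:%d-%d", 1:(n - n %/% 2),
                                       2:(n - n %/% 2 + 1)))
  mixed <- rbind(half, fake)
  scm <- score_recovery(mixed, perfect_pg, truth)
  expect_equal(scm$tf_peak$precision, (n %/% 2) / n)
  expect_equal(scm$tf_peak$recall, (n %/% 2) / n)
})

test_that("fewer samples degrade recovery on average", {
  base <- simulation_params(n_samples = 20, n_tfs = 6, n_peaks = 120,
                            n_genes = 80, features_per_chrom = 50,
                            seed = 101)
  small <- simulation_params(n_samples = 5, n_tfs = 6, n_peaks = 120,
                             n_genes = 80, features_per_chrom = 50,
                             seed = 101)
  truth <- simulate_truth(base)
  auc_for <- function(params) {
    cohort <- simulate_cohort(truth, params)
    res <- suppressMessages(suppressWarnings(run_egrn_pipeline(
      cohort$rna, cohort$atac, cohort$tfbs, cohort$genes)))
    cand <- call_tf_peak_links(res$corr, res$overlap, res$fdr_tables,
                               threshold = 1)
    score_recovery(res$tf_peak_links, res$peak_gene_links, truth,
                   tf_peak_candidates = cand,
                   peak_gene_candidates = res$pairs)$tf_peak$auc
  }
  expect_gt(auc_for(base), auc_for(small))
})
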