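toy_de <- function(n = 120, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%03d", 1:n),
             log2fc = rnorm(n, sd = 2.5),
             p_adj = runif(n, 0, 0.05), stringsAsFactors = FALSE)
}

toy_network <- function(de, n_tfs = 6, density = 0.3, seed = 2) {
  set.seed(seed)
  tfs <- sprintf("TF%d", seq_len(n_tfs))
  edges <- expand.grid(tf = tfs, gene = de$gene_id,
                       stringsAsFactors = FALSE)
  edges[runif(nrow(edges)) < density, ]
}

test_that("the feature matrix is the indicator of network edges", {
  de <- data.frame(gene_id = c("g1", "g2", "g3"),
                   log2fc = c(2, -3, 1.5), p_adj = c(0.01, 0.01, 0.01))
  net <- data.frame(tf = c("TFa", "TFb", "TFa"),
                    gene = c("g1", "g1", "g3"))
  fm <- build_feature_matrix(net, de, min_genes = 3)
  expect_identical(dim(fm$x), c(3L, 2L))
  want <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L), 3,
                 dimnames = list(c("g1", "g2", "g3"), c("TFa", "TFb")))
  expect_identical(fm$x, want)
  # g2 has no edges but is retained with an all-zero row
  expect_identical(unname(fm$x["g2", ]), c(0L, 0L))
  expect_equal(unname(fm$y), de$log2fc)

  # default filters: p_adj < 0.1 and |log2fc| > 1 (strict)
  de2 <- rbind(de, data.frame(gene_id = c("weak", "flat"),
                              log2fc = c(0.5, 5), p_adj = c(0.01, 0.5)))
  fm2 <- build_feature_matrix(net, de2, min_genes = 1)
  expect_setequal(rownames(fm2$x), c("g1", "g2", "g3"))
  expect_identical(eval(formals(build_feature_matrix)$padj_max), 0.1)
  expect_identical(eval(formals(build_feature_matrix)$min_abs_lfc), 1)
  # too little overlap is an error
  expect_error(build_feature_matrix(net, de), "insufficient overlap")
})

test_that("cross-validation recovers clean linear signal and not noise", {
  de <- toy_de(n = 400)
  net <- toy_network(de, n_tfs = 10, density = 0.25)
  fm <- build_feature_matrix(net, de, padj_max = 1, min_abs_lfc = 0)
  # plant y as an exact linear function of 5 TF columns
  beta <- c(3, -2, 4, -1, 2)
  fm$y <- as.numeric(fm$x[, 1:5] %*% beta)
  names(fm$y) <- rownames(fm$x)
  cv <- fit_cv(fm, n_runs = 3, seed = 4)
  expect_gt(mean(cv$runs$r2), 0.9)
  expect_gt(mean(cv$runs$r2_ss), 0.9)

  # permuted response: no signal
  fm$y <- sample(fm$y)
  cv0 <- fit_cv(fm, n_runs = 3, seed = 4)
  expect_lte(mean(cv0$runs$r2), 0.05)

  # every gene is predicted exactly once per run
  expect_false(any(is.na(cv$predictions)))
  for (j in seq_len(ncol(cv$folds))) {
    expect_identical(sort(unique(cv$folds[, j])), 1:10)
  }
  expect_error(fit_cv(fm, n_folds = 1e6), "more folds")

  # constant response is degenerate, reported as 0
  fm$y[] <- 1
  cvc <- fit_cv(fm, n_runs = 1, seed = 1)
  expect_true(all(cvc$runs$degenerate))
  expect_identical(cvc$runs$r2, 0)
})

test_that("AUROC and AUPRC behave at their extremes and under ties", {
  y <- c(-2, -1, 0.5, 1, 3)
  labels <- y > 0
  expect_identical(auroc(y, labels), 1)
  expect_identical(auroc(-y, labels), 0)
  expect_equal(auprc(y, labels), 1)
  expect_warning(expect_identical(auroc(y, rep(TRUE, 5)), NA_real_),
                 "single-class")
  # all-tied scores: AUROC 1/2, AUPRC = prevalence
  expect_equal(auroc(rep(1, 5), labels), 0.5)
  expect_equal(auprc(rep(1, 5), labels), 3 / 5)
  skip_if_not_installed("pROC")
  set.seed(31)
  s <- rnorm(300)
  l <- runif(300) < 0.4
  expect_equal(auroc(s, l),
               as.numeric(pROC::auc(pROC::roc(as.numeric(l), s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("classification metrics summarize pooled predictions per run", {
  de <- toy_de(n = 150)
  net <- toy_network(de)
  fm <- build_feature_matrix(net, de, padj_max = 1, min_abs_lfc = 0)
  cv <- fit_cv(fm, n_runs = 2, seed = 6)
  met <- classification_metrics(cv)
  expect_identical(nrow(met$per_run), 2L)
  expect_equal(met$auroc, mean(met$per_run$auroc))
  expect_true(met$auprc >= 0 && met$auprc <= 1)
})

test_that("controls are degree-preserving, seeded and signal-free", {
  sim <- small_sim()
  truth <- sim$truth
  pert <- with(truth$tf_classes,
               c(head(tf_id[class == "activator"], 2),
                 head(tf_id[class == "repressor"], 1)))
  de <- simulate_de(truth, pert, seed = 17)
  net <- truth_tf_gene_network(truth)
  fm <- build_feature_matrix(net, de, min_genes = 20)
  cv <- fit_cv(fm, n_runs = 4, seed = 8)
  perm <- permuted_control(net, de, seed = 8, n_runs = 4, min_genes = 20)
  expect_gt(mean(cv$runs$r2), mean(perm$runs$r2))
  expect_identical(
    permuted_control(net, de, seed = 8, n_runs = 2, min_genes = 20)$runs,
    permuted_control(net, de, seed = 8, n_runs = 2, min_genes = 20)$runs)
  rnd <- random_signal_control(net, seed = 8, n_runs = 4,
                               genes = sort(truth$genes$gene_id))
  expect_lt(abs(mean(rnd$runs$r2)), 0.1)
  expect_identical(
    random_signal_control(net, seed = 8, n_runs = 1)$runs,
    random_signal_control(net, seed = 8, n_runs = 1)$runs)
})

test_that("run comparison is a two-sample t-test with sane degenerate cases", {
  set.seed(41)
  a <- rnorm(10, 0.2, 0.1)
  expect_gt(compare_runs(a, a), 0.9)
  expect_lt(compare_runs(rnorm(10, 0.2, 0.01), rnorm(10, 0, 0.01)), 1e-3)
  expect_equal(compare_runs(a, a + 10),
               t.test(a, a + 10)$p.value)
  expect_identical(compare_runs(rep(1, 3), rep(1, 3)), 1)
  expect_error(compare_runs(1, c(1, 2)), ">= 2 values")
})

test_that("permutation importance singles out the driving TF", {
  de <- toy_de(n = 300)
  net <- toy_network(de, n_tfs = 8, density = 0.3)
  fm <- build_feature_matrix(net, de, padj_max = 1, min_abs_lfc = 0)
  set.seed(51)
  fm$y <- 5 * fm$x[, "TF3"] + rnorm(nrow(fm$x), sd = 0.5)
  names(fm$y) <- rownames(fm$x)
  imp <- tf_importance(fm, n_runs = 3, seed = 5)
  expect_identical(imp$tf_id[1], "TF3")
  expect_setequal(imp$tf_id, colnames(fm$x))
  # an all-zero TF column cannot matter
  fm$x[, "TF5"] <- 0L
  imp2 <- tf_importance(fm, n_runs = 3, seed = 5)
  expect_lt(abs(imp2$importance[imp2$tf_id == "TF5"]),
            0.05 * max(imp2$importance))
})

test_that("regulon enrichment applies the overlap and significance rules", {
  universe <- sprintf("g%03d", 1:100)
  # planted 2x2 table (a, b, c, d) = (5, 5, 15, 75): odds ratio 5
  regulon <- universe[1:10]
  hits <- c(universe[1:5], universe[11:25])
  enr <- regulon_enrichment(regulon, hits, universe)
  expect_equal(enr$odds_ratio, 5)
  expect_equal(enr$fisher_p,
               fisher.test(matrix(c(5, 5, 15, 75), 2))$p.value)
  expect_identical(enr$overlap_count, 5L)
  # disjoint regulon: odds ratio 0, not significant
  enr0 <- regulon_enrichment(universe[1:10], universe[90:100], universe)
  expect_equal(enr0$odds_ratio, 0)
  expect_false(enr0$significant)
  # a strong overlap below the minimum count is not called significant
  enr4 <- regulon_enrichment(universe[1:4], universe[1:4], universe)
  expect_lt(enr4$fisher_p, 0.05)
  expect_false(enr4$significant)
  expect_error(regulon_enrichment(regulon, hits, character()),
               "empty universe")
})
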