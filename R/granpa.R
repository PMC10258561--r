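# Network evaluation: predicting differential expression from binary
# TF-gene features with cross-validated random-forest regression, with
# permuted-network and random-signal controls, direction-classification
# metrics, permutation-based TF importance, and Fisher regulon enrichment.

#' Build the binary gene x TF feature matrix
#'
#' Rows are the differential-expression genes passing the adjusted-p and
#' absolute log2 fold-change filters; columns are all TFs of the network.
#' X\[g, t\] = 1 iff (t, g) is a network edge. Genes without any network
#' edge keep their all-zero row: predicting them is part of the task.
#'
#' @param network TF-gene edge list (data.frame with `tf`, `gene`).
#' @param de Differential-expression table: data.frame with `gene_id`,
#'   `log2fc`, `p_adj`.
#' @param padj_max Adjusted-p threshold (default 0.1; genes with
#'   `p_adj < padj_max` are kept).
#' @param min_abs_lfc Absolute log2 fold-change threshold (default 1; genes
#'   with `|log2fc| > min_abs_lfc` are kept).
#' @param min_genes Minimum usable genes; fewer is an error, mirroring the
#'   failure mode of evaluating a network that barely overlaps the DE data.
#' @return A `feature_matrix`: list with binary matrix `x` (genes x TFs)
#'   and response `y` (log2 fold-changes, aligned with rows of `x`).
#' @export
build_feature_matrix <- function(network, de, padj_max = 0.1,
                                 min_abs_lfc = 1, min_genes = 50) {
  stopifnot(all(c("tf", "gene") %in% names(network)),
            all(c("gene_id", "log2fc", "p_adj") %in% names(de)))
  if (nrow(network) == 0L) stop("empty network", call. = FALSE)
  if (anyDuplicated(de$gene_id)) stop("duplicate genes in DE table", call. = FALSE)
  keep <- de$p_adj < padj_max & abs(de$log2fc) > min_abs_lfc &
    is.finite(de$log2fc)
  de <- de[keep, , drop = FALSE]
  tfs <- sort(unique(network$tf))
  if (nrow(de) < min_genes || length(tfs) < 2L) {
    stop(sprintf(
      "insufficient overlap: %d usable genes (need >= %d), %d TFs (need >= 2)",
      nrow(de), min_genes, length(tfs)), call. = FALSE)
  }
  x <- matrix(0L, nrow = nrow(de), ncol = length(tfs),
              dimnames = list(de$gene_id, tfs))
  edge <- network[network$gene %in% de$gene_id, , drop = FALSE]
  if (nrow(edge)) x[cbind(edge$gene, edge$tf)] <- 1L
  structure(list(x = x, y = stats::setNames(de$log2fc, de$gene_id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d genes x %d TFs (%.1f%% nonzero)\n",
              nrow(x$x), ncol(x$x), 100 * mean(x$x != 0)))
  invisible(x)
}

# One CV run: seeded fold assignment, a forest per fold, pooled out-of-fold
# predictions over all genes.
.cv_run <- function(x, y, n_folds, n_trees, mtry, run_seed) {
  n <- length(y)
  with_seed(run_seed, {
    folds <- sample(rep(seq_len(n_folds), length.out = n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(n_folds)) {
      test <- folds == f
      fit <- ranger::ranger(
        x = x[!test, , drop = FALSE], y = y[!test],
        num.trees = n_trees, mtry = mtry, seed = sample.int(2^31 - 1, 1),
        num.threads = 1
      )
      pred[test] <- stats::predict(
        fit, data = x[test, , drop = FALSE], num.threads = 1
      )$predictions
    }
    list(predictions = pred, folds = folds)
  })
}

# Out-of-fold R^2 in two flavours. The primary r2 is the squared Pearson
# correlation between pooled out-of-fold predictions and the observed
# values (the usual "cross-validation R^2"; bounded in [0, 1] and ~0 for
# uninformative predictors). r2_ss = 1 - SS_res/SS_tot is reported
# alongside; it can go negative, since pooled OOF predictions of a noise
# target carry leaf-level variance uncorrelated with y. Degenerate cases
# (constant response or constant predictions) are reported as 0 with the
# flag set.
.oof_r2 <- function(y, pred) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(list(r2 = 0, r2_ss = 0, degenerate = TRUE))
  }
  r2_ss <- 1 - sum((y - pred)^2) / ss_tot
  if (stats::sd(pred) == 0) {
    return(list(r2 = 0, r2_ss = r2_ss, degenerate = TRUE))
  }
  list(r2 = stats::cor(y, pred)^2, r2_ss = r2_ss, degenerate = FALSE)
}

#' Cross-validated random-forest evaluation of a feature matrix
#'
#' For each of `n_runs` independent runs, genes are partitioned into
#' `n_folds` seeded folds; a regression forest trained on the remaining
#' folds predicts each held-out fold, and performance is measured on the
#' pooled out-of-fold predictions. The primary `r2` is the squared Pearson
#' correlation between predictions and observed values (cross-validation
#' R^2; ~0 for uninformative predictors); `r2_ss` = 1 - SS_res/SS_tot is
#' reported alongside and may be negative for noise targets.
#' Direction-classification AUROC/AUPRC (label: log2fc > 0) are computed
#' per run from the same pooled predictions. No hyper-parameter tuning is
#' performed.
#'
#' @param fm A `feature_matrix`.
#' @param n_folds Cross-validation folds (default 10).
#' @param n_runs Independent repetitions (default 10); fold assignment and
#'   forest seeds are both re-drawn per run.
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @param mtry Variables per split (default `floor(p/3)`, minimum 1).
#' @return A `cv_result`: list with per-run data.frame `runs` (r2, r2_ss,
#'   auroc, auprc, degenerate), prediction matrix `predictions` (genes x
#'   runs), `y`, fold assignments, and the settings used.
#' @export
fit_cv <- function(fm, n_folds = 10, n_runs = 10, n_trees = 500, seed = 1,
                   mtry = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- length(fm$y)
  if (n_folds > n) stop("more folds than genes", call. = FALSE)
  mtry <- mtry %||% max(1L, floor(ncol(fm$x) / 3))
  preds <- matrix(NA_real_, nrow = n, ncol = n_runs,
                  dimnames = list(names(fm$y), NULL))
  folds <- matrix(NA_integer_, nrow = n, ncol = n_runs)
  runs <- data.frame(run = seq_len(n_runs), r2 = NA_real_,
                     r2_ss = NA_real_, auroc = NA_real_, auprc = NA_real_,
                     degenerate = FALSE)
  for (j in seq_len(n_runs)) {
    res <- .cv_run(fm$x, fm$y, n_folds, n_trees, mtry,
                   run_seed = seed + j - 1L)
    preds[, j] <- res$predictions
    folds[, j] <- res$folds
    r2 <- .oof_r2(fm$y, res$predictions)
    runs$r2[j] <- r2$r2
    runs$r2_ss[j] <- r2$r2_ss
    runs$degenerate[j] <- r2$degenerate
    labels <- fm$y > 0
    if (length(unique(labels)) == 2L) {
      runs$auroc[j] <- auroc(res$predictions, labels)
      runs$auprc[j] <- auprc(res$predictions, labels)
    }
  }
  structure(list(runs = runs, predictions = preds, folds = folds, y = fm$y,
                 settings = list(n_folds = n_folds, n_runs = n_runs,
                                 n_trees = n_trees, seed = seed,
                                 mtry = mtry)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: %d runs on %d genes; mean R^2 = %.3f, AUROC = %.3f, AUPRC = %.3f\n",
    nrow(x$runs), length(x$y), mean(x$runs$r2),
    mean(x$runs$auroc, na.rm = TRUE), mean(x$runs$auprc, na.rm = TRUE)))
  invisible(x)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midranks, so tied scores contribute 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) class labels.
#' @return AUROC in \[0, 1\]; `NA` with a warning when only one class is
#'   present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUROC undefined: single-class labels", call. = FALSE)
    return(NA_real_)
  }
  rk <- rank(scores, ties.method = "average")
  (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' Sweeps thresholds from the highest score down, grouping tied scores, and
#' accumulates precision x recall-increment (average precision).
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\]; `NA` with a warning when no positives exist.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L || all(labels)) {
    warning("AUPRC undefined: single-class labels", call. = FALSE)
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cut points at the end of each tied-score group
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Direction-classification metrics from pooled predictions
#'
#' Binary label is `y > 0`; the score is the predicted differential
#' expression. Reports per-run and mean AUROC/AUPRC.
#'
#' @param cv A `cv_result`.
#' @param y Response vector (defaults to the one stored in `cv`).
#' @return List with `auroc`, `auprc` (means over runs) and `per_run`.
#' @export
classification_metrics <- function(cv, y = cv$y) {
  labels <- y > 0
  per_run <- data.frame(
    run = seq_len(ncol(cv$predictions)),
    auroc = apply(cv$predictions, 2, auroc, labels = labels),
    auprc = apply(cv$predictions, 2, auprc, labels = labels)
  )
  list(auroc = mean(per_run$auroc, na.rm = TRUE),
       auprc = mean(per_run$auprc, na.rm = TRUE),
       per_run = per_run)
}

#' Degree-preserving permuted-network control
#'
#' Applies the gene-label bijection of [permute_tf_gene_edges()] to the
#' network, rebuilds the feature matrix against the unchanged
#' differential-expression values, and evaluates with matched settings.
#' Good performance of this control means even unspecific TF-gene
#' connections predict the response, invalidating the real network's
#' specificity.
#'
#' @inheritParams build_feature_matrix
#' @param seed Integer seed (drives both the permutation and the CV).
#' @param ... Passed to [fit_cv()].
#' @return A `cv_result` for the permuted network.
#' @export
permuted_control <- function(network, de, seed, padj_max = 0.1,
                             min_abs_lfc = 1, min_genes = 50, ...) {
  permuted <- permute_tf_gene_edges(network, seed)
  fm <- build_feature_matrix(permuted, de, padj_max = padj_max,
                             min_abs_lfc = min_abs_lfc,
                             min_genes = min_genes)
  fit_cv(fm, seed = seed, ...)
}

#' Random-signal control for overfitting
#'
#' Keeps the real network structure but replaces the response with i.i.d.
#' Uniform(lo, hi) draws per gene. Any predictive performance here is
#' overfitting; a well-behaved evaluator scores near zero.
#'
#' @param network TF-gene edge list.
#' @param seed Integer seed.
#' @param lo,hi Uniform range (defaults -5 and 5).
#' @param genes Gene universe to predict over (default: all network genes).
#' @param ... Passed to [fit_cv()].
#' @return A `cv_result` for the random signal.
#' @export
random_signal_control <- function(network, seed, lo = -5, hi = 5,
                                  genes = NULL, ...) {
  genes <- genes %||% sort(unique(network$gene))
  y <- with_seed(seed, stats::runif(length(genes), lo, hi))
  tfs <- sort(unique(network$tf))
  x <- matrix(0L, nrow = length(genes), ncol = length(tfs),
              dimnames = list(genes, tfs))
  edge <- network[network$gene %in% genes, , drop = FALSE]
  if (nrow(edge)) x[cbind(edge$gene, edge$tf)] <- 1L
  fm <- structure(list(x = x, y = stats::setNames(y, genes)),
                  class = "feature_matrix")
  fit_cv(fm, seed = seed, ...)
}

#' Compare two R-squared run distributions
#'
#' Two-sided two-sample t-test on the per-run R^2 values (real vs control).
#'
#' @param r2_real,r2_control Numeric vectors of per-run R^2 (length >= 2).
#' @return The t-test p-value; 1 when both groups have zero variance.
#' @export
compare_runs <- function(r2_real, r2_control) {
  if (length(r2_real) < 2L || length(r2_control) < 2L) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  if (stats::var(r2_real) == 0 && stats::var(r2_control) == 0) {
    return(if (isTRUE(all.equal(mean(r2_real), mean(r2_control)))) 1
           else 0)
  }
  stats::t.test(r2_real, r2_control)$p.value
}

#' Permutation-based TF importance
#'
#' Fits a forest on all genes (no CV folds) per run and reads the
#' permutation importance from the out-of-bag samples: the accuracy drop
#' when a TF column is shuffled while all others are kept. Reported per run
#' and as the mean across runs; the ranking of the means identifies the
#' most important TFs.
#'
#' @param fm A `feature_matrix`.
#' @param n_runs Independent forests (default 10).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @param mtry Variables per split (default `floor(p/3)`, minimum 1).
#' @return An `importance_table`: data.frame with `tf_id`, `importance`
#'   (mean), and one `run_<i>` column per run, sorted by decreasing mean.
#' @export
tf_importance <- function(fm, n_runs = 10, n_trees = 500, seed = 1,
                          mtry = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  mtry <- mtry %||% max(1L, floor(ncol(fm$x) / 3))
  per_run <- matrix(NA_real_, nrow = ncol(fm$x), ncol = n_runs,
                    dimnames = list(colnames(fm$x),
                                    paste0("run_", seq_len(n_runs))))
  for (j in seq_len(n_runs)) {
    fit <- ranger::ranger(
      x = fm$x, y = fm$y, num.trees = n_trees, mtry = mtry,
      importance = "permutation", seed = seed + j - 1L, num.threads = 1
    )
    per_run[, j] <- fit$variable.importance[colnames(fm$x)]
  }
  out <- data.frame(tf_id = rownames(per_run),
                    importance = rowMeans(per_run),
                    per_run, stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Fisher enrichment of a regulon in a hit gene set
#'
#' 2x2 table (in/out regulon x in/out hit set) over the universe, with the
#' sample odds ratio (ad)/(bc) and Fisher's exact p. An enrichment is
#' flagged significant only with at least `min_overlap` overlapping genes
#' and p below `alpha`.
#'
#' @param regulon Gene set of the TF.
#' @param hit_set Gene set of interest (e.g. genes downregulated on TF
#'   knockout).
#' @param universe Background universe (e.g. all protein-coding genes);
#'   regulon and hit set are intersected with it.
#' @param min_overlap Minimum overlap for significance (default 5).
#' @param alpha Significance level (default 0.05).
#' @return List with `odds_ratio`, `fisher_p`, `overlap_count`,
#'   `regulon_size`, `set_size`, `universe_size`, `significant`.
#' @export
regulon_enrichment <- function(regulon, hit_set, universe, min_overlap = 5,
                               alpha = 0.05) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  regulon <- intersect(unique(regulon), universe)
  hit_set <- intersect(unique(hit_set), universe)
  a <- length(intersect(regulon, hit_set))
  b <- length(regulon) - a
  c_ <- length(hit_set) - a
  d <- length(universe) - a - b - c_
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
  list(odds_ratio = or, fisher_p = p, overlap_count = a,
       regulon_size = length(regulon), set_size = length(hit_set),
       universe_size = length(universe),
       significant = (a >= min_overlap) && (p < alpha))
}
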