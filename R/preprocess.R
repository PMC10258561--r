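#' Quantile-normalize a count matrix
#'
#' Forces every sample (column) onto the same distribution: the value at
#' rank k in each column becomes the mean over columns of their k-th order
#' statistics. Ties within a column receive the mean of the reference values
#' at their tied ranks, so the result does not depend on the order of tied
#' entries. Used by default for RNA-seq counts to blunt the influence of
#' outlier values on downstream correlations.
#'
#' @param m A `count_matrix` with `normalized = "raw"`.
#' @return A `count_matrix` with `normalized = "quantile"`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalized != "raw") {
    stop("quantile_normalize expects raw counts (normalized = 'raw')",
         call. = FALSE)
  }
  x <- m$values
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples", call. = FALSE)
  sorted <- apply(x, 2, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = 1L)
  ref <- rowMeans(sorted)
  cs <- c(0, cumsum(ref))
  out <- apply(x, 2, function(col) {
    # tied entries receive the mean of the reference values over their
    # tied rank range [rk_min, rk_max]
    rk_min <- rank(col, ties.method = "min")
    rk_max <- rank(col, ties.method = "max")
    (cs[rk_max + 1] - cs[rk_min]) / (rk_max - rk_min + 1)
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = 1L)
  dimnames(out) <- dimnames(x)
  res <- count_matrix(out, normalized = "raw")
  res$normalized <- "quantile"
  res
}

#' Compute median-of-ratios size factors
#'
#' Per-feature geometric means over samples form the pseudo-reference
#' (features with any zero count are excluded); each sample's factor is the
#' median over features of count/reference.
#'
#' @param values Non-negative numeric matrix (features x samples).
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(values) {
  log_geo <- rowMeans(log(values))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("cannot form reference: no feature with all-positive counts",
         call. = FALSE)
  }
  apply(values[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo[use]))
  })
}

#' Size-factor normalize a count matrix
#'
#' Median-of-ratios normalization: divides each sample by its
#' [size_factors()] value. Used by default for chromatin accessibility
#' counts.
#'
#' @param m A `count_matrix` with `normalized = "raw"`.
#' @return A `count_matrix` with `normalized = "size_factor"`.
#' @export
size_factor_normalize <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$normalized != "raw") {
    stop("size_factor_normalize expects raw counts (normalized = 'raw')",
         call. = FALSE)
  }
  sf <- size_factors(m$values)
  out <- sweep(m$values, 2, sf, "/")
  res <- count_matrix(out, normalized = "raw")
  res$normalized <- "size_factor"
  attr(res, "size_factors") <- sf
  res
}

#' Drop features with low mean counts
#'
#' Removes features whose mean across samples is strictly below `min_mean`
#' (features sitting exactly at the threshold are kept). Order is preserved.
#'
#' @param m A `count_matrix` (any normalization state).
#' @param min_mean Mean-count threshold (default 5).
#' @return A filtered `count_matrix`.
#' @export
filter_low_count <- function(m, min_mean = 5) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- rowMeans(m$values) >= min_mean
  if (!any(keep)) warning("no features pass the mean-count filter", call. = FALSE)
  res <- m
  res$values <- m$values[keep, , drop = FALSE]
  res
}

#' Log-transform a normalized count matrix
#'
#' Applies `log2(offset + x)` entrywise. Pearson correlations are
#' outlier-sensitive and their null distribution is sign-asymmetric in the
#' tails on right-skewed count scales, so all correlations in the pipeline
#' are computed on log counts by default.
#'
#' @param m A `count_matrix`.
#' @param offset Pseudocount added before the log (default 1).
#' @return The transformed `count_matrix` (normalization state unchanged;
#'   attribute `log2` set).
#' @export
log_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "count_matrix"))
  if (isTRUE(attr(m, "log2"))) {
    stop("count matrix is already log-transformed", call. = FALSE)
  }
  m$values <- log2(offset + m$values)
  attr(m, "log2") <- TRUE
  m
}

#' Remove features on excluded chromosomes
#'
#' Drops the matrix rows and the matching interval rows for features on any
#' excluded chromosome, keeping the two structures consistent.
#'
#' @param m A `count_matrix` whose feature IDs appear in `intervals$name`
#'   (peaks) or `intervals$gene_id` (genes).
#' @param intervals Interval or gene-annotation data.frame with a `chrom`
#'   column.
#' @param exclude Character vector of chromosome names to remove.
#' @return A list with elements `matrix` (filtered `count_matrix`) and
#'   `intervals` (filtered data.frame).
#' @export
filter_chromosomes <- function(m, intervals, exclude = character()) {
  stopifnot(inherits(m, "count_matrix"))
  id_col <- if ("gene_id" %in% names(intervals)) "gene_id" else "name"
  keep_iv <- !(intervals$chrom %in% exclude)
  intervals <- intervals[keep_iv, , drop = FALSE]
  keep_m <- feature_ids(m) %in% intervals[[id_col]]
  res <- m
  res$values <- m$values[keep_m, , drop = FALSE]
  intervals <- intervals[intervals[[id_col]] %in% feature_ids(res), , drop = FALSE]
  list(matrix = res, intervals = intervals)
}
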