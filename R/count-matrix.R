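#' Construct a count matrix container
#'
#' A light container for a features x samples numeric matrix together with a
#' normalization state flag. Feature and sample identifiers are the matrix
#' dimnames and must be unique; values must be finite and non-negative.
#'
#' @param values Numeric matrix (features x samples) with rownames and
#'   colnames set.
#' @param normalized Normalization state, one of `"raw"`, `"quantile"`,
#'   `"size_factor"`, `"user"`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values,
                         normalized = c("raw", "quantile", "size_factor", "user")) {
  normalized <- match.arg(normalized)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry feature (row) and sample (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1], call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("count matrix contains non-finite or missing values; ",
         "missing data are not supported", call. = FALSE)
  }
  if (any(values < 0)) stop("count matrix contains negative values", call. = FALSE)
  structure(list(values = values, normalized = normalized),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (normalized: %s)\n",
              nrow(x$values), ncol(x$values), x$normalized))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Feature identifiers of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of feature IDs.
#' @export
feature_ids <- function(m) rownames(m$values)

#' Sample identifiers of a count matrix
#' @param m A `count_matrix`.
#' @return Character vector of sample IDs.
#' @export
sample_ids <- function(m) colnames(m$values)

#' Read a count matrix from a TSV file
#'
#' Expects a header row of sample IDs and a first column of feature IDs,
#' followed by a numeric body. For `kind = "chromatin"` the feature IDs must
#' be parseable as `"chrom:start-end"` peak coordinates.
#'
#' @param path Path to a tab-separated file.
#' @param kind `"rna"` or `"chromatin"`.
#' @return A `count_matrix` with `normalized = "raw"`.
#' @export
read_count_matrix <- function(path, kind = c("rna", "chromatin")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("count matrix needs >= 1 sample column", call. = FALSE)
  feats <- tab[[1]]
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1], call. = FALSE)
  }
  if (anyDuplicated(feats)) {
    stop("duplicate feature id: ", feats[duplicated(feats)][1], call. = FALSE)
  }
  body <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (any(is.na(num))) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                 feats[idx[1]], samples[idx[2]]), call. = FALSE)
  }
  dimnames(num) <- list(feats, samples)
  if (kind == "chromatin") parse_peak_id(feats) # validates coordinates
  count_matrix(num, normalized = "raw")
}

#' Write a count matrix to a TSV file
#'
#' Inverse of [read_count_matrix()]; the first column is named `feature_id`.
#'
#' @param m A `count_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  df <- data.frame(feature_id = feature_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
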