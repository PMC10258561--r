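# TF-peak link inference: motif-overlap matrix, TF-expression vs
# peak-accessibility correlation, bin-wise empirical FDR, link calling,
# activator/repressor classification, and the twofold randomized background.

#' Build the binary TF-peak motif-overlap matrix
#'
#' Entry (tf, peak) is 1 iff at least one predicted binding site of the TF
#' intersects the peak by >= 1 bp (0-based half-open intersection).
#'
#' @param tfbs Named list of TFBS interval data.frames (one per TF), as from
#'   [read_tfbs_dir()].
#' @param peaks Peak interval data.frame with unique `name` IDs.
#' @return Binary integer matrix, TFs x peaks, with dimnames.
#' @export
build_overlap_matrix <- function(tfbs, peaks) {
  if (anyDuplicated(peaks$name)) stop("duplicate peak IDs", call. = FALSE)
  peak_gr <- intervals_to_granges(peaks)
  out <- matrix(0L, nrow = length(tfbs), ncol = nrow(peaks),
                dimnames = list(names(tfbs), peaks$name))
  for (tf in names(tfbs)) {
    iv <- tfbs[[tf]]
    if (is.null(iv) || nrow(iv) == 0L) {
      warning("TF '", tf, "' has no binding sites: all-zero row", call. = FALSE)
      next
    }
    hits <- GenomicRanges::findOverlaps(intervals_to_granges(iv), peak_gr)
    out[tf, unique(S4Vectors::subjectHits(hits))] <- 1L
  }
  out
}

#' Correlate TF expression with peak accessibility
#'
#' Pearson correlation across samples between each TF's expression and each
#' peak's signal. Zero-variance TFs or peaks are flagged and excluded from
#' the correlation matrix (their r is undefined).
#'
#' @param rna Normalized RNA `count_matrix` containing the TF rows.
#' @param atac Normalized chromatin `count_matrix` (peaks x samples).
#' @param tf_ids TFs to correlate (must be features of `rna`).
#' @return A `tf_peak_correlation` object: list with `r` (TF x peak matrix),
#'   `n_samples`, `dropped_tfs`, `dropped_peaks`.
#' @export
correlate_tf_peak <- function(rna, atac, tf_ids) {
  stopifnot(inherits(rna, "count_matrix"), inherits(atac, "count_matrix"))
  if (!identical(sample_ids(rna), sample_ids(atac))) {
    stop("RNA and chromatin matrices must share identically ordered samples",
         call. = FALSE)
  }
  n <- ncol(rna$values)
  if (n < 3L) stop("need >= 3 samples to correlate", call. = FALSE)
  missing_tf <- setdiff(tf_ids, feature_ids(rna))
  if (length(missing_tf)) {
    stop("TF(s) absent from RNA matrix: ",
         paste(utils::head(missing_tf, 5), collapse = ", "), call. = FALSE)
  }
  tf_expr <- rna$values[tf_ids, , drop = FALSE]
  peak_sig <- atac$values
  tf_var <- apply(tf_expr, 1, stats::var)
  peak_var <- apply(peak_sig, 1, stats::var)
  dropped_tfs <- rownames(tf_expr)[tf_var == 0]
  dropped_peaks <- rownames(peak_sig)[peak_var == 0]
  if (length(dropped_tfs) || length(dropped_peaks)) {
    message(length(dropped_tfs), " TF(s) and ", length(dropped_peaks),
            " peak(s) with zero variance excluded from correlation")
  }
  tf_expr <- tf_expr[tf_var > 0, , drop = FALSE]
  peak_sig <- peak_sig[peak_var > 0, , drop = FALSE]
  r <- stats::cor(t(tf_expr), t(peak_sig))
  structure(list(r = r, n_samples = n, dropped_tfs = dropped_tfs,
                 dropped_peaks = dropped_peaks),
            class = "tf_peak_correlation")
}

# 40 bins of width 0.05 spanning [-1, 1]; positive-direction thresholds are
# the lower bin edges, negative-direction thresholds the upper edges.
.efdr_bin_lo <- function() round(seq(-100L, 95L, by = 5L)) / 100

# Bin index of a correlation value: bin i covers [lo_i, lo_i + 0.05), with
# r = 1 assigned to the top bin. The 1e-9 nudge guards against values such
# as 0.8 landing below their own bin edge through floating-point error.
.efdr_bin_index <- function(r) {
  pmin(40L, pmax(1L, floor((r + 1) / 0.05 + 1e-9) + 1L))
}

#' Empirical FDR table for one TF
#'
#' Peaks are split into a foreground (motif present) and background (motif
#' absent) set. The correlation axis is discretized into 40 bins of width
#' 0.05 over \[-1, 1\] and, per direction, a cumulative count is formed at
#' each bin threshold k: the positive direction counts peaks with r >= k
#' (thresholds are lower bin edges, swept left to right), the negative
#' direction counts r < k (upper bin edges, right to left). The background
#' count is rescaled by ntp/nfp (total foreground / total background) before
#' the quotient
#' \deqn{efdr_k = nfp_k / (nfp_k + ntp_k)}
#' is taken, so that efdr is calibrated to the foreground size.
#'
#' @param corr A `tf_peak_correlation`.
#' @param overlap Binary TF x peak overlap matrix.
#' @param tf_id The TF to tabulate.
#' @return An `efdr_table`: data.frame with columns `direction`, `k`,
#'   `bin_lo`, `bin_hi`, `ntp_k`, `nfp_k_raw`, `nfp_k_norm`, `efdr`;
#'   attributes `ntp`, `nfp`, `tf_id`.
#' @export
empirical_fdr <- function(corr, overlap, tf_id) {
  stopifnot(inherits(corr, "tf_peak_correlation"))
  if (!tf_id %in% rownames(corr$r)) {
    stop("cannot compute efdr for TF '", tf_id,
         "': no defined correlations", call. = FALSE)
  }
  peaks <- intersect(colnames(corr$r), colnames(overlap))
  r <- corr$r[tf_id, peaks]
  fg <- r[overlap[tf_id, peaks] == 1L]
  bg <- r[overlap[tf_id, peaks] == 0L]
  if (length(fg) == 0L || length(bg) == 0L) {
    stop("cannot compute efdr for TF '", tf_id,
         "': empty foreground or background", call. = FALSE)
  }
  ntp <- length(fg)
  nfp <- length(bg)
  ratio <- ntp / nfp
  lo <- .efdr_bin_lo()
  hi <- lo + 0.05
  # cumulative counts per bin via the bin histogram
  fg_bin <- tabulate(.efdr_bin_index(fg), nbins = 40L)
  bg_bin <- tabulate(.efdr_bin_index(bg), nbins = 40L)
  ntp_pos <- rev(cumsum(rev(fg_bin)))   # count of r >= lo_k
  nfp_pos <- rev(cumsum(rev(bg_bin)))
  ntp_neg <- cumsum(fg_bin)             # count of r < hi_k
  nfp_neg <- cumsum(bg_bin)
  mk <- function(direction, k, lo, hi, ntp_k, nfp_k) {
    nfp_norm <- nfp_k * ratio
    data.frame(direction = direction, k = k, bin_lo = lo, bin_hi = hi,
               ntp_k = ntp_k, nfp_k_raw = nfp_k, nfp_k_norm = nfp_norm,
               efdr = ifelse(nfp_norm + ntp_k == 0, NA_real_,
                             nfp_norm / (nfp_norm + ntp_k)),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(mk("positive", lo, lo, hi, ntp_pos, nfp_pos),
               mk("negative", hi, lo, hi, ntp_neg, nfp_neg))
  structure(tab, class = c("efdr_table", "data.frame"),
            ntp = ntp, nfp = nfp, tf_id = tf_id)
}

#' Empirical FDR tables for all TFs
#'
#' @param corr A `tf_peak_correlation`.
#' @param overlap Binary overlap matrix.
#' @return Named list of `efdr_table`s; TFs with empty foreground or
#'   background are skipped with a warning.
#' @export
empirical_fdr_all <- function(corr, overlap) {
  tfs <- rownames(corr$r)
  out <- list()
  for (tf in tfs) {
    tab <- tryCatch(empirical_fdr(corr, overlap, tf), error = function(e) NULL)
    if (is.null(tab)) {
      warning("skipping TF '", tf, "': empty foreground or background",
              call. = FALSE)
    } else {
      out[[tf]] <- tab
    }
  }
  out
}

#' Call significant TF-peak links
#'
#' Every motif-containing (TF, peak) pair is assigned, per direction, the
#' efdr of the bin containing its correlation (positive: largest threshold
#' k <= r; negative: mirrored). A pair is retained if the smaller of the two
#' efdrs is at or below the threshold; the winning direction is recorded,
#' with exact ties broken toward positive.
#'
#' @param corr A `tf_peak_correlation`.
#' @param overlap Binary overlap matrix.
#' @param fdr_tables Named list from [empirical_fdr_all()].
#' @param threshold Maximum efdr to retain a link (default 0.2).
#' @return Data.frame with columns `tf_id`, `peak_id`, `r`, `direction`,
#'   `efdr`, `provenance`.
#' @export
call_tf_peak_links <- function(corr, overlap, fdr_tables, threshold = 0.2) {
  out <- vector("list", length(fdr_tables))
  for (i in seq_along(fdr_tables)) {
    tab <- fdr_tables[[i]]
    tf <- attr(tab, "tf_id")
    peaks <- intersect(colnames(corr$r), colnames(overlap))
    fg_peaks <- peaks[overlap[tf, peaks] == 1L]
    if (length(fg_peaks) == 0L) next
    r <- corr$r[tf, fg_peaks]
    idx <- .efdr_bin_index(r)
    pos <- tab[tab$direction == "positive", ]
    neg <- tab[tab$direction == "negative", ]
    efdr_pos <- pos$efdr[idx]
    efdr_neg <- neg$efdr[idx]
    # NA efdr (empty cumulative sets) can never support a link
    ep <- ifelse(is.na(efdr_pos), Inf, efdr_pos)
    en <- ifelse(is.na(efdr_neg), Inf, efdr_neg)
    direction <- ifelse(ep <= en, "positive", "negative")
    efdr <- pmin(ep, en)
    keep <- efdr <= threshold
    if (!any(keep)) next
    out[[i]] <- data.frame(
      tf_id = tf, peak_id = fg_peaks[keep], r = unname(r[keep]),
      direction = direction[keep], efdr = unname(efdr[keep]),
      provenance = "real", stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(tf_id = character(), peak_id = character(),
                      r = numeric(), direction = character(),
                      efdr = numeric(), provenance = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Classify a TF as activator, repressor or undetermined
#'
#' Compares the foreground (motif-containing peaks) correlation distribution
#' against the background with a two-sided Mann-Whitney rank test. The TF is
#' an activator when the test is significant and the foreground median
#' exceeds the background's upper stringency quantile, a repressor when it
#' falls below the lower one, and undetermined otherwise.
#'
#' @param corr A `tf_peak_correlation`.
#' @param overlap Binary overlap matrix.
#' @param tf_id TF to classify.
#' @param stringency Background quantile defining the classification band
#'   (default 0.1, i.e. the 10th percentile).
#' @param alpha Rank-test significance level (default 0.05).
#' @return A list with `tf_id`, `class`, `p_value`, `fg_median`.
#' @export
classify_tf <- function(corr, overlap, tf_id, stringency = 0.1, alpha = 0.05) {
  stopifnot(stringency > 0, stringency < 0.5)
  peaks <- intersect(colnames(corr$r), colnames(overlap))
  r <- corr$r[tf_id, peaks]
  fg <- r[overlap[tf_id, peaks] == 1L]
  bg <- r[overlap[tf_id, peaks] == 0L]
  if (length(fg) < 5L) {
    warning("TF '", tf_id, "': fewer than 5 motif-containing peaks; ",
            "classified undetermined", call. = FALSE)
    return(list(tf_id = tf_id, class = "undetermined", p_value = NA_real_,
                fg_median = stats::median(fg)))
  }
  p <- suppressWarnings(stats::wilcox.test(fg, bg, exact = FALSE)$p.value)
  fg_med <- stats::median(fg)
  cls <- "undetermined"
  if (!is.na(p) && p < alpha) {
    if (fg_med > stats::quantile(bg, 1 - stringency)) cls <- "activator"
    if (fg_med < stats::quantile(bg, stringency)) cls <- "repressor"
  }
  list(tf_id = tf_id, class = cls, p_value = p, fg_median = fg_med)
}

#' Classify all TFs
#'
#' @inheritParams classify_tf
#' @return Data.frame with columns `tf_id`, `class`, `p_value`, `fg_median`.
#' @export
classify_tfs <- function(corr, overlap, stringency = 0.1, alpha = 0.05) {
  rows <- lapply(rownames(corr$r), function(tf) {
    as.data.frame(classify_tf(corr, overlap, tf, stringency, alpha),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shuffle a binary overlap matrix
#'
#' `scheme = "global"` shuffles all entries of the matrix (preserving
#' overall motif density); `scheme = "per_tf"` shuffles within each row
#' (preserving per-TF motif counts).
#'
#' @param overlap Binary matrix.
#' @param scheme `"global"` or `"per_tf"`.
#' @return Shuffled matrix with the same dimnames.
#' @keywords internal
shuffle_overlap <- function(overlap, scheme = c("global", "per_tf")) {
  scheme <- match.arg(scheme)
  out <- overlap
  if (scheme == "global") {
    out[] <- sample(as.vector(overlap))
  } else {
    for (i in seq_len(nrow(out))) out[i, ] <- sample(overlap[i, ])
  }
  out
}

#' Randomized background TF-peak links (quality control)
#'
#' Applies the twofold randomization scheme - shuffling the entries of the
#' TF-peak overlap matrix and permuting the RNA sample labels - and reruns
#' the identical correlation + empirical-FDR pipeline. On well-behaved data
#' the background yields far fewer links than the real run.
#'
#' @param rna Normalized RNA `count_matrix`.
#' @param atac Normalized chromatin `count_matrix`.
#' @param overlap Binary overlap matrix.
#' @param seed Integer seed controlling both shuffles.
#' @param threshold efdr threshold passed to [call_tf_peak_links()].
#' @param scheme Overlap shuffling scheme (see [shuffle_overlap]).
#' @return Link data.frame with `provenance = "background"`.
#' @export
background_tf_peak <- function(rna, atac, overlap, seed, threshold = 0.2,
                               scheme = c("global", "per_tf")) {
  scheme <- match.arg(scheme)
  with_seed(seed, {
    ov_shuf <- shuffle_overlap(overlap, scheme)
    perm <- sample(ncol(rna$values))
    rna_shuf <- rna
    rna_shuf$values <- rna$values[, perm, drop = FALSE]
    colnames(rna_shuf$values) <- colnames(rna$values)
    corr <- suppressMessages(
      correlate_tf_peak(rna_shuf, atac, rownames(overlap))
    )
    tabs <- suppressWarnings(empirical_fdr_all(corr, ov_shuf))
    links <- call_tf_peak_links(corr, ov_shuf, tabs, threshold)
  })
  if (nrow(links)) links$provenance <- "background"
  links
}
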