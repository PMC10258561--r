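# Independent brute-force oracles, kept free of the package's internals:
# they recompute expected values from first principles on small inputs.

# Empirical-FDR oracle: explicit double loop over the 40 bins x both
# directions, counting foreground/background correlations against each
# threshold directly.
oracle_efdr <- function(fg, bg) {
  ntp <- length(fg)
  nfp <- length(bg)
  rows <- list()
  for (i in 1:40) {
    lo <- (-100L + 5L * (i - 1L)) / 100
    hi <- (-100L + 5L * i) / 100
    for (dir in c("positive", "negative")) {
      if (dir == "positive") {
        k <- lo
        ntp_k <- sum(fg >= k)
        nfp_k <- sum(bg >= k)
      } else {
        k <- hi
        # the top bin is closed at 1 so that r = 1 belongs to a bin
        ntp_k <- if (i == 40L) length(fg) else sum(fg < k)
        nfp_k <- if (i == 40L) length(bg) else sum(bg < k)
      }
      nfp_norm <- nfp_k * (ntp / nfp)
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dir, k = k, bin_lo = lo, bin_hi = hi,
        ntp_k = ntp_k, nfp_k_raw = nfp_k, nfp_k_norm = nfp_norm,
        efdr = if (nfp_norm + ntp_k == 0) NA_real_
               else nfp_norm / (nfp_norm + ntp_k),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$direction, c("positive", "negative")), out$bin_lo), ]
}

# Benjamini-Hochberg step-up from its definition: sort ascending, q_i =
# min_{j >= i} p_(j) * n / j, mapped back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(p[ord] * n / seq_len(n))))
  q <- numeric(n)
  q[ord] <- pmin(1, q_sorted)
  q
}

# Quadratic all-pairs interval overlap check on 0-based half-open
# intervals.
oracle_overlaps <- function(a, b) {
  out <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      out[i, j] <- a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]
    }
  }
  out
}

# Quantile normalization from its definition, one column at a time.
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    for (i in seq_along(col)) {
      tied <- which(col == col[i])
      ranks <- rank(col, ties.method = "first")[tied]
      out[i, j] <- mean(ref[sort(ranks)])
    }
  }
  out
}

# Helper: wrap a plain correlation matrix as the object the TF-peak
# functions consume.
as_tf_peak_correlation <- function(r, n_samples = 10) {
  structure(list(r = r, n_samples = n_samples,
                 dropped_tfs = character(), dropped_peaks = character()),
            class = "tf_peak_correlation")
}
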