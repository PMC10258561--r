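# Peak-gene link inference: cis candidate enumeration (window- or
# TAD-constrained), Pearson correlation with t-based p-values,
# Benjamini-Hochberg adjustment after filtering, and the shuffled background.

#' Enumerate candidate peak-gene pairs
#'
#' Without TADs, a pair is tested iff the gene's TSS lies within
#' `[peak_start - window, peak_end + window)` (anchor `"tss"`), or the gene
#' body intersects that extended interval (anchor `"anywhere"`, requires
#' `start`/`end` columns in the annotation). With TADs, a pair is tested iff
#' one TAD contains both the peak midpoint and the TSS. The recorded TSS
#' distance is 0 when the TSS falls inside the peak and otherwise the
#' distance from the TSS to the nearest peak base.
#'
#' @param peaks Peak interval data.frame (`chrom`, `start`, `end`, `name`).
#' @param genes Gene annotation data.frame.
#' @param window Neighbourhood size in bp up- and downstream of the peak
#'   (default 250000).
#' @param tads Optional TAD interval data.frame; when given, the window is
#'   ignored and TAD co-membership decides which pairs are tested.
#' @param anchor `"tss"` (default) or `"anywhere"`.
#' @param gene_types Gene types to retain (default protein_coding and
#'   lincRNA). Types absent from the annotation raise an error.
#' @return Data.frame with `peak_id`, `gene_id`, `tss_distance`, `same_tad`.
#' @export
enumerate_pairs <- function(peaks, genes, window = 250000,
                            tads = NULL, anchor = c("tss", "anywhere"),
                            gene_types = c("protein_coding", "lincRNA")) {
  anchor <- match.arg(anchor)
  genes <- genes[genes$gene_type %in% gene_types, , drop = FALSE]
  if (nrow(genes) == 0L) {
    stop("unknown gene_type string(s): no gene matches ",
         paste(gene_types, collapse = ", "), call. = FALSE)
  }
  if (anchor == "anywhere" && !all(c("start", "end") %in% names(genes))) {
    stop("anchor = 'anywhere' requires gene body start/end columns",
         call. = FALSE)
  }
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      tss_distance = integer(), same_tad = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(empty)

  if (is.null(tads)) {
    ext <- data.frame(chrom = peaks$chrom,
                      start = pmax(0L, peaks$start - as.integer(window)),
                      end = peaks$end + as.integer(window))
    target <- if (anchor == "tss") {
      data.frame(chrom = genes$chrom, start = genes$tss,
                 end = genes$tss + 1L)
    } else {
      data.frame(chrom = genes$chrom, start = genes$start, end = genes$end)
    }
    hits <- GenomicRanges::findOverlaps(intervals_to_granges(ext),
                                        intervals_to_granges(target))
    pi <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    same_tad <- rep(NA, length(pi))
  } else {
    tad_gr <- intervals_to_granges(tads)
    mid <- data.frame(chrom = peaks$chrom,
                      start = (peaks$start + peaks$end) %/% 2L)
    mid$end <- mid$start + 1L
    tss <- data.frame(chrom = genes$chrom, start = genes$tss,
                      end = genes$tss + 1L)
    ph <- GenomicRanges::findOverlaps(intervals_to_granges(mid), tad_gr,
                                      type = "within")
    gh <- GenomicRanges::findOverlaps(intervals_to_granges(tss), tad_gr,
                                      type = "within")
    # pairs sharing at least one TAD
    pt <- split(S4Vectors::subjectHits(ph), S4Vectors::queryHits(ph))
    gt <- split(S4Vectors::queryHits(gh), S4Vectors::subjectHits(gh))
    pi <- integer(); gi <- integer()
    for (p in names(pt)) {
      gset <- unique(unlist(gt[as.character(pt[[p]])], use.names = FALSE))
      if (length(gset)) {
        pi <- c(pi, rep(as.integer(p), length(gset)))
        gi <- c(gi, gset)
      }
    }
    same_tad <- rep(TRUE, length(pi))
  }
  if (length(pi) == 0L) return(empty)
  tssv <- genes$tss[gi]
  ps <- peaks$start[pi]
  pe <- peaks$end[pi]
  inside <- tssv >= ps & tssv < pe
  dist <- ifelse(inside, 0L, pmin(abs(tssv - ps), abs(tssv - (pe - 1L))))
  out <- data.frame(peak_id = peaks$name[pi], gene_id = genes$gene_id[gi],
                    tss_distance = as.integer(dist), same_tad = same_tad,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Correlate candidate peak-gene pairs
#'
#' Pearson r across samples per pair, with a two-sided p-value from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom
#' (p = 0 at |r| = 1). Pairs whose peak or gene has zero variance are
#' dropped with a message.
#'
#' @param pairs Candidate pair data.frame from [enumerate_pairs()].
#' @param atac Normalized chromatin `count_matrix`.
#' @param rna Normalized RNA `count_matrix`.
#' @return `pairs` with added columns `r` and `p_raw`.
#' @export
correlate_pairs <- function(pairs, atac, rna) {
  stopifnot(inherits(atac, "count_matrix"), inherits(rna, "count_matrix"))
  if (!identical(sample_ids(rna), sample_ids(atac))) {
    stop("RNA and chromatin matrices must share identically ordered samples",
         call. = FALSE)
  }
  n <- ncol(rna$values)
  if (n < 3L) stop("need >= 3 samples to correlate", call. = FALSE)
  keep <- pairs$peak_id %in% feature_ids(atac) &
    pairs$gene_id %in% feature_ids(rna)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    pairs$r <- numeric(0); pairs$p_raw <- numeric(0)
    return(pairs)
  }
  a <- atac$values[pairs$peak_id, , drop = FALSE]
  g <- rna$values[pairs$gene_id, , drop = FALSE]
  ac <- a - rowMeans(a)
  gc <- g - rowMeans(g)
  den <- sqrt(rowSums(ac^2) * rowSums(gc^2))
  degenerate <- den == 0
  if (any(degenerate)) {
    message(sum(degenerate),
            " pair(s) dropped: zero-variance peak or gene")
    pairs <- pairs[!degenerate, , drop = FALSE]
    ac <- ac[!degenerate, , drop = FALSE]
    gc <- gc[!degenerate, , drop = FALSE]
    den <- den[!degenerate]
  }
  r <- rowSums(ac * gc) / den
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
  pairs$r <- unname(r)
  pairs$p_raw <- unname(p)
  rownames(pairs) <- NULL
  pairs
}

#' Filter peak-gene pairs and adjust for multiple testing
#'
#' Applies the distance and positivity filters first, then
#' Benjamini-Hochberg over the surviving p-values only, then retains pairs
#' with adjusted FDR at or below the threshold.
#'
#' @param pairs Correlated pair data.frame (with `r`, `p_raw`).
#' @param fdr_threshold Maximum BH-adjusted FDR (default 0.1). `Inf` keeps
#'   all filtered pairs with their FDR, which is useful for ranking.
#' @param positive_only Keep only positively correlated pairs (default TRUE;
#'   negative peak-gene correlations carry no clear regulatory meaning).
#' @param max_distance Maximum TSS distance in bp (default 250000).
#' @return Data.frame with `peak_id`, `gene_id`, `r`, `p_raw`, `fdr_bh`,
#'   `tss_distance`, `provenance`.
#' @export
filter_and_adjust <- function(pairs, fdr_threshold = 0.1,
                              positive_only = TRUE, max_distance = 250000) {
  keep <- pairs$tss_distance <= max_distance
  if (positive_only) keep <- keep & pairs$r > 0
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no peak-gene pairs survive the filters", call. = FALSE)
    return(data.frame(peak_id = character(), gene_id = character(),
                      r = numeric(), p_raw = numeric(), fdr_bh = numeric(),
                      tss_distance = integer(), provenance = character(),
                      stringsAsFactors = FALSE))
  }
  out$fdr_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out <- out[out$fdr_bh <= fdr_threshold, , drop = FALSE]
  out$provenance <- rep("real", nrow(out))
  rownames(out) <- NULL
  out[, c("peak_id", "gene_id", "r", "p_raw", "fdr_bh", "tss_distance",
          "provenance")]
}

#' Shuffled background peak-gene pairs (quality control)
#'
#' Relabels the peak column of the candidate table with a random bijection
#' on peak IDs (preserving every peak's and gene's pair count exactly) and
#' permutes the RNA sample labels, then recomputes r and p on the permuted
#' pairs.
#'
#' @param pairs Candidate pair data.frame (the real table).
#' @param atac Normalized chromatin `count_matrix`.
#' @param rna Normalized RNA `count_matrix`.
#' @param seed Integer seed.
#' @return Correlated pair data.frame with `provenance = "background"`.
#' @export
background_peak_gene <- function(pairs, atac, rna, seed) {
  bg <- with_seed(seed, {
    peaks <- unique(pairs$peak_id)
    mapping <- stats::setNames(sample(peaks), peaks)
    shuffled <- pairs
    shuffled$peak_id <- unname(mapping[pairs$peak_id])
    perm <- sample(ncol(rna$values))
    rna_shuf <- rna
    rna_shuf$values <- rna$values[, perm, drop = FALSE]
    colnames(rna_shuf$values) <- colnames(rna$values)
    suppressMessages(correlate_pairs(shuffled, atac, rna_shuf))
  })
  bg$provenance <- rep("background", nrow(bg))
  bg
}

#' Signal-to-noise summary of peak-gene correlations
#'
#' Counts, per TSS-distance stratum, the pairs with p < `p_cut` split by
#' the sign of r, for the real and background tables. The ratio of positive
#' to negative significant pairs is the signal-to-noise readout: functional
#' links are expected to be positively correlated, so the real table should
#' show an excess of positive signal that the background lacks.
#'
#' @param real_pairs Correlated real pair table.
#' @param background_pairs Correlated background pair table.
#' @param breaks Distance bin edges in bp (default 50-kb bins up to 250 kb).
#' @param p_cut Significance cut for counting (default 0.05).
#' @return Data.frame with one row per (set, distance bin): counts of
#'   significant positive/negative pairs and their ratio.
#' @export
peak_gene_qc <- function(real_pairs, background_pairs,
                         breaks = seq(0, 250000, by = 50000), p_cut = 0.05) {
  summarize <- function(df, set) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    bin <- cut(df$tss_distance, breaks = breaks, include.lowest = TRUE,
               right = FALSE)
    out <- do.call(rbind, lapply(levels(bin), function(b) {
      sel <- !is.na(bin) & bin == b
      sig <- sel & df$p_raw < p_cut
      data.frame(set = set, distance_bin = b,
                 n_pairs = sum(sel),
                 n_sig_pos = sum(sig & df$r > 0),
                 n_sig_neg = sum(sig & df$r < 0),
                 stringsAsFactors = FALSE)
    }))
    out$ratio <- ifelse(out$n_sig_neg > 0, out$n_sig_pos / out$n_sig_neg,
                        ifelse(out$n_sig_pos > 0, Inf, NA_real_))
    out
  }
  rbind(summarize(real_pairs, "real"),
        summarize(background_pairs, "background"))
}
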