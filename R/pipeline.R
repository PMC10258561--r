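# End-to-end orchestration: normalize and filter the two count matrices,
# call TF-peak and peak-gene links, and assemble the tripartite network.

#' Run the full network-inference pipeline
#'
#' Applies the default processing chain: low-count filtering of both
#' matrices, quantile normalization of the RNA counts and median-of-ratios
#' size-factor normalization of the chromatin counts (prenormalised input
#' with `normalized = "user"` bypasses both), motif-overlap construction,
#' TF-peak link calling by empirical FDR, TF classification, cis peak-gene
#' link calling with BH adjustment, and assembly of the tripartite network.
#'
#' @param rna RNA `count_matrix` (genes + TFs x samples).
#' @param atac Chromatin `count_matrix` (peaks x samples; peak IDs carry
#'   coordinates).
#' @param tfbs TFBS collection (named list of interval data.frames). TFs
#'   absent from the RNA matrix are dropped with a warning.
#' @param genes Gene annotation data.frame.
#' @param tads Optional TAD interval data.frame.
#' @param config Configuration list (see [default_config()]).
#' @param exclude_chroms Chromosomes to drop up front (e.g. sex
#'   chromosomes).
#' @param background_seed If non-NULL, also compute the randomized
#'   TF-peak and shuffled peak-gene backgrounds with this seed.
#' @return A list with the intermediate tables (`tf_peak_links`,
#'   `fdr_tables`, `tf_classes`, `pairs`, `peak_gene_links`), the assembled
#'   `egrn`, the normalized matrices, and (if requested) the `background`
#'   tables.
#' @export
run_egrn_pipeline <- function(rna, atac, tfbs, genes, tads = NULL,
                              config = default_config(),
                              exclude_chroms = character(),
                              background_seed = NULL) {
  stopifnot(inherits(rna, "count_matrix"), inherits(atac, "count_matrix"))
  peaks_all <- parse_peak_id(feature_ids(atac))
  peaks_all$strand <- "."
  if (length(exclude_chroms)) {
    fa <- filter_chromosomes(atac, peaks_all, exclude_chroms)
    atac <- fa$matrix
    genes <- genes[!genes$chrom %in% exclude_chroms, , drop = FALSE]
  }

  rna <- filter_low_count(rna, config$min_mean_count)
  atac <- filter_low_count(atac, config$min_mean_count)
  if (rna$normalized == "raw") rna <- quantile_normalize(rna)
  if (atac$normalized == "raw") atac <- size_factor_normalize(atac)
  if (isTRUE(config$log_counts)) {
    rna <- log_transform(rna)
    atac <- log_transform(atac)
  }
  peaks <- parse_peak_id(feature_ids(atac))
  peaks$strand <- "."

  unmatched <- setdiff(names(tfbs), feature_ids(rna))
  if (length(unmatched)) {
    warning(length(unmatched), " TF(s) not in the RNA matrix, dropped: ",
            paste(utils::head(unmatched, 5), collapse = ", "), call. = FALSE)
    tfbs <- tfbs[setdiff(names(tfbs), unmatched)]
  }
  if (length(tfbs) == 0L) stop("no TFs left to test", call. = FALSE)

  overlap <- build_overlap_matrix(tfbs, peaks)
  corr <- correlate_tf_peak(rna, atac, names(tfbs))
  fdr_tables <- empirical_fdr_all(corr, overlap)
  tf_peak_links <- call_tf_peak_links(corr, overlap, fdr_tables,
                                      threshold = config$tf_peak_fdr)
  tf_classes <- classify_tfs(corr, overlap,
                             stringency = config$classify_stringency,
                             alpha = config$classify_alpha)

  pairs <- enumerate_pairs(peaks, genes, window = config$window,
                           tads = tads, anchor = config$anchor,
                           gene_types = intersect(config$gene_types,
                                                  unique(genes$gene_type)))
  pairs <- correlate_pairs(pairs, atac, rna)
  peak_gene_links <- filter_and_adjust(pairs,
                                       fdr_threshold = config$peak_gene_fdr,
                                       positive_only = config$positive_only,
                                       max_distance = config$window)
  egrn <- assemble_egrn(tf_peak_links, peak_gene_links,
                        tf_classes = tf_classes, genes = genes)

  background <- NULL
  if (!is.null(background_seed)) {
    background <- list(
      tf_peak = background_tf_peak(rna, atac, overlap, background_seed,
                                   threshold = config$tf_peak_fdr),
      peak_gene = background_peak_gene(pairs, atac, rna, background_seed)
    )
  }
  list(rna = rna, atac = atac, overlap = overlap, corr = corr,
       fdr_tables = fdr_tables, tf_peak_links = tf_peak_links,
       tf_classes = tf_classes, pairs = pairs,
       peak_gene_links = peak_gene_links, egrn = egrn,
       background = background, config = config)
}

#' Write a simulated cohort to disk in the formats the pipeline consumes
#'
#' Emits `rna.tsv`, `atac.tsv`, `genes.tsv`, a `tfbs/` directory of per-TF
#' BED files, and `truth.json` describing the planted network.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param truth The `true_network` behind the cohort.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(cohort$rna, file.path(dir, "rna.tsv"))
  write_count_matrix(cohort$atac, file.path(dir, "atac.tsv"))
  write_gene_annotation(cohort$genes, file.path(dir, "genes.tsv"))
  write_tfbs_dir(cohort$tfbs, file.path(dir, "tfbs"))
  jsonlite::write_json(
    list(tf_peak = truth$tf_peak, peak_gene = truth$peak_gene,
         tf_classes = truth$tf_classes),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA
  )
  invisible(dir)
}
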