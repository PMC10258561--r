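# Synthetic paired-cohort generator: a planted tripartite TF-peak-gene
# network on a synthetic genome, negative-binomial RNA/ATAC count matrices
# driven by latent Gaussian TF activities, matched knockout-style
# differential-expression vectors, and truth-scoring of inferred networks.

#' Simulation parameters
#'
#' Defines a synthetic paired RNA/ATAC cohort with a planted regulatory
#' network. Defaults describe a cohort of 30 samples with 20 TFs, 500
#' accessible peaks and 300 genes laid out on synthetic chromosomes of
#' ~100 features spaced 20 kb apart, so that plenty of decoy peak-gene
#' pairs fall inside the 250-kb testing window.
#'
#' @param n_samples Cohort size (default 30).
#' @param n_tfs Number of transcription factors (default 20).
#' @param n_peaks Number of accessibility peaks (default 500).
#' @param n_genes Number of genes (default 300).
#' @param frac_true_tf_peak Fraction of peaks that are true targets of some
#'   TF (default 0.5).
#' @param frac_true_peak_gene Fraction of genes that are true targets of
#'   some regulated peak (default 0.7); each such gene receives 1-3 parent
#'   peaks within the window.
#' @param effect_sd Scale of the TF-to-peak signal slopes (default 1).
#' @param noise_sd Latent Gaussian noise added at each layer (default 0.5).
#' @param nb_dispersion Negative-binomial dispersion of the counts
#'   (default 0.1; variance = mu + dispersion * mu^2).
#' @param decoy_motif_rate Probability that a non-target peak carries a
#'   decoy binding site of a given TF (default 0.1).
#' @param activator_prob Probability a TF is an activator rather than a
#'   repressor (default 0.65, activators being the more common class).
#' @param peak_width Peak width in bp (default 500).
#' @param feature_spacing Distance between adjacent feature slots in bp
#'   (default 20000).
#' @param features_per_chrom Feature slots per synthetic chromosome
#'   (default 100).
#' @param window Maximum true peak-gene distance in bp (default 250000).
#' @param base_log_mean Log mean count at latent value 0 (default log(100)).
#' @param latent_scale Multiplier mapping latent values to log-mean counts
#'   (default 0.5).
#' @param seed Integer seed (default 1).
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(n_samples = 30, n_tfs = 20, n_peaks = 500,
                              n_genes = 300, frac_true_tf_peak = 0.5,
                              frac_true_peak_gene = 0.7, effect_sd = 1,
                              noise_sd = 0.5, nb_dispersion = 0.1,
                              decoy_motif_rate = 0.1, activator_prob = 0.65,
                              peak_width = 500, feature_spacing = 20000,
                              features_per_chrom = 100, window = 250000,
                              base_log_mean = log(100), latent_scale = 0.5,
                              seed = 1) {
  p <- list(n_samples = n_samples, n_tfs = n_tfs, n_peaks = n_peaks,
            n_genes = n_genes, frac_true_tf_peak = frac_true_tf_peak,
            frac_true_peak_gene = frac_true_peak_gene, effect_sd = effect_sd,
            noise_sd = noise_sd, nb_dispersion = nb_dispersion,
            decoy_motif_rate = decoy_motif_rate,
            activator_prob = activator_prob, peak_width = peak_width,
            feature_spacing = feature_spacing,
            features_per_chrom = features_per_chrom, window = window,
            base_log_mean = base_log_mean, latent_scale = latent_scale,
            seed = seed)
  counts <- c("n_samples", "n_tfs", "n_peaks", "n_genes", "peak_width",
              "feature_spacing", "features_per_chrom", "window")
  for (nm in counts) {
    if (p[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  for (nm in c("frac_true_tf_peak", "frac_true_peak_gene")) {
    if (p[[nm]] < 0 || p[[nm]] >= 1) {
      stop(nm, " must be in [0, 1)", call. = FALSE)
    }
  }
  if (p$feature_spacing >= p$window) {
    stop("feature_spacing must be smaller than window (no cis pairs exist ",
         "otherwise)", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

#' Simulate the ground-truth regulatory network and genome layout
#'
#' Places peaks and gene TSSs on synthetic chromosomes, assigns each TF a
#' set of true target peaks with signed slopes (negative for repressors),
#' wires regulated genes to 1-3 nearby regulated peaks with positive
#' slopes, plants a binding site in every true target peak and sprinkles
#' decoy binding sites into non-target peaks.
#'
#' @param params A `simulation_params`.
#' @return A `true_network`: list with `tf_peak` (tf_id, peak_id, slope),
#'   `peak_gene` (peak_id, gene_id, beta), `tf_classes`, `peaks`, `genes`,
#'   `tfbs`, `params`.
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  n_feat <- p$n_peaks + p$n_genes
  n_chrom <- ceiling(n_feat / p$features_per_chrom)
  with_seed(p$seed, {
    # genome layout: feature slots along chromosomes, randomly typed
    slot_chrom <- rep(sprintf("chr%d", seq_len(n_chrom)),
                      each = p$features_per_chrom)[seq_len(n_feat)]
    slot_pos <- unlist(lapply(table(slot_chrom)[unique(slot_chrom)],
                              function(k) seq_len(k) * p$feature_spacing),
                       use.names = FALSE)
    is_peak <- sample(rep(c(TRUE, FALSE), c(p$n_peaks, p$n_genes)))
    peak_start <- slot_pos[is_peak]
    peaks <- data.frame(
      chrom = slot_chrom[is_peak],
      start = peak_start,
      end = peak_start + p$peak_width,
      stringsAsFactors = FALSE
    )
    peaks$name <- peak_id(peaks$chrom, peaks$start, peaks$end)
    peaks$strand <- "."
    genes <- data.frame(
      gene_id = sprintf("G%03d", seq_len(p$n_genes)),
      chrom = slot_chrom[!is_peak],
      strand = sample(c("+", "-"), p$n_genes, replace = TRUE),
      tss = slot_pos[!is_peak],
      gene_type = "protein_coding",
      stringsAsFactors = FALSE
    )

    tf_ids <- sprintf("TF%02d", seq_len(p$n_tfs))
    tf_classes <- data.frame(
      tf_id = tf_ids,
      class = ifelse(stats::runif(p$n_tfs) < p$activator_prob,
                     "activator", "repressor"),
      stringsAsFactors = FALSE
    )
    tf_sign <- ifelse(tf_classes$class == "activator", 1, -1)
    names(tf_sign) <- tf_ids

    # true TF -> peak edges: each regulated peak is driven by one TF
    n_reg_peaks <- round(p$frac_true_tf_peak * p$n_peaks)
    tf_peak <- data.frame(tf_id = character(), peak_id = character(),
                          slope = numeric(), stringsAsFactors = FALSE)
    if (n_reg_peaks > 0) {
      reg_peaks <- sample(peaks$name, n_reg_peaks)
      driver <- sample(rep(tf_ids, length.out = n_reg_peaks))
      slope <- tf_sign[driver] *
        stats::runif(n_reg_peaks, 0.75, 1.25) * p$effect_sd
      tf_peak <- data.frame(tf_id = driver, peak_id = reg_peaks,
                            slope = unname(slope), stringsAsFactors = FALSE)
    }

    # true peak -> gene edges: regulated genes pick 1-3 regulated parent
    # peaks within the window, with positive slopes
    n_reg_genes <- round(p$frac_true_peak_gene * p$n_genes)
    peak_gene <- data.frame(peak_id = character(), gene_id = character(),
                            beta = numeric(), stringsAsFactors = FALSE)
    if (n_reg_genes > 0 && nrow(tf_peak) > 0) {
      reg_gene_ids <- sample(genes$gene_id, n_reg_genes)
      reg_peak_tab <- peaks[peaks$name %in% tf_peak$peak_id, , drop = FALSE]
      rows <- lapply(reg_gene_ids, function(gid) {
        g <- genes[genes$gene_id == gid, ]
        cand <- reg_peak_tab[reg_peak_tab$chrom == g$chrom, , drop = FALSE]
        inside <- g$tss >= cand$start & g$tss < cand$end
        d <- ifelse(inside, 0,
                    pmin(abs(g$tss - cand$start),
                         abs(g$tss - (cand$end - 1))))
        cand <- cand$name[d <= p$window]
        if (length(cand) == 0L) return(NULL)
        k <- min(length(cand), 1L + stats::rbinom(1L, 2L, 0.5))
        chosen <- if (length(cand) == 1L) cand else sample(cand, k)
        data.frame(peak_id = chosen, gene_id = gid,
                   beta = stats::runif(length(chosen), 0.5, 1.5),
                   stringsAsFactors = FALSE)
      })
      peak_gene <- do.call(rbind, rows)
      if (is.null(peak_gene)) {
        peak_gene <- data.frame(peak_id = character(), gene_id = character(),
                                beta = numeric(), stringsAsFactors = FALSE)
      }
      dropped <- n_reg_genes -
        length(unique(peak_gene$gene_id))
      if (dropped > 0) {
        message(dropped,
                " regulated gene(s) had no regulated peak in range; left",
                " unregulated")
      }
    }

    # binding sites: one planted site per true edge, decoys elsewhere
    tfbs <- lapply(tf_ids, function(tf) {
      targets <- tf_peak$peak_id[tf_peak$tf_id == tf]
      decoy_pool <- setdiff(peaks$name, targets)
      decoys <- decoy_pool[stats::runif(length(decoy_pool)) <
                             p$decoy_motif_rate]
      sites <- peaks[peaks$name %in% c(targets, decoys), , drop = FALSE]
      if (nrow(sites) == 0L) {
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          strand = character(), stringsAsFactors = FALSE))
      }
      data.frame(chrom = sites$chrom,
                 start = sites$start + 10L,
                 end = sites$start + 25L,
                 name = paste0(tf, "_site"),
                 strand = ".",
                 stringsAsFactors = FALSE)
    })
    names(tfbs) <- tf_ids

    structure(list(tf_peak = tf_peak, peak_gene = peak_gene,
                   tf_classes = tf_classes, peaks = peaks, genes = genes,
                   tfbs = tfbs, params = p),
              class = "true_network")
  })
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf(
    "true_network: %d TFs, %d peaks (%d regulated), %d genes (%d regulated)\n",
    nrow(x$tf_classes), nrow(x$peaks), length(unique(x$tf_peak$peak_id)),
    nrow(x$genes), length(unique(x$peak_gene$gene_id))))
  invisible(x)
}

# Draw NB counts around exp(base + scale * z); size = 1/dispersion.
.latent_to_counts <- function(z, p) {
  mu <- exp(p$base_log_mean + p$latent_scale * z)
  n <- length(mu)
  if (p$nb_dispersion <= 0) return(matrix(stats::rpois(n, mu), nrow = nrow(z)))
  matrix(stats::rnbinom(n, mu = mu, size = 1 / p$nb_dispersion),
         nrow = nrow(z))
}

#' Simulate a paired RNA/ATAC cohort from a planted truth
#'
#' Latent per-sample TF activities are standard normal; each peak's latent
#' signal is its driver-TF activity times the planted slope plus Gaussian
#' noise (unregulated peaks get an independent latent driver); each gene's
#' latent signal is the positive-weighted sum of its parent peaks' latent
#' signals plus noise. Counts are negative-binomial with mean
#' `exp(base_log_mean + latent_scale * z)`. TF expression counts are
#' generated from the activities through the same link.
#'
#' @param truth A `true_network`.
#' @param params A `simulation_params` (defaults to the one stored in
#'   `truth`).
#' @param seed Seed for the cohort draw (default `params$seed + 1`, so the
#'   cohort is reproducible but distinct from the truth draw).
#' @return A list with `rna` (`count_matrix` of TFs + genes), `atac`
#'   (`count_matrix` of peaks), `tfbs` (TFBS collection), `genes`
#'   (annotation), and the latent matrices in `latent`.
#' @export
simulate_cohort <- function(truth, params = truth$params,
                            seed = params$seed + 1L) {
  stopifnot(inherits(truth, "true_network"))
  p <- params
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(p$n_samples))
    tf_ids <- truth$tf_classes$tf_id
    act <- matrix(stats::rnorm(length(tf_ids) * p$n_samples),
                  nrow = length(tf_ids),
                  dimnames = list(tf_ids, samples))

    z_peak <- matrix(0, nrow = nrow(truth$peaks), ncol = p$n_samples,
                     dimnames = list(truth$peaks$name, samples))
    for (i in seq_len(nrow(truth$tf_peak))) {
      e <- truth$tf_peak[i, ]
      z_peak[e$peak_id, ] <- z_peak[e$peak_id, ] + e$slope * act[e$tf_id, ]
    }
    unreg <- !(truth$peaks$name %in% truth$tf_peak$peak_id)
    z_peak[unreg, ] <- stats::rnorm(sum(unreg) * p$n_samples)
    z_peak <- z_peak + stats::rnorm(length(z_peak), sd = p$noise_sd)

    z_gene <- matrix(0, nrow = nrow(truth$genes), ncol = p$n_samples,
                     dimnames = list(truth$genes$gene_id, samples))
    for (i in seq_len(nrow(truth$peak_gene))) {
      e <- truth$peak_gene[i, ]
      z_gene[e$gene_id, ] <- z_gene[e$gene_id, ] + e$beta * z_peak[e$peak_id, ]
    }
    unreg_g <- !(truth$genes$gene_id %in% truth$peak_gene$gene_id)
    z_gene[unreg_g, ] <- stats::rnorm(sum(unreg_g) * p$n_samples)
    z_gene <- z_gene + stats::rnorm(length(z_gene), sd = p$noise_sd)

    rna_z <- rbind(act, z_gene)
    rna_counts <- .latent_to_counts(rna_z, p)
    dimnames(rna_counts) <- dimnames(rna_z)
    atac_counts <- .latent_to_counts(z_peak, p)
    dimnames(atac_counts) <- dimnames(z_peak)

    list(rna = count_matrix(rna_counts),
         atac = count_matrix(atac_counts),
         tfbs = truth$tfbs,
         genes = truth$genes,
         latent = list(activities = act, peaks = z_peak, genes = z_gene))
  })
}

#' Simulate knockout-style differential expression from perturbed TFs
#'
#' Each gene's log2 fold-change is `effect` times its signed pathway weight
#' from the perturbed TFs (sum over true TF-peak-gene paths of
#' slope x beta) plus Gaussian noise. Adjusted p-values derive from a
#' z-model on the fold-change (`p_raw = 2 * pnorm(-|lfc| / noise_sd)`,
#' BH-adjusted), so pathway genes get small p and null genes roughly
#' uniform p.
#'
#' @param truth A `true_network`.
#' @param perturbed_tfs TFs to perturb (must exist in the truth).
#' @param effect Perturbation strength on the log2 scale (default 3).
#' @param noise_sd Fold-change noise (default 0.5).
#' @param seed Integer seed.
#' @return Data.frame with `gene_id`, `log2fc`, `p_adj`, and the latent
#'   `pathway_weight`.
#' @export
simulate_de <- function(truth, perturbed_tfs, effect = 3, noise_sd = 0.5,
                        seed = 1) {
  stopifnot(inherits(truth, "true_network"))
  unknown <- setdiff(perturbed_tfs, truth$tf_classes$tf_id)
  if (length(unknown)) {
    stop("unknown TF(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  w <- stats::setNames(numeric(nrow(truth$genes)), truth$genes$gene_id)
  tp <- truth$tf_peak[truth$tf_peak$tf_id %in% perturbed_tfs, , drop = FALSE]
  if (nrow(tp) > 0 && nrow(truth$peak_gene) > 0) {
    paths <- merge(tp, truth$peak_gene, by = "peak_id")
    if (nrow(paths)) {
      contrib <- tapply(paths$slope * paths$beta, paths$gene_id, sum)
      w[names(contrib)] <- contrib
    }
  }
  with_seed(seed, {
    lfc <- effect * w + stats::rnorm(length(w), sd = noise_sd)
    p_raw <- 2 * stats::pnorm(-abs(lfc) / noise_sd)
    data.frame(gene_id = names(w), log2fc = unname(lfc),
               p_adj = stats::p.adjust(p_raw, method = "BH"),
               pathway_weight = unname(w), stringsAsFactors = FALSE)
  })
}

#' Choose perturbation-target TFs from a planted truth
#'
#' Selects the activators and repressors with the largest truth regulons
#' (distinct downstream genes). Knockout-style evaluations need perturbed
#' TFs whose regulons cover enough genes for the predictive model, which
#' mirrors how real knockout comparisons target well-connected TFs.
#'
#' @param truth A `true_network`.
#' @param n_activators Number of activators to pick (default 2).
#' @param n_repressors Number of repressors to pick (default 1).
#' @return Character vector of TF identifiers, largest regulons first
#'   within each class.
#' @export
select_perturbed_tfs <- function(truth, n_activators = 2, n_repressors = 1) {
  net <- truth_tf_gene_network(truth)
  sizes <- vapply(split(net$gene, net$tf), function(g) length(unique(g)),
                  integer(1))
  cls <- stats::setNames(truth$tf_classes$class, truth$tf_classes$tf_id)
  ranked <- names(sort(sizes, decreasing = TRUE))
  c(utils::head(ranked[cls[ranked] == "activator"], n_activators),
    utils::head(ranked[cls[ranked] == "repressor"], n_repressors))
}

#' Regulons of the planted truth (TF -> gene projection)
#'
#' @param truth A `true_network`.
#' @return Data.frame with `tf`, `gene` (unique pairs).
#' @export
truth_tf_gene_network <- function(truth) {
  el <- merge(truth$tf_peak, truth$peak_gene, by = "peak_id")
  unique(data.frame(tf = el$tf_id, gene = el$gene_id,
                    stringsAsFactors = FALSE))
}

# Edge-level precision/recall of a called set against a truth set, with
# the empty-call convention precision = 1 (flagged).
.pr <- function(called, true) {
  if (length(called) == 0L) {
    return(list(precision = 1, recall = if (length(true)) 0 else NA_real_,
                empty = TRUE))
  }
  tp <- length(intersect(called, true))
  list(precision = tp / length(called),
       recall = if (length(true)) tp / length(true) else NA_real_,
       empty = FALSE)
}

#' Score an inferred network against the planted truth
#'
#' Edge-level precision and recall for the thresholded TF-peak and
#' peak-gene link tables, and ranking AUCs over the candidate edges scored
#' by 1 - efdr (TF-peak; candidates are all motif-containing pairs) and
#' 1 - BH FDR (peak-gene; candidates are all window pairs, with
#' non-positively-correlated pairs ranked last).
#'
#' @param tf_peak_links Thresholded TF-peak link table.
#' @param peak_gene_links Thresholded peak-gene link table.
#' @param truth A `true_network`.
#' @param tf_peak_candidates Optional unthresholded link table (from
#'   [call_tf_peak_links()] with `threshold = 1`) for the ranking AUC.
#' @param peak_gene_candidates Optional correlated candidate table (with
#'   `r`, `p_raw`) for the ranking AUC.
#' @return List with `tf_peak` and `peak_gene`, each carrying `precision`,
#'   `recall` and (when candidates are given) `auc`.
#' @export
score_recovery <- function(tf_peak_links, peak_gene_links, truth,
                           tf_peak_candidates = NULL,
                           peak_gene_candidates = NULL) {
  key <- function(a, b) paste(a, b, sep = "\r")
  true_tp <- key(truth$tf_peak$tf_id, truth$tf_peak$peak_id)
  true_pg <- key(truth$peak_gene$peak_id, truth$peak_gene$gene_id)
  tp_score <- .pr(key(tf_peak_links$tf_id, tf_peak_links$peak_id), true_tp)
  pg_score <- .pr(key(peak_gene_links$peak_id, peak_gene_links$gene_id),
                  true_pg)
  if (!is.null(tf_peak_candidates) && nrow(tf_peak_candidates)) {
    lab <- key(tf_peak_candidates$tf_id, tf_peak_candidates$peak_id) %in%
      true_tp
    tp_score$auc <- auroc(1 - tf_peak_candidates$efdr, lab)
  }
  if (!is.null(peak_gene_candidates) && nrow(peak_gene_candidates)) {
    cand <- peak_gene_candidates
    fdr <- rep(1, nrow(cand))
    pos <- !is.na(cand$r) & cand$r > 0
    fdr[pos] <- stats::p.adjust(cand$p_raw[pos], method = "BH")
    lab <- key(cand$peak_id, cand$gene_id) %in% true_pg
    pg_score$auc <- auroc(1 - fdr, lab)
  }
  list(tf_peak = tp_score, peak_gene = pg_score)
}
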