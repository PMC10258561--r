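# Tripartite network assembly and downstream analyses: joining TF-peak and
# peak-gene links, network statistics, community detection, regulons, and
# the degree-preserving gene-label permutation used as a null control.

#' Assemble the tripartite TF-peak-gene network
#'
#' Inner join of the thresholded TF-peak and peak-gene link tables on the
#' peak ID; one triplet per (TF, peak, gene). Node tables are restricted to
#' nodes appearing in at least one triplet.
#'
#' @param tf_peak TF-peak link table from [call_tf_peak_links()].
#' @param peak_gene Peak-gene link table from [filter_and_adjust()].
#' @param tf_classes Optional TF classification table from [classify_tfs()].
#' @param genes Optional gene annotation to attach to the gene node table.
#' @return An `egrn` object: list with `edges` (triplet table) and node
#'   tables `tfs`, `peaks`, `genes`.
#' @export
assemble_egrn <- function(tf_peak, peak_gene, tf_classes = NULL, genes = NULL) {
  shared <- intersect(tf_peak$peak_id, peak_gene$peak_id)
  if (length(shared) == 0L) {
    warning("TF-peak and peak-gene links share no peaks: empty network",
            call. = FALSE)
  }
  tp <- tf_peak[tf_peak$peak_id %in% shared, , drop = FALSE]
  pg <- peak_gene[peak_gene$peak_id %in% shared, , drop = FALSE]
  edges <- merge(
    data.frame(tf_id = tp$tf_id, peak_id = tp$peak_id, r_tf_peak = tp$r,
               fdr_tf_peak = tp$efdr, tf_peak_direction = tp$direction,
               stringsAsFactors = FALSE),
    data.frame(peak_id = pg$peak_id, gene_id = pg$gene_id,
               r_peak_gene = pg$r, fdr_peak_gene = pg$fdr_bh,
               tss_distance = pg$tss_distance, stringsAsFactors = FALSE),
    by = "peak_id"
  )
  edges <- edges[, c("tf_id", "peak_id", "gene_id", "r_tf_peak",
                     "fdr_tf_peak", "tf_peak_direction", "r_peak_gene",
                     "fdr_peak_gene", "tss_distance")]
  edges <- edges[order(edges$tf_id, edges$peak_id, edges$gene_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  tf_tab <- data.frame(tf_id = sort(unique(edges$tf_id)),
                       stringsAsFactors = FALSE)
  if (!is.null(tf_classes)) {
    tf_tab <- merge(tf_tab, tf_classes[, c("tf_id", "class")],
                    by = "tf_id", all.x = TRUE)
  }
  peak_tab <- if (nrow(edges)) parse_peak_id(sort(unique(edges$peak_id)))
  else data.frame(chrom = character(), start = integer(),
                  end = integer(), name = character())
  gene_tab <- data.frame(gene_id = sort(unique(edges$gene_id)),
                         stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    gene_tab <- merge(gene_tab, genes, by = "gene_id", all.x = TRUE)
  }
  structure(list(edges = edges, tfs = tf_tab, peaks = peak_tab,
                 genes = gene_tab),
            class = "egrn")
}

#' @export
print.egrn <- function(x, ...) {
  cat(sprintf("egrn: %d TFs, %d peaks, %d genes, %d TF-peak-gene triplets\n",
              nrow(x$tfs), nrow(x$peaks), nrow(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Network summary statistics
#'
#' Node and edge counts, degree distributions, per-gene peak counts and the
#' fraction of network peaks linked to their closest annotated gene (by TSS
#' distance among all supplied genes, linked or not).
#'
#' @param egrn An `egrn`.
#' @param all_genes Gene annotation covering at least the network genes;
#'   used to determine each peak's closest gene.
#' @return A list of summary statistics.
#' @export
network_stats <- function(egrn, all_genes = NULL) {
  e <- egrn$edges
  tf_degree <- table(e$tf_id)
  gene_degree <- table(e$gene_id)
  peaks_per_gene <- tapply(e$peak_id, e$gene_id,
                           function(p) length(unique(p)))
  closest_fraction <- NA_real_
  if (!is.null(all_genes) && nrow(egrn$peaks) > 0) {
    frac <- vapply(seq_len(nrow(egrn$peaks)), function(i) {
      pk <- egrn$peaks[i, ]
      same <- all_genes[all_genes$chrom == pk$chrom, , drop = FALSE]
      if (nrow(same) == 0L) return(NA)
      inside <- same$tss >= pk$start & same$tss < pk$end
      d <- ifelse(inside, 0L,
                  pmin(abs(same$tss - pk$start), abs(same$tss - (pk$end - 1L))))
      closest <- same$gene_id[d == min(d)]
      linked <- unique(e$gene_id[e$peak_id == pk$name])
      as.numeric(any(closest %in% linked))
    }, numeric(1))
    closest_fraction <- mean(frac, na.rm = TRUE)
  }
  list(
    n_tfs = nrow(egrn$tfs),
    n_peaks = nrow(egrn$peaks),
    n_genes = nrow(egrn$genes),
    n_triplets = nrow(e),
    tf_degree = tf_degree,
    gene_degree = gene_degree,
    peaks_per_gene = peaks_per_gene,
    mean_peaks_per_gene = if (length(peaks_per_gene)) mean(peaks_per_gene)
    else NA_real_,
    closest_gene_fraction = closest_fraction
  )
}

# Project the tripartite network to an undirected igraph over TF, peak and
# gene nodes, one edge per component link; optionally weighted by |r|.
egrn_graph <- function(egrn, weighted = FALSE) {
  e <- egrn$edges
  tp <- unique(data.frame(from = paste0("tf:", e$tf_id),
                          to = paste0("peak:", e$peak_id),
                          w = abs(e$r_tf_peak), stringsAsFactors = FALSE))
  pg <- unique(data.frame(from = paste0("peak:", e$peak_id),
                          to = paste0("gene:", e$gene_id),
                          w = abs(e$r_peak_gene), stringsAsFactors = FALSE))
  el <- rbind(tp, pg)
  g <- igraph::graph_from_data_frame(el[, c("from", "to")], directed = FALSE)
  if (weighted) igraph::E(g)$weight <- el$w
  g
}

#' Detect communities in the network
#'
#' Runs a seeded community-detection algorithm on the unweighted undirected
#' tripartite projection of the network.
#'
#' @param egrn An `egrn`.
#' @param method One of `"louvain"` (default), `"walktrap"`,
#'   `"leading_eigen"`, `"fast_greedy"`, `"optimal"`.
#' @param seed Integer seed (community detection can be stochastic).
#' @param weighted Weight edges by |r| instead of treating them uniformly.
#' @return A list with `membership` (data.frame of node, type, community),
#'   `modularity` and `method`.
#' @export
detect_communities <- function(egrn, method = "louvain", seed = 1,
                               weighted = FALSE) {
  methods <- c(louvain = igraph::cluster_louvain,
               walktrap = igraph::cluster_walktrap,
               leading_eigen = igraph::cluster_leading_eigen,
               fast_greedy = igraph::cluster_fast_greedy,
               optimal = igraph::cluster_optimal)
  if (!method %in% names(methods)) {
    stop("unknown community method '", method, "'; supported: ",
         paste(names(methods), collapse = ", "), call. = FALSE)
  }
  g <- egrn_graph(egrn, weighted = weighted)
  comm <- with_seed(seed, methods[[method]](g))
  nodes <- igraph::V(g)$name
  membership <- data.frame(
    node = sub("^[a-z]+:", "", nodes),
    type = sub(":.*$", "", nodes),
    community = as.integer(igraph::membership(comm)),
    stringsAsFactors = FALSE
  )
  list(membership = membership,
       modularity = igraph::modularity(comm),
       method = method)
}

#' Extract TF regulons
#'
#' A TF's regulon is the set of distinct genes reachable through its
#' TF-peak-gene triplets.
#'
#' @param egrn An `egrn`.
#' @return Named list mapping each network TF to its gene set.
#' @export
extract_regulons <- function(egrn) {
  if (nrow(egrn$edges) == 0L) return(stats::setNames(list(), character()))
  lapply(split(egrn$edges$gene_id, egrn$edges$tf_id), unique)
}

#' Apply a random gene-label bijection to a TF-gene edge list
#'
#' @param edges Data.frame with `tf` and `gene` columns.
#' @param seed Integer seed.
#' @return Edge list with genes relabelled; TF degrees, gene degrees and
#'   edge count are preserved exactly.
#' @export
permute_tf_gene_edges <- function(edges, seed) {
  genes <- unique(edges$gene)
  mapping <- with_seed(seed, stats::setNames(sample(genes), genes))
  out <- edges
  out$gene <- unname(mapping[edges$gene])
  attr(out, "gene_mapping") <- mapping
  out
}

#' Degree-preserving permutation of the network's gene labels
#'
#' Applies a seeded random bijection to gene identities, so the permuted
#' network has the same TF degrees, gene degrees and edge count as the
#' original, with only the TF-gene (and peak-gene) assignments randomised.
#'
#' @param egrn An `egrn` with >= 1 gene.
#' @param seed Integer seed.
#' @return The permuted `egrn`; the bijection is stored in attribute
#'   `gene_mapping`.
#' @export
permute_egrn <- function(egrn, seed) {
  genes <- unique(egrn$edges$gene_id)
  if (length(genes) <= 1L) return(egrn)
  mapping <- with_seed(seed, stats::setNames(sample(genes), genes))
  out <- egrn
  out$edges$gene_id <- unname(mapping[egrn$edges$gene_id])
  out$genes$gene_id <- unname(mapping[egrn$genes$gene_id])
  attr(out, "gene_mapping") <- mapping
  out
}

#' Bipartite TF-gene projection of a network
#'
#' @param egrn An `egrn`.
#' @return Data.frame with unique `tf`, `gene` pairs.
#' @export
as_tf_gene_network <- function(egrn) {
  el <- unique(data.frame(tf = egrn$edges$tf_id, gene = egrn$edges$gene_id,
                          stringsAsFactors = FALSE))
  rownames(el) <- NULL
  el
}

#' Hypergeometric enrichment of a gene set in network communities or regulons
#'
#' Generic one-sided hypergeometric (equivalently Fisher) enrichment of a
#' user-supplied gene set within each queried gene collection.
#'
#' @param collections Named list of gene sets (e.g. regulons or community
#'   gene memberships).
#' @param hit_set Gene set of interest.
#' @param universe Background gene universe.
#' @return Data.frame with per-collection overlap, expected overlap and
#'   hypergeometric p-value.
#' @export
gene_set_enrichment <- function(collections, hit_set, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  hit_set <- intersect(hit_set, universe)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(collections[[nm]], universe)
    q <- length(intersect(set, hit_set))
    p <- stats::phyper(q - 1, length(hit_set),
                       length(universe) - length(hit_set), length(set),
                       lower.tail = FALSE)
    data.frame(collection = nm, size = length(set), overlap = q,
               expected = length(set) * length(hit_set) / length(universe),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
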