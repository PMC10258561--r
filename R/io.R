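#' Read genomic intervals from a BED file
#'
#' BED3+ with 0-based half-open coordinates. The name (column 4) and strand
#' (column 6) are preserved when present.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, in file order. Empty files yield a zero-row data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 3L)) {
    stop("BED line ", which(nf < 3L)[1], ": fewer than 3 fields", call. = FALSE)
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3L)))
  if (any(is.na(start) | is.na(end))) {
    stop("BED line ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinates", call. = FALSE)
  }
  bad <- start >= end
  if (any(bad)) {
    stop("BED line ", which(bad)[1], ": start >= end", call. = FALSE)
  }
  if (any(start < 0)) {
    stop("BED line ", which(start < 0)[1], ": negative start", call. = FALSE)
  }
  name <- ifelse(nf >= 4L, vapply(parts, function(p) p[4], character(1)), "")
  strand <- ifelse(nf >= 6L, vapply(parts, function(p) p[6], character(1)), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  data.frame(chrom = chrom, start = start, end = end, name = name,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write genomic intervals to a BED file
#'
#' @param intervals A data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `strand` columns (0-based half-open).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   intervals$name %||% ".",
                   0L,
                   intervals$strand %||% ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-TF binding-site predictions from a directory of BED files
#'
#' One BED file per transcription factor; the TF identifier is the file name
#' without the `.bed` extension.
#'
#' @param dir Directory containing `<TF>.bed` files.
#' @return A named list of interval data.frames (a TFBS collection).
#' @export
read_tfbs_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (length(files) == 0L) stop("no .bed files found in ", dir, call. = FALSE)
  tfbs <- lapply(files, read_bed)
  names(tfbs) <- sub("\\.bed$", "", basename(files))
  tfbs
}

#' Write a TFBS collection to a directory of BED files
#'
#' @param tfbs Named list of interval data.frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_tfbs_dir <- function(tfbs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tf in names(tfbs)) {
    write_bed(tfbs[[tf]], file.path(dir, paste0(tf, ".bed")))
  }
  invisible(dir)
}

#' Read a gene annotation table
#'
#' A 5-column TSV with header `gene_id`, `chrom`, `strand`, `tss`,
#' `gene_type`. `tss` is the strand-aware 5' position in 0-based coordinates.
#' Optional `start`/`end` columns (gene body, 0-based half-open) are kept if
#' present. Genes with missing TSS are dropped with a message.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of gene annotation.
#' @export
read_gene_annotation <- function(path) {
  g <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "strand", "tss", "gene_type")
  missing_cols <- setdiff(required, names(g))
  if (length(missing_cols)) {
    stop("gene annotation missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(g$gene_id)) {
    stop("duplicate gene_id: ", g$gene_id[duplicated(g$gene_id)][1],
         call. = FALSE)
  }
  drop <- is.na(g$tss) | is.na(g$chrom) | g$chrom == ""
  if (any(drop)) {
    message(sum(drop), " gene(s) dropped: missing TSS or chromosome")
    g <- g[!drop, , drop = FALSE]
  }
  if (any(g$tss < 0)) stop("negative TSS position", call. = FALSE)
  g
}

#' Write a gene annotation table
#' @param genes Gene annotation data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert GTF-lite gene records to the package's gene annotation
#'
#' Reads a tab-separated GTF-like file and extracts `gene` feature rows. The
#' TSS is the strand-aware 5' end converted to 0-based coordinates (GTF is
#' 1-based closed): `start - 1` on `+`, `end - 1` on `-`. `gene_id` and
#' `gene_type`/`gene_biotype` are taken from the attribute field.
#'
#' @param path Path to a GTF file (uncompressed).
#' @return A gene annotation data.frame.
#' @export
gtf_to_gene_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p) length(p) >= 9 && p[3] == "gene", logical(1))
  parts <- parts[keep]
  if (length(parts) == 0L) stop("no gene records found in ", path, call. = FALSE)
  attr_field <- vapply(parts, `[`, character(1), 9L)
  get_attr <- function(key) {
    m <- regmatches(attr_field,
                    regexec(paste0(key, "[ =]+\"?([^\";]+)\"?"), attr_field))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  gene_id <- get_attr("gene_id")
  gene_type <- get_attr("gene_type")
  biotype <- get_attr("gene_biotype")
  gene_type[is.na(gene_type)] <- biotype[is.na(gene_type)]
  strand <- vapply(parts, `[`, character(1), 7L)
  start1 <- as.integer(vapply(parts, `[`, character(1), 4L))
  end1 <- as.integer(vapply(parts, `[`, character(1), 5L))
  data.frame(
    gene_id = gene_id,
    chrom = vapply(parts, `[`, character(1), 1L),
    strand = strand,
    tss = ifelse(strand == "-", end1 - 1L, start1 - 1L),
    gene_type = ifelse(is.na(gene_type), "unknown", gene_type),
    start = start1 - 1L,
    end = end1,
    stringsAsFactors = FALSE
  )
}

#' Read TAD intervals from a BED file
#'
#' @param path Path to a BED file of topologically associating domains.
#' @param merge_overlapping Merge overlapping domains per chromosome.
#' @return A data.frame of intervals; if merged, non-overlapping per
#'   chromosome.
#' @export
read_tads <- function(path, merge_overlapping = FALSE) {
  tads <- read_bed(path)
  if (merge_overlapping && nrow(tads) > 1) {
    gr <- GenomicRanges::reduce(intervals_to_granges(tads))
    tads <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      name = sprintf("tad_%d", seq_along(gr)),
      strand = ".",
      stringsAsFactors = FALSE
    )
  }
  attr(tads, "merge_overlapping") <- merge_overlapping
  tads
}

.edge_table_cols <- c("tf_id", "peak_id", "gene_id", "r_tf_peak", "fdr_tf_peak",
                      "tf_peak_direction", "r_peak_gene", "fdr_peak_gene",
                      "tss_distance")

#' Write a tripartite network edge table
#'
#' One row per TF-peak-gene triplet with both component edges' statistics;
#' round-trips losslessly through [read_edge_table()].
#'
#' @param egrn An `egrn` object (see [assemble_egrn()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_table <- function(egrn, path) {
  stopifnot(inherits(egrn, "egrn"))
  df <- egrn$edges[, .edge_table_cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tripartite network edge table
#'
#' @param path Path written by [write_edge_table()].
#' @return A data.frame of TF-peak-gene triplets.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(tf_id = "character",
                                         peak_id = "character",
                                         gene_id = "character"))
  missing_cols <- setdiff(.edge_table_cols, names(df))
  if (length(missing_cols)) {
    stop("edge table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Default run configuration
#'
#' All pipeline thresholds with their default values: 250 kb peak-gene
#' window, TF-peak FDR 0.2, peak-gene FDR 0.1, minimum mean count 5, and the
#' gene types retained in the network.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    window = 250000L,
    tf_peak_fdr = 0.2,
    peak_gene_fdr = 0.1,
    min_mean_count = 5,
    log_counts = TRUE,
    gene_types = c("protein_coding", "lincRNA"),
    anchor = "tss",
    positive_only = TRUE,
    classify_stringency = 0.1,
    classify_alpha = 0.05
  )
}

#' Read a run configuration file (JSON or YAML)
#'
#' Unspecified keys fall back to [default_config()]; unknown keys raise an
#' error.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configuration requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(base, cfg)
}
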