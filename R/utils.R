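#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Format peak identifiers from coordinates
#'
#' Peaks are identified throughout the package by the canonical string
#' `"chrom:start-end"` with 0-based half-open coordinates, matching common
#' ATAC consensus-peak naming.
#'
#' @param chrom Chromosome names.
#' @param start 0-based start positions.
#' @param end End positions (exclusive).
#' @return Character vector of peak IDs.
#' @export
peak_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse canonical peak identifiers
#'
#' @param ids Character vector of `"chrom:start-end"` identifiers.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `name` (the input ID).
#' @export
parse_peak_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("unparseable peak ID(s): ", paste(utils::head(ids[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  chrom <- vapply(m, `[`, character(1), 2L)
  start <- as.integer(vapply(m, `[`, character(1), 3L))
  end <- as.integer(vapply(m, `[`, character(1), 4L))
  if (any(end <= start)) {
    stop("peak ID with end <= start: ",
         paste(utils::head(ids[end <= start], 5), collapse = ", "), call. = FALSE)
  }
  data.frame(chrom = chrom, start = start, end = end, name = ids,
             stringsAsFactors = FALSE)
}

# Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
# Overlap semantics of >=1 bp are preserved by the shift.
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
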