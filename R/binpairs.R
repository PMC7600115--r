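#' Bin-pair count table
#'
#' Counts of Hi-C contacts per pair of genomic bins (conventionally 5 kb
#' for differential-interaction testing), across samples. Anchors are
#' bin start positions in bp with `anchor1 <= anchor2`; library sizes
#' default to column sums at construction.
#'
#' @param pairs `data.frame` with columns `chrom`, `anchor1`, `anchor2`.
#' @param counts Numeric matrix of non-negative counts, one row per bin
#'   pair, one column per sample.
#' @param lib_sizes Optional per-sample library sizes (> 0).
#' @param bin_size Anchor bin size in bp.
#' @return Object of class `bin_pair_table`: list with `pairs`,
#'   `counts`, `lib_sizes`, `bin_size`.
#' @export
bin_pair_table <- function(pairs, counts, lib_sizes = NULL,
                           bin_size = 5000) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(pairs),
            all(c("chrom", "anchor1", "anchor2") %in% names(pairs)),
            nrow(pairs) == nrow(counts))
  if (any(pairs$anchor1 > pairs$anchor2)) {
    stop("`anchor1` must be <= `anchor2`")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  structure(
    list(pairs = pairs[, c("chrom", "anchor1", "anchor2")],
         counts = counts, lib_sizes = lib_sizes,
         bin_size = as.numeric(bin_size)),
    class = "bin_pair_table"
  )
}

#' @export
print.bin_pair_table <- function(x, ...) {
  cat(sprintf("bin_pair_table: %d bin pairs x %d samples @ %s bp\n",
              nrow(x$counts), ncol(x$counts),
              format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' @export
dim.bin_pair_table <- function(x) dim(x$counts)

#' Per-cell log2 counts per million
#'
#' `log2((y + 0.5) / (N + 1) * 1e6)` with a prior count of 0.5 and
#' library sizes incremented by 1, the continuity correction under which
#' the abundance filter below is exact.
#'
#' @param table A [bin_pair_table()].
#' @return Matrix of logCPM values, same shape as the counts.
#' @export
ave_log_cpm <- function(table) {
  stopifnot(inherits(table, "bin_pair_table"))
  y <- table$counts
  N <- rep(table$lib_sizes, each = nrow(y))
  matrix(log2((y + 0.5) / (N + 1) * 1e6), nrow(y), ncol(y))
}

#' Filter low-abundance bin pairs
#'
#' Retains bin pairs whose average logCPM across samples exceeds
#' `min_avg_logcpm` (default 0, i.e. roughly one read per million).
#' Library sizes are kept as computed on the unfiltered table.
#'
#' @param table A [bin_pair_table()].
#' @param min_avg_logcpm Retention threshold on the row-mean logCPM.
#' @return The filtered [bin_pair_table()].
#' @export
filter_low_abundance <- function(table, min_avg_logcpm = 0) {
  stopifnot(inherits(table, "bin_pair_table"))
  keep <- rowMeans(ave_log_cpm(table)) > min_avg_logcpm
  out <- table
  out$pairs <- table$pairs[keep, , drop = FALSE]
  out$counts <- table$counts[keep, , drop = FALSE]
  rownames(out$pairs) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  attr(out, "kept") <- which(keep)
  out
}
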