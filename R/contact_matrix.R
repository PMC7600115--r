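#' Per-chromosome contact matrix
#'
#' A symmetric, non-negative matrix of Hi-C contact counts between
#' fixed-size bins of one chromosome. Bins are 0-based half-open;
#' `counts[i + 1, j + 1]` holds the contacts between bins `i` and `j`.
#' Balancing weights, when present, satisfy
#' `balanced[i, j] = counts[i, j] / (w[i] * w[j])` (see
#' [ice_normalize()]).
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param counts Square symmetric numeric matrix of non-negative counts.
#' @param weights Optional positive balancing weight per bin (`NA` on
#'   masked, all-zero bins).
#' @param balanced Logical; `TRUE` if `counts` already holds balanced
#'   values.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, counts, weights = NULL,
                           balanced = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("`counts` must be square")
  if (any(counts < 0, na.rm = TRUE)) stop("`counts` must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("`counts` must be symmetric")
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(counts)) {
      stop("`weights` must have one entry per bin")
    }
    if (any(weights[!is.na(weights)] <= 0)) {
      stop("`weights` must be strictly positive where defined")
    }
  }
  structure(
    list(chrom = as.character(chrom), bin_size = as.numeric(bin_size),
         counts = unname(counts), weights = weights,
         balanced = isTRUE(balanced)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %s, %d bins @ %s bp, total (upper tri) %.4g%s\n",
    x$chrom, nrow(x$counts), format(x$bin_size, big.mark = ","),
    sum(x$counts[upper.tri(x$counts, diag = TRUE)]),
    if (x$balanced) ", balanced" else ""))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

# Sum over the upper triangle, diagonal counted once: the number of
# distinct contacts represented by a symmetric count matrix.
upper_tri_sum <- function(cm) {
  m <- if (inherits(cm, "contact_matrix")) cm$counts else cm
  sum(m[upper.tri(m, diag = TRUE)])
}
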