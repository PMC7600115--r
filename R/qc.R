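#' Replicate correlation between two contact matrices
#'
#' Pearson correlation of `log2(count + 1)` over bin pairs `i <= j`
#' where at least one of the two matrices is non-zero. Computed on raw
#' (unbalanced) counts, conventionally at 500 kb resolution, to judge
#' replicate reproducibility.
#'
#' @param mat_a,mat_b [contact_matrix()] objects on the same chromosome
#'   at the same bin size.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
replicate_correlation <- function(mat_a, mat_b) {
  stopifnot(inherits(mat_a, "contact_matrix"),
            inherits(mat_b, "contact_matrix"))
  if (mat_a$chrom != mat_b$chrom || mat_a$bin_size != mat_b$bin_size ||
      nrow(mat_a$counts) != nrow(mat_b$counts)) {
    stop("matrices must share chromosome, bin size and dimension")
  }
  up <- upper.tri(mat_a$counts, diag = TRUE)
  a <- mat_a$counts[up]
  b <- mat_b$counts[up]
  use <- a > 0 | b > 0
  if (sum(use) < 3) stop("fewer than 3 usable bin pairs")
  cor(log2(a[use] + 1), log2(b[use] + 1))
}

#' Expected contact count by distance
#'
#' Mean count over all bin pairs at each separation, the empirical
#' distance-decay profile used both for QC and as the background
#' expectation in promoter-pair calling.
#'
#' @param cm A [contact_matrix()].
#' @return `data.frame` with columns `distance` (in bins, 0-based),
#'   `expected` (mean count per pair) and `n_pairs`.
#' @export
expected_by_distance <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$counts
  n <- nrow(m)
  if (n == 0) stop("matrix is empty")
  d <- 0:(n - 1)
  expct <- vapply(d, function(dd) {
    i <- seq_len(n - dd)
    mean(m[cbind(i, i + dd)])
  }, numeric(1))
  data.frame(distance = d, expected = expct, n_pairs = n - d)
}
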