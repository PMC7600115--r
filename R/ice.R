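#' Iterative correction (ICE) of a contact matrix
#'
#' Removes multiplicative bin biases by the square-root variant of
#' iterative correction: at each pass the working matrix is divided by
#' the outer product of the square roots of its (mean-normalized) row
#' sums, until the non-masked row sums are uniform to within `tol`
#' (coefficient of variation). Bins whose rows are entirely zero are
#' masked and carry `NA` weights. The accumulated per-bin weights `w`
#' satisfy `balanced[i, j] = counts[i, j] / (w[i] * w[j])` up to a global
#' scale.
#'
#' @param cm A [contact_matrix()] of raw counts.
#' @param max_iter Maximum number of correction passes.
#' @param tol Convergence tolerance on the coefficient of variation of
#'   non-masked row sums.
#' @return A [contact_matrix()] with balanced counts, `weights` set, and
#'   attributes `converged` (logical) and `iterations`.
#' @examples
#' cm <- contact_matrix("chr1", 1000, matrix(c(0, 4, 4, 0), 2))
#' ice_normalize(cm)$weights
#' @export
ice_normalize <- function(cm, max_iter = 200L, tol = 1e-5) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$counts
  n <- nrow(m)
  mask <- rowSums(m) == 0
  w <- rep(1, n)
  converged <- FALSE
  it <- 0L
  if (all(mask)) {
    out <- contact_matrix(cm$chrom, cm$bin_size, m,
                          weights = rep(NA_real_, n), balanced = TRUE)
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    return(out)
  }
  keep <- !mask
  while (it < max_iter) {
    it <- it + 1L
    rs <- rowSums(m)[keep]
    cv <- sd(rs) / mean(rs)
    if (is.na(cv) || cv < tol) {
      converged <- TRUE
      break
    }
    dw <- rep(1, n)
    dw[keep] <- sqrt(rs / mean(rs))
    m <- m / outer(dw, dw)
    w <- w * dw
  }
  if (!converged) {
    # check once more after the final pass
    rs <- rowSums(m)[keep]
    converged <- isTRUE(sd(rs) / mean(rs) < tol)
    if (!converged) {
      warning("ICE did not converge in ", max_iter, " iterations")
    }
  }
  w[mask] <- NA_real_
  out <- contact_matrix(cm$chrom, cm$bin_size, m, weights = w,
                        balanced = TRUE)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}
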