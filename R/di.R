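#' Directionality index of a contact matrix
#'
#' For each bin `i`, let `A` be the sum of contacts between `i` and bins
#' strictly upstream within the window, and `B` the sum to bins strictly
#' downstream. With `E = (A + B) / 2` the directionality index is
#'
#' \deqn{DI = \mathrm{sign}(B - A)\left(\frac{(A-E)^2}{E} +
#'        \frac{(B-E)^2}{E}\right)}
#'
#' a chi-square-like measure of biased interaction whose sign indicates
#' the bias direction (positive = downstream-biased, as at domain
#' starts). `DI = 0` where `A = B`; bins with `A + B = 0` are masked
#' (`NA`). The window is truncated at chromosome ends. The conventional
#' parameters are 40 kb bins with a 2 Mb window.
#'
#' @param cm A [contact_matrix()] (raw counts by default in this
#'   pipeline; balanced input is accepted and recorded by the caller).
#' @param window Window size in bp on each side (>= 2 bins).
#' @return `data.frame` with columns `chrom`, `bin` (0-based), `start`
#'   (bp), `A`, `B`, `di`; attributes `window` and `bin_size`.
#' @examples
#' m <- matrix(1, 6, 6)
#' di <- directionality_index(contact_matrix("chr1", 40000, m), 2e6)
#' all(di$di == 0)  # symmetric matrix has no directional bias
#' @export
directionality_index <- function(cm, window = 2e6) {
  stopifnot(inherits(cm, "contact_matrix"))
  w <- floor(window / cm$bin_size)
  if (w < 2) stop("`window` must span at least 2 bins")
  m <- cm$counts
  n <- nrow(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))  # cs[i, j+1] = sum m[i, 1..j]
  i <- seq_len(n)
  lo <- pmax(i - w, 1)
  hi <- pmin(i + w, n)
  A <- cs[cbind(i, i)] - cs[cbind(i, lo)]          # bins (i-w .. i-1)
  B <- cs[cbind(i, hi + 1)] - cs[cbind(i, i + 1)]  # bins (i+1 .. i+w)
  E <- (A + B) / 2
  di <- rep(NA_real_, n)
  active <- A + B > 0
  eq <- active & A == B
  di[eq] <- 0
  ne <- active & A != B
  di[ne] <- sign(B[ne] - A[ne]) *
    ((A[ne] - E[ne])^2 / E[ne] + (B[ne] - E[ne])^2 / E[ne])
  out <- data.frame(chrom = cm$chrom, bin = i - 1L,
                    start = (i - 1) * cm$bin_size, A = A, B = B, di = di)
  attr(out, "window") <- window
  attr(out, "bin_size") <- cm$bin_size
  out
}
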