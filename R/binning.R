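#' Bin cis contacts into per-chromosome contact matrices
#'
#' Retains cis pairs (same chromosome, separation at or above
#' `self_cutoff`) and accumulates them into symmetric count matrices at
#' `bin_size` resolution. Positions are 1-based, so position `pos` falls
#' in 0-based bin `floor((pos - 1) / bin_size)`; a position exactly at a
#' bin-size multiple belongs to the lower bin (half-open convention).
#' The upper-triangle sum (diagonal counted once) of each matrix equals
#' the number of retained cis records on that chromosome.
#'
#' @param pairs `data.frame` of pair records (see [read_pairs()]).
#' @param layout A [genome_layout()].
#' @param bin_size Bin size in bp (> 0); defaults to the layout's.
#' @param self_cutoff Separation cutoff passed to [classify_pairs()].
#' @return Named list of [contact_matrix()] objects, one per layout
#'   chromosome (all-zero matrices for chromosomes without records).
#' @export
bin_contacts <- function(pairs, layout, bin_size = layout$bin_size,
                         self_cutoff = 20000) {
  stopifnot(inherits(layout, "genome_layout"))
  if (bin_size <= 0) stop("`bin_size` must be positive")
  cls <- classify_pairs(pairs, self_cutoff)
  cis <- pairs[cls == "cis", , drop = FALSE]
  out <- lapply(layout$chroms, function(ch) {
    nb <- as.integer(ceiling(layout$lengths[[ch]] / bin_size))
    m <- matrix(0, nb, nb)
    p <- cis[cis$chrom1 == ch, , drop = FALSE]
    if (nrow(p) > 0) {
      i <- floor((p$pos1 - 1) / bin_size)
      j <- floor((p$pos2 - 1) / bin_size)
      lo <- pmin(i, j)
      hi <- pmax(i, j)
      tab <- table(lo * nb + hi)
      idx <- as.numeric(names(tab))
      li <- idx %/% nb + 1
      hj <- idx %% nb + 1
      m[cbind(li, hj)] <- as.numeric(tab)
      m <- m + t(m) - diag(diag(m))
    }
    contact_matrix(ch, bin_size, m)
  })
  names(out) <- layout$chroms
  out
}
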