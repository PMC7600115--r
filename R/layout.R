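#' Genome layout
#'
#' Describes the chromosomes an analysis runs over: names, lengths in bp
#' and the working bin size. Bin indices throughout the package are
#' 0-based half-open at this bin size, so chromosome `c` has
#' `ceiling(length(c) / bin_size)` bins and a position `pos` (1-based, as
#' in `.pairs` files) falls in bin `floor((pos - 1) / bin_size)`.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Numeric vector of chromosome lengths in bp (> 0), one
#'   per chromosome.
#' @param bin_size Bin size in bp (> 0). Default 40000 (40 kb), the
#'   resolution used for TAD calling.
#' @return An object of class `genome_layout`.
#' @examples
#' layout <- genome_layout("chr1", 2e6, bin_size = 40000)
#' n_bins(layout, "chr1")
#' @export
genome_layout <- function(chroms, lengths, bin_size = 40000) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (length(lengths) != length(chroms)) {
    stop("`lengths` must have one entry per chromosome")
  }
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  bin_size <- as.numeric(bin_size)
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0) {
    stop("`bin_size` must be a single positive number")
  }
  structure(
    list(chroms = chroms, lengths = setNames(lengths, chroms),
         bin_size = bin_size),
    class = "genome_layout"
  )
}

#' Number of bins on a chromosome
#'
#' @param layout A [genome_layout()].
#' @param chrom Chromosome name; if missing, all chromosomes.
#' @return Integer vector of bin counts (`ceiling(length / bin_size)`).
#' @export
n_bins <- function(layout, chrom) {
  stopifnot(inherits(layout, "genome_layout"))
  len <- if (missing(chrom)) layout$lengths else {
    if (!all(chrom %in% layout$chroms)) stop("unknown chromosome")
    layout$lengths[chrom]
  }
  as.integer(ceiling(len / layout$bin_size))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chroms), "chromosome(s), bin size",
      format(x$bin_size, big.mark = ","), "bp\n")
  for (ch in x$chroms) {
    cat(sprintf("  %s  %s bp  (%d bins)\n", ch,
                format(x$lengths[[ch]], big.mark = ","),
                n_bins(x, ch)))
  }
  invisible(x)
}
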