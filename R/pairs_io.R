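#' Read a valid-pairs file
#'
#' Parses text `.pairs`-convention files (columns readID, chrom1, pos1,
#' chrom2, pos2, strand1, strand2; positions 1-based; `#`-prefixed header
#' lines allowed). Malformed lines (wrong field count, non-numeric or
#' non-positive positions, bad strand) are counted and dropped; records
#' on chromosomes absent from `layout` are skipped with a warning. If
#' more than 10% of data lines are malformed the file is rejected.
#'
#' @param path Path to a pairs file.
#' @param layout A [genome_layout()]; records must lie on its
#'   chromosomes.
#' @return `data.frame` with columns `read_id`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `strand1`, `strand2`, with attributes
#'   `n_malformed` and `n_skipped_chrom`.
#' @export
read_pairs <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!file.exists(path)) stop("pairs file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(read_id = character(0), chrom1 = character(0),
                      pos1 = numeric(0), chrom2 = character(0),
                      pos2 = numeric(0), strand1 = character(0),
                      strand2 = character(0))
    attr(out, "n_malformed") <- 0L
    attr(out, "n_skipped_chrom") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf == 7L
  mat <- matrix(unlist(fields[ok], use.names = FALSE), ncol = 7L,
                byrow = TRUE)
  pos1 <- suppressWarnings(as.numeric(mat[, 3]))
  pos2 <- suppressWarnings(as.numeric(mat[, 5]))
  good <- !is.na(pos1) & !is.na(pos2) & pos1 >= 1 & pos2 >= 1 &
    mat[, 6] %in% c("+", "-") & mat[, 7] %in% c("+", "-")
  n_malformed <- sum(!ok) + sum(!good)
  if (n_malformed > 0.1 * length(lines)) {
    stop(sprintf("%d of %d lines malformed (> 10%%); refusing to parse",
                 n_malformed, length(lines)))
  }
  out <- data.frame(read_id = mat[good, 1], chrom1 = mat[good, 2],
                    pos1 = pos1[good], chrom2 = mat[good, 4],
                    pos2 = pos2[good], strand1 = mat[good, 6],
                    strand2 = mat[good, 7])
  known <- out$chrom1 %in% layout$chroms & out$chrom2 %in% layout$chroms
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(n_skipped, " record(s) on chromosomes absent from the layout",
            " were skipped")
    out <- out[known, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_malformed") <- as.integer(n_malformed)
  attr(out, "n_skipped_chrom") <- as.integer(n_skipped)
  out
}

#' Classify read pairs as self, cis or trans
#'
#' A pair is `trans` iff its ends map to different chromosomes; `self`
#' iff same chromosome with separation `|pos2 - pos1|` below
#' `self_cutoff` (dominated by self-ligation and re-ligation artefacts);
#' `cis` otherwise.
#'
#' @param pairs `data.frame` of pair records (see [read_pairs()]).
#' @param self_cutoff Separation cutoff in bp (> 0). Default 20 kb.
#' @return Factor with levels `self`, `cis`, `trans`.
#' @export
classify_pairs <- function(pairs, self_cutoff = 20000) {
  if (self_cutoff <= 0) stop("`self_cutoff` must be positive")
  cls <- ifelse(pairs$chrom1 != pairs$chrom2, "trans",
                ifelse(abs(pairs$pos2 - pairs$pos1) < self_cutoff,
                       "self", "cis"))
  factor(cls, levels = c("self", "cis", "trans"))
}

#' QC summary of a pairs set
#'
#' Fractions of self/cis/trans pairs (summing to one over classified
#' pairs) and the total count, as inspected when judging Hi-C library
#' quality.
#'
#' @inheritParams classify_pairs
#' @return List with `fractions` (named numeric, sums to 1), `counts`
#'   and `total`.
#' @export
qc_summary <- function(pairs, self_cutoff = 20000) {
  cls <- classify_pairs(pairs, self_cutoff)
  counts <- table(cls)
  total <- sum(counts)
  fr <- if (total > 0) as.numeric(counts) / total else rep(NA_real_, 3)
  list(fractions = setNames(fr, names(counts)),
       counts = setNames(as.integer(counts), names(counts)),
       total = as.integer(total))
}
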