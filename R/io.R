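# Plain-text exporters and importers for the standard interval and
# matrix formats used by the pipeline. All exported intervals follow the
# BED convention (0-based half-open).

#' Write intervals as BED
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[, c("chrom", "start", "end")]
  if (!is.null(intervals$name)) df$name <- intervals$name
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a DI track as bedGraph
#'
#' @param di DI track from [directionality_index()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(di, path) {
  bs <- attr(di, "bin_size")
  df <- data.frame(chrom = di$chrom, start = di$start,
                   end = di$start + bs,
                   value = ifelse(is.na(di$di), 0, di$di))
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write anchor pairs as BEDPE
#'
#' @param pairs `data.frame` with `chrom`, `anchor1`, `anchor2` plus any
#'   extra columns (written after the six BEDPE coordinates).
#' @param path Output file.
#' @param bin_size Anchor width in bp.
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(pairs, path, bin_size = 5000) {
  df <- data.frame(chrom1 = pairs$chrom, start1 = pairs$anchor1,
                   end1 = pairs$anchor1 + bin_size,
                   chrom2 = pairs$chrom, start2 = pairs$anchor2,
                   end2 = pairs$anchor2 + bin_size)
  extra <- setdiff(names(pairs), c("chrom", "anchor1", "anchor2"))
  for (cc in extra) df[[cc]] <- pairs[[cc]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write a contact matrix as a bin-pair triplet TSV
#'
#' Columns: chrom, bin1_start, bin2_start, count; only the non-zero
#' upper triangle (diagonal included) is written.
#'
#' @param cm A [contact_matrix()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$counts
  up <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(chrom = cm$chrom,
                   bin1_start = (up[, 1] - 1) * cm$bin_size,
                   bin2_start = (up[, 2] - 1) * cm$bin_size,
                   count = m[up])
  df <- df[order(df$bin1_start, df$bin2_start), ]
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a contact matrix from a bin-pair triplet TSV
#'
#' @param path File written by [write_contact_matrix()].
#' @param layout A [genome_layout()]; the matrix is dimensioned from it.
#' @param bin_size Bin size in bp of the stored matrix.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, layout, bin_size) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  ch <- unique(df$chrom)
  if (length(ch) != 1) stop("triplet file must cover one chromosome")
  nb <- as.integer(ceiling(layout$lengths[[ch]] / bin_size))
  m <- matrix(0, nb, nb)
  i <- df$bin1_start / bin_size + 1
  j <- df$bin2_start / bin_size + 1
  m[cbind(i, j)] <- df$count
  m[cbind(j, i)] <- df$count
  contact_matrix(ch, bin_size, m)
}
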