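#' Call TADs from a bias-state path
#'
#' A domain opens at the first bin of a maximal run of at least `k`
#' consecutive downstream-biased (`D`) states and closes at the last bin
#' of the next maximal run of at least `k` consecutive upstream-biased
#' (`U`) states. No-bias bins (and masked bins) between the two runs are
#' interior; unpaired runs produce no domain. Output domains are
#' bin-aligned, half-open, sorted and non-overlapping by construction,
#' and never cross chromosome ends.
#'
#' @param path A `bias_path` from [fit_bias_hmm()].
#' @param layout A [genome_layout()] providing chromosome lengths.
#' @param k Minimum run length interpreting "consecutive" (default 2).
#' @return `data.frame` with columns `chrom`, `start`, `end` (bp,
#'   0-based half-open).
#' @export
call_tads <- function(path, layout, k = 2L) {
  stopifnot(inherits(path, "bias_path"), inherits(layout, "genome_layout"))
  bs <- layout$bin_size
  out <- list()
  for (ch in names(path$states)) {
    s <- as.character(path$states[[ch]])
    s[is.na(s)] <- "N"
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    qual <- which(r$values %in% c("D", "U") & r$lengths >= k)
    open <- NA_integer_
    for (q in qual) {
      if (r$values[q] == "D") {
        if (is.na(open)) open <- starts[q]
      } else if (!is.na(open)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start = (open - 1L) * bs,
          end = min(ends[q] * bs, layout$lengths[[ch]]))
        open <- NA_integer_
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# For each interval of `tx`, the index in `ty` of the maximally
# overlapping interval (ties broken toward larger fraction of the ty
# interval, then leftmost ty start), plus the overlap width. NA where
# nothing overlaps. Intervals are bp half-open data.frames with
# chrom/start/end.
.best_partner <- function(tx, ty) {
  partner <- rep(NA_integer_, nrow(tx))
  ovl <- rep(0, nrow(tx))
  for (ch in unique(tx$chrom)) {
    xi <- which(tx$chrom == ch)
    yi <- which(ty$chrom == ch)
    if (length(yi) == 0) next
    qx <- IRanges::IRanges(start = tx$start[xi] + 1, end = tx$end[xi])
    qy <- IRanges::IRanges(start = ty$start[yi] + 1, end = ty$end[yi])
    h <- IRanges::findOverlaps(qx, qy)
    if (length(h) == 0) next
    qh <- S4Vectors::queryHits(h)
    sh <- S4Vectors::subjectHits(h)
    w <- IRanges::width(IRanges::pintersect(qx[qh], qy[sh]))
    frac_y <- w / IRanges::width(qy)[sh]
    # order hits so the preferred partner comes first per query
    o <- order(qh, -w, -frac_y, ty$start[yi][sh])
    first <- !duplicated(qh[o])
    partner[xi[qh[o][first]]] <- yi[sh[o][first]]
    ovl[xi[qh[o][first]]] <- w[o][first]
  }
  list(partner = partner, overlap = ovl)
}

#' Maximally overlapping TAD pairs between two TAD sets
#'
#' For every domain in `tads_x`, finds the domain in `tads_y` with the
#' largest overlap length (ties broken toward the candidate with the
#' larger fraction of its own length covered, then the leftmost), and
#' flags pairs that point at each other from both sides as reciprocal.
#'
#' @param tads_x,tads_y Sorted, non-overlapping TAD `data.frame`s
#'   (`chrom`, `start`, `end`; bp half-open), e.g. from [call_tads()].
#' @return List with `pairs` — one row per `tads_x` domain with any
#'   overlap (`chrom`, `start_x`, `end_x`, `start_y`, `end_y`,
#'   `overlap_bp`, `frac_x`, `frac_y`, `reciprocal`) — and counts
#'   `n_x`, `n_y`, `n_x_overlapped`, `n_y_overlapped`, `n_reciprocal`.
#' @export
max_overlap_pairs <- function(tads_x, tads_y) {
  fx <- .best_partner(tads_x, tads_y)
  fy <- .best_partner(tads_y, tads_x)
  has <- which(!is.na(fx$partner))
  recip <- vapply(has, function(i) {
    j <- fx$partner[i]
    !is.na(fy$partner[j]) && fy$partner[j] == i
  }, logical(1))
  pairs <- data.frame(
    chrom = tads_x$chrom[has],
    start_x = tads_x$start[has], end_x = tads_x$end[has],
    start_y = tads_y$start[fx$partner[has]],
    end_y = tads_y$end[fx$partner[has]],
    overlap_bp = fx$overlap[has])
  pairs$frac_x <- pairs$overlap_bp / (pairs$end_x - pairs$start_x)
  pairs$frac_y <- pairs$overlap_bp / (pairs$end_y - pairs$start_y)
  pairs$reciprocal <- recip
  list(pairs = pairs,
       n_x = nrow(tads_x), n_y = nrow(tads_y),
       n_x_overlapped = sum(!is.na(fx$partner)),
       n_y_overlapped = sum(!is.na(fy$partner)),
       n_reciprocal = sum(recip))
}

#' 2-D histogram of reciprocal overlap fractions
#'
#' Bins the `(frac_x, frac_y)` overlap fractions of reciprocal TAD pairs
#' over an `n_bins x n_bins` grid on `[0, 1]^2`. Conserved domain
#' architecture shows up as mass concentrated near `(1, 1)`.
#'
#' @param overlaps Result of [max_overlap_pairs()], or its `pairs`
#'   `data.frame` (rows with `reciprocal == TRUE` are used when the
#'   column is present).
#' @param n_bins Number of grid cells per axis.
#' @return `n_bins x n_bins` integer matrix; rows index `frac_x` bins,
#'   columns `frac_y` bins, both low to high. The total equals the
#'   number of reciprocal pairs.
#' @export
overlap_fraction_histogram <- function(overlaps, n_bins = 20L) {
  df <- if (is.list(overlaps) && !is.data.frame(overlaps)) {
    overlaps$pairs
  } else {
    overlaps
  }
  if (!is.null(df$reciprocal)) df <- df[df$reciprocal, , drop = FALSE]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  h <- matrix(0L, n_bins, n_bins)
  if (nrow(df) == 0) {
    warning("no reciprocal overlap pairs; returning empty histogram")
    return(h)
  }
  ix <- findInterval(df$frac_x, breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(df$frac_y, breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1L
  h
}
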