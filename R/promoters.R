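#' Load promoters from a gene annotation
#'
#' One promoter per gene: the window `[TSS - window, TSS + window)`
#' clipped to chromosome bounds.
#'
#' @param annotation `data.frame` (or path to a TSV with a header) with
#'   columns `gene_id`, `chrom`, `tss` and optionally `strand`. Gene ids
#'   must be unique.
#' @param layout A [genome_layout()] for clipping.
#' @param window Half-width of the promoter window in bp (> 0); default
#'   +/- 2 kb around the TSS.
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss`, `start`,
#'   `end` (bp half-open).
#' @export
load_promoters <- function(annotation, layout, window = 2000) {
  if (is.character(annotation)) {
    annotation <- read.table(annotation, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(annotation)),
            inherits(layout, "genome_layout"))
  if (window <= 0) stop("`window` must be positive")
  dup <- annotation$gene_id[duplicated(annotation$gene_id)]
  if (length(dup)) {
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  }
  if (!all(annotation$chrom %in% layout$chroms)) {
    stop("annotation contains chromosomes absent from the layout")
  }
  L <- layout$lengths[annotation$chrom]
  if (any(annotation$tss < 0 | annotation$tss > L)) {
    stop("TSS outside chromosome bounds")
  }
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             tss = annotation$tss,
             start = pmax(annotation$tss - window, 0),
             end = pmin(annotation$tss + window, L))
}

#' Call promoter-promoter contacts against a distance-decay expectation
#'
#' Candidate pairs are bin pairs whose two anchors each contain at
#' least one promoter and whose separation is at least `min_sep` bins.
#' Each candidate's observed count is compared with the matrix-wide
#' expected count at that separation (from [expected_by_distance()])
#' by an upper-tail Poisson test, `P(X >= observed | lambda =
#' expected)`; Benjamini-Hochberg adjustment is applied over all
#' candidates and pairs below `q_threshold` are returned, expanded to
#' gene level (every promoter combination across the two anchors).
#'
#' @param cm A [contact_matrix()].
#' @param promoters Promoter table from [load_promoters()]; promoters on
#'   other chromosomes are skipped with a warning.
#' @param expected Optional precomputed [expected_by_distance()] result
#'   for `cm`.
#' @param q_threshold FDR threshold on candidate bin pairs.
#' @param min_sep Minimum anchor separation in bins (default 2).
#' @return `data.frame` of significant promoter pairs: `gene_a`,
#'   `gene_b`, `bin_a`, `bin_b`, `observed`, `expected`, `p_value`,
#'   `q_value`. The candidate-level table is in `attr(, "candidates")`.
#' @export
call_promoter_pairs <- function(cm, promoters, expected = NULL,
                                q_threshold = 0.05, min_sep = 2L) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (is.null(expected)) expected <- expected_by_distance(cm)
  off_chrom <- promoters$chrom != cm$chrom
  if (any(off_chrom)) {
    warning(sum(off_chrom), " promoter(s) on other chromosomes skipped")
    promoters <- promoters[!off_chrom, , drop = FALSE]
  }
  n <- nrow(cm$counts)
  bs <- cm$bin_size
  # promoter -> bins its window overlaps
  first_bin <- pmax(floor(promoters$start / bs), 0)
  last_bin <- pmin(floor((promoters$end - 1) / bs), n - 1)
  prom_bins <- mapply(function(a, b) a:b, first_bin, last_bin,
                      SIMPLIFY = FALSE)
  bin_genes <- split(
    rep(promoters$gene_id, lengths(prom_bins)),
    unlist(prom_bins))
  pbins <- sort(as.integer(names(bin_genes)))
  if (length(pbins) < 2) {
    out <- data.frame(gene_a = character(0), gene_b = character(0))
    attr(out, "candidates") <- NULL
    return(out)
  }
  grid <- expand.grid(bin_a = pbins, bin_b = pbins)
  grid <- grid[grid$bin_b - grid$bin_a >= min_sep, , drop = FALSE]
  lam <- expected$expected[grid$bin_b - grid$bin_a + 1]
  obs <- cm$counts[cbind(grid$bin_a + 1, grid$bin_b + 1)]
  usable <- lam > 0
  grid <- grid[usable, , drop = FALSE]
  lam <- lam[usable]
  obs <- obs[usable]
  p <- ppois(obs - 1, lambda = lam, lower.tail = FALSE)
  q <- bh_adjust(p)
  cand <- data.frame(grid, observed = obs, expected = lam,
                     p_value = p, q_value = q)
  sig <- cand[q < q_threshold, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(sig)), function(r) {
    ga <- bin_genes[[as.character(sig$bin_a[r])]]
    gb <- bin_genes[[as.character(sig$bin_b[r])]]
    gp <- expand.grid(gene_a = unique(ga), gene_b = unique(gb),
                      stringsAsFactors = FALSE)
    gp <- gp[gp$gene_a != gp$gene_b, , drop = FALSE]
    if (nrow(gp) == 0) return(NULL)
    cbind(gp, sig[r, c("bin_a", "bin_b", "observed", "expected",
                       "p_value", "q_value")], row.names = NULL)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      bin_a = integer(0), bin_b = integer(0),
                      observed = numeric(0), expected = numeric(0),
                      p_value = numeric(0), q_value = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "candidates") <- cand
  out
}
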