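#' Cross-tabulate promoter-pair group transitions between conditions
#'
#' Pairs are identified by their unordered gene-id pair. Pairs present
#' in both conditions are cross-classified by (group in A, group in B);
#' pairs private to one condition are counted separately. Cell counts
#' sum to the number of shared pairs, and shared plus private counts
#' reproduce each input's total.
#'
#' @param pairs_a,pairs_b Labelled pair tables from
#'   [classify_coherence()] for the two conditions.
#' @return List of class `transition_table` with `table` (4 x 4 group
#'   cross-tabulation, rows = condition A groups), `shared` (the joined
#'   `data.frame` with `group_a`, `group_b`), `n_shared`, `n_private_a`,
#'   `n_private_b`.
#' @export
group_transitions <- function(pairs_a, pairs_b) {
  key <- function(p) {
    paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b), sep = "|")
  }
  ka <- key(pairs_a)
  kb <- key(pairs_b)
  if (anyDuplicated(ka)) {
    pairs_a <- pairs_a[!duplicated(ka), , drop = FALSE]
    ka <- ka[!duplicated(ka)]
  }
  if (anyDuplicated(kb)) {
    pairs_b <- pairs_b[!duplicated(kb), , drop = FALSE]
    kb <- kb[!duplicated(kb)]
  }
  m <- match(ka, kb)
  shared_idx <- which(!is.na(m))
  shared <- data.frame(
    gene_a = pmin(pairs_a$gene_a[shared_idx], pairs_a$gene_b[shared_idx]),
    gene_b = pmax(pairs_a$gene_a[shared_idx], pairs_a$gene_b[shared_idx]),
    group_a = pairs_a$group[shared_idx],
    group_b = pairs_b$group[m[shared_idx]])
  levs <- c("G1", "G2", "incoherent", "intermediate")
  tab <- table(factor(shared$group_a, levels = levs),
               factor(shared$group_b, levels = levs))
  structure(
    list(table = tab, shared = shared,
         n_shared = nrow(shared),
         n_private_a = nrow(pairs_a) - nrow(shared),
         n_private_b = nrow(pairs_b) - nrow(shared)),
    class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("transition_table:", x$n_shared, "shared pairs;",
      x$n_private_a, "private to A,", x$n_private_b, "private to B\n")
  print(x$table)
  invisible(x)
}

#' Genes of pairs in a transition cell
#'
#' @param transitions A `transition_table` from [group_transitions()].
#' @param from,to Group labels in condition A and B selecting the cell.
#' @return Character vector of unique gene ids of the selected pairs.
#' @export
transition_genes <- function(transitions, from, to) {
  stopifnot(inherits(transitions, "transition_table"))
  sh <- transitions$shared
  sel <- sh$group_a == from & sh$group_b == to
  sort(unique(c(sh$gene_a[sel], sh$gene_b[sel])))
}

#' Expression-shift test between transition classes
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of expression
#' between two gene sets — typically the genes of pairs that became
#' activated (G1 in the stem state, G2 after differentiation) against
#' those that stayed suppressed (G1 to G1). Values compared are either
#' the post-differentiation FPKM (default) or the FPKM change. The test
#' is exact for combined n of at most 20 without ties, and uses the
#' normal approximation with tie correction otherwise.
#'
#' @param genes_x,genes_y Character vectors of gene ids (or directly
#'   numeric value vectors, in which case `fpkm_b` is ignored).
#' @param fpkm_b `data.frame` (`gene_id`, `fpkm`) of post-shift
#'   expression.
#' @param fpkm_a Optional pre-shift expression table; required for
#'   `mode = "change"`.
#' @param mode `"post"` compares post-shift FPKM; `"change"` compares
#'   FPKM differences.
#' @return List with `statistic` (Mann-Whitney U for the first sample),
#'   `p_value` (two-sided), `n_x`, `n_y`, `exact`.
#' @export
expression_shift_test <- function(genes_x, genes_y, fpkm_b = NULL,
                                  fpkm_a = NULL,
                                  mode = c("post", "change")) {
  mode <- match.arg(mode)
  values <- function(g) {
    if (is.numeric(g)) return(g)
    vb <- fpkm_b$fpkm[match(g, fpkm_b$gene_id)]
    if (mode == "change") {
      if (is.null(fpkm_a)) stop("`fpkm_a` required for mode = 'change'")
      vb <- vb - fpkm_a$fpkm[match(g, fpkm_a$gene_id)]
    }
    vb[!is.na(vb)]
  }
  x <- values(genes_x)
  y <- values(genes_y)
  if (length(x) == 0 || length(y) == 0) {
    stop("both gene sets must be non-empty")
  }
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                n_x = length(x), n_y = length(y), exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_x = length(x), n_y = length(y), exact = exact)
}
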