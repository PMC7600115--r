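#' Simulate FPKM expression tables with planted coherence groups
#'
#' Generates per-condition gene-level FPKM values that respect a planted
#' group plan exactly: genes planned `G1` (suppressed) draw from a low
#' distribution with support in `[0, 1)`, genes planned `G2` (activated)
#' from a high distribution with support in `(2, Inf)`, and genes planned
#' `incoherent` from an even mixture of the two. The gap between the
#' suppressed threshold (FPKM < 1) and the activated threshold (FPKM > 2)
#' is left empty by construction, so classification against the planted
#' plan is exact.
#'
#' @param genes `data.frame` with at least a `gene_id` column (see
#'   [load_promoters()] for the full annotation format).
#' @param group_plan `data.frame` with column `gene_id` plus one column
#'   per condition giving the planned label in
#'   `c("G1", "G2", "incoherent")`. Every planned gene must exist in
#'   `genes`.
#' @param seed Integer seed.
#' @return List with `fpkm`: a `data.frame` of `gene_id` plus one
#'   `fpkm_<condition>` column per plan column, and `truth`: the plan.
#' @export
simulate_expression <- function(genes, group_plan, seed = 1L) {
  stopifnot(is.data.frame(group_plan), "gene_id" %in% names(group_plan))
  cond_cols <- setdiff(names(group_plan), "gene_id")
  if (length(cond_cols) == 0) stop("`group_plan` needs condition columns")
  if (!all(group_plan$gene_id %in% genes$gene_id)) {
    stop("every planned gene must exist in the annotation")
  }
  labs <- unlist(group_plan[cond_cols], use.names = FALSE)
  if (!all(labs %in% c("G1", "G2", "incoherent"))) {
    stop("unknown group label; use G1, G2 or incoherent")
  }
  draw_low <- function(n) runif(n, 0, 0.9)
  draw_high <- function(n) 2 + stats::rlnorm(n, meanlog = 1, sdlog = 0.5)
  with_seed(seed, {
    out <- data.frame(gene_id = group_plan$gene_id)
    for (cc in cond_cols) {
      lab <- group_plan[[cc]]
      n <- length(lab)
      v <- numeric(n)
      v[lab == "G1"] <- draw_low(sum(lab == "G1"))
      v[lab == "G2"] <- draw_high(sum(lab == "G2"))
      inc <- which(lab == "incoherent")
      if (length(inc)) {
        hi <- runif(length(inc)) < 0.5
        v[inc[hi]] <- draw_high(sum(hi))
        v[inc[!hi]] <- draw_low(sum(!hi))
      }
      out[[paste0("fpkm_", cc)]] <- v
    }
    list(fpkm = out, truth = group_plan)
  })
}
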