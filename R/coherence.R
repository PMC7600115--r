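#' Classify promoter pairs by expression coherence
#'
#' A pair of interacting genes is coherent when both members share
#' expression status: **G1** (suppressed) when both have FPKM below
#' `low`, **G2** (activated) when both are above `high`. Pairs with one
#' suppressed and one activated member are **incoherent**; everything
#' else (at least one gene in the `[low, high]` gap) is
#' **intermediate**. The four groups are mutually exclusive and
#' exhaustive. Default thresholds: suppressed below FPKM 1, activated
#' above FPKM 2.
#'
#' @param pairs `data.frame` with columns `gene_a`, `gene_b` (e.g. from
#'   [call_promoter_pairs()]).
#' @param fpkm `data.frame` with columns `gene_id` and `fpkm`. Pairs
#'   with a missing gene are dropped with a warning (count in
#'   `attr(, "n_dropped")`).
#' @param low,high Group thresholds (`low <= high`).
#' @return The input pairs with columns `fpkm_a`, `fpkm_b` and `group`
#'   (factor: `G1`, `G2`, `incoherent`, `intermediate`).
#' @export
classify_coherence <- function(pairs, fpkm, low = 1, high = 2) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)),
            all(c("gene_id", "fpkm") %in% names(fpkm)),
            low <= high)
  # reclassification: discard any previous labels so they cannot shadow
  # the new ones
  pairs <- pairs[, setdiff(names(pairs), c("fpkm_a", "fpkm_b", "group")),
                 drop = FALSE]
  fa <- fpkm$fpkm[match(pairs$gene_a, fpkm$gene_id)]
  fb <- fpkm$fpkm[match(pairs$gene_b, fpkm$gene_id)]
  miss <- is.na(fa) | is.na(fb)
  if (any(miss)) {
    warning(sum(miss), " pair(s) with missing expression dropped")
    pairs <- pairs[!miss, , drop = FALSE]
    fa <- fa[!miss]
    fb <- fb[!miss]
  }
  group <- ifelse(fa < low & fb < low, "G1",
           ifelse(fa > high & fb > high, "G2",
           ifelse((fa < low & fb > high) | (fa > high & fb < low),
                  "incoherent", "intermediate")))
  out <- cbind(pairs, fpkm_a = fa, fpkm_b = fb,
               group = factor(group, levels = c("G1", "G2", "incoherent",
                                                "intermediate")))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(miss)
  out
}

#' Permutation test for coherence enrichment
#'
#' Tests whether interacting promoter pairs are more often coherent
#' (both suppressed or both activated) than expected when expression is
#' unrelated to the interaction structure. The statistic is the
#' fraction of pairs in G1 or G2; the null is built by permuting the
#' gene-to-FPKM assignment genome-wide and re-classifying.
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @inheritParams classify_coherence
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `observed` (coherent fraction), `ratio`
#'   (observed / mean null), `p_value` and `null` (the permuted
#'   fractions).
#' @export
coherence_enrichment <- function(pairs, fpkm, n_perm = 999L, seed = 1L,
                                 low = 1, high = 2) {
  if (nrow(pairs) < 20) stop("need at least 20 promoter pairs")
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  coh_frac <- function(ftab) {
    cl <- suppressWarnings(
      classify_coherence(pairs, ftab, low = low, high = high))
    mean(cl$group %in% c("G1", "G2"))
  }
  obs <- coh_frac(fpkm)
  if (sd(fpkm$fpkm) < 1e-12) {
    warning("degenerate expression (all genes identical); p = 1")
    return(list(observed = obs, ratio = 1, p_value = 1,
                null = rep(obs, n_perm)))
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- fpkm
      perm$fpkm <- sample(fpkm$fpkm)
      coh_frac(perm)
    }, numeric(1))
  })
  list(observed = obs,
       ratio = obs / mean(null),
       p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       null = null)
}
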