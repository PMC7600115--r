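# Negative-binomial group fitting and the quasi-likelihood F-test for
# differential interactions.

# Fisher scoring for a one-parameter NB log-linear model per row:
# mu[s] = exp(beta + o[s]), known dispersion phi. Vectorized over rows.
# Returns the fitted beta (natural-log scale).
.nb_fit_group <- function(y, o, phi, max_iter = 50L, tol = 1e-10) {
  eo <- exp(o)
  beta <- log(pmax(rowMeans(y / eo), 1e-8))
  for (it in seq_len(max_iter)) {
    mu <- eo * exp(beta)
    denom <- 1 + phi * mu
    f <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- f / pmax(info, 1e-300)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Per-row NB deviance with known dispersion (Poisson limit as phi -> 0).
.nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  phi <- pmax(phi, 1e-8)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / phi) * (log1p(phi * y) - log1p(phi * mu))
  2 * rowSums(t1 - t2)
}

#' Quasi-likelihood F-test for differential interactions
#'
#' Fits, per bin pair, a negative-binomial log-linear model with a
#' condition effect and per-cell offsets, at the dispersions from
#' [estimate_dispersion()]. Significance of the condition effect is
#' assessed by a deviance-ratio quasi-likelihood F-statistic: the
#' per-row quasi-dispersion (residual deviance over residual degrees of
#' freedom from replication) is moderated across rows by
#' empirical-Bayes squeezing, and the drop in deviance between the
#' null (common mean) and full (per-condition mean) fits is divided by
#' it. The log2 fold change is the offset-adjusted difference of
#' condition means, second condition level versus first.
#'
#' @param table A filtered [bin_pair_table()].
#' @param condition Factor of sample conditions (two levels).
#' @param offsets Optional per-cell log2 offsets from [loess_offsets()];
#'   when `NULL`, log2 library sizes are used.
#' @param dispersion Optional `dispersion_model`; estimated from the
#'   data when `NULL`.
#' @param moderate Logical; apply empirical-Bayes moderation of the
#'   quasi-dispersion (recommended with few replicates).
#' @return `data.frame` with columns `chrom`, `anchor1`, `anchor2`,
#'   `log2fc`, `ave_logcpm`, `f_stat`, `p_value`, `flagged` (rows with a
#'   non-finite fit, forced to `p = 1`). Attributes `df_test`,
#'   `df_resid` and `df_prior` record the F-test degrees of freedom.
#' @export
test_differential <- function(table, condition, offsets = NULL,
                              dispersion = NULL, moderate = TRUE) {
  stopifnot(inherits(table, "bin_pair_table"))
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("`condition` must have two levels")
  if (ncol(table$counts) != length(condition)) {
    stop("`condition` must have one entry per sample column")
  }
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(table, condition, offsets)
  }
  phi <- dispersion$phi
  y <- table$counts
  n <- nrow(y)
  if (is.null(offsets)) {
    depth <- log2(table$lib_sizes + 1) - mean(log2(table$lib_sizes + 1))
    offsets <- matrix(rep(depth, each = n), n, ncol(y))
  }
  o_nat <- log(2) * offsets

  lev <- levels(condition)
  ia <- which(condition == lev[1])
  ib <- which(condition == lev[2])
  beta_a <- .nb_fit_group(y[, ia, drop = FALSE],
                          o_nat[, ia, drop = FALSE], phi)
  beta_b <- .nb_fit_group(y[, ib, drop = FALSE],
                          o_nat[, ib, drop = FALSE], phi)
  beta_0 <- .nb_fit_group(y, o_nat, phi)

  mu_full <- cbind(exp(o_nat[, ia, drop = FALSE] + beta_a),
                   exp(o_nat[, ib, drop = FALSE] + beta_b))
  y_perm <- cbind(y[, ia, drop = FALSE], y[, ib, drop = FALSE])
  dev_full <- .nb_deviance(y_perm, mu_full, phi)
  dev_red <- .nb_deviance(y, exp(o_nat + beta_0), phi)
  lrt <- pmax(dev_red - dev_full, 0)

  df_resid <- ncol(y) - 2L
  if (df_resid < 1) stop("no residual degrees of freedom; add replicates")
  s2 <- dev_full / df_resid
  if (moderate && n >= 2) {
    sq <- limma::squeezeVar(s2, df = df_resid)
    var_post <- sq$var.post
    df_prior <- sq$df.prior
  } else {
    var_post <- s2
    df_prior <- 0
  }
  f_stat <- lrt / pmax(var_post, 1e-10)
  df_total <- df_resid + min(df_prior, 1e6)
  p <- pf(f_stat, 1, df_total, lower.tail = FALSE)
  flagged <- !is.finite(beta_a) | !is.finite(beta_b) | !is.finite(p)
  p[flagged] <- 1
  out <- data.frame(table$pairs,
                    log2fc = (beta_b - beta_a) / log(2),
                    ave_logcpm = dispersion$ave_logcpm,
                    f_stat = f_stat, p_value = p, flagged = flagged)
  attr(out, "df_test") <- 1L
  attr(out, "df_resid") <- df_resid
  attr(out, "df_prior") <- df_prior
  attr(out, "condition_levels") <- lev
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` over the sorted p-values.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (q-values) in the original order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Call differential interacting regions (DIRs)
#'
#' Applies Benjamini-Hochberg adjustment over all tested bin pairs and
#' returns those below the FDR threshold, labelled `up` when the log2
#' fold change is positive (higher in the second condition level, e.g.
#' the differentiated state) and `down` otherwise.
#'
#' @param stats Result of [test_differential()].
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return `data.frame` of significant bin pairs with `q_value` and
#'   `direction` columns; the full adjusted table is in
#'   `attr(, "all")`.
#' @export
call_dirs <- function(stats, fdr_threshold = 0.05) {
  q <- bh_adjust(stats$p_value)
  all <- cbind(stats, q_value = q)
  sel <- all[q < fdr_threshold, , drop = FALSE]
  sel$direction <- ifelse(sel$log2fc > 0, "up", "down")
  rownames(sel) <- NULL
  attr(sel, "all") <- all
  sel
}

#' Associate genes with DIR anchors
#'
#' A gene is associated with a DIR when its padded interval overlaps or
#' touches either anchor bin of the pair (so a gene exactly `pad` bp
#' away from an anchor still counts). Gene sets are reported separately
#' for up- and down-DIRs, deduplicated; a gene may appear in both.
#'
#' @param dirs DIR table from [call_dirs()] (needs `chrom`, `anchor1`,
#'   `anchor2`, `direction`).
#' @param annotation `data.frame` of gene intervals: `gene_id`, `chrom`,
#'   `start`, `end` (bp half-open).
#' @param pad Padding in bp added to each side of the gene interval.
#' @param bin_size Anchor bin size in bp.
#' @return List with character vectors `up` and `down` of gene ids.
#' @export
associate_genes <- function(dirs, annotation, pad = 0, bin_size = 5000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in%
                  names(annotation)))
  hit_genes <- function(dd) {
    if (nrow(dd) == 0) return(character(0))
    anchors <- rbind(
      data.frame(chrom = dd$chrom, start = dd$anchor1,
                 end = dd$anchor1 + bin_size),
      data.frame(chrom = dd$chrom, start = dd$anchor2,
                 end = dd$anchor2 + bin_size))
    out <- character(0)
    for (ch in unique(anchors$chrom)) {
      ga <- annotation[annotation$chrom == ch, , drop = FALSE]
      if (nrow(ga) == 0) next
      aa <- anchors[anchors$chrom == ch, , drop = FALSE]
      qg <- IRanges::IRanges(start = ga$start - pad + 1,
                             end = ga$end + pad)
      qa <- IRanges::IRanges(start = aa$start + 1, end = aa$end)
      h <- IRanges::findOverlaps(qg, qa, maxgap = 0L)
      out <- c(out, ga$gene_id[unique(S4Vectors::queryHits(h))])
    }
    sort(unique(out))
  }
  list(up = hit_genes(dirs[dirs$direction == "up", , drop = FALSE]),
       down = hit_genes(dirs[dirs$direction == "down", , drop = FALSE]))
}
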