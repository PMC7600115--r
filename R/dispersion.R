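#' Estimate negative-binomial dispersions for bin pairs
#'
#' Per-row raw dispersions by the method of moments on condition-centered
#' counts (`phi = (s^2 - m) / m^2`, pooled within-condition variance
#' against the grand mean), a trended dispersion obtained as a running
#' median of the raw values in average-abundance order, and a final
#' per-row value shrunk toward the trend:
#' `phi = (1 - w) * raw + w * trend`, floored at zero. With few
#' replicates the raw values are individually almost uninformative, so
#' the default weight of 1 uses the trend alone (the classical
#' quasi-likelihood arrangement: the generalized linear model runs at
#' the trended dispersion and row-level variance heterogeneity is
#' absorbed by the moderated quasi-dispersion of
#' [test_differential()]).
#'
#' @param table A filtered [bin_pair_table()].
#' @param condition Factor of sample conditions (two levels, >= 2
#'   replicates each).
#' @param offsets Optional per-cell log2 offsets from [loess_offsets()];
#'   counts are rescaled by the row-centered offsets before moments are
#'   taken.
#' @param shrink_weight Weight on the trend in the final combination,
#'   in `[0, 1]`.
#' @param trend_window Window (odd integer) of the running median; capped
#'   at the number of rows.
#' @return List of class `dispersion_model` with `raw`, `trend`, `phi`
#'   (all per row) and `ave_logcpm`.
#' @export
estimate_dispersion <- function(table, condition, offsets = NULL,
                                shrink_weight = 1,
                                trend_window = 501L) {
  stopifnot(inherits(table, "bin_pair_table"))
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("`condition` must have two levels")
  if (any(table(condition) < 2)) {
    stop("at least 2 replicates per condition are required to",
         " estimate variance")
  }
  y <- table$counts
  if (!is.null(offsets)) {
    oc <- offsets - rowMeans(offsets)
    y <- y / 2^oc
  }
  grand <- rowMeans(y)
  ss <- 0
  df <- 0
  for (lev in levels(condition)) {
    yc <- y[, condition == lev, drop = FALSE]
    mc <- rowMeans(yc)
    ss <- ss + rowSums((yc - mc)^2)
    df <- df + ncol(yc) - 1
  }
  s2 <- ss / df
  raw <- (s2 - grand) / pmax(grand, 1e-8)^2  # may be negative; floored below
  alc <- rowMeans(ave_log_cpm(table))
  o <- order(alc)
  k <- min(as.integer(trend_window), nrow(y))
  if (k %% 2 == 0) k <- k - 1L
  trend <- numeric(length(raw))
  if (k >= 3 && length(raw) >= 3) {
    trend[o] <- stats::runmed(raw[o], k = k, endrule = "constant")
  } else {
    trend[] <- median(raw)
  }
  # The running median of moment estimates is biased low: the pooled
  # variance is chi-square distributed with `df` degrees of freedom, so
  # its median sits at qchisq(0.5, df)/df of its mean. Invert that
  # relation (using the row's mean count for the Poisson part) so the
  # trend is median-unbiased for the true dispersion.
  cmed <- stats::qchisq(0.5, df) / df
  trend <- (trend + (1 - cmed) / pmax(grand, 1e-8)) / cmed
  trend <- pmax(trend, 0)
  phi <- pmax((1 - shrink_weight) * pmax(raw, 0) +
                shrink_weight * trend, 0)
  structure(list(raw = pmax(raw, 0), trend = trend, phi = phi,
                 ave_logcpm = alc),
            class = "dispersion_model")
}
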