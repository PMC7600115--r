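#' Simulation parameters for synthetic Hi-C data
#'
#' Bundles the generative model parameters used by
#' [simulate_contact_map()], [simulate_condition_experiment()] and
#' [simulate_pairs_file()]. For cis bins `i <= j` the expected count is
#'
#' \deqn{E[i,j] = s \cdot (|i-j|+1)^{-\alpha} \cdot
#'       (1 + \beta \, 1[i,j \textrm{ in same TAD}]) \cdot b_i b_j}
#'
#' and counts are drawn negative-binomially with
#' `variance = mean + phi * mean^2` (Poisson when `phi = 0`).
#'
#' @param depth Depth scale `s`: expected counts per bin pair at distance
#'   0 before TAD enrichment and bias (> 0).
#' @param alpha Distance-decay exponent (> 0).
#' @param beta TAD enrichment: within-domain expected counts are
#'   multiplied by `1 + beta` (>= 0).
#' @param phi Negative-binomial dispersion (>= 0; 0 gives Poisson).
#' @param bias Optional list of per-chromosome positive bin-bias vectors
#'   (named by chromosome), or `NULL` for unbiased bins. Use
#'   [draw_bin_biases()] for log-normal biases with known truth.
#' @param self_frac,trans_frac Fractions of read pairs written by
#'   [simulate_pairs_file()] that are self-ligation and trans pairs; both
#'   in `[0, 1]` with `self_frac + trans_frac < 1` (the remainder is
#'   cis). Defaults 0.5 and 0.15 emulate typical in situ Hi-C libraries,
#'   where self pairs make up 40-60% of uniquely mapped reads, cis 20-30%
#'   and trans 10-20%.
#' @param self_cutoff Separation in bp below which an intra-chromosomal
#'   pair counts as self-ligation (see [classify_pairs()]).
#' @param seed Integer seed making the generators deterministic.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(depth = 100, alpha = 1, beta = 2,
                              phi = 0.05, bias = NULL,
                              self_frac = 0.5, trans_frac = 0.15,
                              self_cutoff = 20000, seed = 1L) {
  if (depth <= 0) stop("`depth` must be positive")
  if (alpha <= 0) stop("`alpha` must be positive")
  if (beta < 0) stop("`beta` must be non-negative")
  if (phi < 0) stop("`phi` must be non-negative")
  if (self_frac < 0 || trans_frac < 0 || self_frac + trans_frac > 1) {
    stop("fractions must lie in [0,1] with self_frac + trans_frac <= 1")
  }
  if (!is.null(bias)) {
    if (!is.list(bias) || is.null(names(bias))) {
      stop("`bias` must be a named list of per-chromosome vectors")
    }
    if (any(vapply(bias, function(b) any(b <= 0), logical(1)))) {
      stop("bias multipliers must be strictly positive")
    }
  }
  structure(
    list(depth = depth, alpha = alpha, beta = beta, phi = phi,
         bias = bias, self_frac = self_frac, trans_frac = trans_frac,
         self_cutoff = self_cutoff, seed = as.integer(seed)),
    class = "simulation_params"
  )
}

#' Draw log-normal bin biases with known truth
#'
#' @param layout A [genome_layout()].
#' @param sdlog Standard deviation of log biases.
#' @param seed Integer seed.
#' @return Named list (per chromosome) of positive bias vectors, mean-one
#'   on the log scale.
#' @export
draw_bin_biases <- function(layout, sdlog = 0.3, seed = 1L) {
  with_seed(seed, {
    out <- lapply(layout$chroms, function(ch) {
      stats::rlnorm(n_bins(layout, ch), meanlog = 0, sdlog = sdlog)
    })
    names(out) <- layout$chroms
    out
  })
}

#' Plant non-overlapping TADs tiling a genome
#'
#' Partitions each chromosome into contiguous, bin-aligned, half-open
#' domains whose sizes follow an exponential law with a floor at
#' `min_size` and the stated mean. These planted domains are the ground
#' truth against which TAD calling is scored.
#'
#' @param layout A [genome_layout()].
#' @param mean_size Mean domain size in bp (>= `min_size`).
#' @param min_size Minimum domain size in bp (>= 2 bins).
#' @param seed Integer seed.
#' @return `data.frame` with columns `chrom`, `start`, `end` (bp, 0-based
#'   half-open, bin-aligned except possibly at the chromosome end),
#'   sorted and tiling each chromosome exactly.
#' @examples
#' layout <- genome_layout("chr1", 1e6, bin_size = 40000)
#' plant_tads(layout, mean_size = 250000, min_size = 80000, seed = 7)
#' @export
plant_tads <- function(layout, mean_size, min_size, seed = 1L) {
  bs <- layout$bin_size
  if (min_size < 2 * bs) stop("`min_size` must be at least 2 bins")
  if (mean_size < min_size) stop("`mean_size` must be >= `min_size`")
  with_seed(seed, {
    res <- lapply(layout$chroms, function(ch) {
      L <- layout$lengths[[ch]]
      if (L <= min_size) {
        return(data.frame(chrom = ch, start = 0, end = L))
      }
      starts <- numeric(0)
      pos <- 0
      while (pos < L) {
        size <- if (mean_size > min_size) {
          min_size + stats::rexp(1, rate = 1 / (mean_size - min_size))
        } else {
          min_size
        }
        size <- max(round(size / bs), ceiling(min_size / bs)) * bs
        starts <- c(starts, pos)
        pos <- pos + size
      }
      ends <- c(starts[-1], L)
      # a truncated terminal domain shorter than min_size is merged into
      # its predecessor
      k <- length(starts)
      if (k > 1 && (ends[k] - starts[k]) < min_size) {
        starts <- starts[-k]
        ends <- ends[-k]
        ends[k - 1] <- L
      }
      data.frame(chrom = ch, start = starts, end = ends)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

# Map each bin (0-based) of a chromosome to the planted TAD covering its
# start, or NA when uncovered. `tads` may be NULL/empty.
bin_tad_id <- function(tads, chrom, nb, bin_size) {
  id <- rep(NA_integer_, nb)
  if (is.null(tads) || nrow(tads) == 0) return(id)
  td <- tads[tads$chrom == chrom, , drop = FALSE]
  if (nrow(td) == 0) return(id)
  starts <- (seq_len(nb) - 1) * bin_size
  k <- findInterval(starts, td$start)
  covered <- k >= 1 & starts < td$end[pmax(k, 1)]
  id[covered] <- k[covered]
  id
}

# Expected cis contact model for one chromosome; returns an nb x nb
# symmetric matrix of means.
expected_cis_matrix <- function(nb, tad_id, params, bias = NULL) {
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  E <- params$depth * (d + 1)^(-params$alpha)
  if (params$beta > 0 && any(!is.na(tad_id))) {
    same <- outer(tad_id, tad_id, function(a, b) !is.na(a) & !is.na(b) & a == b)
    E <- E * (1 + params$beta * same)
  }
  if (!is.null(bias)) E <- E * outer(bias, bias)
  E
}

#' Simulate a Hi-C contact map with planted TADs
#'
#' Draws symmetric per-chromosome count matrices from the distance-decay
#' model of [simulation_params()], with within-TAD enrichment `1 + beta`
#' and optional multiplicative bin biases.
#'
#' @param layout A [genome_layout()].
#' @param tads Planted domains from [plant_tads()] (or `NULL` for none).
#' @param params A [simulation_params()]; the draw is seeded with
#'   `params$seed`.
#' @return Named list of [contact_matrix()] objects, one per chromosome.
#' @export
simulate_contact_map <- function(layout, tads, params) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "simulation_params"))
  with_seed(params$seed, {
    out <- lapply(layout$chroms, function(ch) {
      nb <- n_bins(layout, ch)
      id <- bin_tad_id(tads, ch, nb, layout$bin_size)
      b <- if (!is.null(params$bias)) params$bias[[ch]] else NULL
      E <- expected_cis_matrix(nb, id, params, b)
      up <- upper.tri(E, diag = TRUE)
      counts <- matrix(0, nb, nb)
      counts[up] <- rnbinom_disp(sum(up), mu = E[up], phi = params$phi)
      counts <- counts + t(counts) - diag(diag(counts))
      contact_matrix(ch, layout$bin_size, counts)
    })
    names(out) <- layout$chroms
    out
  })
}

#' Simulate a two-condition bin-pair experiment with planted differences
#'
#' Generates replicate count tables over cis bin pairs for two conditions
#' A and B from the [simulation_params()] contact model. Condition B
#' expected counts of planted pairs are `fold` times their condition A
#' expectation; all other pairs share expectations, so `fold = 1`
#' everywhere yields a full null. Replicates are independent
#' negative-binomial draws.
#'
#' @param layout A [genome_layout()] at the analysis bin size (e.g. 5 kb).
#' @param tads Planted domains (or `NULL`).
#' @param params A [simulation_params()].
#' @param planted_dirs `data.frame` with columns `chrom`, `anchor1`,
#'   `anchor2` (bin start positions in bp, bin-aligned, `anchor1 <=
#'   anchor2`) and `fold` (> 0), or `NULL` for none. Duplicate pairs are
#'   rejected.
#' @param n_reps_per_condition Replicates per condition (>= 1).
#' @param max_sep Maximum anchor separation in bins; pairs with
#'   separation `1 .. max_sep` are tabulated.
#' @return List with `table` (a [bin_pair_table()] whose columns are
#'   `A1..An, B1..Bn`), `condition` (factor of column conditions) and
#'   `truth` (the planted pairs with their row indices in the table).
#' @export
simulate_condition_experiment <- function(layout, tads, params,
                                          planted_dirs = NULL,
                                          n_reps_per_condition = 2L,
                                          max_sep = 20L) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "simulation_params"),
            n_reps_per_condition >= 1)
  bs <- layout$bin_size
  pairs <- do.call(rbind, lapply(layout$chroms, function(ch) {
    nb <- n_bins(layout, ch)
    d <- rep(seq_len(min(max_sep, nb - 1)),
             times = pmax(nb - seq_len(min(max_sep, nb - 1)), 0))
    i <- unlist(lapply(seq_len(min(max_sep, nb - 1)),
                       function(dd) seq_len(nb - dd))) - 1L
    data.frame(chrom = ch, bin1 = i, bin2 = i + d)
  }))
  pairs$anchor1 <- pairs$bin1 * bs
  pairs$anchor2 <- pairs$bin2 * bs

  mu0 <- numeric(nrow(pairs))
  for (ch in unique(pairs$chrom)) {
    sel <- pairs$chrom == ch
    p <- pairs[sel, , drop = FALSE]
    nb <- n_bins(layout, ch)
    id <- bin_tad_id(tads, ch, nb, bs)
    b <- if (!is.null(params$bias)) params$bias[[ch]] else rep(1, nb)
    same <- !is.na(id[p$bin1 + 1]) & !is.na(id[p$bin2 + 1]) &
      id[p$bin1 + 1] == id[p$bin2 + 1]
    mu0[sel] <- params$depth * (p$bin2 - p$bin1 + 1)^(-params$alpha) *
      (1 + params$beta * same) * b[p$bin1 + 1] * b[p$bin2 + 1]
  }

  fold <- rep(1, nrow(pairs))
  truth <- NULL
  if (!is.null(planted_dirs) && nrow(planted_dirs) > 0) {
    pd <- planted_dirs
    if (any(pd$fold <= 0)) stop("planted fold changes must be positive")
    if (any(pd$anchor1 %% bs != 0 | pd$anchor2 %% bs != 0)) {
      stop("planted anchors must be aligned to the bin size")
    }
    key <- paste(pd$chrom, pd$anchor1, pd$anchor2)
    if (anyDuplicated(key)) stop("duplicate planted pairs are not allowed")
    idx <- match(key, paste(pairs$chrom, pairs$anchor1, pairs$anchor2))
    if (anyNA(idx)) stop("planted pair outside the tabulated pair set")
    fold[idx] <- pd$fold
    truth <- cbind(pd, row = idx)
  }

  nr <- as.integer(n_reps_per_condition)
  cond <- factor(rep(c("A", "B"), each = nr), levels = c("A", "B"))
  with_seed(params$seed, {
    counts <- sapply(seq_len(2 * nr), function(s) {
      mu <- if (cond[s] == "A") mu0 else mu0 * fold
      rnbinom_disp(length(mu), mu = mu, phi = params$phi)
    })
    colnames(counts) <- paste0(cond, rep(seq_len(nr), 2))
    tab <- bin_pair_table(pairs[, c("chrom", "anchor1", "anchor2")],
                          counts, bin_size = bs)
    list(table = tab, condition = cond,
         truth = list(planted = truth, tads = tads, mu = mu0))
  })
}
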