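# Shared fixtures and independent oracles, built in code at test time.

# Standard two-condition bin-pair simulation: one 1.3 Mb chromosome at
# 5 kb bins, log-normal bin biases, NB noise (phi = 0.05), 250 planted
# 4-fold pairs at baseline mean ~50, 2 replicates per condition.
make_dir_sim <- function(seed, n_bins_chr = 260L, max_sep = 20L,
                         n_plant = 250L, fold = 4, phi = 0.05,
                         depth = 55) {
  layout <- genome_layout("chrS", n_bins_chr * 5000, bin_size = 5000)
  bias <- draw_bin_biases(layout, sdlog = 0.4, seed = seed + 5000L)
  params <- simulation_params(depth = depth, alpha = 0.05, beta = 0,
                              phi = phi, bias = bias, seed = seed)
  planted <- NULL
  if (n_plant > 0) {
    d <- rep(seq_len(max_sep), times = n_bins_chr - seq_len(max_sep))
    i <- unlist(lapply(seq_len(max_sep),
                       function(dd) seq_len(n_bins_chr - dd))) - 1L
    pool <- data.frame(chrom = "chrS", anchor1 = i * 5000,
                       anchor2 = (i + d) * 5000)
    planted <- with_test_seed(seed + 10000L, {
      cbind(pool[sample(nrow(pool), n_plant), ], fold = fold)
    })
  }
  sim <- simulate_condition_experiment(layout, NULL, params, planted,
                                       n_reps_per_condition = 2L,
                                       max_sep = max_sep)
  c(sim, list(layout = layout, planted = planted))
}

pair_key <- function(p) paste(p$chrom, p$anchor1, p$anchor2)

# Local RNG scope for test-side randomness.
with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# --- independent oracles -------------------------------------------------

# BH step-up by definition: q_(i) = min_{j >= i} m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exhaustive most-likely path over all K^T state sequences.
viterbi_brute <- function(x, init, trans, means, sds) {
  K <- length(init)
  Tn <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(init[s[1]]) + dnorm(x[1], means[s[1]], sds[s[1]], log = TRUE)
    for (t in seq_len(Tn - 1)) {
      lp <- lp + log(trans[s[t], s[t + 1]]) +
        dnorm(x[t + 1], means[s[t + 1]], sds[s[t + 1]], log = TRUE)
    }
    if (lp > best) {
      best <- lp
      best_path <- s
    }
  }
  unname(best_path)
}

# Quadratic scan for the maximally overlapping partner (same tie rules:
# overlap length, then fraction of the partner covered, then leftmost).
best_partner_brute <- function(tx, ty) {
  ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  partner <- rep(NA_integer_, nrow(tx))
  for (i in seq_len(nrow(tx))) {
    best <- c(-1, -1, Inf)  # overlap, frac_y, y start
    for (j in seq_len(nrow(ty))) {
      if (tx$chrom[i] != ty$chrom[j]) next
      w <- ov(tx$start[i], tx$end[i], ty$start[j], ty$end[j])
      if (w <= 0) next
      fy <- w / (ty$end[j] - ty$start[j])
      if (w > best[1] ||
          (w == best[1] && fy > best[2]) ||
          (w == best[1] && fy == best[2] && ty$start[j] < best[3])) {
        best <- c(w, fy, ty$start[j])
        partner[i] <- j
      }
    }
  }
  partner
}

# Random sorted non-overlapping interval set on one chromosome.
random_interval_set <- function(n, chrom = "chr1", max_gap = 5,
                                max_len = 20, unit = 1e4) {
  gaps <- sample(0:max_gap, n, replace = TRUE)
  lens <- sample(seq_len(max_len), n, replace = TRUE)
  starts <- cumsum(gaps + c(0, lens[-n]))
  data.frame(chrom = chrom, start = starts * unit,
             end = (starts + lens) * unit)
}

# Brute-force padded-overlap gene association.
associate_brute <- function(dirs, annotation, pad = 0, bin_size = 5000) {
  hit <- function(dd) {
    out <- character(0)
    for (i in seq_len(nrow(dd))) {
      for (g in seq_len(nrow(annotation))) {
        if (annotation$chrom[g] != dd$chrom[i]) next
        gs <- annotation$start[g] - pad
        ge <- annotation$end[g] + pad
        for (a in c(dd$anchor1[i], dd$anchor2[i])) {
          # padded interval overlapping or touching the anchor bin
          if (max(gs, a) <= min(ge, a + bin_size)) {
            out <- c(out, annotation$gene_id[g])
          }
        }
      }
    }
    sort(unique(out))
  }
  list(up = hit(dirs[dirs$direction == "up", , drop = FALSE]),
       down = hit(dirs[dirs$direction == "down", , drop = FALSE]))
}

# A small labelled promoter-pair table with arbitrary groups.
random_labelled_pairs <- function(n, genes, groups) {
  g1 <- sample(genes, n, replace = TRUE)
  g2 <- sample(genes, n, replace = TRUE)
  ok <- g1 != g2
  data.frame(gene_a = g1[ok], gene_b = g2[ok],
             group = factor(sample(groups, sum(ok), replace = TRUE),
                            levels = c("G1", "G2", "incoherent",
                                       "intermediate")))
}
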