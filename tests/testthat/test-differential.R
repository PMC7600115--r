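# Abundance filtering, loess offsets, dispersion estimation, the QL
# F-test, BH control and gene association.

toy_table <- function(counts, bin_size = 5000) {
  n <- nrow(counts)
  bin_pair_table(data.frame(chrom = "c", anchor1 = (0:(n - 1)) * bin_size,
                            anchor2 = (0:(n - 1) + 3) * bin_size),
                 counts, bin_size = bin_size)
}

test_that("logCPM filter follows the continuity-corrected formula", {
  counts <- rbind(rep(2, 4), rep(0, 4))
  tab <- bin_pair_table(data.frame(chrom = "c", anchor1 = c(0, 5000),
                                   anchor2 = c(15000, 20000)),
                        counts, lib_sizes = rep(1e6, 4))
  lc <- ave_log_cpm(tab)
  expect_equal(lc[1, 1], log2((2 + 0.5) / (1e6 + 1) * 1e6))
  expect_lt(abs(lc[1, 1] - 1.32), 0.01)
  expect_lt(lc[2, 1], 0)
  kept <- filter_low_abundance(tab)
  expect_equal(nrow(kept$counts), 1L)
  expect_equal(kept$pairs$anchor1, 0)
  # -Inf threshold keeps everything
  expect_equal(nrow(filter_low_abundance(tab, -Inf)$counts), 2L)
})

test_that("raising the filter threshold never adds rows", {
  sim <- make_dir_sim(3, n_plant = 0)
  kept <- sapply(c(-1, 0, 1, 3), function(th) {
    nrow(filter_low_abundance(sim$table, th)$counts)
  })
  expect_true(all(diff(kept) <= 0))
})

test_that("offsets vanish for identical samples and recover scale factors", {
  mu <- with_test_seed(2, 2^runif(500, 7, 10))
  y1 <- with_test_seed(3, rpois(500, mu))
  tab_same <- toy_table(cbind(y1, y1))
  off_same <- loess_offsets(tab_same)
  expect_lt(max(abs(off_same)), 0.01)
  # exact scalar multiple: offset difference equals the log2 factor
  tab_scaled <- toy_table(cbind(y1, 3 * y1))
  off <- loess_offsets(tab_scaled)
  expect_lt(max(abs((off[, 2] - off[, 1]) - log2(3))), 0.01)
})

test_that("a planted abundance-dependent trend is removed by the offsets", {
  mu <- with_test_seed(4, 2^runif(2000, 6, 11))
  y1 <- with_test_seed(5, rpois(2000, mu))
  y2 <- with_test_seed(6, rpois(2000, mu * 2^(0.5 * sin(log2(mu)))))
  tab <- toy_table(cbind(y1, y2))
  off <- loess_offsets(tab)
  lc <- ave_log_cpm(tab)
  A <- rowMeans(lc)
  M_corr <- (lc[, 2] - off[, 2]) - (lc[, 1] - off[, 1])
  # remove the constant depth component: residual *trend* is what matters
  M_corr <- M_corr - mean(M_corr)
  refit <- fitted(stats::loess(M_corr ~ A, span = 0.3, degree = 2,
                               family = "symmetric"))
  expect_lt(max(abs(refit)), 0.05)
})

test_that("dispersion estimates recover the simulation truth", {
  # Poisson data: dispersion near zero
  y <- with_test_seed(7, matrix(rpois(5000 * 4, 50), ncol = 4))
  tabp <- toy_table(y)
  cond <- factor(rep(c("A", "B"), each = 2))
  dp <- estimate_dispersion(tabp, cond)
  expect_lt(median(dp$phi), 0.02)
  # NB data with phi = 0.1
  y2 <- with_test_seed(8, matrix(rnbinom(5000 * 4, mu = 50, size = 10),
                                 ncol = 4))
  dn <- estimate_dispersion(toy_table(y2), cond)
  expect_gt(median(dn$phi), 0.05)
  expect_lt(median(dn$phi), 0.2)
  # constant counts within condition: zero raw dispersion
  y3 <- matrix(5, 10, 4)
  d3 <- estimate_dispersion(toy_table(y3), cond)
  expect_equal(d3$raw, rep(0, 10))
  # single replicate per condition is not estimable
  expect_error(estimate_dispersion(toy_table(y[, 1:2, drop = FALSE]),
                                   factor(c("A", "B"))),
               "replicates")
})

test_that("null p-values are approximately uniform", {
  sim <- make_dir_sim(17, n_plant = 0)
  tab <- filter_low_abundance(sim$table)
  off <- loess_offsets(tab)
  st <- test_differential(tab, sim$condition, off)
  expect_gte(nrow(st), 4500)
  ks <- suppressWarnings(stats::ks.test(st$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("planted fold changes are estimated and the labels symmetric", {
  sim <- make_dir_sim(19)
  tab <- filter_low_abundance(sim$table)
  off <- loess_offsets(tab)
  st <- test_differential(tab, sim$condition, off)
  planted_rows <- match(pair_key(sim$planted), pair_key(st))
  planted_rows <- planted_rows[!is.na(planted_rows)]
  expect_gt(length(planted_rows), 200)
  expect_lt(abs(median(st$log2fc[planted_rows]) - 2), 0.5)
  # swapping condition labels negates log2FC and keeps p
  swapped <- factor(sim$condition, levels = rev(levels(sim$condition)))
  st2 <- test_differential(tab, swapped, off)
  expect_equal(st2$log2fc, -st$log2fc, tolerance = 1e-6)
  expect_equal(st2$p_value, st$p_value, tolerance = 1e-6)
})

test_that("BH adjustment matches the hand-evaluated and brute-force rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (seed in 1:20) {
    p <- with_test_seed(seed + 300, runif(50)^2)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # adjusted values are non-decreasing in sorted-p order
  p <- with_test_seed(99, runif(200))
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("DIR calling selects by FDR and assigns directions", {
  st <- data.frame(chrom = "c", anchor1 = (0:3) * 5000,
                   anchor2 = (0:3) * 5000 + 15000,
                   log2fc = c(2, -1, 0.5, 0.1),
                   ave_logcpm = 5, f_stat = 1,
                   p_value = c(1e-5, 1e-4, 0.5, 1), flagged = FALSE)
  dirs <- call_dirs(st, fdr_threshold = 0.05)
  expect_equal(nrow(dirs), 2L)
  expect_equal(dirs$direction, c("up", "down"))
  # all-null input yields no calls
  st$p_value <- rep(1, 4)
  expect_equal(nrow(call_dirs(st)), 0L)
})

test_that("error rates are controlled with good power on planted truth", {
  res <- t(sapply(1:6, function(seed) {
    sim <- make_dir_sim(seed)
    tab <- filter_low_abundance(sim$table)
    off <- loess_offsets(tab)
    dirs <- call_dirs(test_differential(tab, sim$condition, off))
    tp <- sum(pair_key(dirs) %in% pair_key(sim$planted))
    c(fdp = if (nrow(dirs)) (nrow(dirs) - tp) / nrow(dirs) else 0,
      power = tp / nrow(sim$planted))
  }))
  expect_lte(mean(res[, "fdp"]), 1.5 * 0.05)
  expect_gte(mean(res[, "power"]), 0.8)
})

test_that("under a full null the false-discovery rate stays at the
           nominal level", {
  fdp <- sapply(1:20, function(seed) {
    sim <- make_dir_sim(seed + 200, n_plant = 0, n_bins_chr = 120L)
    tab <- filter_low_abundance(sim$table)
    dirs <- call_dirs(test_differential(tab, sim$condition,
                                        loess_offsets(tab)))
    as.numeric(nrow(dirs) > 0)  # every call is false under the null
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})

test_that("gene association uses padded anchor overlap, matching brute
           force", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c",
                      start = c(10e3, 10e3), end = c(20e3, 20e3))
  dirs <- data.frame(chrom = "c", anchor1 = c(15e3, 25e3),
                     anchor2 = c(40e3, 40e3),
                     direction = c("up", "up"))
  got0 <- associate_genes(dirs[1, ], genes, pad = 0)
  expect_equal(got0$up, c("gA", "gB"))
  # second DIR touches the gene only once padded
  got_far <- associate_genes(dirs[2, ], genes, pad = 0)
  expect_equal(got_far$up, character(0))
  got_pad <- associate_genes(dirs[2, ], genes, pad = 5000)
  expect_equal(got_pad$up, c("gA", "gB"))
  # random instance against the quadratic scan
  for (seed in 1:3) {
    inst <- with_test_seed(seed + 500, {
      ann <- data.frame(gene_id = paste0("g", 1:100), chrom = "c",
                        start = sample(0:400, 100) * 1e3)
      ann$end <- ann$start + sample(1:30, 100, replace = TRUE) * 1e3
      dd <- data.frame(chrom = "c",
                       anchor1 = sample(0:80, 60, replace = TRUE) * 5e3,
                       direction = sample(c("up", "down"), 60,
                                          replace = TRUE))
      dd$anchor2 <- dd$anchor1 + sample(2:40, 60, replace = TRUE) * 5e3
      list(ann = ann, dd = dd)
    })
    expect_equal(associate_genes(inst$dd, inst$ann, pad = 2500),
                 associate_brute(inst$dd, inst$ann, pad = 2500))
  }
})
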