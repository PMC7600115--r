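# Promoter loading, pair calling, coherence classification, transitions
# and expression-shift testing.

prom_layout <- function() genome_layout("chr1", 2e6, bin_size = 4e4)

test_that("promoter windows are centred on the TSS and clipped", {
  layout <- prom_layout()
  ann <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                    tss = c(100000, 500))
  pr <- load_promoters(ann, layout, window = 2000)
  expect_equal(c(pr$start[1], pr$end[1]), c(98000, 102000))
  expect_equal(c(pr$start[2], pr$end[2]), c(0, 2500))
  expect_error(load_promoters(rbind(ann, ann[1, ]), layout),
               "duplicate")
})

test_that("Poisson enrichment p-values match direct tail summation", {
  # P(X >= 10 | lambda = 2) by pmf summation
  lam <- 2
  p_direct <- 1 - sum(dpois(0:9, lam))
  expect_equal(ppois(9, lam, lower.tail = FALSE), p_direct)
  expect_lt(abs(p_direct - 4.6e-5), 1e-6)
  # observed at or below expectation is never extreme
  for (lam in c(1.5, 3, 7.2, 20)) {
    for (obs in 0:floor(lam)) {
      expect_gte(ppois(obs - 1, lam, lower.tail = FALSE), 0.5)
    }
  }
})

test_that("promoter-pair calling flags planted enriched anchor pairs
           and only promoter-bearing anchors", {
  layout <- prom_layout()
  n <- n_bins(layout, "chr1")
  base <- with_test_seed(31, {
    d <- abs(outer(1:n, 1:n, "-"))
    E <- 80 * (d + 1)^-1
    m <- matrix(rpois(n * n, E), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  })
  # plant a strong contact between bins 5 and 15 (promoter-bearing)
  base[6, 16] <- base[16, 6] <- 60
  cm <- contact_matrix("chr1", 4e4, base)
  ann <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                    tss = c(5, 15, 30, 42) * 4e4 + 2e4)
  pr <- load_promoters(ann, layout, window = 2000)
  pp <- call_promoter_pairs(cm, pr, q_threshold = 0.05)
  expect_true(any(pp$gene_a == "g1" & pp$gene_b == "g2"))
  cand <- attr(pp, "candidates")
  expect_true(all(cand$bin_a %in% c(5, 15, 30, 42)))
  expect_true(all(cand$bin_b - cand$bin_a >= 2))
  # promoters on a chromosome missing from the matrix are skipped
  ann2 <- rbind(ann, data.frame(gene_id = "gX", chrom = "chr9",
                                tss = 1e5))
  pr2 <- rbind(pr, data.frame(gene_id = "gX", chrom = "chr9",
                              tss = 1e5, start = 98000, end = 102000))
  expect_warning(call_promoter_pairs(cm, pr2), "skipped")
})

test_that("coherence classification partitions pairs by the thresholds", {
  fpkm <- data.frame(gene_id = c("a", "b", "c", "d", "e", "f", "g", "h"),
                     fpkm = c(0.2, 0.5, 5, 3, 0.5, 5, 1.5, 3))
  pairs <- data.frame(gene_a = c("a", "c", "e", "g"),
                      gene_b = c("b", "d", "f", "h"))
  cl <- classify_coherence(pairs, fpkm)
  expect_equal(as.character(cl$group),
               c("G1", "G2", "incoherent", "intermediate"))
  # partition: every classified pair lands in exactly one group
  rnd <- with_test_seed(41, {
    ids <- paste0("r", 1:100)
    list(fpkm = data.frame(gene_id = ids, fpkm = runif(100, 0, 6)),
         pairs = data.frame(gene_a = sample(ids, 200, replace = TRUE),
                            gene_b = sample(ids, 200, replace = TRUE)))
  })
  rnd$pairs <- rnd$pairs[rnd$pairs$gene_a != rnd$pairs$gene_b, ]
  cl2 <- classify_coherence(rnd$pairs, rnd$fpkm)
  expect_false(anyNA(cl2$group))
  # missing genes are dropped with a warning
  expect_warning(
    out <- classify_coherence(data.frame(gene_a = c("a", "zz"),
                                         gene_b = c("b", "c")), fpkm),
    "missing")
  expect_equal(nrow(out), 1L)
})

test_that("coherence enrichment separates planted structure from noise", {
  ids <- paste0("g", 1:400)
  fpkm <- data.frame(gene_id = ids,
                     fpkm = rep(c(0.3, 5), each = 200))
  # fully coherent pairing: low with low, high with high
  coh <- data.frame(gene_a = ids[c(1:99, 201:299)],
                    gene_b = ids[c(2:100, 202:300)])
  enr <- coherence_enrichment(coh, fpkm, n_perm = 199, seed = 5)
  expect_equal(enr$observed, 1)
  expect_gt(enr$ratio, 1)
  expect_lte(enr$p_value, 1 / (1 + 199))
  # random pairing: enrichment ratio near 1
  rnd <- with_test_seed(51, data.frame(
    gene_a = sample(ids, 300, replace = TRUE),
    gene_b = sample(ids, 300, replace = TRUE)))
  rnd <- rnd[rnd$gene_a != rnd$gene_b, ]
  enr0 <- coherence_enrichment(rnd, fpkm, n_perm = 199, seed = 6)
  expect_lt(abs(enr0$ratio - 1), 0.1)
  # degenerate expression
  flat <- data.frame(gene_id = ids, fpkm = rep(3, 400))
  expect_warning(e1 <- coherence_enrichment(coh, flat, n_perm = 100,
                                            seed = 1),
                 "degenerate")
  expect_equal(e1$p_value, 1)
})

test_that("permutation p-values are valid under the random-pairing null", {
  ids <- paste0("g", 1:200)
  fpkm <- data.frame(gene_id = ids, fpkm = rep(c(0.3, 5), 100))
  ps <- sapply(1:60, function(b) {
    rnd <- with_test_seed(b + 700, data.frame(
      gene_a = sample(ids, 80, replace = TRUE),
      gene_b = sample(ids, 80, replace = TRUE)))
    rnd <- rnd[rnd$gene_a != rnd$gene_b, ]
    coherence_enrichment(rnd, fpkm, n_perm = 199, seed = b)$p_value
  })
  for (alpha in c(0.1, 0.25, 0.5)) {
    mc_tol <- 3 * sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(mean(ps <= alpha), alpha + mc_tol)
  }
})

test_that("group transitions cross-tabulate shared pairs exactly", {
  pa <- data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g4"),
                   group = factor(c("G1", "G2"),
                                  levels = c("G1", "G2", "incoherent",
                                             "intermediate")))
  pb <- data.frame(gene_a = c("g2", "g5"), gene_b = c("g1", "g6"),
                   group = factor(c("G2", "G1"),
                                  levels = levels(pa$group)))
  tr <- group_transitions(pa, pb)
  expect_equal(tr$n_shared, 1L)
  expect_equal(unname(tr$table["G1", "G2"]), 1L)
  expect_equal(tr$n_private_a, 1L)
  expect_equal(tr$n_private_b, 1L)
  # identical lists give a diagonal table
  tr2 <- group_transitions(pa, pa)
  expect_equal(sum(tr2$table), tr2$n_shared)
  expect_equal(unname(diag(tr2$table)[c("G1", "G2")]), c(1L, 1L))
})

test_that("transitions equal a brute-force dictionary join on random
           instances", {
  for (seed in 1:3) {
    inst <- with_test_seed(seed + 900, {
      genes <- paste0("g", 1:60)
      list(a = random_labelled_pairs(200, genes, levels(factor(
             c("G1", "G2", "incoherent", "intermediate")))),
           b = random_labelled_pairs(200, genes, c("G1", "G2",
                                                   "incoherent",
                                                   "intermediate")))
    })
    tr <- group_transitions(inst$a, inst$b)
    # dictionary join oracle
    dict <- new.env()
    key <- function(x, y) paste(pmin(x, y), pmax(x, y))
    a <- inst$a[!duplicated(key(inst$a$gene_a, inst$a$gene_b)), ]
    b <- inst$b[!duplicated(key(inst$b$gene_a, inst$b$gene_b)), ]
    for (i in seq_len(nrow(a))) {
      assign(key(a$gene_a[i], a$gene_b[i]), as.character(a$group[i]),
             envir = dict)
    }
    cells <- table(factor(character(0), levels = levels(inst$a$group)),
                   factor(character(0), levels = levels(inst$a$group)))
    n_shared <- 0
    for (i in seq_len(nrow(b))) {
      k <- key(b$gene_a[i], b$gene_b[i])
      if (exists(k, envir = dict, inherits = FALSE)) {
        ga <- get(k, envir = dict)
        cells[ga, as.character(b$group[i])] <-
          cells[ga, as.character(b$group[i])] + 1
        n_shared <- n_shared + 1
      }
    }
    expect_equal(tr$n_shared, n_shared)
    expect_equal(as.vector(tr$table), as.vector(cells))
  }
})

test_that("the Mann-Whitney shift test matches exact small-sample
           enumeration", {
  res <- expression_shift_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 0)
  expect_true(res$exact)
  # identical samples
  same <- expression_shift_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  # label swap: same p, reflected U
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(0.4, 2.8, 6.3)
  r1 <- expression_shift_test(a, b)
  r2 <- expression_shift_test(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, length(a) * length(b) - r2$statistic)
})

test_that("planted activated transitions show the expected expression
           shift", {
  genes <- data.frame(gene_id = paste0("g", 1:300))
  plan <- data.frame(gene_id = genes$gene_id,
                     A = "G1",
                     B = rep(c("G2", "G1"), each = 150))
  ex <- simulate_expression(genes, plan, seed = 77)
  fpkm_b <- data.frame(gene_id = ex$fpkm$gene_id, fpkm = ex$fpkm$fpkm_B)
  up_genes <- genes$gene_id[plan$B == "G2"]
  stay_genes <- genes$gene_id[plan$B == "G1"]
  res <- expression_shift_test(up_genes, stay_genes, fpkm_b)
  expect_lt(res$p_value, 0.01)
  expect_gt(median(fpkm_b$fpkm[match(up_genes, fpkm_b$gene_id)]),
            median(fpkm_b$fpkm[match(stay_genes, fpkm_b$gene_id)]))
})
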