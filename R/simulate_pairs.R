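#' Write a synthetic valid-pairs file from contact matrices
#'
#' Emits one `.pairs`-convention record per simulated read pair. Cis
#' records are taken from the matrix counts with positions uniform within
#' bins; self-ligation records (same chromosome, separation below
#' `params$self_cutoff`) and uniform trans records are added so the
#' self/cis/trans composition matches `params$self_frac` /
#' `params$trans_frac` up to rounding. Output is sorted by `chrom1`,
#' `pos1` and parses back identically through [read_pairs()].
#'
#' @param matrices Named list of [contact_matrix()] objects (cis counts),
#'   as returned by [simulate_contact_map()].
#' @param params A [simulation_params()]; fractions, self cutoff and seed
#'   are taken from it.
#' @param path Output file path.
#' @param layout A [genome_layout()] covering the matrices (needed for
#'   chromosome lengths of self/trans records).
#' @return Invisibly, the written records as a `data.frame`.
#' @export
simulate_pairs_file <- function(matrices, params, path, layout) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(layout, "genome_layout"))
  if (inherits(matrices, "contact_matrix")) {
    matrices <- setNames(list(matrices), matrices$chrom)
  }
  cis_total <- sum(vapply(matrices, upper_tri_sum, numeric(1)))
  if (!is.finite(cis_total)) stop("matrix counts must be finite")
  cis_frac <- 1 - params$self_frac - params$trans_frac
  if (cis_frac <= 0) stop("cis fraction implied by params must be positive")
  n_self <- round(cis_total * params$self_frac / cis_frac)
  n_trans <- round(cis_total * params$trans_frac / cis_frac)
  if (n_trans > 0 && length(layout$chroms) < 2) {
    stop("trans pairs require at least two chromosomes")
  }

  with_seed(params$seed + 1L, {
    recs <- list()
    # cis: expand matrix counts into read pairs
    for (cm in matrices) {
      m <- cm$counts
      bs <- cm$bin_size
      up <- which(upper.tri(m, diag = TRUE) & m > 0, arr.ind = TRUE)
      if (nrow(up) == 0) next
      cnt <- m[up]
      i <- rep(up[, 1] - 1L, cnt)
      j <- rep(up[, 2] - 1L, cnt)
      L <- layout$lengths[[cm$chrom]]
      p1 <- i * bs + sample.int(bs, length(i), replace = TRUE)
      p2 <- j * bs + sample.int(bs, length(j), replace = TRUE)
      p1 <- pmin(p1, L); p2 <- pmin(p2, L)
      # keep cis records at or beyond the self cutoff so that read
      # classification is invertible on synthetic data
      short <- abs(p2 - p1) < params$self_cutoff
      if (any(short)) {
        lo <- pmin(p1[short], p2[short])
        p2[short] <- pmin(lo + params$self_cutoff, L)
        p1[short] <- pmax(p2[short] - params$self_cutoff, 1)
      }
      recs[[length(recs) + 1L]] <- data.frame(
        chrom1 = cm$chrom, pos1 = p1, chrom2 = cm$chrom, pos2 = p2)
    }
    # self: short-separation intra-chromosomal pairs
    if (n_self > 0) {
      w <- layout$lengths / sum(layout$lengths)
      ch <- sample(layout$chroms, n_self, replace = TRUE, prob = w)
      L <- layout$lengths[ch]
      sep <- sample.int(params$self_cutoff, n_self, replace = TRUE) - 1L
      p1 <- floor(runif(n_self, 1, pmax(2, L - sep)))
      recs[[length(recs) + 1L]] <- data.frame(
        chrom1 = ch, pos1 = p1, chrom2 = ch, pos2 = p1 + sep)
    }
    # trans: uniform inter-chromosomal pairs
    if (n_trans > 0) {
      w <- layout$lengths / sum(layout$lengths)
      c1 <- sample(layout$chroms, n_trans, replace = TRUE, prob = w)
      c2 <- vapply(c1, function(a) {
        sample(setdiff(layout$chroms, a), 1L)
      }, character(1))
      recs[[length(recs) + 1L]] <- data.frame(
        chrom1 = c1, pos1 = floor(runif(n_trans, 1, layout$lengths[c1] + 1)),
        chrom2 = c2, pos2 = floor(runif(n_trans, 1, layout$lengths[c2] + 1)))
    }
    out <- do.call(rbind, recs)
    n <- nrow(out)
    out$strand1 <- sample(c("+", "-"), n, replace = TRUE)
    out$strand2 <- sample(c("+", "-"), n, replace = TRUE)
    out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), ]
    out <- data.frame(read_id = sprintf("r%08d", seq_len(n)), out)
    rownames(out) <- NULL
    write_pairs(out, path)
    invisible(out)
  })
}

#' Write pair records in the text `.pairs` convention
#'
#' Columns: readID, chrom1, pos1, chrom2, pos2, strand1, strand2;
#' positions are 1-based. A `#columns:` header line is written.
#'
#' @param pairs `data.frame` with columns `read_id`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `strand1`, `strand2`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("## pairs format v1.0",
               "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2"),
             con)
  write.table(
    pairs[, c("read_id", "chrom1", "pos1", "chrom2", "pos2",
              "strand1", "strand2")],
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
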