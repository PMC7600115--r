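# Gaussian hidden Markov machinery for bias-state decoding of DI tracks.

# Scaled forward-backward for one sequence. Returns gamma (T x K state
# posteriors), xi_sum (K x K expected transition counts) and the
# log-likelihood.
.hmm_forward_backward <- function(x, init, trans, means, sds) {
  K <- length(init)
  Tn <- length(x)
  e <- vapply(seq_len(K), function(k) {
    stats::dnorm(x, means[k], sds[k])
  }, numeric(Tn))
  e <- matrix(pmax(e, 1e-300), Tn, K)
  alpha <- matrix(0, Tn, K)
  scale <- numeric(Tn)
  a <- init * e[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% trans) * e[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  for (t in (Tn - 1):1) {
    b <- trans %*% (e[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / scale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  for (t in seq_len(Tn - 1)) {
    xi <- (alpha[t, ] %o% (e[t + 1, ] * beta[t + 1, ])) * trans
    xi_sum <- xi_sum + xi / sum(xi)
  }
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(log(scale)))
}

# Baum-Welch EM over a list of sequences with shared parameters.
.hmm_em <- function(seqs, n_states = 3L, max_iter = 100L, tol = 1e-6) {
  all_x <- unlist(seqs, use.names = FALSE)
  s_all <- sd(all_x)
  sd_floor <- max(1e-8, 1e-3 * s_all)
  means <- as.numeric(quantile(all_x, seq(0.1, 0.9,
                                          length.out = n_states)))
  sds <- rep(max(s_all, sd_floor), n_states)
  init <- rep(1 / n_states, n_states)
  trans <- matrix(0.1 / (n_states - 1), n_states, n_states)
  diag(trans) <- 0.9
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    g_sum <- numeric(n_states)
    gx_sum <- numeric(n_states)
    gx2_sum <- numeric(n_states)
    init_sum <- numeric(n_states)
    xi_sum <- matrix(0, n_states, n_states)
    ll <- 0
    for (x in seqs) {
      if (length(x) < 2) {  # too short to inform transitions
        next
      }
      fb <- .hmm_forward_backward(x, init, trans, means, sds)
      ll <- ll + fb$loglik
      init_sum <- init_sum + fb$gamma[1, ]
      g_sum <- g_sum + colSums(fb$gamma)
      gx_sum <- gx_sum + colSums(fb$gamma * x)
      gx2_sum <- gx2_sum + colSums(fb$gamma * x^2)
      xi_sum <- xi_sum + fb$xi_sum
    }
    if (ll + 1e-6 * (1 + abs(ll)) < prev_ll) {
      stop(errorCondition(
        sprintf("EM log-likelihood decreased at iteration %d", iter),
        params = list(init = init, trans = trans, means = means,
                      sds = sds, loglik = prev_ll),
        class = c("tadir_em_error", "error", "condition")))
    }
    done <- is.finite(prev_ll) &&
      (ll - prev_ll) < tol * (1 + abs(prev_ll))
    prev_ll <- ll
    init <- init_sum / sum(init_sum)
    trans <- xi_sum / pmax(rowSums(xi_sum), 1e-300)
    means <- gx_sum / pmax(g_sum, 1e-300)
    sds <- pmax(sqrt(pmax(gx2_sum / pmax(g_sum, 1e-300) - means^2, 0)),
                sd_floor)
    if (done) break
  }
  list(init = init, trans = trans, means = means, sds = sds,
       loglik = prev_ll, iterations = iter)
}

#' Viterbi decoding of a Gaussian hidden Markov model
#'
#' Most-likely state path for one observation sequence under fixed
#' parameters. Exposed so that decoding can be run with externally
#' chosen parameters (e.g. on toy problems).
#'
#' @param x Numeric observation sequence.
#' @param init Initial state probabilities (length `K`).
#' @param trans `K x K` transition matrix (rows sum to 1).
#' @param means,sds Gaussian emission means and standard deviations.
#' @return Integer vector of decoded states in `1..K`.
#' @export
hmm_viterbi <- function(x, init, trans, means, sds) {
  K <- length(init)
  Tn <- length(x)
  loge <- vapply(seq_len(K), function(k) {
    stats::dnorm(x, means[k], sds[k], log = TRUE)
  }, numeric(Tn))
  loge <- matrix(loge, Tn, K)
  lt <- log(pmax(trans, 1e-300))
  delta <- log(pmax(init, 1e-300)) + loge[1, ]
  psi <- matrix(0L, Tn, K)
  if (Tn > 1) {
    for (t in 2:Tn) {
      cand <- delta + lt  # cand[j, k] = delta[j] + log trans[j -> k]
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[t, ], seq_len(K))] + loge[t, ]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) {
    for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  path
}

#' Fit a 3-state bias HMM to directionality-index tracks
#'
#' Trains a Gaussian hidden Markov model by expectation-maximization on
#' the DI values of all chromosomes jointly (masked bins split the
#' track into separate training sequences) and decodes the most-likely
#' state path per chromosome by Viterbi. States are relabeled post hoc
#' so the state with the highest emission mean is `D`
#' (downstream-biased), the lowest is `U` (upstream-biased) and the
#' middle is `N` (no bias).
#'
#' @param tracks A DI track from [directionality_index()], or a list of
#'   them (one per chromosome).
#' @param min_bins Minimum number of unmasked bins required genome-wide.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return An object of class `bias_path`: list with `states` (named
#'   list per chromosome of factors with levels `U`, `N`, `D`; `NA` on
#'   masked bins) and `params` (fitted HMM parameters on the relabeled
#'   state order `U`, `N`, `D`).
#' @export
fit_bias_hmm <- function(tracks, min_bins = 100L, max_iter = 100L,
                         tol = 1e-6) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  di_list <- lapply(tracks, function(tr) {
    stopifnot(all(c("chrom", "di") %in% names(tr)))
    tr
  })
  chroms <- vapply(di_list, function(tr) tr$chrom[1], character(1))
  names(di_list) <- chroms
  all_di <- unlist(lapply(di_list, `[[`, "di"), use.names = FALSE)
  n_ok <- sum(!is.na(all_di))
  if (n_ok < min_bins) {
    stop("need at least ", min_bins, " unmasked bins genome-wide")
  }
  levels3 <- c("U", "N", "D")
  # degenerate: constant DI carries no bias information
  if (sd(all_di, na.rm = TRUE) < 1e-12) {
    states <- lapply(di_list, function(tr) {
      f <- factor(ifelse(is.na(tr$di), NA, "N"), levels = levels3)
      f
    })
    return(structure(list(states = states, params = NULL),
                     class = "bias_path"))
  }
  # split each chromosome's track at masked bins into runs
  segments <- list()
  seg_where <- list()
  for (ch in chroms) {
    di <- di_list[[ch]]$di
    ok <- !is.na(di)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      segments[[length(segments) + 1L]] <- di[starts[k]:ends[k]]
      seg_where[[length(seg_where) + 1L]] <- list(chrom = ch,
                                                  from = starts[k],
                                                  to = ends[k])
    }
  }
  fit <- .hmm_em(segments, n_states = 3L, max_iter = max_iter, tol = tol)
  ord <- order(fit$means)  # lowest mean -> U, middle -> N, highest -> D
  relab <- integer(3)
  relab[ord] <- 1:3
  params <- list(init = fit$init[ord], trans = fit$trans[ord, ord],
                 means = fit$means[ord], sds = fit$sds[ord],
                 loglik = fit$loglik, iterations = fit$iterations)
  states <- lapply(di_list, function(tr) {
    factor(rep(NA_character_, nrow(tr)), levels = levels3)
  })
  names(states) <- chroms
  for (k in seq_along(segments)) {
    path <- hmm_viterbi(segments[[k]], fit$init, fit$trans, fit$means,
                        fit$sds)
    wh <- seg_where[[k]]
    states[[wh$chrom]][wh$from:wh$to] <- levels3[relab[path]]
  }
  structure(list(states = states, params = params), class = "bias_path")
}

#' @export
print.bias_path <- function(x, ...) {
  cat("bias_path:", length(x$states), "chromosome(s)\n")
  if (!is.null(x$params)) {
    cat("  emission means (U, N, D):",
        paste(signif(x$params$means, 4), collapse = ", "), "\n")
  }
  invisible(x)
}
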