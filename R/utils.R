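# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored afterwards, so simulation
# functions are deterministic without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Draw counts with variance = mean + phi * mean^2 (Poisson when phi = 0).
rnbinom_disp <- function(n, mu, phi) {
  if (phi == 0) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / phi)
  }
}

# Overlap length of half-open intervals [s1,e1) and [s2,e2).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
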