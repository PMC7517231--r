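# Naive scalar-loop oracles, deliberately independent of the package's
# vectorized and C++ code paths.

# Chebyshev template distance by explicit scalar loop.
oracle_cheb <- function(x, i, j, m, tau) {
  d <- 0
  for (k in seq_len(m)) {
    d <- max(d, abs(x[i + (k - 1) * tau] - x[j + (k - 1) * tau]))
  }
  d
}

# Ordered match count over the first `templates` start positions by a
# triple loop (pairs x coordinates).
oracle_matches <- function(x, m, tau, r, templates = NULL) {
  L <- if (is.null(templates)) length(x) - (m - 1) * tau else templates
  cnt <- 0L
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      if (oracle_cheb(x, i, j, m, tau) <= r) cnt <- cnt + 1L
    }
  }
  cnt
}

# Sign-change count by direct scan with explicit state.
oracle_sign_changes <- function(d, eps = 1e-12) {
  last <- 0
  changes <- 0L
  for (v in d) {
    if (is.na(v) || abs(v) <= eps) next
    s <- sign(v)
    if (last != 0 && s != last) changes <- changes + 1L
    last <- s
  }
  changes
}

rand_series <- function(n, seed) {
  set.seed(seed)
  round(stats::rnorm(n), 2)   # rounding creates occasional exact ties
}
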