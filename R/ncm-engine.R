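# Fast multi-threshold correlation sums. Instead of re-scanning all
# template pairs once per tolerance radius, every pair's Chebyshev
# distance is computed once and mapped arithmetically to its bin in a
# uniform threshold grid; cumulative bin counts then yield the full
# correlation-sum profile (and hence the whole SampEn profile) in a
# single pass, at a cost independent of the number of radii.

#' Uniform grid of tolerance radii
#'
#' @param r_min Smallest radius (>= 0).
#' @param r_max Largest radius (> `r_min`).
#' @param n Number of radii (>= 2), equally spaced from `r_min` to `r_max`.
#' @return A list of class `threshold_grid` with fields `r_min`, `r_max`,
#'   `n`, `step` and `radii`.
#' @examples
#' threshold_grid(0.02, 4, 200)
#' @export
threshold_grid <- function(r_min, r_max, n) {
  if (!is.numeric(r_min) || !is.numeric(r_max) || length(r_min) != 1L ||
      length(r_max) != 1L || is.na(r_min) || is.na(r_max) || r_min < 0 ||
      r_max <= r_min) {
    stop("need 0 <= r_min < r_max", call. = FALSE)
  }
  n <- check_count(n, "n", min = 2L)
  radii <- seq(r_min, r_max, length.out = n)
  structure(list(r_min = r_min, r_max = r_max, n = n,
                 step = (r_max - r_min) / (n - 1), radii = radii),
            class = "threshold_grid")
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf("<threshold_grid> %d radii in [%g, %g], step %g\n",
              x$n, x$r_min, x$r_max, x$step))
  invisible(x)
}

#' Triangular matrix of first-coordinate distances
#'
#' Stores the scalar distances `n[i, k] = |u(i) - u(i + k tau)|` for all
#' lag multiples `k >= 1`, each unordered pair once (store-once semantics
#' realize the symmetry halving of the conceptual full matrix). Chebyshev
#' distances between m-dimensional templates are maxima of `m` stored
#' entries, so the maximum norm costs m rather than m^2 scalar operations.
#'
#' This structure is the didactic/oracle form of the look-up-table engine;
#' [sampen_profile()] streams the same values without materializing them.
#'
#' @param x Numeric series (or [sampen_series]).
#' @param tau Time lag (>= 1).
#' @return A list of class `ncm_distance_matrix` with fields `diagonals`
#'   (element `k` holds `|u(i) - u(i + k tau)|` for all valid `i`), `N`
#'   and `tau`.
#' @examples
#' build_distance_matrix(c(1, 4, 2), tau = 1)
#' @export
build_distance_matrix <- function(x, tau = 1L) {
  tau <- check_count(tau, "tau", min = 1L)
  x <- as.numeric(x)
  N <- length(x)
  if (N < tau + 2L) {
    stop("insufficient data: need N >= tau + 2", call. = FALSE)
  }
  kmax <- (N - 1L) %/% tau
  diagonals <- lapply(seq_len(kmax), function(k) {
    i <- seq_len(N - k * tau)
    abs(x[i] - x[i + k * tau])
  })
  structure(list(diagonals = diagonals, N = N, tau = tau),
            class = "ncm_distance_matrix")
}

#' @export
print.ncm_distance_matrix <- function(x, ...) {
  cat(sprintf("<ncm_distance_matrix> N = %d, tau = %d, %d diagonals, %d entries\n",
              x$N, x$tau, length(x$diagonals),
              sum(lengths(x$diagonals))))
  invisible(x)
}

#' Template Chebyshev distance looked up from the distance matrix
#'
#' Returns the m-dimensional template distance between (1-based) start
#' positions `i` and `j` as the maximum of `m` stored scalar entries.
#' Only pairs whose index difference is a multiple of `tau` are
#' representable in the lag-`tau` matrix (for `tau = 1`, all pairs).
#'
#' @param dm An `ncm_distance_matrix` from [build_distance_matrix()].
#' @param i,j 1-based template start positions.
#' @param m Embedding dimension.
#' @return A single nonnegative number, equal to [chebyshev_distance()].
#' @export
template_distance_from_matrix <- function(dm, i, j, m) {
  stopifnot(inherits(dm, "ncm_distance_matrix"))
  m <- check_count(m, "m", min = 1L)
  if (i == j) return(0)
  lo <- min(i, j); hi <- max(i, j)
  if ((hi - lo) %% dm$tau != 0L) {
    stop("pair separation is not a multiple of tau; not representable",
         call. = FALSE)
  }
  k <- (hi - lo) %/% dm$tau
  if (lo < 1L || hi + (m - 1L) * dm$tau > dm$N) {
    stop("template out of bounds", call. = FALSE)
  }
  max(dm$diagonals[[k]][lo + (seq_len(m) - 1L) * dm$tau])
}

#' Full SampEn profile over a threshold grid (single-pass engine)
#'
#' Computes the correlation sums `C^m(r)` and `C^{m+1}(r)` and the Sample
#' Entropy `-ln(C^{m+1}/C^m)` at every radius of `grid` in one pass over
#' template pairs: each pair's distance is binned arithmetically into the
#' smallest grid index whose radius is `>= d` (boundary distances count as
#' matches, consistent with the `<=` convention); pairs beyond `r_max`
#' land in an overflow bin so the pair bookkeeping stays exact. Match
#' counts agree exactly (integer equality) with calling
#' [correlation_sum()] radius by radius.
#'
#' @inheritParams sample_entropy
#' @param grid A [threshold_grid()].
#' @return A data frame of class `sampen_profile` with columns `r`, `c_m`,
#'   `c_m1` and `sampen` (`NA` marks radii where either correlation sum is
#'   zero). Attributes: `counts` (a list with ordered match counts
#'   `match_m`, `match_m1`, denominators `pairs_m`, `pairs_m1`, and the
#'   overflow-bin pair counts), `m`, `tau`, `convention`, `grid`, and the
#'   input's `meta`.
#' @examples
#' x <- generate_mix(0.3, N = 400, seed = 11)
#' prof <- sampen_profile(x, m = 2, grid = threshold_grid(0.01, 4 * sd(x), 50))
#' head(prof)
#' @export
sampen_profile <- function(x, m, tau = 1L, grid,
                           convention = c("richman", "paper")) {
  convention <- match.arg(convention)
  cfg <- check_embedding(m, tau)
  if (!inherits(grid, "threshold_grid")) {
    stop("grid must be a threshold_grid", call. = FALSE)
  }
  meta <- series_meta(x)
  x <- as.numeric(x)
  N <- length(x)
  limit_m1 <- template_count(N, cfg$m + 1L, cfg$tau)
  if (limit_m1 < 2L) {
    stop("insufficient data for m+1 templates", call. = FALSE)
  }
  limit_m <- if (convention == "richman") limit_m1
             else template_count(N, cfg$m, cfg$tau)

  h <- ncm_pair_histogram(x, cfg$m, cfg$tau, grid$radii, limit_m, limit_m1)
  nbin <- grid$n
  match_m <- 2 * cumsum(h$hist_m[seq_len(nbin)])   # ordered pairs, <= r
  match_m1 <- 2 * cumsum(h$hist_m1[seq_len(nbin)])
  pairs_m <- as.numeric(limit_m) * (limit_m - 1)
  pairs_m1 <- as.numeric(limit_m1) * (limit_m1 - 1)

  c_m <- match_m / pairs_m
  c_m1 <- match_m1 / pairs_m1
  sampen <- ifelse(c_m > 0 & c_m1 > 0, -log(c_m1 / c_m), NA_real_)

  out <- data.frame(r = grid$radii, c_m = c_m, c_m1 = c_m1, sampen = sampen)
  structure(out,
            counts = list(match_m = match_m, match_m1 = match_m1,
                          pairs_m = pairs_m, pairs_m1 = pairs_m1,
                          overflow_m = 2 * h$hist_m[nbin + 1L],
                          overflow_m1 = 2 * h$hist_m1[nbin + 1L]),
            m = cfg$m, tau = cfg$tau, convention = convention, grid = grid,
            meta = meta,
            class = c("sampen_profile", "data.frame"))
}
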