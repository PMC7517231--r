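# Reference (brute-force) Sample Entropy machinery: delay embedding,
# Chebyshev template distances, correlation sums, and the finite-N SampEn
# estimator. This module is the correctness oracle for the fast
# look-up-table engine in ncm-engine.R.

# Number of m-dimensional templates available in a series of length N at
# lag tau: L_m = N - (m - 1) * tau.
template_count <- function(N, m, tau) N - (m - 1L) * tau

check_embedding <- function(m, tau) {
  m <- check_count(m, "m", min = 1L)
  tau <- check_count(tau, "tau", min = 1L)
  list(m = m, tau = tau)
}

#' Chebyshev distance between two embedded templates
#'
#' The m-dimensional template starting at (1-based) position `i` is
#' `(u(i), u(i + tau), ..., u(i + (m-1) tau))`. The distance between the
#' templates at `i` and `j` is the maximum absolute coordinate-wise
#' difference `max_k |u(i + (k-1) tau) - u(j + (k-1) tau)|`.
#'
#' @param x Numeric series (or [sampen_series]).
#' @param i,j 1-based start positions of the two templates.
#' @param m Embedding dimension (>= 1).
#' @param tau Time lag (>= 1, default 1).
#' @return A single nonnegative number.
#' @examples
#' chebyshev_distance(c(1, 2, 3, 5), 1, 3, m = 2)  # max(|1-3|, |2-5|) = 3
#' @export
chebyshev_distance <- function(x, i, j, m, tau = 1L) {
  cfg <- check_embedding(m, tau)
  x <- as.numeric(x)
  idx <- (seq_len(cfg$m) - 1L) * cfg$tau
  if (i < 1L || j < 1L || i + idx[cfg$m] > length(x) ||
      j + idx[cfg$m] > length(x)) {
    stop("template out of bounds", call. = FALSE)
  }
  max(abs(x[i + idx] - x[j + idx]))
}

# All unordered template pair distances as an L x L matrix (used by the
# brute-force correlation sum). templates limits the embedding to the
# first `templates` start positions.
template_distance_matrix <- function(x, m, tau, templates) {
  d <- abs(outer(x[seq_len(templates)], x[seq_len(templates)], "-"))
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      o <- k * tau
      sl <- seq_len(templates) + o
      d <- pmax(d, abs(outer(x[sl], x[sl], "-")))
    }
  }
  d
}

#' Correlation sum at a single tolerance radius (brute force)
#'
#' Fraction of ordered template pairs (self-matches excluded) whose
#' Chebyshev distance is less than or equal to `r`; equality counts as a
#' match (Heaviside convention `theta(0) = 1`).
#'
#' @param x Numeric series (or [sampen_series]).
#' @param m Embedding dimension.
#' @param tau Time lag (default 1).
#' @param r Tolerance radius, `r >= 0`, in absolute signal units.
#' @param templates Number of template start positions to use; defaults to
#'   all `N - (m-1) tau`. [sample_entropy()] uses this to restrict both
#'   the m- and (m+1)-dimensional sums to a common template set.
#' @return A list of class `correlation_result` with fields `r`,
#'   `match_count` (ordered pairs within `r`), `template_pairs` (ordered
#'   pairs considered) and `c_value = match_count / template_pairs`.
#' @examples
#' correlation_sum(c(0, 10, 0, 10, 0), m = 1, r = 1)$c_value  # 0.4
#' @export
correlation_sum <- function(x, m, tau = 1L, r, templates = NULL) {
  cfg <- check_embedding(m, tau)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0) {
    stop("r must be a single nonnegative number", call. = FALSE)
  }
  x <- as.numeric(x)
  L <- template_count(length(x), cfg$m, cfg$tau)
  if (!is.null(templates)) {
    templates <- check_count(templates, "templates", min = 2L)
    if (templates > L) stop("templates exceeds available count", call. = FALSE)
    L <- templates
  }
  if (L < 2L) {
    stop("insufficient data: fewer than 2 templates", call. = FALSE)
  }
  d <- template_distance_matrix(x, cfg$m, cfg$tau, L)
  matches <- sum(d <= r) - L         # remove the L self-matches on diagonal
  pairs <- as.numeric(L) * (L - 1)
  structure(
    list(r = r, match_count = as.integer(matches), template_pairs = pairs,
         c_value = matches / pairs),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("C(r = %g) = %d / %d = %.6g\n", x$r, x$match_count,
              x$template_pairs, x$c_value))
  invisible(x)
}

#' Sample Entropy at a single tolerance radius (brute force)
#'
#' `SampEn(m, r, N) = -ln( C^{m+1}(r) / C^m(r) )`: the negative logarithm
#' of the conditional probability that template pairs within `r` for `m`
#' points remain within `r` for `m + 1` points. When either correlation
#' sum is zero, the estimator is undefined and the value is `NA` (an
#' explicit undefined marker, not an error).
#'
#' Two template-count conventions are supported. Under `"richman"` (the
#' default, the classical estimator) both sums run over the first
#' `N - m tau` templates, so the ratio is a true conditional probability
#' and `C^{m+1} <= C^m` holds structurally. Under `"paper"` each dimension
#' uses all of its own `N - (m-1) tau` templates.
#'
#' @inheritParams correlation_sum
#' @param convention `"richman"` or `"paper"` (see Details).
#' @return A list of class `sampen_value` with fields `value` (`NA` when
#'   undefined), `c_m`, `c_m1`, `r`, `m`, `tau`, `convention`.
#' @examples
#' x <- generate_mix(0.5, N = 200, seed = 7)
#' sample_entropy(x, m = 2, r = 0.5)
#' @export
sample_entropy <- function(x, m, tau = 1L, r,
                           convention = c("richman", "paper")) {
  convention <- match.arg(convention)
  cfg <- check_embedding(m, tau)
  x <- as.numeric(x)
  N <- length(x)
  if (template_count(N, cfg$m + 1L, cfg$tau) < 2L) {
    stop("insufficient data for m+1 templates", call. = FALSE)
  }
  lim <- if (convention == "richman") N - cfg$m * cfg$tau else NULL
  cm <- correlation_sum(x, cfg$m, cfg$tau, r, templates = lim)
  cm1 <- correlation_sum(x, cfg$m + 1L, cfg$tau, r)
  value <- if (cm$c_value > 0 && cm1$c_value > 0) {
    -log(cm1$c_value / cm$c_value)
  } else {
    NA_real_
  }
  structure(
    list(value = value, c_m = cm$c_value, c_m1 = cm1$c_value, r = r,
         m = cfg$m, tau = cfg$tau, convention = convention),
    class = "sampen_value"
  )
}

#' @export
print.sampen_value <- function(x, ...) {
  v <- if (is.na(x$value)) "undefined (zero correlation sum)"
       else sprintf("%.7g", x$value)
  cat(sprintf("SampEn(m = %d, r = %g, tau = %d, %s) = %s\n",
              x$m, x$r, x$tau, x$convention, v))
  invisible(x)
}
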