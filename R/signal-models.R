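# Seeded surrogate-signal generators: deterministic sinusoid, MIX(p)
# (random replacement of sinusoid samples by uniform noise) and
# MIXTURE(lambda) (sinusoid plus bounded zero-mean uniform noise).

#' Construct a time series with provenance metadata
#'
#' Wraps a numeric vector as a `sampen_series`: a plain numeric vector
#' carrying a `meta` attribute that records how it was produced (process
#' name, tuning parameter, seed, sinusoid discretization). All entropy
#' functions in this package accept either a `sampen_series` or a bare
#' numeric vector.
#'
#' @param values Numeric vector of signal values; must be finite, length >= 2.
#' @param meta Named list of provenance fields (process, parameter, seed, ...).
#' @return A numeric vector of class `sampen_series` with a `meta` attribute.
#' @export
sampen_series <- function(values, meta = list(process = "external")) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a time series must contain at least 2 values", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("time series values must all be finite", call. = FALSE)
  }
  structure(values, meta = meta, class = c("sampen_series", "numeric"))
}

#' @export
print.sampen_series <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<sampen_series> N = %d, process = %s\n", length(x),
              if (is.null(meta$process)) "?" else meta$process))
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Provenance metadata of a series
#'
#' @param x A `sampen_series`.
#' @return The `meta` attribute (a list), or `NULL` for bare numerics.
#' @export
series_meta <- function(x) attr(x, "meta", exact = TRUE)

# Evaluate a closure with a private, seeded RNG stream, leaving the
# caller's .Random.seed untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

#' Deterministic sinusoid
#'
#' Generates `amplitude * sin(2*pi*j / samples_per_period)` for
#' `j = 0, ..., N-1` (0-based sample index). `samples_per_period = 2*pi`
#' recovers the undiscretized form `amplitude * sin(j)`.
#'
#' @param N Number of samples (>= 2).
#' @param samples_per_period Samples per full sinusoid period (> 0). The
#'   default, `10 * pi` (~31.4), is the unit-angular-rate sinusoid
#'   `sin(t)` sampled at 5 Hz; `2 * pi` gives the undiscretized `sin(j)`,
#'   and large values (e.g. 1000) give a densely sampled, nearly smooth
#'   wave.
#' @param amplitude Peak amplitude (default 2).
#' @return A [sampen_series].
#' @examples
#' generate_sinusoid(8, samples_per_period = 8)
#' @export
generate_sinusoid <- function(N, samples_per_period = 10 * pi, amplitude = 2) {
  N <- check_count(N, "N", min = 2L)
  if (!is.numeric(samples_per_period) || length(samples_per_period) != 1L ||
      !is.finite(samples_per_period) || samples_per_period <= 0) {
    stop("samples_per_period must be a single positive number", call. = FALSE)
  }
  j <- seq_len(N) - 1
  sampen_series(
    amplitude * sin(2 * pi * j / samples_per_period),
    meta = list(process = "sine", parameter = NA_real_, seed = NA_integer_,
                samples_per_period = samples_per_period, amplitude = amplitude)
  )
}

#' MIX(p) process: sinusoid with random uniform-noise replacement
#'
#' Each sample of the base sinusoid is independently replaced, with
#' probability `p`, by a draw from `Uniform(noise_low, noise_high)`:
#' `MIX(p)_j = (1 - Z_j) X_j + Z_j Y_j`, `Z_j ~ Bernoulli(p)`,
#' `Y_j ~ Uniform(noise_low, noise_high)`. The tuning parameter `p`
#' controls *how many* samples are random while the variance of a single
#' random insertion stays fixed.
#'
#' The Bernoulli and uniform variates are drawn interleaved per sample
#' from one seeded stream, so the output is reproducible regardless of
#' vectorization strategy, and the same seed yields bit-identical series.
#'
#' @param p Replacement probability in \[0, 1\].
#' @param N Number of samples (>= 2).
#' @param seed Integer seed for the private RNG stream.
#' @param noise_low,noise_high Bounds of the uniform replacement noise
#'   (defaults -3 and 3). The classical convention with noise variance 1
#'   is available as `noise_low = -sqrt(3), noise_high = sqrt(3)`.
#' @param samples_per_period,amplitude Passed to [generate_sinusoid()].
#' @return A [sampen_series].
#' @examples
#' x <- generate_mix(0.5, N = 100, seed = 1)
#' @export
generate_mix <- function(p, N, seed, noise_low = -3, noise_high = 3,
                         samples_per_period = 10 * pi, amplitude = 2) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(noise_low) || !is.numeric(noise_high) ||
      noise_low >= noise_high) {
    stop("noise_low must be strictly less than noise_high", call. = FALSE)
  }
  x <- as.numeric(generate_sinusoid(N, samples_per_period, amplitude))
  n <- length(x)
  u <- with_seed(seed, stats::runif(2L * n))
  z <- u[seq(1L, 2L * n, by = 2L)] < p          # Bernoulli(p) via inversion
  y <- noise_low + (noise_high - noise_low) * u[seq(2L, 2L * n, by = 2L)]
  out <- ifelse(z, y, x)
  sampen_series(out, meta = list(
    process = "mix", parameter = p, seed = as.integer(seed),
    samples_per_period = samples_per_period, amplitude = amplitude,
    noise_low = noise_low, noise_high = noise_high
  ))
}

#' MIXTURE(lambda) process: sinusoid plus bounded uniform noise
#'
#' Adds zero-mean uniform noise of total width `lambda` to every sample:
#' `MIXTURE(lambda)_j = X_j + lambda * (Z_j - 0.5)`, `Z_j ~ Uniform(0, 1)`.
#' Here every sample carries a random contribution and `lambda` controls
#' *how large* it is; the residual `output - sinusoid` is bounded by
#' `lambda / 2` in absolute value.
#'
#' @param lam Noise width `lambda` (>= 0).
#' @param N Number of samples (>= 2).
#' @param seed Integer seed for the private RNG stream.
#' @param samples_per_period,amplitude Passed to [generate_sinusoid()].
#' @return A [sampen_series].
#' @examples
#' x <- generate_mixture(0.6, N = 100, seed = 1)
#' @export
generate_mixture <- function(lam, N, seed, samples_per_period = 10 * pi,
                             amplitude = 2) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0) {
    stop("lam must be a single nonnegative number", call. = FALSE)
  }
  x <- as.numeric(generate_sinusoid(N, samples_per_period, amplitude))
  z <- with_seed(seed, stats::runif(length(x)))
  sampen_series(x + lam * (z - 0.5), meta = list(
    process = "mixture", parameter = lam, seed = as.integer(seed),
    samples_per_period = samples_per_period, amplitude = amplitude
  ))
}

# Shared validator for positive integer-valued scalars.
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("%s must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}
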