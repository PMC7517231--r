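# Relative-consistency experiment: replicate generation, mean SampEn
# profiles per tuning-parameter level, crossing detection between profiles
# by sign-change bracketing, and mapping of the consistency region in
# (r, parameter) space.
#
# SampEn is relatively consistent between two processes when the ordering
# of their entropies at one (m, r) holds at every other (m, r). A crossing
# of two entropy profiles is a direct violation of that property.

#' Specification of a profile-crossing experiment
#'
#' Bundles everything needed to reproduce a multi-level entropy-profile
#' experiment: the process, its tuning-parameter levels, replicate count,
#' series length, embedding, threshold grid and seeding scheme.
#'
#' Profiles are computed per replicate on that replicate's own grid of
#' `n_r` radii spanning `(0, r_max_sd * SD]` where SD is the replicate's
#' sample standard deviation (`grid_mode = "per_signal_sd"`, the default);
#' profiles are then averaged and compared on the shared normalized `r/SD`
#' axis, which is the axis on which tolerance radii of signals with
#' different variances are conventionally compared. Alternatively
#' (`grid_mode = "absolute"`) one shared absolute grid
#' `[r_max_sd * SD_max / n_r, r_max_sd * SD_max]` is used, where `SD_max`
#' is the largest per-level standard deviation measured on a long
#' calibration realization.
#'
#' Replicate `k` (1-based) at level index `l` (0-based) uses seed
#' `base_seed + l * 1e6 + k`, so levels differ in their noise
#' realizations; with `paired_noise = TRUE` the level term is dropped and
#' all levels share noise streams, reducing comparison variance.
#'
#' @param process `"mix"` or `"mixture"`.
#' @param levels Ordered vector of tuning-parameter values (p or lambda).
#' @param replicates Signals generated per level (>= 1).
#' @param N Samples per signal.
#' @param m Embedding dimension (default 1: template pairs of single
#'   points extended to 2-point templates, `-ln(C^2/C^1)`). Note that some
#'   SampEn software labels this same quantity by the extended dimension,
#'   i.e. calls it m = 2.
#' @param tau Time lag (default 1).
#' @param n_r Number of threshold radii (default 200).
#' @param r_max_sd Upper end of the grid in SD multiples (default 4).
#' @param base_seed Integer seed from which all replicate seeds derive.
#' @param convention Template-count convention, see [sample_entropy()].
#' @param grid_mode `"per_signal_sd"` (default) or `"absolute"`.
#' @param average `"sampen"` (default; mean of per-replicate SampEn values,
#'   undefined values excluded pointwise) or `"csum"` (mean the
#'   correlation sums first, then take `-ln` of their ratio).
#' @param paired_noise Share noise seeds across levels (default `FALSE`).
#' @param noise_low,noise_high MIX replacement-noise bounds (default -3, 3).
#' @param samples_per_period,amplitude Sinusoid discretization, see
#'   [generate_sinusoid()].
#' @param eps Differences with absolute value below `eps` are numerical
#'   ties, never crossings (default 1e-12).
#' @return A list of class `experiment_spec`.
#' @examples
#' spec <- experiment_spec("mix", levels = c(0.8, 0.9), replicates = 2,
#'                         N = 500, base_seed = 1)
#' @export
experiment_spec <- function(process = c("mix", "mixture"), levels,
                            replicates, N, m = 1L, tau = 1L, n_r = 200L,
                            r_max_sd = 4, base_seed = 1L,
                            convention = c("richman", "paper"),
                            grid_mode = c("per_signal_sd", "absolute"),
                            average = c("sampen", "csum"),
                            paired_noise = FALSE,
                            noise_low = -3, noise_high = 3,
                            samples_per_period = 10 * pi, amplitude = 2,
                            eps = 1e-12) {
  process <- match.arg(process)
  if (!is.numeric(levels) || length(levels) < 1L || anyNA(levels)) {
    stop("levels must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(duplicated(levels))) {
    stop("levels must be distinct", call. = FALSE)
  }
  if (process == "mix" && any(levels < 0 | levels > 1)) {
    stop("MIX levels must lie in [0, 1]", call. = FALSE)
  }
  if (process == "mixture" && any(levels < 0)) {
    stop("MIXTURE levels must be nonnegative", call. = FALSE)
  }
  spec <- list(
    process = process, levels = as.numeric(levels),
    replicates = check_count(replicates, "replicates", 1L),
    N = check_count(N, "N", 2L),
    m = check_count(m, "m", 1L), tau = check_count(tau, "tau", 1L),
    n_r = check_count(n_r, "n_r", 2L), r_max_sd = r_max_sd,
    base_seed = as.integer(base_seed),
    convention = match.arg(convention), grid_mode = match.arg(grid_mode),
    average = match.arg(average), paired_noise = isTRUE(paired_noise),
    noise_low = noise_low, noise_high = noise_high,
    samples_per_period = samples_per_period, amplitude = amplitude,
    eps = eps
  )
  class(spec) <- "experiment_spec"
  spec
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> %s, %d levels x %d replicates, N = %d, m = %d, tau = %d\n",
              x$process, length(x$levels), x$replicates, x$N, x$m, x$tau))
  cat(sprintf("  grid: %d radii to %g SD (%s), convention %s, base seed %d\n",
              x$n_r, x$r_max_sd, x$grid_mode, x$convention, x$base_seed))
  invisible(x)
}

replicate_seed <- function(spec, level_index0, k) {
  lvl_term <- if (spec$paired_noise) 0L else level_index0 * 1000000L
  spec$base_seed + lvl_term + k
}

generate_level_series <- function(spec, level, seed) {
  switch(spec$process,
    mix = generate_mix(level, spec$N, seed,
                       noise_low = spec$noise_low,
                       noise_high = spec$noise_high,
                       samples_per_period = spec$samples_per_period,
                       amplitude = spec$amplitude),
    mixture = generate_mixture(level, spec$N, seed,
                               samples_per_period = spec$samples_per_period,
                               amplitude = spec$amplitude)
  )
}

# Shared absolute grid for grid_mode = "absolute": one long calibration
# realization per level (seed = base_seed + l * 1e6), SD_max across levels.
calibration_sd_max <- function(spec, n_cal = max(spec$N, 20000L)) {
  sds <- vapply(seq_along(spec$levels), function(li) {
    sp <- spec
    sp$N <- n_cal
    stats::sd(generate_level_series(sp, spec$levels[li],
                                    replicate_seed(spec, li - 1L, 0L)))
  }, numeric(1))
  max(sds)
}

experiment_grid <- function(spec) {
  rho <- seq(spec$r_max_sd / spec$n_r, spec$r_max_sd, length.out = spec$n_r)
  if (spec$grid_mode == "per_signal_sd") {
    list(rho = rho, sd_max = NA_real_, r_units = "sd")
  } else {
    sd_max <- calibration_sd_max(spec)
    list(rho = rho * sd_max, sd_max = sd_max, r_units = "absolute")
  }
}

#' Mean entropy profile at one tuning-parameter level
#'
#' Generates `spec$replicates` seeded realizations at `level`, computes
#' each SampEn profile with the single-pass engine, and returns the
#' pointwise mean profile. Undefined SampEn values (zero correlation sums,
#' typical at the smallest radii) are excluded pointwise; the number of
#' replicates contributing at each radius is recorded in `n_defined`, and
#' radii where all replicates are undefined stay `NA`.
#'
#' @param spec An [experiment_spec()].
#' @param level A value from `spec$levels`.
#' @param grid_info Optional precomputed shared-grid info (used internally
#'   by [run_experiment()] so the absolute-grid calibration runs once).
#' @return A `sampen_profile` data frame with columns `r` (normalized
#'   `r/SD` units under `grid_mode = "per_signal_sd"`, absolute units
#'   otherwise), `c_m`, `c_m1`, `sampen`, `n_defined`; attribute `level`.
#' @export
mean_profile <- function(spec, level, grid_info = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  li <- match(level, spec$levels)
  if (is.na(li)) stop("level is not one of spec$levels", call. = FALSE)
  if (is.null(grid_info)) grid_info <- experiment_grid(spec)
  rho <- grid_info$rho

  se_sum <- numeric(spec$n_r)
  se_n <- integer(spec$n_r)
  cm_acc <- numeric(spec$n_r)
  cm1_acc <- numeric(spec$n_r)

  for (k in seq_len(spec$replicates)) {
    x <- generate_level_series(spec, level, replicate_seed(spec, li - 1L, k))
    radii <- if (grid_info$r_units == "sd") rho * stats::sd(x) else rho
    grid <- threshold_grid(radii[1], radii[spec$n_r], spec$n_r)
    prof <- sampen_profile(x, spec$m, spec$tau, grid, spec$convention)
    cm_acc <- cm_acc + prof$c_m
    cm1_acc <- cm1_acc + prof$c_m1
    ok <- !is.na(prof$sampen)
    se_sum[ok] <- se_sum[ok] + prof$sampen[ok]
    se_n <- se_n + ok
  }

  c_m <- cm_acc / spec$replicates
  c_m1 <- cm1_acc / spec$replicates
  sampen <- if (spec$average == "sampen") {
    ifelse(se_n > 0, se_sum / pmax(se_n, 1L), NA_real_)
  } else {
    ifelse(c_m > 0 & c_m1 > 0, -log(c_m1 / c_m), NA_real_)
  }

  out <- data.frame(r = rho, c_m = c_m, c_m1 = c_m1, sampen = sampen,
                    n_defined = se_n)
  structure(out, level = level, r_units = grid_info$r_units,
            m = spec$m, tau = spec$tau, convention = spec$convention,
            replicates = spec$replicates,
            class = c("sampen_profile", "data.frame"))
}

#' Run a full multi-level profile experiment
#'
#' Computes the mean entropy profile at every level of `spec` on a shared
#' comparison axis.
#'
#' @param spec An [experiment_spec()].
#' @return A list of class `entropy_experiment` with fields `spec`,
#'   `r` (shared radii axis), `r_units`, `sd_max` (absolute mode only) and
#'   `profiles` (named list of mean profiles, one per level).
#' @examples
#' spec <- experiment_spec("mixture", levels = c(0.1, 0.9), replicates = 2,
#'                         N = 400, n_r = 50, base_seed = 3)
#' exp <- run_experiment(spec)
#' crossing_table(exp)
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  gi <- experiment_grid(spec)
  profiles <- lapply(spec$levels, function(lv) mean_profile(spec, lv, gi))
  names(profiles) <- format_level(spec$levels)
  structure(list(spec = spec, r = gi$rho, r_units = gi$r_units,
                 sd_max = gi$sd_max, profiles = profiles),
            class = "entropy_experiment")
}

format_level <- function(x) formatC(x, format = "fg", digits = 8, width = 1L)

#' @export
print.entropy_experiment <- function(x, ...) {
  cat(sprintf("<entropy_experiment> %s, levels: %s\n", x$spec$process,
              paste(names(x$profiles), collapse = ", ")))
  cat(sprintf("  %d radii (%s units), %d replicates per level\n",
              length(x$r), x$r_units, x$spec$replicates))
  invisible(x)
}

#' Count strict sign changes in a difference sequence
#'
#' Counts adjacent transitions between strictly positive and strictly
#' negative values. `NA` entries and values with `|d| <= eps` (exact zeros
#' and numerical ties) are transparent: a zero between opposite signs
#' contributes one change, a zero between equal signs contributes none.
#'
#' @param d Numeric vector (differences of two profiles), may contain `NA`.
#' @param eps Tie tolerance (default 1e-12).
#' @return Integer number of sign changes.
#' @examples
#' count_sign_changes(c(1, -1, 1))   # 2
#' count_sign_changes(c(1, 0, -1))   # 1
#' @export
count_sign_changes <- function(d, eps = 1e-12) {
  s <- sign(d[!is.na(d) & abs(d) > eps])
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Locate and interpolate crossings between two entropy profiles
#'
#' Scans the difference of the two SampEn profiles for strict sign changes
#' (`NA`s and ties below `eps` are transparent, as in
#' [count_sign_changes()]) and linearly interpolates both profiles inside
#' each bracket to localize the intersection.
#'
#' @param profile_a,profile_b `sampen_profile` data frames on an identical
#'   `r` axis (e.g. two [mean_profile()] results from one experiment).
#' @param eps Tie tolerance (default 1e-12).
#' @return A data frame of class `crossing_records` with one row per
#'   crossing, ordered by `r_cross`: columns `level_a`, `level_b`,
#'   `r_cross`, `sampen_cross`, `bracket_lo`, `bracket_hi`.
#' @examples
#' g <- threshold_grid(0, 1, 11)
#' a <- data.frame(r = g$radii, sampen = rep(1, 11))
#' b <- data.frame(r = g$radii, sampen = seq(0, 2, length.out = 11))
#' locate_crossings(a, b)  # one crossing at r = 0.5, SampEn = 1
#' @export
locate_crossings <- function(profile_a, profile_b, eps = 1e-12) {
  ra <- profile_a$r; rb <- profile_b$r
  if (length(ra) != length(rb) || max(abs(ra - rb)) > 0) {
    stop("profiles must share an identical radii grid", call. = FALSE)
  }
  la <- attr(profile_a, "level"); lb <- attr(profile_b, "level")
  if (is.null(la)) la <- NA_real_
  if (is.null(lb)) lb <- NA_real_

  d <- profile_a$sampen - profile_b$sampen
  idx <- which(!is.na(d) & abs(d) > eps)
  rec <- list()
  if (length(idx) >= 2L) {
    for (t in seq_len(length(idx) - 1L)) {
      i1 <- idx[t]; i2 <- idx[t + 1L]
      if (sign(d[i1]) == sign(d[i2])) next
      w <- d[i1] / (d[i1] - d[i2])       # root of the interpolated difference
      r_cross <- ra[i1] + w * (ra[i2] - ra[i1])
      s_cross <- profile_a$sampen[i1] +
        w * (profile_a$sampen[i2] - profile_a$sampen[i1])
      rec[[length(rec) + 1L]] <- data.frame(
        level_a = la, level_b = lb, r_cross = r_cross,
        sampen_cross = s_cross, bracket_lo = ra[i1], bracket_hi = ra[i2])
    }
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(level_a = numeric(), level_b = numeric(),
               r_cross = numeric(), sampen_cross = numeric(),
               bracket_lo = numeric(), bracket_hi = numeric())
  out <- out[order(out$r_cross), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("crossing_records", "data.frame")
  out
}

#' Crossing report for all level pairs of an experiment
#'
#' Applies [locate_crossings()] to every unordered pair of mean profiles.
#' An empty result means the process is relatively consistent over the
#' studied grid: no pair of entropy profiles ever reverses its ordering.
#'
#' @param experiment An `entropy_experiment` from [run_experiment()].
#' @param eps Tie tolerance (default: the spec's `eps`).
#' @return A `crossing_records` data frame (zero rows when there are no
#'   crossings).
#' @export
crossing_table <- function(experiment, eps = NULL) {
  stopifnot(inherits(experiment, "entropy_experiment"))
  if (is.null(eps)) eps <- experiment$spec$eps
  levels <- experiment$spec$levels
  recs <- list()
  n <- length(levels)
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        recs[[length(recs) + 1L]] <- locate_crossings(
          experiment$profiles[[a]], experiment$profiles[[b]], eps)
      }
    }
  }
  empty <- data.frame(level_a = numeric(), level_b = numeric(),
                      r_cross = numeric(), sampen_cross = numeric(),
                      bracket_lo = numeric(), bracket_hi = numeric())
  out <- do.call(rbind, c(list(empty), recs))
  rownames(out) <- NULL
  class(out) <- c("crossing_records", "data.frame")
  out
}

#' Map the relative-consistency region of an experiment
#'
#' For every radius of the shared grid, a cell `(r, level)` is consistent
#' when every pair of mean profiles involving that level has the same
#' ordering at `r` as at the pair's reference radius — the smallest radius
#' at which both profiles are defined. Ties (differences below `eps`) and
#' radii where a profile is undefined cannot witness an order reversal and
#' count as consistent.
#'
#' @param experiment An `entropy_experiment`, or an [experiment_spec()]
#'   (which is then run).
#' @param eps Tie tolerance (default: the spec's `eps`).
#' @return A list of class `consistency_region` with fields `axis_r`,
#'   `axis_level` and `consistent` (logical matrix, radii x levels).
#' @export
consistency_region <- function(experiment, eps = NULL) {
  if (inherits(experiment, "experiment_spec")) {
    experiment <- run_experiment(experiment)
  }
  stopifnot(inherits(experiment, "entropy_experiment"))
  if (is.null(eps)) eps <- experiment$spec$eps
  levels <- experiment$spec$levels
  n_lvl <- length(levels)
  if (n_lvl < 2L) stop("need at least 2 levels", call. = FALSE)
  n_r <- length(experiment$r)

  consistent <- matrix(TRUE, n_r, n_lvl,
                       dimnames = list(NULL, format_level(levels)))
  for (a in seq_len(n_lvl - 1L)) {
    for (b in seq((a + 1L), n_lvl)) {
      d <- experiment$profiles[[a]]$sampen - experiment$profiles[[b]]$sampen
      defined <- which(!is.na(d) & abs(d) > eps)
      if (!length(defined)) next
      s_ref <- sign(d[defined[1L]])
      bad <- !is.na(d) & abs(d) > eps & sign(d) != s_ref
      consistent[bad, a] <- FALSE
      consistent[bad, b] <- FALSE
    }
  }
  structure(list(axis_r = experiment$r, axis_level = levels,
                 consistent = consistent, r_units = experiment$r_units),
            class = "consistency_region")
}

#' @export
print.consistency_region <- function(x, ...) {
  frac <- mean(x$consistent)
  cat(sprintf("<consistency_region> %d radii x %d levels, %.1f%% consistent\n",
              length(x$axis_r), length(x$axis_level), 100 * frac))
  invisible(x)
}
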