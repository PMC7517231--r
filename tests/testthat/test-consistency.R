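spec_smoke <- function(process = "mix", levels = c(0.2, 0.8), replicates = 2,
                       N = 300, n_r = 40, ...) {
  experiment_spec(process, levels = levels, replicates = replicates, N = N,
                  n_r = n_r, base_seed = 123, ...)
}

test_that("count_sign_changes follows the zero-transparency rule", {
  expect_identical(count_sign_changes(c(1, -1, 1)), 2L)
  expect_identical(count_sign_changes(c(1, 0, -1)), 1L)
  expect_identical(count_sign_changes(c(1, 0, 1)), 0L)
  expect_identical(count_sign_changes(c(NA, 1, NA, -1)), 1L)
  expect_identical(count_sign_changes(numeric(0)), 0L)
  expect_identical(count_sign_changes(c(0, 0, 0)), 0L)

  set.seed(31)
  for (rep in 1:200) {
    d <- sample(c(-1, 0, 1, NA), 25, replace = TRUE)
    expect_identical(count_sign_changes(d), oracle_sign_changes(d))
  }
})

test_that("locate_crossings solves the linear test case exactly", {
  g <- threshold_grid(0, 1, 11)
  a <- structure(data.frame(r = g$radii, sampen = rep(1, 11)),
                 level = 1, class = c("sampen_profile", "data.frame"))
  b <- structure(data.frame(r = g$radii, sampen = seq(0, 2, length.out = 11)),
                 level = 2, class = c("sampen_profile", "data.frame"))
  cr <- locate_crossings(a, b)
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$r_cross, 0.5)
  expect_equal(cr$sampen_cross, 1)
  expect_equal(cr$level_a, 1)
  expect_equal(cr$level_b, 2)
  expect_true(cr$bracket_lo <= cr$r_cross && cr$r_cross <= cr$bracket_hi)

  # identical profiles: no crossings
  expect_equal(nrow(locate_crossings(a, a)), 0L)

  # symmetry in the argument order
  cr2 <- locate_crossings(b, a)
  expect_equal(cr2$r_cross, cr$r_cross)
  expect_equal(cr2$sampen_cross, cr$sampen_cross)

  bad <- data.frame(r = g$radii + 1, sampen = rep(1, 11))
  expect_error(locate_crossings(a, bad), "identical radii")
})

test_that("mean_profile averages SampEn pointwise with undefined exclusion", {
  spec1 <- spec_smoke(replicates = 1)
  single <- mean_profile(spec1, 0.8)
  # replicates = 1: mean profile equals the lone replicate's profile
  x <- generate_mix(0.8, 300, seed = 123 + 1e6 + 1)
  rho <- single$r
  g <- threshold_grid(rho[1] * sd(x), rho[length(rho)] * sd(x), length(rho))
  direct <- sampen_profile(x, spec1$m, spec1$tau, g)
  expect_equal(single$sampen, direct$sampen)
  expect_equal(single$c_m, direct$c_m)
  expect_true(all(single$n_defined %in% 0:1))

  # paired-noise mode shares replicate seeds across levels
  specp <- spec_smoke(levels = c(0.3, 0.7), replicates = 2,
                      paired_noise = TRUE)
  x3 <- generate_mix(0.3, 300, seed = 123 + 1)
  x7 <- generate_mix(0.7, 300, seed = 123 + 1)
  sine <- as.numeric(generate_sinusoid(300))
  # nested Bernoulli coupling: every sample replaced at p = 0.3 is also
  # replaced (with the same value) at p = 0.7
  sub3 <- which(as.numeric(x3) != sine)
  expect_true(all(as.numeric(x7)[sub3] == as.numeric(x3)[sub3]))
})

test_that("zero-noise MIX and MIXTURE levels give identical mean profiles", {
  sm <- experiment_spec("mix", levels = c(0, 0.5), replicates = 2, N = 300,
                        n_r = 30, base_seed = 9)
  sx <- experiment_spec("mixture", levels = c(0, 0.5), replicates = 2, N = 300,
                        n_r = 30, base_seed = 9)
  pm <- mean_profile(sm, 0)
  px <- mean_profile(sx, 0)
  expect_identical(pm$sampen, px$sampen)
  expect_identical(pm$c_m, px$c_m)
})

test_that("crossing_table is symmetric-complete and respects replicate scaling", {
  spec <- spec_smoke(levels = c(0.1, 0.9), replicates = 3, N = 400)
  exp <- run_experiment(spec)
  ct <- crossing_table(exp)
  expect_s3_class(ct, "crossing_records")
  expect_true(all(c("level_a", "level_b", "r_cross", "sampen_cross")
                  %in% names(ct)))
  # crossings from the pair's two orderings coincide
  cr_ab <- locate_crossings(exp$profiles[[1]], exp$profiles[[2]])
  cr_ba <- locate_crossings(exp$profiles[[2]], exp$profiles[[1]])
  expect_equal(cr_ab$r_cross, cr_ba$r_cross)
})

test_that("MIXTURE mean profiles are ordered by lambda at every defined radius", {
  spec <- experiment_spec("mixture", levels = c(0.1, 0.9), replicates = 3,
                          N = 2000, n_r = 100, base_seed = 4)
  exp <- run_experiment(spec)
  lo <- exp$profiles[["0.1"]]$sampen
  hi <- exp$profiles[["0.9"]]$sampen
  ok <- !is.na(lo) & !is.na(hi)
  expect_gt(mean(ok), 0.8)
  expect_true(all(lo[ok] <= hi[ok]))
})

test_that("consistency_region marks identical-ordering cells consistent", {
  spec <- experiment_spec("mixture", levels = c(0.2, 0.6, 1.0), replicates = 2,
                          N = 800, n_r = 50, base_seed = 21)
  exp <- run_experiment(spec)
  region <- consistency_region(exp)
  expect_equal(dim(region$consistent), c(50L, 3L))
  # an experiment compared against itself is consistent everywhere
  expect_true(all(consistency_region(exp)$consistent ==
                  region$consistent))
  expect_error(consistency_region(
    run_experiment(experiment_spec("mix", levels = 0.5, replicates = 1,
                                   N = 200, n_r = 20, base_seed = 1))),
    "at least 2 levels")
})

test_that("experiment_spec validates inputs", {
  expect_error(experiment_spec("mix", levels = c(0.5, 1.2), replicates = 1,
                               N = 100), "\\[0, 1\\]")
  expect_error(experiment_spec("mixture", levels = -1, replicates = 1,
                               N = 100), "nonnegative")
  expect_error(experiment_spec("mix", levels = c(0.5, 0.5), replicates = 1,
                               N = 100), "distinct")
  expect_error(mean_profile(spec_smoke(), 0.55), "not one of")
})
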