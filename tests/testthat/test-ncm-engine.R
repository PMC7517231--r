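test_that("threshold_grid validates and spaces radii uniformly", {
  g <- threshold_grid(0.02, 4, 200)
  expect_equal(g$radii[1], 0.02)
  expect_equal(g$radii[200], 4)
  expect_equal(length(g$radii), 200L)
  expect_true(all(diff(g$radii) > 0))
  expect_equal(max(abs(diff(g$radii) - g$step)), 0, tolerance = 1e-12)
  expect_error(threshold_grid(1, 1, 10), "r_min < r_max")
  expect_error(threshold_grid(-1, 1, 10), "r_min")
  expect_error(threshold_grid(0, 1, 1), "integer >= 2")
})

test_that("distance matrix stores each scalar pair distance once", {
  dm <- build_distance_matrix(c(1, 4, 2), tau = 1)
  expect_equal(sort(unlist(dm$diagonals)), c(1, 2, 3))  # |1-4|,|1-2|,|4-2|

  dm0 <- build_distance_matrix(rep(3, 10), tau = 2)
  expect_true(all(unlist(dm0$diagonals) == 0))

  x <- rand_series(50, seed = 4)
  dm2 <- build_distance_matrix(x, tau = 2)
  for (k in seq_along(dm2$diagonals)) {
    i <- seq_len(50 - 2 * k)
    expect_identical(dm2$diagonals[[k]], abs(x[i] - x[i + 2 * k]))
  }
  expect_error(build_distance_matrix(c(1, 2), tau = 1), "insufficient")
})

test_that("template distances from the matrix equal the direct Chebyshev form", {
  x <- rand_series(40, seed = 5)
  for (tau in 1:2) {
    dm <- build_distance_matrix(x, tau = tau)
    for (m in 1:3) {
      L <- 40 - (m - 1) * tau
      for (i in seq_len(L)) {
        for (j in seq_len(L)) {
          if ((abs(j - i)) %% tau != 0) next
          expect_identical(template_distance_from_matrix(dm, i, j, m),
                           if (i == j) 0 else chebyshev_distance(x, i, j, m, tau))
        }
      }
    }
  }
  dm <- build_distance_matrix(x, tau = 2)
  expect_error(template_distance_from_matrix(dm, 1, 5, m = 30), "out of bounds")
  expect_error(template_distance_from_matrix(dm, 1, 2, m = 2), "not representable")
})

test_that("profile engine agrees exactly with per-radius brute force", {
  x <- generate_mix(0.3, 400, seed = 13)
  grid <- threshold_grid(0.01, 4 * sd(x), 50)
  for (conv in c("richman", "paper")) {
    prof <- sampen_profile(x, m = 2, grid = grid, convention = conv)
    counts <- attr(prof, "counts")
    lim <- if (conv == "richman") 398L else NULL
    for (k in seq(1, 50, by = 7)) {
      cm <- correlation_sum(x, 2, 1, grid$radii[k], templates = lim)
      cm1 <- correlation_sum(x, 3, 1, grid$radii[k])
      expect_identical(as.integer(counts$match_m[k]), cm$match_count)
      expect_identical(as.integer(counts$match_m1[k]), cm1$match_count)
      expect_equal(prof$c_m[k], cm$c_value)
      expect_equal(prof$c_m1[k], cm1$c_value)
    }
  }
})

test_that("profile engine matches brute force over random configurations", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(30:120, 1)
    x <- rand_series(n, seed = 400 + rep)
    m <- sample(1:3, 1); tau <- sample(1:2, 1)
    if (n - (m + 1 - 1) * tau < 2) next
    grid <- threshold_grid(runif(1, 0, 0.1), runif(1, 2, 6), sample(5:40, 1))
    prof <- sampen_profile(x, m, tau, grid)
    counts <- attr(prof, "counts")
    lim <- n - m * tau
    for (k in seq_len(grid$n)) {
      expect_identical(as.integer(counts$match_m[k]),
                       correlation_sum(x, m, tau, grid$radii[k],
                                       templates = lim)$match_count)
      expect_identical(as.integer(counts$match_m1[k]),
                       correlation_sum(x, m + 1L, tau,
                                       grid$radii[k])$match_count)
    }
  }
})

test_that("boundary distances land in the correct bin (theta(0) = 1)", {
  # series engineered so one pair sits exactly at a grid radius
  grid <- threshold_grid(0.5, 2.5, 5)     # radii 0.5 1.0 1.5 2.0 2.5
  x <- c(0, 1.5, 10, 11.5, 20)            # |0-1.5| = 1.5 == radii[3], etc.
  prof <- sampen_profile(x, m = 1, grid = grid)
  counts <- attr(prof, "counts")
  cm_direct <- vapply(grid$radii,
                      function(r) correlation_sum(x, 1, 1, r,
                                                  templates = 4L)$match_count,
                      integer(1))
  expect_identical(as.integer(counts$match_m), cm_direct)
})

test_that("profile on a constant series is identically zero entropy", {
  prof <- sampen_profile(rep(5, 60), m = 2, grid = threshold_grid(0, 1, 10))
  expect_true(all(prof$c_m == 1))
  expect_true(all(prof$c_m1 == 1))
  expect_true(all(prof$sampen == 0))
})

test_that("overflow bin keeps total pair bookkeeping exact", {
  x <- rand_series(80, seed = 9)
  grid <- threshold_grid(0.01, 0.5, 8)    # r_max below the series range
  prof <- sampen_profile(x, m = 2, grid = grid)
  counts <- attr(prof, "counts")
  expect_equal(counts$match_m[grid$n] + counts$overflow_m, counts$pairs_m)
  expect_equal(counts$match_m1[grid$n] + counts$overflow_m1, counts$pairs_m1)
  expect_true(all(diff(counts$match_m) >= 0))
  expect_true(all(diff(counts$match_m1) >= 0))
})
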