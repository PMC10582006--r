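test_that("cluster finding follows the suprathreshold-contiguity definition", {
  df <- 47
  none <- find_clusters(c(0.5, -1.2, 1.8, -1.9), df)
  expect_equal(nrow(none), 0)

  one <- find_clusters(c(0, 3.0, 3.5, 2.8, 0), df)
  expect_equal(nrow(one), 1)
  expect_equal(one$stat, 9.3)
  expect_equal(one$sign, 1L)
  expect_equal(c(one$i_start, one$i_end), c(2L, 4L))

  two <- find_clusters(c(3, 3, 0, -3, -3, -3), df)
  expect_equal(nrow(two), 2)
  expect_equal(sort(two$stat), c(-9, 6))
  expect_equal(two$sign[match(c(6, -9), two$stat)], c(1L, -1L))

  # adjacent positive and negative runs form separate clusters
  pn <- find_clusters(c(3, 3, -3, -3), df)
  expect_equal(nrow(pn), 2)
})

test_that("2-D clusters use 4-connectivity and split by sign", {
  tm <- matrix(0, 5, 6)
  tm[1:2, 1:2] <- 3 # one positive blob
  tm[4:5, 5:6] <- 3 # second blob, diagonal-separated from everything
  tm[4, 2] <- -4 # negative singleton
  cl <- find_clusters(tm, df = 30)
  expect_equal(nrow(cl), 3)
  expect_equal(sort(cl$stat), c(-4, 12, 12))
  # diagonal touching does not merge blobs
  tm2 <- matrix(0, 3, 3)
  tm2[1, 1] <- 3
  tm2[2, 2] <- 3
  expect_equal(nrow(find_clusters(tm2, df = 30)), 2)
})

test_that("corrected p follows the add-one rule and is monotone", {
  null_max <- seq_len(2000)
  expect_equal(corrected_p(3000, null_max), 1 / 2001)
  expect_equal(corrected_p(0.5, null_max), 1)
  expect_equal(corrected_p(-3000, null_max), 1 / 2001) # two-sided pooling
  ps <- corrected_p(c(10, 100, 1000, 1999), null_max)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("the two-level permutation detects an embedded effect", {
  bp <- fake_band_power(71, n_sites = 12, effect_q = 0.5, effect_idx = 10:15)
  cl <- cluster_correct(bp,
    condition = "reward", n_shuffles = 60,
    n_combinations = 800, seed = 8, min_trials = 10
  )
  qcl <- cl$by_regressor$z_q$clusters
  sig <- qcl[qcl$pc < 0.05, ]
  expect_gte(nrow(sig), 1)
  # the significant cluster covers the effect window
  expect_true(any(sig$i_start <= 15 & sig$i_end >= 10 & sig$sign == 1))

  # determinism: identical null under the same seed
  cl2 <- cluster_correct(bp,
    condition = "reward", n_shuffles = 60,
    n_combinations = 800, seed = 8, min_trials = 10
  )
  expect_identical(cl$by_regressor$z_q$null_max, cl2$by_regressor$z_q$null_max)
  expect_error(
    cluster_correct(bp, n_shuffles = 1, min_trials = 10),
    "n_shuffles"
  )
})

test_that("restricting the tested maps skips their null but keeps clusters", {
  bp <- fake_band_power(72, n_sites = 10, effect_q = 0.5)
  cl <- cluster_correct(bp,
    condition = "reward", n_shuffles = 40, n_combinations = 300,
    seed = 9, min_trials = 10, test_regressors = "z_q"
  )
  expect_false(is.null(cl$by_regressor$z_q$null_max))
  expect_null(cl$by_regressor$z_r$null_max)
  expect_true(all(is.na(cl$by_regressor$z_r$clusters$pc)))
})

test_that("the two-level null is calibrated on null data", {
  hits <- vapply(seq_len(150), function(i) {
    bp <- fake_band_power(3000 + 7 * i, n_sites = 10, n_trials = 30, n_t = 25)
    cl <- cluster_correct(bp,
      condition = "reward", n_shuffles = 50,
      n_combinations = 400, seed = i, min_trials = 10,
      test_regressors = "z_q"
    )
    any(cl$by_regressor$z_q$clusters$pc < 0.05)
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.045)
})

test_that("build_null is seeded, shaped and nonnegative", {
  set.seed(5)
  bs <- array(rnorm(8 * 20 * 15), c(8, 20, 15))
  n1 <- build_null(bs, n_combinations = 200, seed = 3)
  n2 <- build_null(bs, n_combinations = 200, seed = 3)
  expect_identical(n1, n2)
  expect_length(n1, 200)
  expect_true(all(n1 >= 0))
  expect_false(identical(n1, build_null(bs, n_combinations = 200, seed = 4)))
  expect_error(build_null(bs[, 1, , drop = FALSE], seed = 1), "n_shuffles")
  expect_error(build_null(matrix(1, 2, 2)), "array")
})
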