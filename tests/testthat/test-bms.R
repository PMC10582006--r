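test_that("log evidence is order-invariant and penalizes complexity", {
  set.seed(81)
  n <- 48
  p_lfo <- rnorm(n)
  p_delta <- rnorm(n)
  y <- -0.5 * p_lfo + rnorm(n, sd = 0.5)
  e12 <- log_model_evidence(y, cbind(p_lfo, p_delta))
  e21 <- log_model_evidence(y, cbind(p_delta, p_lfo))
  expect_equal(e12, e21, tolerance = 1e-10)
  expect_error(log_model_evidence(y, cbind(p_lfo, 2 * p_lfo)), "Collinear")
  expect_error(log_model_evidence(y, cbind(p_lfo, rep(1, n))), "Constant")

  # Occam penalty: an irrelevant extra band lowers the evidence on average
  diffs <- vapply(seq_len(200), function(i) {
    set.seed(1000 + i)
    p1 <- rnorm(n)
    p2 <- rnorm(n)
    yy <- -0.5 * p1 + rnorm(n, sd = 0.8)
    log_model_evidence(yy, cbind(p1)) - log_model_evidence(yy, cbind(p1, p2))
  }, numeric(1))
  expect_gt(mean(diffs), 0)

  # and the generating model attains the best average evidence
  space <- bms_model_space()
  expect_length(space, 8)
  expect_true(all(vapply(space, function(m) "LFO" %in% m, logical(1))))
  wins <- vapply(seq_len(200), function(i) {
    set.seed(2000 + i)
    bands <- matrix(rnorm(n * 4), n,
      dimnames = list(NULL, c("LFO", "delta", "beta", "gamma"))
    )
    yy <- -0.6 * bands[, "LFO"] + 0.5 * bands[, "delta"] + rnorm(n, sd = 0.6)
    ev <- vapply(
      space,
      function(m) log_model_evidence(yy, bands[, m, drop = FALSE]),
      numeric(1)
    )
    names(which.max(ev))
  }, character(1))
  expect_equal(names(which.max(table(wins))), "LFO+delta")
})

test_that("BIC approximation ranks like the conjugate evidence", {
  set.seed(82)
  n <- 60
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- x1 + rnorm(n, sd = 0.4)
  conj <- c(
    log_model_evidence(y, cbind(x1)),
    log_model_evidence(y, cbind(x2)),
    log_model_evidence(y, cbind(x1, x2))
  )
  bic <- c(
    log_model_evidence(y, cbind(x1), method = "bic"),
    log_model_evidence(y, cbind(x2), method = "bic"),
    log_model_evidence(y, cbind(x1, x2), method = "bic")
  )
  expect_equal(order(conj), order(bic))
})

test_that("RFX-BMS reproduces symmetric and hard-assignment closed forms", {
  # equal evidence everywhere: uniform expected frequencies
  lme <- matrix(0, 48, 8, dimnames = list(NULL, paste0("m", 1:8)))
  res <- rfx_bms(lme, seed = 1)
  expect_equal(unname(res$ef), rep(1 / 8, 8), tolerance = 1e-8)
  expect_equal(unname(res$xp), rep(1 / 8, 8), tolerance = 0.02)

  # one model dominating by 10 nats at every site: alpha = 1 + n
  lme[, 3] <- 10
  res2 <- rfx_bms(lme, seed = 2)
  expect_equal(unname(res2$alpha[3]), 49, tolerance = 0.01)
  expect_equal(unname(res2$ef[3]), 49 / 56, tolerance = 1e-3)
  expect_gt(res2$xp[3], 0.999)
  expect_equal(res2$winner, "m3")

  # single site, two models, equal evidence: one-step update
  res3 <- rfx_bms(matrix(0, 1, 2), seed = 3)
  expect_equal(unname(res3$alpha), c(1.5, 1.5), tolerance = 1e-8)
  expect_equal(unname(res3$ef), c(0.5, 0.5), tolerance = 1e-8)

  expect_error(rfx_bms(matrix(c(0, NA), 1, 2)), "finite")
  expect_error(rfx_bms(matrix(0, 4, 1)), "2 models")
})

test_that("RFX-BMS is invariant to per-site evidence offsets and xp is precise", {
  set.seed(83)
  lme <- matrix(rnorm(30 * 4, sd = 2), 30, 4)
  res <- rfx_bms(lme, seed = 4)
  shifted <- rfx_bms(lme + rowMeans(lme) %o% rep(1, 4) + 100, seed = 4)
  expect_equal(res$alpha, shifted$alpha, tolerance = 1e-6)
  expect_equal(res$xp, shifted$xp)

  # Monte Carlo error of the exceedance probabilities
  a <- rfx_bms(lme, seed = 5)$xp
  b <- rfx_bms(lme, seed = 6)$xp
  expect_lt(max(abs(a - b)), 0.01)
  expect_equal(sum(a), 1)
})

test_that("band regression recovers slopes and rejects constants", {
  df <- tibble::tibble(
    site_id = rep(1:4, each = 20),
    power = rnorm(80),
    pe = NA_real_
  )
  df$pe <- df$power # identical vectors: slope exactly 1
  fit <- band_pe_regression(df)
  expect_equal(fit$per_site$beta, rep(1, 4), tolerance = 1e-12)
  expect_equal(fit$mean_beta, 1, tolerance = 1e-12)

  set.seed(84)
  null_df <- tibble::tibble(
    site_id = rep(1:48, each = 40),
    power = rnorm(48 * 40),
    pe = rnorm(48 * 40)
  )
  null_fit <- band_pe_regression(null_df)
  expect_lt(abs(null_fit$mean_beta), 0.03)
  expect_gt(null_fit$p, 0.001)

  const <- tibble::tibble(site_id = rep(1, 10), power = 1, pe = rnorm(10))
  expect_error(band_pe_regression(const), "Constant")
})
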