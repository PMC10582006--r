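test_that("q_step follows the delta rule", {
  s <- q_step(0, 1, 0.5)
  expect_equal(s$pe, 1)
  expect_equal(s$q_updated, 0.5)

  s <- q_step(0.42, 0.42, 0.13)
  expect_equal(s$pe, 0)
  expect_equal(s$q_updated, 0.42)

  s <- q_step(0.3, -1, 1)
  expect_equal(s$pe, -1.3)
  expect_equal(s$q_updated, -1)

  expect_error(q_step(0, 1, 1.2), "alpha")
  expect_error(q_step(0, 1, -0.1), "alpha")
})

test_that("softmax choice probabilities are symmetric, stable and exact", {
  expect_equal(softmax_prob(0.37, 0.37, 2), 0.5)
  expect_equal(softmax_prob(1, 0, 1e6), 0.5, tolerance = 1e-5)
  expect_equal(softmax_prob(1, 0, 1), 1 / (1 + exp(-1)))
  # extreme values must not overflow
  expect_equal(softmax_prob(1000, -1000, 0.01), 1)
  expect_error(softmax_prob(1, 0, 0), "beta")
})

test_that("forward pass reproduces hand-iterated values and initialization", {
  trials <- tibble::tibble(
    patient_id = 1L, session_id = 1L, trial_index = 1:3, pair_id = 1L,
    condition = "reward", cue_chosen = "A", side_chosen = "left",
    outcome = c(1, 0, 1), rt = 1, valid = TRUE
  )
  out <- compute_regressors(trials, list(alpha = 0.5))
  expect_equal(out$q_chosen, c(0, 0.5, 0.25))
  expect_equal(out$pe, c(1, -0.5, 0.75))

  # first trial of every pair starts from zero expected value
  cohort <- simulate_cohort(task_config(n_sessions = 2, n_patients = 1),
    list(alpha = 0.4, beta = 0.3),
    seed = 5
  )
  reg <- compute_regressors(cohort, list(alpha = 0.4))
  firsts <- reg |>
    dplyr::group_by(session_id, pair_id) |>
    dplyr::slice_min(trial_index, n = 1)
  expect_true(all(firsts$q_chosen == 0))
  # Q values bounded by the outcome range
  expect_true(all(abs(reg$q_chosen) <= 1))
})

test_that("summed log softmax over an agent's choices equals the fitted nll", {
  cohort <- make_regressed_cohort(11, n_patients = 1, n_sessions = 2)
  fit <- cohort$fits$fit[[1]]
  tr <- cohort$trials
  ll <- 0
  for (i in seq_len(nrow(tr))) {
    p_chosen <- softmax_prob(tr$q_chosen[i], tr$q_unchosen[i], fit$beta)
    ll <- ll + log(p_chosen)
  }
  expect_equal(-ll, fit$nll, tolerance = 1e-10)
})

test_that("fitting matches a brute-force grid search and nests random choice", {
  trials <- simulate_cohort(task_config(n_sessions = 3, n_patients = 1),
    list(alpha = 0.3, beta = 0.3),
    seed = 21
  )
  fit <- fit_qlearning(trials)
  # independent oracle: dense grid evaluation of the likelihood surface
  grid_nll <- Inf
  for (a in seq(0, 1, by = 0.02)) {
    fwd <- rlpower:::qlearn_forward(rlpower:::sort_trials(trials), a)
    dq <- fwd$q_chosen - fwd$q_unchosen
    for (b in exp(seq(log(0.01), log(10), length.out = 80))) {
      grid_nll <- min(grid_nll, rlpower:::qlearn_nll(dq, b))
    }
  }
  expect_lte(fit$nll, grid_nll + 1e-6)
  # random responding is nested at infinite temperature
  expect_lte(fit$nll, nrow(trials) * log(2))
  expect_equal(fit$aic, 4 + 2 * fit$nll)
  expect_equal(fit$aic_random, 2 * nrow(trials) * log(2))
})

test_that("degenerate and invalid behavioral inputs are rejected", {
  expect_error(fit_qlearning(tibble::tibble()), "missing column")
  cohort <- simulate_cohort(task_config(n_patients = 2, n_sessions = 1),
    list(alpha = 0.3, beta = 0.3),
    seed = 2
  )
  expect_error(fit_qlearning(cohort), "one patient")
  # all-identical choices still yield a finite likelihood
  one <- dplyr::filter(cohort, patient_id == 1)
  one$cue_chosen <- "A"
  fit <- fit_qlearning(one)
  expect_true(is.finite(fit$nll))
})

test_that("regressors are z-scored within scope and zero variance is flagged", {
  cohort <- make_regressed_cohort(31, n_patients = 1, n_sessions = 2)
  tr <- cohort$trials
  for (cond in c("reward", "punishment")) {
    sel <- tr$condition == cond
    expect_equal(mean(tr$z_q[sel]), 0, tolerance = 1e-12)
    expect_equal(sd(tr$z_q[sel]), 1, tolerance = 1e-12)
    expect_equal(mean(tr$z_r[sel]), 0, tolerance = 1e-12)
  }
  # z-scoring across all trials instead of within condition
  all_scope <- compute_regressors(
    dplyr::select(tr, -z_q, -z_r, -z_pe, -q_chosen, -q_unchosen, -pe),
    cohort$fits$fit[[1]],
    scope = "all"
  )
  expect_equal(mean(all_scope$z_r), 0, tolerance = 1e-12)
  expect_equal(sd(all_scope$z_r), 1, tolerance = 1e-12)

  # constant outcomes cannot be z-scored
  const <- dplyr::filter(tr, condition == "reward")
  const$outcome <- 1
  expect_warning(
    out <- compute_regressors(
      dplyr::select(const, -z_q, -z_r, -z_pe, -q_chosen, -q_unchosen, -pe),
      cohort$fits$fit[[1]]
    ),
    "zero variance"
  )
  expect_true(all(is.na(out$z_r)))
})

test_that("behavioral summary handles group tests and degenerate edges", {
  cohort <- simulate_cohort(task_config(n_patients = 3, n_sessions = 1),
    list(alpha = 0.5, beta = 0.2),
    seed = 8
  )
  bs <- behavioral_summary(cohort)
  expect_s3_class(tidy(bs), "tbl_df")
  expect_equal(nrow(bs$patients), 3)
  expect_true(all(c("statistic", "p_value") %in% names(bs$tests)))

  # all patients always choose the correct cue -> zero variance, flagged
  perfect <- cohort
  perfect$cue_chosen <- perfect$cue_good
  bs2 <- behavioral_summary(perfect)
  acc <- bs2$tests[bs2$tests$test == "accuracy_reward_vs_chance", ]
  expect_equal(acc$estimate, 1)
  expect_true(is.na(acc$statistic))
  expect_match(acc$note, "degenerate")

  # identical reaction times in both conditions -> paired t of exactly 0
  flat <- cohort
  flat$rt <- 1.5
  bs3 <- behavioral_summary(flat)
  rt_row <- bs3$tests[bs3$tests$test == "rt_reward_vs_punishment", ]
  expect_equal(rt_row$statistic, 0)

  expect_error(
    behavioral_summary(dplyr::filter(cohort, patient_id == 1)),
    "at least 2 patients"
  )
})

test_that("group accuracy tests are calibrated for random agents", {
  hits <- vapply(1000 + 17 * seq_len(30), function(seed) {
    cohort <- simulate_cohort(task_config(n_patients = 8, n_sessions = 1),
      agent = NULL, seed = seed
    )
    bs <- behavioral_summary(cohort)
    stat <- bs$tests$statistic[bs$tests$test == "accuracy_reward_vs_chance"]
    abs(stat) < 2.36
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
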