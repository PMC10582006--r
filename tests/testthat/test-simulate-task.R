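test_that("a session has the task's structure", {
  task <- task_config()
  s <- simulate_session(task, list(alpha = 0.3, beta = 0.3), seed = 4)
  expect_equal(nrow(s), 96)
  expect_equal(as.vector(table(s$pair_id)), rep(24L, 4))
  expect_equal(sort(unique(s$condition)), c("punishment", "reward"))
  # two pairs per condition
  cond_by_pair <- unique(s[, c("pair_id", "condition")])
  expect_equal(as.vector(table(cond_by_pair$condition)), c(2L, 2L))
  # outcome domain respects the condition
  expect_true(all(s$outcome[s$condition == "reward"] %in% c(0, 1)))
  expect_true(all(s$outcome[s$condition == "punishment"] %in% c(-1, 0)))
  expect_true(all(s$rt > 0))
  expect_silent(rlpower:::assert_trials(s))
  # event stream ordering: cue, choice, outcome
  expect_true(all(s$t_choice > s$t_cue))
  expect_true(all(s$t_outcome > s$t_choice))
})

test_that("cue sides are counterbalanced exactly within each pair", {
  s <- simulate_session(task_config(), list(alpha = 0.2, beta = 0.5), seed = 9)
  a_left <- (s$cue_chosen == "A" & s$side_chosen == "left") |
    (s$cue_chosen == "B" & s$side_chosen == "right")
  counts <- tapply(a_left, s$pair_id, sum)
  expect_true(all(counts == 12))
})

test_that("outcomes follow the reciprocal contingencies", {
  pooled <- dplyr::bind_rows(lapply(1:40, function(i) {
    simulate_session(task_config(), list(alpha = 0.3, beta = 0.3), seed = 100 + i)
  }))
  good <- pooled$cue_chosen == pooled$cue_good
  # good reward cue pays +1 with p = 0.75
  sel <- good & pooled$condition == "reward"
  p_hat <- mean(pooled$outcome[sel] == 1)
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / sum(sel)))
  # good punishment cue loses with p = 0.25
  sel <- good & pooled$condition == "punishment"
  p_hat <- mean(pooled$outcome[sel] == -1)
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.75 * 0.25 / sum(sel)))
  # punishment decisions are slower on average
  expect_gt(
    mean(pooled$rt[pooled$condition == "punishment"]),
    mean(pooled$rt[pooled$condition == "reward"])
  )
})

test_that("cohort generation is bit-identical under the same seed", {
  task <- task_config(n_patients = 2, n_sessions = 2)
  a <- simulate_cohort(task, list(alpha = 0.3, beta = 0.3), seed = 77)
  b <- simulate_cohort(task, list(alpha = 0.3, beta = 0.3), seed = 77)
  expect_identical(a, b)
  c <- simulate_cohort(task, list(alpha = 0.3, beta = 0.3), seed = 78)
  expect_false(identical(a, c))
})

test_that("AIC prefers the learning model on learner data and random on noise", {
  ql_better <- vapply(seq_len(30), function(i) {
    tr <- simulate_cohort(task_config(n_patients = 1, n_sessions = 2),
      list(alpha = 0.3, beta = 0.3),
      seed = 300 + i
    )
    fit <- fit_qlearning(tr)
    fit$aic < fit$aic_random
  }, logical(1))
  expect_gte(mean(ql_better), 0.95)

  random_better <- vapply(seq_len(30), function(i) {
    tr <- simulate_cohort(task_config(n_patients = 1, n_sessions = 2),
      agent = NULL, seed = 600 + i
    )
    fit <- fit_qlearning(tr)
    fit$aic_random < fit$aic
  }, logical(1))
  expect_gte(mean(random_better), 0.8)
})
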