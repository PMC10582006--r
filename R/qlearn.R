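#' Single Q-learning update step
#'
#' Updates the value of the chosen option by a fraction `alpha` of the
#' outcome prediction error. The prediction error is the difference between
#' the obtained outcome and the expected value of the chosen option; the
#' unchosen option keeps its value.
#'
#' @param q_chosen Expected value of the chosen option (monetary units).
#' @param outcome Obtained outcome, typically in `{-1, 0, +1}`.
#' @param alpha Learning rate in `[0, 1]`.
#'
#' @return A list with elements `pe` (prediction error) and `q_updated`
#'   (post-update value of the chosen option).
#' @examples
#' q_step(0, 1, 0.5) # pe = 1, q_updated = 0.5
#' @export
q_step <- function(q_chosen, outcome, alpha) {
  stopifnot_scalar(alpha, "alpha", 0, 1)
  pe <- outcome - q_chosen
  list(pe = pe, q_updated = q_chosen + alpha * pe)
}

#' Softmax choice probability
#'
#' Probability of choosing option A given the two options' expected values
#' and a choice temperature. Higher temperatures yield more random choice.
#' Computed in a numerically stable form (max-subtraction before
#' exponentiation); vectorized over values.
#'
#' @param q_a,q_b Expected values of options A and B.
#' @param beta Choice temperature, strictly positive.
#'
#' @return Probability of choosing A.
#' @examples
#' softmax_prob(1, 0, 1) # 1 / (1 + exp(-1))
#' @export
softmax_prob <- function(q_a, q_b, beta) {
  stopifnot_scalar(beta, "beta", lo = .Machine$double.xmin)
  m <- pmax(q_a, q_b)
  ea <- exp((q_a - m) / beta)
  eb <- exp((q_b - m) / beta)
  ea / (ea + eb)
}

# Forward pass of the Q-learning model over one patient's trials
# (already sorted by session and trial index). Values are reset to 0 at
# each session start for every cue; each cue pair holds its own (Qa, Qb).
# Returns per-trial pre-update values of the chosen/unchosen option, the
# value difference (chosen minus unchosen), and the prediction error.
qlearn_forward <- function(trials, alpha) {
  n <- nrow(trials)
  state_key <- paste(trials$session_id, trials$pair_id)
  keys <- unique(state_key)
  key_idx <- match(state_key, keys)
  chose_a <- trials$cue_chosen == "A"
  outcome <- trials$outcome

  qa <- numeric(length(keys))
  qb <- numeric(length(keys))
  q_chosen <- numeric(n)
  q_unchosen <- numeric(n)
  pe <- numeric(n)
  for (t in seq_len(n)) {
    k <- key_idx[t]
    if (chose_a[t]) {
      q_chosen[t] <- qa[k]
      q_unchosen[t] <- qb[k]
      pe[t] <- outcome[t] - qa[k]
      qa[k] <- qa[k] + alpha * pe[t]
    } else {
      q_chosen[t] <- qb[k]
      q_unchosen[t] <- qa[k]
      pe[t] <- outcome[t] - qb[k]
      qb[k] <- qb[k] + alpha * pe[t]
    }
  }
  list(q_chosen = q_chosen, q_unchosen = q_unchosen, pe = pe)
}

# Negative log-likelihood of the observed choices. The value-difference
# trajectory depends only on alpha, so it can be reused across beta values.
qlearn_nll <- function(dq, beta) {
  # p(chosen) = 1 / (1 + exp(-dq / beta)); -log p in a stable form
  z <- -dq / beta
  sum(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))))
}

sort_trials <- function(trials) {
  dplyr::arrange(trials, .data$session_id, .data$trial_index)
}

#' Fit the Q-learning model to one patient's choices
#'
#' Maximizes the likelihood of the observed choices over the learning rate
#' `alpha` and choice temperature `beta`, pooling all of the patient's
#' sessions (values are reset at each session start and for each cue pair).
#' The optimizer is a deterministic multistart: an 11 x 11 grid over
#' `alpha` in `[0, 1]` and log-spaced `beta` in `[beta_min, beta_max]`,
#' refined by bounded quasi-Newton search from the best grid point.
#'
#' @param trials Trial table for a single patient (see [simulate_cohort()]
#'   for the column layout).
#' @param beta_min,beta_max Bounds for the choice temperature.
#' @param grid_n Grid resolution per parameter for the multistart.
#'
#' @return An object of class `qlearn_fit`: a list with `alpha`, `beta`,
#'   `nll` (negative log-likelihood, nats), `aic` (`2k + 2 nll`, `k = 2`),
#'   `aic_random` (`2 n log 2`, the AIC of uniform random responding),
#'   `n_trials`, and a per-session breakdown. Supports [tidy()] and
#'   [glance()].
#' @export
fit_qlearning <- function(trials, beta_min = 0.01, beta_max = 10, grid_n = 11) {
  assert_trials(trials)
  if (length(unique(trials$patient_id)) > 1L) {
    abort("`fit_qlearning()` fits one patient; use `fit_cohort()` for several.")
  }
  trials <- sort_trials(trials)
  n <- nrow(trials)

  alphas <- seq(0, 1, length.out = grid_n)
  betas <- exp(seq(log(beta_min), log(beta_max), length.out = grid_n))

  best <- list(nll = Inf, alpha = NA_real_, beta = NA_real_)
  for (a in alphas) {
    fwd <- qlearn_forward(trials, a)
    dq <- fwd$q_chosen - fwd$q_unchosen
    for (b in betas) {
      nll <- qlearn_nll(dq, b)
      if (nll < best$nll) best <- list(nll = nll, alpha = a, beta = b)
    }
  }

  obj <- function(par) {
    fwd <- qlearn_forward(trials, par[1])
    qlearn_nll(fwd$q_chosen - fwd$q_unchosen, exp(par[2]))
  }
  opt <- stats::optim(
    c(best$alpha, log(best$beta)), obj,
    method = "L-BFGS-B",
    lower = c(0, log(beta_min)), upper = c(1, log(beta_max))
  )
  if (opt$value <= best$nll) {
    best <- list(nll = opt$value, alpha = opt$par[1], beta = exp(opt$par[2]))
  }

  fwd <- qlearn_forward(trials, best$alpha)
  dq <- fwd$q_chosen - fwd$q_unchosen
  per_session <- vapply(
    split(seq_len(n), trials$session_id),
    function(i) qlearn_nll(dq[i], best$beta),
    numeric(1)
  )

  structure(
    list(
      alpha = best$alpha,
      beta = best$beta,
      nll = best$nll,
      aic = 2 * 2 + 2 * best$nll,
      aic_random = aic_random(n),
      n_trials = n,
      patient_id = trials$patient_id[1],
      session_nll = per_session
    ),
    class = "qlearn_fit"
  )
}

#' AIC of uniform random responding
#'
#' Closed form for a model with no free parameters that assigns probability
#' 1/2 to every choice: `2 n log(2)`.
#'
#' @param n_trials Number of trials.
#' @return The AIC value.
#' @examples
#' aic_random(96) # 192 * log(2)
#' @export
aic_random <- function(n_trials) 2 * n_trials * log(2)

#' @export
print.qlearn_fit <- function(x, ...) {
  cat(sprintf(
    "Q-learning fit (patient %s): alpha = %.3f, beta = %.3f\n",
    as.character(x$patient_id), x$alpha, x$beta
  ))
  cat(sprintf(
    "  nll = %.2f nats over %d trials; AIC = %.1f (random: %.1f)\n",
    x$nll, x$n_trials, x$aic, x$aic_random
  ))
  invisible(x)
}

#' Fit the Q-learning model to every patient in a cohort
#'
#' @param trials Cohort trial table (multiple patients).
#' @param ... Passed to [fit_qlearning()].
#' @return A tibble with one row per patient: `patient_id`, `alpha`,
#'   `beta`, `nll`, `aic`, `aic_random`, `n_trials`, and a `fit`
#'   list-column holding the full `qlearn_fit` objects.
#' @export
fit_cohort <- function(trials, ...) {
  assert_trials(trials)
  fits <- lapply(
    split(trials, trials$patient_id),
    fit_qlearning, ...
  )
  tibble::tibble(
    patient_id = names(fits),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    nll = vapply(fits, `[[`, numeric(1), "nll"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    aic_random = vapply(fits, `[[`, numeric(1), "aic_random"),
    n_trials = vapply(fits, `[[`, numeric(1), "n_trials"),
    fit = unname(fits)
  )
}

#' Latent value and prediction-error regressors from a fitted model
#'
#' Runs the fitted model forward over the patient's trials and augments the
#' trial table with the pre-update chosen-option value (`q_chosen`), the
#' unchosen value, the prediction error (`pe = outcome - q_chosen`), and
#' z-scored regressors `z_q`, `z_r` (outcome) and `z_pe`. By default each
#' regressor is z-scored across the patient's valid trials of its own
#' condition (the encoding models are fitted per condition); set
#' `scope = "all"` to z-score across all valid trials instead.
#'
#' @param trials One patient's trial table.
#' @param fit A `qlearn_fit` for the same trials, or a list with `alpha`.
#' @param scope `"condition"` (default) or `"all"`.
#' @return The trial table with latent and z-scored regressor columns,
#'   in chronological order.
#' @export
compute_regressors <- function(trials, fit, scope = c("condition", "all")) {
  scope <- match.arg(scope)
  assert_trials(trials)
  if (length(unique(trials$patient_id)) > 1L) {
    abort("`compute_regressors()` operates on a single patient.")
  }
  trials <- sort_trials(trials)
  fwd <- qlearn_forward(trials, fit$alpha)
  trials$q_chosen <- fwd$q_chosen
  trials$q_unchosen <- fwd$q_unchosen
  trials$pe <- fwd$pe

  valid <- if ("valid" %in% names(trials)) trials$valid else rep(TRUE, nrow(trials))
  zcols <- list(z_q = "q_chosen", z_r = "outcome", z_pe = "pe")
  for (zc in names(zcols)) {
    src <- trials[[zcols[[zc]]]]
    out <- rep(NA_real_, nrow(trials))
    groups <- if (scope == "condition") trials$condition else rep("all", nrow(trials))
    for (g in unique(groups)) {
      in_g <- groups == g
      z <- zscore_by(src[in_g], ref = valid[in_g])
      if (all(is.na(z))) {
        warn(sprintf(
          "Regressor `%s` has zero variance in scope `%s`; z-score not attempted.",
          zc, g
        ))
      }
      out[in_g] <- z
    }
    trials[[zc]] <- out
  }
  trials
}

# Which cue is "correct" (the 0.75-reward or the 0.25-punishment cue).
# Uses the generator's `cue_good` column when present, otherwise infers it
# from empirical mean outcomes per (session, pair); ties resolve to the
# higher-expected-value cue (cannot occur under the 0.75/0.25 design).
correct_cue <- function(trials) {
  if ("cue_good" %in% names(trials)) {
    return(trials$cue_good)
  }
  key <- paste(trials$patient_id, trials$session_id, trials$pair_id)
  out <- character(nrow(trials))
  for (k in unique(key)) {
    i <- key == k
    mean_a <- mean(trials$outcome[i & trials$cue_chosen == "A"])
    mean_b <- mean(trials$outcome[i & trials$cue_chosen == "B"])
    if (is.na(mean_a)) mean_a <- -Inf
    if (is.na(mean_b)) mean_b <- -Inf
    out[i] <- if (mean_a >= mean_b) "A" else "B"
  }
  out
}

#' Group-level behavioral statistics
#'
#' Per-patient correct-choice rates (overall and over the last four
#' presentations of each cue pair) and mean reaction times by condition,
#' with group tests: two-tailed one-sample t-tests of accuracy against
#' chance (0.5) per condition, and paired t-tests between the reward and
#' punishment conditions for both accuracy and reaction time.
#'
#' @param trials Cohort trial table with at least two patients.
#' @return An object of class `rl_behavior_summary` with elements
#'   `patients` (per-patient tibble) and `tests` (group-test tibble with
#'   columns `test`, `estimate`, `statistic`, `df`, `p_value`, `note`).
#'   Degenerate tests (zero variance) are reported with `NA` statistics and
#'   an explanatory note rather than infinities.
#' @export
behavioral_summary <- function(trials) {
  assert_trials(trials)
  if (length(unique(trials$patient_id)) < 2L) {
    abort("Group behavioral statistics need at least 2 patients.")
  }
  trials$correct <- trials$cue_chosen == correct_cue(trials)

  per_pat <- trials |>
    dplyr::group_by(.data$patient_id, .data$condition) |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      rt_mean = mean(.data$rt),
      .groups = "drop"
    )

  last4 <- trials |>
    dplyr::group_by(.data$patient_id, .data$session_id, .data$pair_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::slice_tail(n = 4) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$patient_id, .data$condition) |>
    dplyr::summarise(accuracy_last4 = mean(.data$correct), .groups = "drop")

  per_pat <- dplyr::left_join(per_pat, last4, by = c("patient_id", "condition"))

  wide <- tidyr::pivot_wider(
    per_pat,
    id_cols = "patient_id", names_from = "condition",
    values_from = c("accuracy", "rt_mean", "accuracy_last4")
  )

  one_sample <- function(x, mu, label) {
    est <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      return(tibble::tibble(
        test = label, estimate = est, statistic = NA_real_,
        df = length(x) - 1, p_value = NA_real_, note = "degenerate: zero variance"
      ))
    }
    tt <- stats::t.test(x, mu = mu)
    tibble::tibble(
      test = label, estimate = est, statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value, note = ""
    )
  }
  paired <- function(x, y, label) {
    d <- x - y
    s <- stats::sd(d)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      stat <- if (all(d == 0)) 0 else NA_real_
      return(tibble::tibble(
        test = label, estimate = mean(d), statistic = stat,
        df = length(d) - 1, p_value = if (identical(stat, 0)) 1 else NA_real_,
        note = "degenerate: zero variance of differences"
      ))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    tibble::tibble(
      test = label, estimate = mean(d), statistic = unname(tt$statistic),
      df = unname(tt$parameter), p_value = tt$p.value, note = ""
    )
  }

  tests <- dplyr::bind_rows(
    one_sample(wide$accuracy_reward, 0.5, "accuracy_reward_vs_chance"),
    one_sample(wide$accuracy_punishment, 0.5, "accuracy_punishment_vs_chance"),
    one_sample(wide$accuracy_last4_reward, 0.5, "accuracy_last4_reward_vs_chance"),
    one_sample(wide$accuracy_last4_punishment, 0.5, "accuracy_last4_punishment_vs_chance"),
    paired(wide$accuracy_reward, wide$accuracy_punishment, "accuracy_reward_vs_punishment"),
    paired(wide$rt_mean_reward, wide$rt_mean_punishment, "rt_reward_vs_punishment")
  )

  structure(
    list(patients = wide, tests = tests),
    class = "rl_behavior_summary"
  )
}

#' @export
print.rl_behavior_summary <- function(x, ...) {
  cat(sprintf("Behavioral summary over %d patients\n", nrow(x$patients)))
  print(x$tests, ...)
  invisible(x)
}
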