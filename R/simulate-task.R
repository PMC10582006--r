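#' Task configuration for the synthetic cohort generator
#'
#' Describes a probabilistic instrumental learning task: each session holds
#' `n_pairs` new cue pairs (half reward, half punishment), each presented
#' `n_repeats` times in randomized order. Within a pair the two cues pay
#' out with reciprocal probabilities (`p_good` / `1 - p_good`): the good
#' reward cue wins `+outcome_magnitude` with probability `p_good` (else
#' nothing), the good punishment cue loses `-outcome_magnitude` with
#' probability `1 - p_good` (else nothing). Cue screen sides are
#' counterbalanced across presentations.
#'
#' @param n_pairs Cue pairs per session (even; half per condition).
#' @param n_repeats Presentations per pair (default 24, i.e. 96 trials for
#'   4 pairs).
#' @param p_good Payout probability of the good cue.
#' @param outcome_magnitude Monetary magnitude of non-zero outcomes.
#' @param n_sessions Sessions per patient.
#' @param n_patients Patients in the cohort.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (seconds).
#' @param rt_punishment_shift Additive shift (seconds) of punishment-trial
#'   reaction times, emulating slower punishment-avoidance decisions.
#' @param rt_patient_sd Between-patient jitter (SD, log scale) of
#'   `rt_meanlog`.
#' @param rt_shift_sd Between-patient jitter (SD, log scale) of the
#'   punishment shift, giving group reaction-time contrasts realistic
#'   inter-individual spread.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_pairs = 4, n_repeats = 24, p_good = 0.75,
                        outcome_magnitude = 1, n_sessions = 6, n_patients = 8,
                        rt_meanlog = log(1.15), rt_sdlog = 0.3,
                        rt_punishment_shift = 0.4, rt_patient_sd = 0.15,
                        rt_shift_sd = 0.5) {
  if (n_pairs %% 2 != 0) abort("`n_pairs` must be even (half per condition).")
  stopifnot_scalar(p_good, "p_good", 0, 1)
  structure(
    list(
      n_pairs = as.integer(n_pairs), n_repeats = as.integer(n_repeats),
      p_good = p_good, outcome_magnitude = outcome_magnitude,
      n_sessions = as.integer(n_sessions), n_patients = as.integer(n_patients),
      rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
      rt_punishment_shift = rt_punishment_shift,
      rt_patient_sd = rt_patient_sd, rt_shift_sd = rt_shift_sd
    ),
    class = "task_config"
  )
}

#' Simulate one task session played by a Q-learning agent
#'
#' Draws the trial order, cue-side counterbalancing, softmax choices of an
#' agent with parameters `(alpha, beta)` learning on-line, probabilistic
#' outcomes, and log-normal reaction times (shifted additively in the
#' punishment condition). Fully reproducible from `seed`.
#'
#' @param task A [task_config()].
#' @param agent List with `alpha` and `beta`; `beta = Inf` (or `alpha`
#'   `NULL`) gives a uniform random agent.
#' @param seed Integer seed for this session.
#' @param patient_id,session_id Identifiers stamped on the rows.
#' @param rt_meanlog,rt_shift Patient-specific reaction-time parameters;
#'   default to the task-level values.
#' @return A tibble of trials with columns `patient_id`, `session_id`,
#'   `trial_index`, `pair_id`, `condition`, `cue_good`, `cue_chosen`,
#'   `side_chosen`, `correct`, `outcome`, `rt`, `valid`, and event times
#'   `t_cue`, `t_choice`, `t_outcome` (seconds from cue onset).
#' @export
simulate_session <- function(task, agent, seed, patient_id = 1L, session_id = 1L,
                             rt_meanlog = task$rt_meanlog,
                             rt_shift = task$rt_punishment_shift) {
  with_seed(seed, {
    n_pairs <- task$n_pairs
    n_trials <- n_pairs * task$n_repeats
    conditions <- rep(c("reward", "punishment"), each = n_pairs / 2)
    pair_condition <- sample(conditions) # which pairs are reward/punishment
    cue_good <- sample(c("A", "B"), n_pairs, replace = TRUE)

    pair_seq <- sample(rep(seq_len(n_pairs), task$n_repeats))
    # counterbalance: cue A on the left for exactly half the presentations
    a_left <- matrix(FALSE, n_pairs, task$n_repeats)
    for (p in seq_len(n_pairs)) {
      a_left[p, sample(task$n_repeats, task$n_repeats / 2)] <- TRUE
    }
    seen <- integer(n_pairs)

    random_agent <- is.null(agent$alpha) || !is.finite(agent$beta)
    qa <- numeric(n_pairs)
    qb <- numeric(n_pairs)

    cue_chosen <- character(n_trials)
    side_chosen <- character(n_trials)
    outcome <- numeric(n_trials)
    u_choice <- runif(n_trials)
    u_outcome <- runif(n_trials)

    for (t in seq_len(n_trials)) {
      p <- pair_seq[t]
      seen[p] <- seen[p] + 1L
      p_a <- if (random_agent) 0.5 else softmax_prob(qa[p], qb[p], agent$beta)
      chose_a <- u_choice[t] < p_a
      cue_chosen[t] <- if (chose_a) "A" else "B"
      side_chosen[t] <- if (chose_a == a_left[p, seen[p]]) "left" else "right"

      good_chosen <- cue_chosen[t] == cue_good[p]
      p_pay <- if (good_chosen) task$p_good else 1 - task$p_good
      pays <- u_outcome[t] < p_pay
      outcome[t] <- if (pair_condition[p] == "reward") {
        if (pays) task$outcome_magnitude else 0
      } else {
        # good punishment cue "pays" (i.e. loses) rarely
        if (good_chosen) {
          if (u_outcome[t] < 1 - task$p_good) -task$outcome_magnitude else 0
        } else {
          if (u_outcome[t] < task$p_good) -task$outcome_magnitude else 0
        }
      }
      if (!random_agent) {
        if (chose_a) {
          qa[p] <- qa[p] + agent$alpha * (outcome[t] - qa[p])
        } else {
          qb[p] <- qb[p] + agent$alpha * (outcome[t] - qb[p])
        }
      }
    }

    rt <- rlnorm(n_trials, rt_meanlog, task$rt_sdlog) +
      ifelse(pair_condition[pair_seq] == "punishment", rt_shift, 0)

    tibble::tibble(
      patient_id = patient_id,
      session_id = session_id,
      trial_index = seq_len(n_trials),
      pair_id = pair_seq,
      condition = pair_condition[pair_seq],
      cue_good = cue_good[pair_seq],
      cue_chosen = cue_chosen,
      side_chosen = side_chosen,
      correct = cue_chosen == cue_good[pair_seq],
      outcome = outcome,
      rt = rt,
      valid = TRUE,
      t_cue = 0,
      t_choice = rt,
      # chosen cue highlighted 0.25 s, outcome 1 s later
      t_outcome = rt + 1.25
    )
  })
}

#' Simulate a cohort of Q-learning agents performing the task
#'
#' One master seed deterministically spawns per-patient and per-session
#' substreams, so regeneration with the same seed is bit-identical and any
#' patient can be regenerated in isolation.
#'
#' @param task A [task_config()].
#' @param agent Agent parameters shared by all patients (list with `alpha`,
#'   `beta`), or `NULL` for uniform random agents.
#' @param seed Master cohort seed.
#' @return A tibble of trials for all patients and sessions.
#' @export
simulate_cohort <- function(task = task_config(), agent = list(alpha = 0.3, beta = 0.3),
                            seed = 1L) {
  agent <- agent %||% list(alpha = NULL, beta = Inf)
  out <- vector("list", task$n_patients * task$n_sessions)
  i <- 0L
  for (p in seq_len(task$n_patients)) {
    # patient-level reaction-time effects, on their own substream so the
    # task/choice stream is unaffected
    rt_pars <- with_seed(substream_seed(seed, "rt", p), {
      c(
        task$rt_meanlog + rnorm(1, 0, task$rt_patient_sd %||% 0),
        task$rt_punishment_shift * exp(rnorm(1, 0, task$rt_shift_sd %||% 0))
      )
    })
    for (s in seq_len(task$n_sessions)) {
      i <- i + 1L
      out[[i]] <- simulate_session(
        task, agent,
        seed = substream_seed(seed, "session", p, s),
        patient_id = p, session_id = s,
        rt_meanlog = rt_pars[1], rt_shift = rt_pars[2]
      )
    }
  }
  dplyr::bind_rows(out)
}
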