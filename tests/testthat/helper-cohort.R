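# Shared fixtures, all generated in code.

# Simulated cohort with fitted Q-learning regressors attached.
make_regressed_cohort <- function(seed, n_patients = 2, n_sessions = 1,
                                  agent = list(alpha = 0.3, beta = 0.3)) {
  task <- task_config(n_sessions = n_sessions, n_patients = n_patients)
  trials <- simulate_cohort(task, agent, seed = seed)
  fits <- fit_cohort(trials)
  trials <- dplyr::bind_rows(lapply(
    split(trials, trials$patient_id),
    function(tp) {
      compute_regressors(tp, fits$fit[[match(tp$patient_id[1], fits$patient_id)]])
    }
  ))
  list(trials = trials, fits = fits)
}

# Hand-built band-power object: per-site series are white noise plus an
# additive effect of the z-scored regressors inside an index window.
fake_band_power <- function(seed, n_sites = 12, n_trials = 40, n_t = 30,
                            effect_q = 0, effect_r = 0, effect_idx = 10:15) {
  withr::with_seed(seed, {
    trials <- tibble::tibble(
      patient_id = 1L,
      condition = "reward",
      z_q = as.vector(scale(rnorm(n_trials))),
      z_r = as.vector(scale(sample(c(0, 1), n_trials, replace = TRUE)))
    )
    series <- lapply(seq_len(n_sites), function(i) {
      y <- matrix(rnorm(n_trials * n_t, sd = 1), n_trials, n_t)
      y[, effect_idx] <- y[, effect_idx] +
        outer(effect_q * trials$z_q + effect_r * trials$z_r, rep(1, length(effect_idx)))
      y
    })
    structure(
      list(
        series = series, times = seq(0, by = 0.1, length.out = n_t),
        band = "LFO",
        sites = tibble::tibble(site_id = seq_len(n_sites), patient_id = 1L),
        trials = trials, lock = "outcome", normalized = TRUE
      ),
      class = "band_power"
    )
  })
}

# Minimal epochs object wrapping externally built signal matrices.
wrap_epochs <- function(signal_list, fs = 512, epoch_start = -5,
                        trials = NULL) {
  n <- nrow(signal_list[[1]])
  ntr <- ncol(signal_list[[1]])
  if (is.null(trials)) {
    trials <- tibble::tibble(
      patient_id = 1L, session_id = 1L, trial_index = seq_len(ntr),
      pair_id = 1L, condition = "reward", cue_chosen = "A",
      side_chosen = "left", outcome = 0, rt = 1, valid = TRUE
    )
  }
  structure(
    list(
      signal = signal_list,
      sites = tibble::tibble(
        site_id = seq_along(signal_list),
        patient_id = trials$patient_id[1]
      ),
      trials = trials,
      times = epoch_start + (seq_len(n) - 1) / fs,
      fs = fs, lock = "outcome",
      spec = encoding_spec(sampling_rate = fs, epoch = c(epoch_start, epoch_start + n / fs))
    ),
    class = "lfp_epochs"
  )
}
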