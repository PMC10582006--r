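test_that("Slepian tapers are orthonormal and concentrated", {
  tp <- dpss_tapers(128, 2, 3)
  expect_equal(dim(tp), c(128, 3))
  expect_equal(crossprod(tp), diag(3), tolerance = 1e-8)
  # leading taper is bell-shaped: positive, peaked near the center
  expect_true(all(tp[, 1] > 0))
  expect_gt(tp[64, 1], tp[5, 1])
})

test_that("spectral-truncation resampling reproduces band-limited signals", {
  fs <- 512
  t_full <- (0:5119) / fs
  x <- 0.7 * sin(2 * pi * 6 * t_full) + 0.2 * cos(2 * pi * 11 * t_full + 1)
  xd <- rlpower:::decimate_fft(cbind(x, 2 * x, x - 1, 0.5 - x), 400)
  t_dec <- (0:399) / 40
  ref <- 0.7 * sin(2 * pi * 6 * t_dec) + 0.2 * cos(2 * pi * 11 * t_dec + 1)
  expect_equal(xd[, 1], ref, tolerance = 1e-9)
  expect_equal(xd[, 2], 2 * ref, tolerance = 1e-9)
  expect_equal(xd[, 3], ref - 1, tolerance = 1e-9)
  expect_equal(xd[, 4], 0.5 - ref, tolerance = 1e-9)
})

test_that("multitaper power concentrates at the stimulus frequency and scales", {
  fs <- 512
  x <- matrix(sin(2 * pi * 10 * (0:5119) / fs), 5120, 2)
  ep <- wrap_epochs(list(x), fs = fs)
  tf <- multitaper_tfr(ep, freqs = 1:32, t_step = 0.25)
  pw <- apply(tf$power[[1]], 2, mean, na.rm = TRUE)
  # concentration at the stimulus frequency: the peak sits inside the
  # multitaper bandwidth around 10 Hz and out-of-band bins are far down
  expect_true(tf$freqs[which.max(pw)] %in% 9:11)
  expect_gt(pw[10] / pw[20], 20)
  expect_gt(pw[10] / pw[3], 20)

  ep2 <- wrap_epochs(list(2 * x), fs = fs)
  tf2 <- multitaper_tfr(ep2, freqs = 1:32, t_step = 0.25)
  ratio <- mean(tf2$power[[1]][, 10, ], na.rm = TRUE) /
    mean(tf$power[[1]][, 10, ], na.rm = TRUE)
  expect_equal(ratio, 4, tolerance = 1e-9)

  # the low-range decimation is an implementation detail: full-rate analysis
  # gives the same power field up to window-length rounding
  tf_full <- multitaper_tfr(ep, freqs = 8:12, t_step = 0.25, low_decimate = FALSE)
  tf_dec <- multitaper_tfr(ep, freqs = 8:12, t_step = 0.25)
  ok <- is.finite(tf_full$power[[1]]) & is.finite(tf_dec$power[[1]])
  rel <- abs(tf_full$power[[1]][ok] - tf_dec$power[[1]][ok]) /
    max(tf_full$power[[1]][ok])
  expect_lt(max(rel), 0.05)

  expect_error(multitaper_tfr(ep, freqs = c(10, 400)), "Nyquist")
  short <- wrap_epochs(list(x[1:512, , drop = FALSE]), fs = fs)
  expect_error(multitaper_tfr(short, freqs = 1:12), "too short")
})

test_that("white-noise power is flat across the high-frequency range", {
  set.seed(71)
  x <- matrix(rnorm(5120 * 200), 5120, 200)
  tr <- tibble::tibble(
    patient_id = 1L, session_id = 1L, trial_index = 1:200, pair_id = 1L,
    condition = "reward", cue_chosen = "A", side_chosen = "left",
    outcome = 0, rt = 1, valid = TRUE
  )
  ep <- wrap_epochs(list(x), trials = tr)
  tf <- multitaper_tfr(ep, freqs = seq(52, 148, by = 8), t_step = 0.5)
  pm <- apply(tf$power[[1]], 2, mean, na.rm = TRUE)
  expect_lt(max(abs(pm / mean(pm) - 1)), 0.2)
})

test_that("normalization gives zero-mean unit-SD log power per trial", {
  cohort <- make_regressed_cohort(51, n_patients = 1)
  ep <- synthesize_epochs(
    dplyr::filter(cohort$trials, condition == "reward"),
    encoding_spec(n_sites_per_patient = 1),
    seed = 4
  )
  tf <- multitaper_tfr(ep, freqs = 4:12, t_step = 0.25)
  tfn <- normalize_power(tf)
  arr <- tfn$power[[1]]
  for (f in c(1, 5, 9)) {
    sl <- arr[, f, ]
    m <- apply(sl, 1, mean, na.rm = TRUE)
    s <- apply(sl, 1, sd, na.rm = TRUE)
    expect_equal(max(abs(m)), 0, tolerance = 1e-10)
    expect_equal(range(s), c(1, 1), tolerance = 1e-10)
  }
  expect_error(normalize_power(tfn), "already")

  # pooled variant normalizes per frequency across trials
  tfp <- normalize_power(tf, method = "pooled")
  sl <- tfp$power[[1]][, 3, ]
  expect_equal(mean(sl, na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(sd(sl[is.finite(sl)]), 1, tolerance = 0.01)

  # a constant-power trial cannot be z-scored and is flagged invalid
  flat <- tf
  flat$power[[1]][3, 2, ] <- 2.5
  flat_n <- normalize_power(flat)
  expect_true(all(is.na(flat_n$power[[1]][3, 2, ])))
  expect_false(anyNA(flat_n$power[[1]][4, 2, is.finite(tf$power[[1]][4, 2, ])]))

  # non-positive power is a domain error
  bad <- tf
  bad$power[[1]][1, 1, 5] <- 0
  expect_error(normalize_power(bad), "Non-positive")
})

test_that("artifact rejection separates transients from background", {
  cohort <- make_regressed_cohort(52, n_patients = 1)
  spec <- encoding_spec(n_sites_per_patient = 2)
  ep <- synthesize_epochs(cohort$trials, spec, seed = 5)

  clean <- reject_artifact_trials(ep)
  expect_lt(mean(clean$fraction), 0.02)

  dirty <- inject_artifacts(ep, rate = 0.1, amplitude = 50, seed = 6)
  rep_ <- reject_artifact_trials(dirty)
  for (i in seq_along(rep_$valid)) {
    truth <- dirty$artifact_truth[[i]]
    expect_true(all(!rep_$valid[[i]][truth]))
  }

  # an all-zero signal exercises the degenerate-SD guard without exclusions
  zero <- wrap_epochs(list(matrix(0, 5120, 4)))
  expect_true(all(reject_artifact_trials(zero)$valid[[1]]))
})

test_that("band averaging is an unweighted mean with correct band handling", {
  fake <- structure(
    list(
      power = list(array(rep(1:4, each = 2, times = 3), c(2, 4, 3))),
      freqs = c(4, 6, 8, 10), times = c(0, 1, 2),
      sites = tibble::tibble(site_id = 1L, patient_id = 1L),
      trials = tibble::tibble(patient_id = 1L), lock = "outcome",
      normalized = TRUE
    ),
    class = "tf_power"
  )
  bp <- band_average(fake, c(6, 6)) # single bin
  expect_equal(bp$series[[1]], matrix(2, 2, 3))
  bp2 <- band_average(fake, "LFO") # mean of the four bins
  expect_equal(bp2$series[[1]], matrix(2.5, 2, 3))
  tab <- band_average(fake, "LFO", time_window = c(0, 2))
  expect_equal(tab$power, c(2.5, 2.5))
  expect_error(band_average(fake, "gamma"), "does not intersect")

  # the 4 Hz bin belongs to the low-frequency band, not delta
  expect_equal(rlpower:::band_bins(1:32, "delta"), 1:3)
  expect_equal(rlpower:::band_bins(1:32, "LFO"), 4:12)
  expect_equal(rlpower:::band_bins(1:32, "beta"), 13:32)
})

test_that("bipolar montage takes adjacent-contact differences", {
  x <- cbind(a = c(1, 2, 3), b = c(0, 1, 1), c = c(5, 5, 5), d = c(1, 0, 2))
  bm <- bipolar_montage(x)
  expect_equal(colnames(bm), c("b-a", "c-b", "d-c"))
  expect_equal(unname(bm[, 1]), c(-1, -1, -2))
  # a common-reference component cancels exactly
  ref <- rnorm(3)
  expect_equal(bipolar_montage(x + ref), bm)
  expect_error(bipolar_montage(x[, 1, drop = FALSE]), "two contacts")
})

test_that("an 8 Hz carrier raises low-frequency power above gamma", {
  cohort <- make_regressed_cohort(53, n_patients = 1)
  rew <- dplyr::filter(cohort$trials, condition == "reward")
  ep <- synthesize_epochs(rew, encoding_spec(snr = 2, n_sites_per_patient = 1),
    seed = 7, clip_tol = 1
  )
  tf <- multitaper_tfr(ep,
    freqs = c(4:12, seq(52, 148, 16)),
    t_step = 0.5
  )
  win <- tf$times >= 0.5 & tf$times <= 1.5
  lfo <- mean(band_average(tf, "LFO")$series[[1]][, win])
  gam <- mean(band_average(tf, "gamma")$series[[1]][, win])
  expect_gt(lfo, gam)
})
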