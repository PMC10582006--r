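#' Oscillatory-encoding specification for synthetic field potentials
#'
#' Describes how synthetic epoched signals are built: a 1/f background plus
#' a band-limited carrier oscillation whose amplitude envelope inside a
#' coupling window is modulated linearly by z-scored latent regressors.
#' The envelope for trial t is
#' `a0 * max(0, 1 + c * (gain_q * z_q(t) + gain_r * z_r(t)))`,
#' with `a0 = snr` in units of the background-noise standard deviation.
#' Gains are expressed in recovered-power units -- one unit of gain is
#' intended to produce one unit of z-scored log-power per z-scored
#' regressor after the standard analysis chain (multitaper transform,
#' log, trial-wise z-score, band average). The fixed envelope calibration
#' factor `c` maps power gains to envelope modulation depth; it was
#' measured once for the default configuration (8 Hz carrier in the
#' 4-12 Hz band, `snr = 0.4`, 0.3 s window ramps, 1/f background) by
#' simulating cohorts with known gains and regressing normalized band
#' power on the regressors (see the package vignette). Away from the
#' default configuration the mapping is only approximate.
#'
#' @param carrier_freq Carrier frequency in Hz (inside the 4-12 Hz band by
#'   default).
#' @param gain_q,gain_r Envelope coupling gains to the z-scored expected
#'   value and outcome regressors.
#' @param coupling_window Two-element window (s, relative to the lock
#'   event) in which the carrier is active.
#' @param coupling_ramp Cosine on/off ramp (s) applied inside the window
#'   edges. Gating the carrier with a hard rectangle would spread its
#'   energy across all frequency bands (onset/offset splatter) and induce
#'   spurious cross-band coupling; the ramp confines the carrier to its
#'   own band.
#' @param noise_exponent Spectral slope of the background (power ~ 1/f^x).
#' @param snr Carrier amplitude in noise-SD units.
#' @param artifact_rate Per-trial probability of an injected transient.
#' @param artifact_amplitude Transient amplitude in signal-SD units.
#' @param sampling_rate Sampling rate, Hz.
#' @param epoch Epoch limits (s) around the lock event; samples cover
#'   `[epoch[1], epoch[2])`.
#' @param n_sites_per_patient Bipolar recording sites per patient.
#' @return A list of class `encoding_spec`.
#' @export
encoding_spec <- function(carrier_freq = 8, gain_q = 0, gain_r = 0,
                          coupling_window = c(0, 2), coupling_ramp = 0.3,
                          noise_exponent = 1,
                          snr = 0.4, artifact_rate = 0, artifact_amplitude = 20,
                          sampling_rate = 512, epoch = c(-5, 5),
                          n_sites_per_patient = 6) {
  n_samples <- (epoch[2] - epoch[1]) * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort("`epoch` and `sampling_rate` must produce an integer sample count.")
  }
  if (carrier_freq >= sampling_rate / 2) {
    abort("`carrier_freq` must be below the Nyquist frequency.")
  }
  structure(
    list(
      carrier_freq = carrier_freq, gain_q = gain_q, gain_r = gain_r,
      coupling_window = coupling_window, coupling_ramp = coupling_ramp,
      noise_exponent = noise_exponent,
      snr = snr, artifact_rate = artifact_rate,
      artifact_amplitude = artifact_amplitude,
      sampling_rate = sampling_rate, epoch = epoch,
      n_sites_per_patient = as.integer(n_sites_per_patient)
    ),
    class = "encoding_spec"
  )
}

# Envelope modulation depth per unit of requested power gain, measured
# once on the default encoding configuration (see encoding_spec() and the
# methods vignette). The analysis chain attenuates an envelope gain
# (band dilution across the 4-12 Hz bins, window-edge and ramp
# attenuation of the constant-cycle analysis windows, log compression at
# moderate band SNR, the trial-wise z-score's variance inflation, and
# clipping of negative envelopes), so requested power gains are scaled up
# by the inverse of the measured attenuation at synthesis time.
.envelope_per_power_gain <- 2.6

# 1/f^x background noise, one column per trial, unit SD overall.
# Built in the frequency domain (random-phase spectrum shaped by f^(-x/2));
# two real traces are synthesized per inverse transform by packing a
# second hermitian spectrum into the imaginary part.
pink_noise_matrix <- function(n, n_trials, fs, exponent) {
  n_half <- n %/% 2
  f <- seq_len(n_half - 1) * fs / n
  amp <- f^(-exponent / 2)
  n_cols <- ceiling(n_trials / 2)
  spec <- matrix(0 + 0i, n, 2 * n_cols)
  re <- matrix(rnorm((n_half - 1) * 2 * n_cols), n_half - 1)
  im <- matrix(rnorm((n_half - 1) * 2 * n_cols), n_half - 1)
  spec[2:n_half, ] <- (re + 1i * im) * amp
  spec[(n_half + 2):n, ] <- Conj(spec[n_half:2, ])
  packed <- spec[, seq_len(n_cols), drop = FALSE] +
    1i * spec[, n_cols + seq_len(n_cols), drop = FALSE]
  z <- stats::mvfft(packed, inverse = TRUE) / n
  x <- cbind(Re(z), Im(z))[, seq_len(n_trials), drop = FALSE]
  x / stats::sd(x)
}

#' Synthesize epoched field potentials with known regressor coupling
#'
#' Builds one epoch per trial and recording site: independent 1/f noise per
#' site plus a shared-carrier oscillation whose amplitude inside the
#' coupling window follows the trial's z-scored regressors (see
#' [encoding_spec()]). Sites are assigned to patients in blocks of
#' `n_sites_per_patient`; each site's epochs cover that patient's trials.
#'
#' @param trials Cohort trial table carrying the z-scored regressor columns
#'   named in `gains` (from [compute_regressors()]); may be pre-filtered
#'   (e.g. one condition).
#' @param spec An [encoding_spec()].
#' @param seed Master seed; per-site substreams are derived from it.
#' @param lock Label for the event the epochs are centered on.
#' @param gains Named vector of power-coupling gains per regressor column;
#'   defaults to `c(z_q = spec$gain_q, z_r = spec$gain_r)`. Passing e.g.
#'   `c(z_pe = -0.3)` couples the carrier to the prediction error instead.
#' @param clip_tol Warn when more than this fraction of trials had their
#'   envelope clipped at zero.
#' @return An object of class `lfp_epochs`: a list with `signal` (per-site
#'   `time x trial` matrices), `sites` (tibble mapping sites to patients),
#'   `trials`, `times`, `fs`, `lock` and `spec`.
#' @export
synthesize_epochs <- function(trials, spec = encoding_spec(), seed = 1L,
                              lock = "outcome", gains = NULL, clip_tol = 0.2) {
  assert_trials(trials)
  gains <- gains %||% c(z_q = spec$gain_q, z_r = spec$gain_r)
  if (!all(names(gains) %in% names(trials))) {
    abort(paste0(
      "`trials` must carry regressor column(s) ",
      paste(names(gains), collapse = ", "),
      " (run `compute_regressors()` first)."
    ))
  }
  fs <- spec$sampling_rate
  n <- as.integer(round((spec$epoch[2] - spec$epoch[1]) * fs))
  times <- spec$epoch[1] + (seq_len(n) - 1) / fs
  in_win <- times >= spec$coupling_window[1] & times < spec$coupling_window[2]
  # cosine on/off ramps confine the gated carrier to its own band
  ramp <- rep(0, n)
  r <- min(spec$coupling_ramp %||% 0, diff(spec$coupling_window) / 2)
  tw <- times[in_win]
  up <- pmin(1, (tw - spec$coupling_window[1]) / max(r, 1e-12))
  down <- pmin(1, (spec$coupling_window[2] - tw) / max(r, 1e-12))
  ramp[in_win] <- (1 - cos(pi * up)) / 2 * (1 - cos(pi * down)) / 2

  patients <- unique(trials$patient_id)
  sites <- tibble::tibble(
    site_id = seq_len(length(patients) * spec$n_sites_per_patient),
    patient_id = rep(patients, each = spec$n_sites_per_patient)
  )

  modulation <- rep(0, nrow(trials))
  for (nm in names(gains)) {
    z <- trials[[nm]]
    modulation <- modulation + gains[[nm]] * ifelse(is.na(z), 0, z)
  }
  envelope <- 1 + .envelope_per_power_gain * modulation
  n_clipped <- sum(envelope < 0)
  if (n_clipped > clip_tol * nrow(trials)) {
    warn(sprintf(
      "Envelope clipped at zero on %d of %d trial(s); consider smaller gains.",
      n_clipped, nrow(trials)
    ))
  }
  envelope <- pmax(envelope, 0) * spec$snr

  signal <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    rows <- which(trials$patient_id == sites$patient_id[i])
    ntr <- length(rows)
    x <- with_seed(substream_seed(seed, "site", i), {
      noise <- pink_noise_matrix(n, ntr, fs, spec$noise_exponent)
      phase <- runif(ntr, 0, 2 * pi)
      carrier <- matrix(0, n, ntr)
      carrier[in_win, ] <- cos(
        outer(2 * pi * spec$carrier_freq * times[in_win], phase, "+")
      ) * ramp[in_win]
      noise + carrier * rep(envelope[rows], each = n)
    })
    signal[[i]] <- x
  }

  structure(
    list(
      signal = signal, sites = sites, trials = trials,
      times = times, fs = fs, lock = lock, spec = spec
    ),
    class = "lfp_epochs"
  )
}

#' @export
print.lfp_epochs <- function(x, ...) {
  cat(sprintf(
    "Epoched signals: %d sites, %d trials total, %d samples at %g Hz (lock: %s)\n",
    length(x$signal), nrow(x$trials), length(x$times), x$fs, x$lock
  ))
  invisible(x)
}

# Trials (rows of epochs$trials) belonging to one site's columns.
site_trial_rows <- function(epochs, site) {
  which(epochs$trials$patient_id == epochs$sites$patient_id[site])
}

#' Inject high-amplitude transient artifacts
#'
#' Randomly selected site-trials receive one brief transient (a raised
#' cosine bump of 20-100 ms) of amplitude `artifact_amplitude` times the
#' site's signal standard deviation, emulating interictal discharges. The
#' ground-truth mask is returned so detector performance can be scored.
#'
#' @param epochs An [synthesize_epochs()] result.
#' @param rate Per-trial artifact probability (defaults to the spec's).
#' @param amplitude Amplitude in site-SD units (defaults to the spec's).
#' @param seed Seed for artifact placement.
#' @return `epochs` with a `artifact_truth` element: a per-site list of
#'   logical vectors marking contaminated trials.
#' @export
inject_artifacts <- function(epochs, rate = NULL, amplitude = NULL, seed = 1L) {
  rate <- rate %||% epochs$spec$artifact_rate
  amplitude <- amplitude %||% epochs$spec$artifact_amplitude
  stopifnot_scalar(rate, "rate", 0, 1)
  fs <- epochs$fs
  n <- length(epochs$times)
  truth <- vector("list", length(epochs$signal))
  for (i in seq_along(epochs$signal)) {
    x <- epochs$signal[[i]]
    ntr <- ncol(x)
    truth[[i]] <- with_seed(substream_seed(seed, "artifact", i), {
      hit <- runif(ntr) < rate
      if (any(hit)) {
        s <- stats::sd(x)
        for (j in which(hit)) {
          dur <- round(runif(1, 0.02, 0.1) * fs)
          start <- sample(n - dur, 1)
          bump <- amplitude * s * (1 - cos(2 * pi * seq_len(dur) / (dur + 1))) / 2
          x[start:(start + dur - 1), j] <- x[start:(start + dur - 1), j] + bump
        }
      }
      hit
    })
    epochs$signal[[i]] <- x
  }
  epochs$artifact_truth <- truth
  epochs
}
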