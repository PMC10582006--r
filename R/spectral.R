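# Cache for Slepian taper sets (keyed by length, bandwidth, count).
.tfr_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` Slepian sequences of length `n` with
#' time-half-bandwidth product `nw`, via the eigendecomposition of the
#' classical symmetric tridiagonal commuting matrix. Tapers are unit-norm
#' columns, ordered by decreasing energy concentration.
#'
#' @param n Taper length in samples.
#' @param nw Time-half-bandwidth product (e.g. 2 for 3 tapers).
#' @param k Number of tapers (at most `2 nw - 1` is well-concentrated).
#' @return An `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.tfr_cache[[key]])) {
    return(.tfr_cache[[key]])
  }
  w <- nw / n
  t_idx <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- matrix(0, n, n)
  m[cbind(1:n, 1:n)] <- diag_main
  m[cbind(1:(n - 1), 2:n)] <- diag_off
  m[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(m, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # polarity convention: positive mean (even orders) / positive first lobe
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) < 1e-9) s <- tapers[which.max(abs(tapers[, j])), j]
    if (s < 0) tapers[, j] <- -tapers[, j]
  }
  .tfr_cache[[key]] <- tapers
  tapers
}

# Forward spectra of a real signal matrix, computed once and reused for
# several decimation targets. Pairs of real columns are packed into single
# complex transforms to halve the FFT cost.
fft_spectra <- function(x) {
  n <- nrow(x)
  ntr <- ncol(x)
  n_cols <- ceiling(ntr / 2)
  if (2 * n_cols > ntr) x <- cbind(x, 0)
  z <- x[, seq_len(n_cols), drop = FALSE] +
    1i * x[, n_cols + seq_len(n_cols), drop = FALSE]
  spec <- stats::mvfft(z)
  rev_idx <- c(1L, n:2L)
  list(
    sa = (spec + Conj(spec[rev_idx, , drop = FALSE])) / 2,
    sb = (spec - Conj(spec[rev_idx, , drop = FALSE])) / (2i),
    n = n, n_cols = n_cols, ntr = ntr
  )
}

# Band-limited resampling to `m` samples by spectral truncation, from
# precomputed spectra (content above the new Nyquist is discarded).
resample_from_spectra <- function(sp, m) {
  keep <- m %/% 2
  trunc_pack <- function(s) {
    out <- matrix(0 + 0i, m, sp$n_cols)
    out[1, ] <- s[1, ]
    out[2:keep, ] <- s[2:keep, , drop = FALSE]
    out[(m - keep + 2):m, ] <- s[(sp$n - keep + 2):sp$n, , drop = FALSE]
    out
  }
  zd <- stats::mvfft(trunc_pack(sp$sa) + 1i * trunc_pack(sp$sb), inverse = TRUE) / sp$n
  cbind(Re(zd), Im(zd))[, seq_len(sp$ntr), drop = FALSE]
}

decimate_fft <- function(x, m) resample_from_spectra(fft_spectra(x), m)

# Number of tapers for the high-frequency range: linear interpolation
# from 4 at 32 Hz to 31 at 200 Hz, rounded.
hf_taper_count <- function(f) {
  pmin(31L, pmax(4L, as.integer(round(4 + (31 - 4) * (f - 32) / (200 - 32)))))
}

#' Default time-frequency analysis grid
#'
#' 1 Hz steps from 1 to 32 Hz (constant-cycle windows) and 4 Hz steps from
#' 36 to 200 Hz (fixed-length windows).
#' @return Numeric vector of frequencies (Hz).
#' @export
tfr_grid <- function() c(1:32, seq(36, 200, by = 4))

# Multitaper power for one site's signal matrix (time x trial) at the
# given frequencies. Returns a [trial, freq, time] array with NA at grid
# times whose analysis window does not fit inside the epoch.
tfr_site <- function(x, fs, times_in, freqs, times_out, cycles = 6,
                     n_tapers_low = 3, nw_low = 2.2, hf_cutoff = 32,
                     hf_window = 0.2, low_decimate = TRUE) {
  ntr <- ncol(x)
  pow <- array(NA_real_, c(ntr, length(freqs), length(times_out)))
  epoch0 <- times_in[1]
  duration <- length(times_in) / fs

  project_power <- function(xm, rate, f, w, tapers, centers_idx, out_cols) {
    k <- ncol(tapers)
    tau <- (seq_len(w) - 1) / rate
    tc <- cbind(tapers * cos(2 * pi * f * tau), tapers * sin(2 * pi * f * tau))
    starts <- centers_idx - (w %/% 2)
    idx <- outer(seq_len(w) - 1L, starts, `+`)
    nc <- length(starts)
    segs <- matrix(xm[as.vector(idx) + rep((seq_len(ncol(xm)) - 1L) * nrow(xm),
      each = w * nc
    )], w, nc * ncol(xm))
    proj <- crossprod(tc, segs)
    p <- (colSums(proj[seq_len(k), , drop = FALSE]^2) +
      colSums(proj[k + seq_len(k), , drop = FALSE]^2)) / (k * rate)
    # p is centers-major within trial blocks; 1/rate puts estimates on a
    # density scale so all analysis rates share one unit
    list(p = matrix(p, nc, ncol(xm)), out_cols = out_cols)
  }

  low <- freqs[freqs <= hf_cutoff]
  if (length(low)) {
    # analysis rate per frequency: the smallest candidate rate that leaves
    # headroom for the frequency plus its taper bandwidth; frequencies
    # sharing a rate share one decimated copy of the signal
    rate_f <- rep(fs, length(low))
    if (low_decimate) {
      t_step <- if (length(times_out) > 1) min(diff(times_out)) else 0.05
      cand <- seq(40, fs, by = 20)
      cand <- cand[abs(cand * t_step - round(cand * t_step)) < 1e-9 &
        abs(cand * duration - round(cand * duration)) < 1e-9]
      if (length(cand)) {
        need <- low * (1 + nw_low / cycles) / 0.45
        rate_f <- vapply(need, function(nd) {
          ok <- cand[cand >= nd]
          if (length(ok)) min(ok) else fs
        }, numeric(1))
      }
    }
    sp <- if (any(rate_f < fs)) fft_spectra(x) else NULL
    for (rate in unique(rate_f)) {
      xl <- if (rate < fs) {
        resample_from_spectra(sp, as.integer(round(rate * duration)))
      } else {
        x
      }
      for (f in low[rate_f == rate]) {
        w <- max(4L, as.integer(round(cycles / f * rate)))
        half <- (w / 2) / rate
        fits <- times_out - half >= epoch0 - 1e-9 &
          times_out + half <= epoch0 + duration + 1e-9
        if (!any(fits)) next
        centers_idx <- as.integer(round((times_out[fits] - epoch0) * rate)) + 1L
        centers_idx <- pmin(pmax(centers_idx, w %/% 2 + 1L), nrow(xl) - (w - w %/% 2) + 1L)
        tapers <- dpss_tapers(w, nw_low, n_tapers_low)
        res <- project_power(xl, rate, f, w, tapers, centers_idx, which(fits))
        pow[, which(freqs == f), res$out_cols] <- t(res$p)
      }
    }
  }

  high <- freqs[freqs > hf_cutoff]
  if (length(high)) {
    w <- as.integer(round(hf_window * fs))
    half <- (w / 2) / fs
    fits <- times_out - half >= epoch0 - 1e-9 &
      times_out + half <= epoch0 + duration + 1e-9
    if (any(fits)) {
      centers_idx <- as.integer(round((times_out[fits] - epoch0) * fs)) + 1L
      centers_idx <- pmin(pmax(centers_idx, w %/% 2 + 1L), nrow(x) - (w - w %/% 2) + 1L)
      starts <- centers_idx - (w %/% 2)
      idx <- outer(seq_len(w) - 1L, starts, `+`)
      nc <- length(starts)
      segs <- matrix(x[as.vector(idx) + rep((seq_len(ntr) - 1L) * nrow(x),
        each = w * nc
      )], w, nc * ntr)
      tau <- (seq_len(w) - 1) / fs
      for (fi in seq_along(high)) {
        f <- high[fi]
        k <- hf_taper_count(f)
        tapers <- dpss_tapers(w, (k + 1) / 2, k)
        tc <- cbind(tapers * cos(2 * pi * f * tau), tapers * sin(2 * pi * f * tau))
        proj <- crossprod(tc, segs)
        p <- (colSums(proj[seq_len(k), , drop = FALSE]^2) +
          colSums(proj[k + seq_len(k), , drop = FALSE]^2)) / (k * fs)
        pow[, which(freqs == f), which(fits)] <- t(matrix(p, nc, ntr))
      }
    }
  }
  pow
}

#' Multitaper time-frequency decomposition
#'
#' Estimates spectral power with Slepian tapers: below `hf_cutoff` Hz each
#' frequency uses a `cycles`-cycle window with `n_tapers_low` tapers
#' (window duration shrinks as frequency grows); above the cutoff a fixed
#' `hf_window`-second window is used with a taper count interpolated from
#' 4 (at 32 Hz) to 31 (at 200 Hz) for increased spectral smoothing. For the
#' low range the signal is first resampled (band-limited spectral
#' truncation) to the smallest rate that accommodates the highest analysis
#' frequency plus taper bandwidth, which keeps the cost independent of the
#' acquisition rate. Grid times whose window does not fit inside the epoch
#' are returned as `NA`.
#'
#' @param epochs An `lfp_epochs` object.
#' @param freqs Frequencies (Hz); defaults to [tfr_grid()].
#' @param t_step Output time stride (s).
#' @param cycles,n_tapers_low Low-range window length (cycles) and taper count.
#' @param nw_low Time-half-bandwidth product of the low-range tapers. The
#'   default 2.2 keeps the third Slepian well concentrated (eigenvalue
#'   0.98, versus 0.96 at the minimal 2.0) while its main lobe at the
#'   bottom of the beta band stays clear of the 4-12 Hz range; poorly
#'   concentrated tapers leak strong low-frequency oscillations into
#'   neighboring-band estimates.
#' @param hf_cutoff,hf_window High-range cutoff (Hz) and window length (s).
#' @param low_decimate Disable to analyze the low range at the full rate.
#' @return An object of class `tf_power`: per-site `[trial, freq, time]`
#'   arrays of raw power plus axis metadata.
#' @export
multitaper_tfr <- function(epochs, freqs = NULL, t_step = 0.05, cycles = 6,
                           n_tapers_low = 3, nw_low = 2.2, hf_cutoff = 32,
                           hf_window = 0.2, low_decimate = TRUE) {
  freqs <- sort(freqs %||% tfr_grid())
  fs <- epochs$fs
  if (max(freqs) >= fs / 2) {
    abort("Requested frequencies reach the Nyquist frequency.")
  }
  duration <- length(epochs$times) / fs
  if (min(freqs) < cycles / duration) {
    abort(sprintf(
      "Epoch too short for a %d-cycle window at %.3g Hz.", cycles, min(freqs)
    ))
  }
  times_out <- seq(epochs$times[1], epochs$times[1] + duration, by = t_step)
  power <- lapply(epochs$signal, tfr_site,
    fs = fs, times_in = epochs$times,
    freqs = freqs, times_out = times_out, cycles = cycles,
    n_tapers_low = n_tapers_low, nw_low = nw_low, hf_cutoff = hf_cutoff,
    hf_window = hf_window, low_decimate = low_decimate
  )
  structure(
    list(
      power = power, freqs = freqs, times = times_out,
      sites = epochs$sites, trials = epochs$trials, lock = epochs$lock,
      fs = fs, normalized = FALSE
    ),
    class = "tf_power"
  )
}

#' @export
print.tf_power <- function(x, ...) {
  cat(sprintf(
    "Time-frequency power: %d sites, %d frequencies (%g-%g Hz), %d times (%s)\n",
    length(x$power), length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$times), if (x$normalized) "normalized" else "raw"
  ))
  invisible(x)
}

#' Log-transform and z-score spectral power
#'
#' Power is first converted to a decibel-like scale (`log10`), then
#' z-scored. With `method = "trialwise"` (default) each trial is normalized
#' by the mean and standard deviation of its own log-power over the whole
#' epoch, per site and frequency (a per-trial baseline using the full
#' window centered on the event of interest); `method = "pooled"` uses the
#' mean and SD pooled over all the site's trials and times, per frequency.
#' Trials with degenerate (zero) variance at a frequency are set to `NA`.
#'
#' @param tf A raw `tf_power` object.
#' @param method Normalization scope.
#' @return The `tf_power` object with normalized values.
#' @export
normalize_power <- function(tf, method = c("trialwise", "pooled")) {
  method <- match.arg(method)
  if (tf$normalized) abort("Power is already normalized.")
  for (i in seq_along(tf$power)) {
    arr <- tf$power[[i]]
    finite <- is.finite(arr)
    if (any(arr[finite] <= 0)) {
      abort("Non-positive power encountered; cannot log-transform.")
    }
    arr <- log10(arr)
    d <- dim(arr)
    n_t <- apply(finite, c(1, 2), sum)
    s1 <- rowSums(arr, dims = 2, na.rm = TRUE)
    s2 <- rowSums(arr^2, dims = 2, na.rm = TRUE)
    if (method == "trialwise") {
      m <- s1 / n_t
      v <- (s2 - n_t * m^2) / pmax(n_t - 1, 1)
    } else {
      m_f <- colSums(s1) / colSums(n_t)
      v_f <- (colSums(s2) - colSums(n_t) * m_f^2) / pmax(colSums(n_t) - 1, 1)
      m <- matrix(m_f, d[1], d[2], byrow = TRUE)
      v <- matrix(v_f, d[1], d[2], byrow = TRUE)
    }
    bad <- v < .Machine$double.eps
    sdev <- sqrt(pmax(v, .Machine$double.eps))
    arr <- (arr - c(m)) / c(sdev)
    if (any(bad)) {
      flat <- which(bad)
      for (b in flat) arr[((b - 1) %% d[1]) + 1, ((b - 1) %/% d[1]) + 1, ] <- NA_real_
    }
    tf$power[[i]] <- arr
  }
  tf$normalized <- TRUE
  tf$normalization <- method
  tf
}

#' Detect and exclude artifact-contaminated trials
#'
#' For each site, root-mean-square signal amplitude is computed in sliding
#' windows across the epoch and compared with `z_thresh` times the
#' standard deviation of the site's signal pooled over all its trials; any
#' trial containing a suprathreshold window is excluded. A sustained
#' excursion of five times the ongoing signal's standard deviation within
#' 50 ms is far outside the range of stationary background activity but is
#' reached by interictal-discharge-like transients, which keeps the
#' false-positive rate on clean data near zero. With
#' `threshold = "window_stats"` the exclusion threshold is instead the
#' mean plus `z_thresh` SDs of the window powers themselves; note that
#' under realistic 1/f background the window-power distribution is heavy
#' tailed and this variant over-excludes.
#'
#' @param epochs An `lfp_epochs` object.
#' @param window Sliding-window length (s).
#' @param overlap Fractional window overlap.
#' @param z_thresh Threshold multiplier.
#' @param threshold Thresholding rule (see above).
#' @return A list of class `artifact_report`: `valid` (per-site logical
#'   vectors), `fraction` (per-site exclusion fraction) and a summary
#'   tibble. Sites with more than 50% exclusions trigger a warning.
#' @export
reject_artifact_trials <- function(epochs, window = 0.05, overlap = 0.5,
                                   z_thresh = 5,
                                   threshold = c("signal_sd", "window_stats")) {
  threshold <- match.arg(threshold)
  fs <- epochs$fs
  w <- max(2L, as.integer(round(window * fs)))
  hop <- max(1L, as.integer(round(w * (1 - overlap))))
  valid <- vector("list", length(epochs$signal))
  frac <- numeric(length(epochs$signal))
  for (i in seq_along(epochs$signal)) {
    x <- epochs$signal[[i]]
    n <- nrow(x)
    ntr <- ncol(x)
    starts <- seq(1L, n - w + 1L, by = hop)
    idx <- as.vector(outer(seq_len(w) - 1L, starts, `+`))
    segs <- matrix(
      x[idx + rep((seq_len(ntr) - 1L) * n, each = length(idx))]^2,
      w, length(starts) * ntr
    )
    p <- matrix(colMeans(segs), length(starts), ntr)
    if (threshold == "signal_sd") {
      thr <- (z_thresh * stats::sd(x))^2
    } else {
      mu <- mean(p)
      sd_p <- stats::sd(p)
      thr <- if (!is.finite(sd_p) || sd_p < .Machine$double.eps) {
        Inf
      } else {
        mu + z_thresh * sd_p
      }
    }
    valid[[i]] <- .colSums(p > thr, length(starts), ntr) == 0L
    frac[i] <- 1 - mean(valid[[i]])
    if (frac[i] > 0.5) {
      warn(sprintf("Site %d: %.0f%% of trials excluded.", i, 100 * frac[i]))
    }
  }
  structure(
    list(
      valid = valid, fraction = frac,
      summary = tibble::tibble(
        site_id = epochs$sites$site_id,
        n_trials = vapply(valid, length, integer(1)),
        n_excluded = vapply(valid, function(v) sum(!v), integer(1)),
        fraction = frac
      )
    ),
    class = "artifact_report"
  )
}

#' Longitudinal bipolar montage from monopolar contacts
#'
#' Raw depth-electrode recordings referenced to a common contact are
#' re-referenced as differences between longitudinally adjacent contacts
#' (three bipolar channels per four-contact electrode), emphasizing local
#' field sources. This is a preprocessing utility for imported raw data;
#' the synthetic generator emits already-referenced site signals.
#'
#' @param contacts Numeric matrix, one column per contact in
#'   ventral-to-dorsal order along one electrode.
#' @return Matrix with `ncol(contacts) - 1` columns of adjacent-pair
#'   differences, named `<upper>-<lower>`.
#' @export
bipolar_montage <- function(contacts) {
  contacts <- as.matrix(contacts)
  if (ncol(contacts) < 2) abort("Need at least two contacts.")
  if (is.null(colnames(contacts))) {
    colnames(contacts) <- paste0("c", seq_len(ncol(contacts)))
  }
  out <- contacts[, -1, drop = FALSE] - contacts[, -ncol(contacts), drop = FALSE]
  colnames(out) <- paste0(
    colnames(contacts)[-1], "-", colnames(contacts)[-ncol(contacts)]
  )
  out
}

#' Canonical frequency bands
#'
#' delta (1-4 Hz, upper edge exclusive), LFO (low-frequency oscillations,
#' 4-12 Hz), beta (13-33 Hz) and gamma (50-150 Hz).
#' @return A tibble with `band`, `lo`, `hi`.
#' @export
band_defs <- function() {
  tibble::tibble(
    band = c("delta", "LFO", "beta", "gamma"),
    lo = c(1, 4, 13, 50),
    hi = c(4, 12, 33, 150)
  )
}

band_bins <- function(freqs, band) {
  if (is.character(band)) {
    defs <- band_defs()
    row <- defs[defs$band == band, ]
    if (nrow(row) == 0) abort(sprintf("Unknown band `%s`.", band))
    # the 4 Hz boundary bin belongs to the LFO band, not delta
    if (band == "delta") {
      return(which(freqs >= row$lo & freqs < row$hi))
    }
    band <- c(row$lo, row$hi)
  }
  which(freqs >= band[1] & freqs <= band[2])
}

#' Average time-frequency power over a frequency band
#'
#' Unweighted mean over the frequency bins inside the band; optionally also
#' over a time window, yielding one scalar per site and trial.
#'
#' @param tf A `tf_power` object (normally normalized).
#' @param band Band name (see [band_defs()]) or a `c(lo, hi)` pair in Hz.
#' @param time_window Optional `c(from, to)` window (s). When given, the
#'   result is a tibble of per-trial scalar powers; otherwise a
#'   `band_power` time-series object.
#' @export
band_average <- function(tf, band = "LFO", time_window = NULL) {
  bins <- band_bins(tf$freqs, band)
  if (!length(bins)) abort("Band does not intersect the frequency grid.")
  series <- lapply(tf$power, function(arr) {
    d <- dim(arr)
    if (length(bins) == 1) {
      out <- arr[, bins, ]
      if (is.null(dim(out))) out <- matrix(out, nrow = d[1])
      return(out)
    }
    sub <- arr[, bins, , drop = FALSE] # trial x bin x time
    m <- aperm(sub, c(2, 1, 3))
    matrix(.colMeans(m, length(bins), d[1] * d[3]), d[1], d[3])
  })
  if (!is.null(time_window)) {
    cols <- which(tf$times >= time_window[1] & tf$times <= time_window[2])
    if (!length(cols)) abort("`time_window` does not intersect the time grid.")
    rows <- lapply(seq_along(series), function(i) {
      tibble::tibble(
        site_id = tf$sites$site_id[i],
        patient_id = tf$sites$patient_id[i],
        trial_row = which(tf$trials$patient_id == tf$sites$patient_id[i]),
        power = rowMeans(series[[i]][, cols, drop = FALSE])
      )
    })
    return(dplyr::bind_rows(rows))
  }
  structure(
    list(
      series = series, times = tf$times, band = band, sites = tf$sites,
      trials = tf$trials, lock = tf$lock, normalized = tf$normalized
    ),
    class = "band_power"
  )
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf(
    "Band power time series (%s): %d sites, %d time points\n",
    paste(x$band, collapse = "-"), length(x$series), length(x$times)
  ))
  invisible(x)
}
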