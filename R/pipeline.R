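#' Full pipeline configuration
#'
#' Collects the stage configurations into one round-trippable list. Every
#' stochastic stage derives its seed from the single `seed` passed to
#' [run_pipeline()], so a run is fully reproducible from (config, seed).
#'
#' @param task A [task_config()].
#' @param agent Agent parameters for the simulated cohort.
#' @param encoding An [encoding_spec()].
#' @param spectral List: `t_step`, `band`, `normalization`.
#' @param glm List: `regressors`, `condition`s to fit, `min_trials`.
#' @param cluster List: `n_shuffles`, `n_combinations`, `alpha_cluster`.
#' @param bms List: `window` (post-outcome seconds), `n_samples`.
#' @param run_bms Whether to run the band model-selection stage (the most
#'   expensive stage, since it needs all four bands).
#' @return A list of class `run_config`.
#' @export
run_config <- function(task = task_config(n_sessions = 1, n_patients = 4),
                       agent = list(alpha = 0.3, beta = 0.3),
                       encoding = encoding_spec(gain_q = 0.3, gain_r = -0.2),
                       spectral = list(
                         t_step = 0.05, band = "LFO",
                         normalization = "trialwise"
                       ),
                       glm = list(
                         regressors = c("z_q", "z_r"),
                         conditions = c("reward", "punishment"),
                         min_trials = 20
                       ),
                       cluster = list(
                         n_shuffles = 100, n_combinations = 2000,
                         alpha_cluster = 0.05
                       ),
                       bms = list(window = c(0, 2), n_samples = 1e5),
                       run_bms = TRUE) {
  structure(
    list(
      task = task, agent = agent, encoding = encoding, spectral = spectral,
      glm = glm, cluster = cluster, bms = bms, run_bms = run_bms
    ),
    class = "run_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    task = do.call(task_config, raw$task[names(raw$task) %in% names(formals(task_config))]),
    agent = raw$agent,
    encoding = do.call(encoding_spec, raw$encoding[
      names(raw$encoding) %in% names(formals(encoding_spec))
    ]),
    spectral = raw$spectral, glm = raw$glm, cluster = raw$cluster,
    bms = raw$bms, run_bms = raw$run_bms
  )
  cfg
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> fit-behavior -> synthesize/preprocess -> encode ->
#' cluster -> band model selection, writing tabular/JSON outputs and a run
#' manifest (stage status, seeds, file digests, timings, exclusion
#' fractions) to `out_dir`. Deterministic given (config, seed).
#'
#' @param config A [run_config()].
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing and returns results only.
#' @param trials Optional pre-existing trial table (skips simulation).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = run_config(), seed = 1L, out_dir = NULL,
                         trials = NULL) {
  t_start <- proc.time()[3]
  stages <- list()
  written <- character()
  tick <- function(name) {
    stages[[name]] <<- list(status = "complete", at = proc.time()[3] - t_start)
  }
  emit <- function(obj, file, writer) {
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      path <- file.path(out_dir, file)
      writer(obj, path)
      written <<- c(written, path)
    }
  }

  # -- simulate -------------------------------------------------------
  if (is.null(trials)) {
    trials <- simulate_cohort(config$task, config$agent,
      seed = substream_seed(seed, "simulate")
    )
  } else {
    assert_trials(trials)
  }
  emit(trials, "trials.tsv", function(x, p) {
    utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE)
  })
  tick("simulate")

  # -- fit behavior ---------------------------------------------------
  fits <- fit_cohort(trials)
  behavior <- behavioral_summary(trials)
  trials <- dplyr::bind_rows(lapply(
    split(trials, trials$patient_id),
    function(tp) {
      compute_regressors(tp, fits$fit[[match(tp$patient_id[1], fits$patient_id)]])
    }
  ))
  emit(fits, "fits.json", function(x, p) {
    payload <- x[c(
      "patient_id", "alpha", "beta", "nll", "aic",
      "aic_random", "n_trials"
    )]
    payload$session_nll <- lapply(x$fit, function(f) as.list(f$session_nll))
    jsonlite::write_json(payload, p, digits = NA)
  })
  emit(behavior, "behavior.json", function(x, p) {
    jsonlite::write_json(lapply(x, as.data.frame), p, digits = NA, na = "null")
  })
  tick("fit_behavior")

  # -- synthesize epochs + artifact screening -------------------------
  epochs <- synthesize_epochs(trials, config$encoding,
    seed = substream_seed(seed, "epochs"), lock = "outcome"
  )
  if (config$encoding$artifact_rate > 0) {
    epochs <- inject_artifacts(epochs, seed = substream_seed(seed, "artifacts"))
  }
  artifacts <- reject_artifact_trials(epochs)
  tick("synthesize")

  # -- spectral preprocessing ----------------------------------------
  band_freqs <- tfr_grid()
  band_freqs <- band_freqs[band_freqs %in%
    band_freqs[band_bins(band_freqs, config$spectral$band)]]
  tf <- multitaper_tfr(epochs,
    freqs = band_freqs,
    t_step = config$spectral$t_step
  )
  tf <- normalize_power(tf, method = config$spectral$normalization)
  bp <- band_average(tf, config$spectral$band)
  emit(bp, paste0("band_", config$spectral$band, "_tcourse.tsv"), function(x, p) {
    mats <- lapply(seq_along(x$series), function(i) {
      colMeans(x$series[[i]], na.rm = TRUE)
    })
    df <- data.frame(time = x$times, do.call(cbind, mats))
    names(df) <- c("time", paste0("site_", x$sites$site_id))
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  })
  tick("preprocess")

  # -- encoding + cluster statistics ---------------------------------
  encodings <- list()
  clusters <- list()
  for (cond in config$glm$conditions) {
    map <- encode_band(bp,
      condition = cond, regressors = config$glm$regressors,
      valid = artifacts$valid, min_trials = config$glm$min_trials
    )
    encodings[[cond]] <- map
    clusters[[cond]] <- cluster_correct(
      bp,
      condition = cond, regressors = config$glm$regressors,
      valid = artifacts$valid, min_trials = config$glm$min_trials,
      n_shuffles = config$cluster$n_shuffles,
      n_combinations = config$cluster$n_combinations,
      alpha_cluster = config$cluster$alpha_cluster,
      seed = substream_seed(seed, "cluster", cond)
    )
  }
  emit(clusters, "clusters.json", function(x, p) {
    out <- lapply(x, function(cl) {
      lapply(cl$by_regressor, function(r) {
        as.data.frame(r$clusters[, c("t_start", "t_end", "sign", "stat", "pc")])
      })
    })
    jsonlite::write_json(out, p, digits = NA)
  })
  tick("encode_cluster")

  # -- band model selection ------------------------------------------
  bms <- NULL
  if (isTRUE(config$run_bms)) {
    bms <- list()
    band_table <- pe_band_table(epochs, config,
      valid = artifacts$valid
    )
    for (cond in config$glm$conditions) {
      d <- band_table[band_table$condition == cond, ]
      lme <- band_lme_matrix(d)
      bms[[cond]] <- list(
        pe_fits = lapply(
          c("delta", "LFO", "beta", "gamma"),
          function(b) {
            band_pe_regression(
              dplyr::rename(d[, c("site_id", "pe", paste0("P_", b))],
                power = paste0("P_", b)
              )
            )
          }
        ),
        bms = rfx_bms(lme,
          n_samples = config$bms$n_samples,
          seed = substream_seed(seed, "bms", cond)
        )
      )
      names(bms[[cond]]$pe_fits) <- c("delta", "LFO", "beta", "gamma")
    }
    emit(bms, "bms.json", function(x, p) {
      out <- lapply(x, function(b) {
        list(
          ef = as.list(b$bms$ef), xp = as.list(b$bms$xp),
          winner = b$bms$winner,
          band_t = lapply(b$pe_fits, function(f) {
            list(mean_beta = f$mean_beta, t = f$t, df = f$df, p = f$p)
          })
        )
      })
      jsonlite::write_json(out, p, digits = NA, auto_unbox = TRUE)
    })
    tick("bms")
  }

  manifest <- list(
    seed = seed,
    stages = stages,
    exclusion_fraction = mean(artifacts$fraction),
    files = if (length(written)) {
      as.list(tools::md5sum(written))
    } else {
      list()
    },
    elapsed_s = proc.time()[3] - t_start
  )
  emit(manifest, "manifest.json", function(x, p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
  })

  invisible(list(
    trials = trials, fits = fits, behavior = behavior, epochs = epochs,
    artifacts = artifacts, band_power = bp, encodings = encodings,
    clusters = clusters, bms = bms, manifest = manifest
  ))
}

#' Per-trial band powers and prediction errors for model selection
#'
#' Runs the spectral path for the four canonical bands and assembles the
#' site-trial table used by [band_lme_matrix()] / [band_pe_regression()]:
#' band power averaged over the post-outcome window plus the trial's
#' z-scored prediction error.
#'
#' @param epochs An `lfp_epochs` whose trials carry `z_pe`.
#' @param config A [run_config()] (uses the bms window and normalization).
#' @param valid Optional artifact masks.
#' @return Tibble: `site_id`, `patient_id`, `condition`, `pe`, `P_delta`,
#'   `P_LFO`, `P_beta`, `P_gamma`.
#' @export
pe_band_table <- function(epochs, config = run_config(), valid = NULL) {
  grid <- tfr_grid()
  bands <- c("delta", "LFO", "beta", "gamma")
  freqs <- sort(unique(unlist(lapply(bands, function(b) {
    grid[band_bins(grid, b)]
  }))))
  tf <- multitaper_tfr(epochs,
    freqs = freqs,
    t_step = config$spectral$t_step %||% 0.05
  )
  tf <- normalize_power(tf, method = config$spectral$normalization %||% "trialwise")
  tabs <- lapply(bands, function(b) {
    tab <- band_average(tf, b, time_window = config$bms$window)
    names(tab)[names(tab) == "power"] <- paste0("P_", b)
    tab
  })
  out <- Reduce(
    function(a, b) dplyr::left_join(a, b, by = c("site_id", "patient_id", "trial_row")),
    tabs
  )
  out$pe <- epochs$trials$z_pe[out$trial_row]
  out$condition <- epochs$trials$condition[out$trial_row]
  if (!is.null(valid)) {
    site_pos <- match(out$site_id, epochs$sites$site_id)
    within <- stats::ave(out$trial_row, out$site_id, FUN = seq_along)
    out <- out[mapply(function(s, j) valid[[s]][j], site_pos, within), ]
  }
  out[!is.na(out$pe), ]
}

#' Import a deposited cohort directory
#'
#' Adapter for locally downloaded data: expects `trials.tsv` (the trial
#' table layout written by [run_pipeline()]) and optionally an `epochs/`
#' directory holding one Feather file per recording site
#' (`site_<id>.feather`, one column per trial) plus `meta.json` with
#' `fs`, `epoch`, `lock` and the site-to-patient map. Trial tables are
#' validated against the task invariants with the offending row named.
#'
#' @param dir Directory path.
#' @return A list with `trials` and, when present, `epochs`.
#' @export
import_accession <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("Directory `%s` does not exist.", dir))
  trial_path <- file.path(dir, "trials.tsv")
  if (!file.exists(trial_path)) {
    abort(paste0(
      "Unrecognized layout: expected `trials.tsv` (and optionally ",
      "`epochs/site_<id>.feather` + `epochs/meta.json`) under ", dir
    ))
  }
  trials <- tibble::as_tibble(utils::read.delim(trial_path))
  assert_trials(trials)

  epochs_dir <- file.path(dir, "epochs")
  epochs <- NULL
  if (dir.exists(epochs_dir)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("Package `arrow` is needed to read epoch containers.")
    }
    meta <- jsonlite::read_json(file.path(epochs_dir, "meta.json"),
      simplifyVector = TRUE
    )
    sites <- tibble::tibble(
      site_id = as.integer(meta$sites$site_id),
      patient_id = meta$sites$patient_id
    )
    signal <- lapply(sites$site_id, function(sid) {
      unname(as.matrix(arrow::read_feather(
        file.path(epochs_dir, sprintf("site_%d.feather", sid))
      )))
    })
    n <- nrow(signal[[1]])
    epochs <- structure(
      list(
        signal = signal, sites = sites, trials = trials,
        times = meta$epoch[1] + (seq_len(n) - 1) / meta$fs,
        fs = meta$fs, lock = meta$lock,
        spec = encoding_spec(
          sampling_rate = meta$fs,
          epoch = as.numeric(meta$epoch)
        )
      ),
      class = "lfp_epochs"
    )
  }
  list(trials = trials, epochs = epochs)
}

#' Export an epoch container to an accession-style directory
#'
#' Writes the layout read by [import_accession()].
#' @param epochs An `lfp_epochs` object.
#' @param dir Target directory.
#' @export
export_accession <- function(epochs, dir) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    abort("Package `arrow` is needed to write epoch containers.")
  }
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(epochs$trials, file.path(dir, "trials.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  for (i in seq_along(epochs$signal)) {
    df <- as.data.frame(epochs$signal[[i]])
    names(df) <- paste0("trial_", seq_len(ncol(df)))
    arrow::write_feather(df, file.path(
      dir, "epochs",
      sprintf("site_%d.feather", epochs$sites$site_id[i])
    ))
  }
  jsonlite::write_json(
    list(
      fs = epochs$fs, epoch = range(epochs$times) + c(0, 1 / epochs$fs),
      lock = epochs$lock,
      sites = as.data.frame(epochs$sites)
    ),
    file.path(dir, "epochs", "meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
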