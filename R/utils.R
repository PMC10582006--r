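#' @importFrom rlang abort warn .data
#' @importFrom stats qt sd var rnorm runif rlnorm rbinom rgamma optim pt
#' @importFrom utils head tail
NULL

# Deterministic substream derivation. A single cohort seed spawns
# per-patient / per-site / per-stage seeds so that any subset of the
# pipeline can be regenerated independently yet bit-identically.
# Keys are small integers (or strings, folded to integers).
substream_seed <- function(seed, ...) {
  keys <- list(...)
  s <- as.double(seed %% 2147483647L)
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k))
    s <- (s * 69069 + as.double(k) * 1234567 + 1) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# z-score using the statistics of a reference subset (e.g. valid trials).
# Returns NA (with a warning upstream) when the reference has no variance.
zscore_by <- function(x, ref = rep(TRUE, length(x))) {
  m <- mean(x[ref])
  s <- stats::sd(x[ref])
  if (!is.finite(s) || s < .Machine$double.eps^0.5) {
    return(rep(NA_real_, length(x)))
  }
  (x - m) / s
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a finite scalar in [%g, %g].", name, lo, hi))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_trials <- function(trials) {
  req <- c(
    "patient_id", "session_id", "trial_index", "pair_id", "condition",
    "cue_chosen", "outcome", "rt"
  )
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols)) {
    abort(paste0(
      "Trial table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(trials) == 0L) abort("Trial table is empty.")
  bad <- which(trials$condition == "punishment" & trials$outcome > 0)
  if (length(bad)) {
    abort(sprintf(
      "Punishment-condition trials must have outcomes in {-1, 0}; first offending row: %d",
      bad[1]
    ))
  }
  bad <- which(trials$condition == "reward" & trials$outcome < 0)
  if (length(bad)) {
    abort(sprintf(
      "Reward-condition trials must have outcomes in {0, +1}; first offending row: %d",
      bad[1]
    ))
  }
  bad <- which(!(trials$rt > 0))
  if (length(bad)) {
    abort(sprintf("Reaction times must be positive; first offending row: %d", bad[1]))
  }
  invisible(trials)
}
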