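#' Ordinary least squares of trial-wise power on design columns
#'
#' Fits `Y = a + X b` independently for every response column (one per
#' time or time-frequency point). An intercept is always included, so the
#' estimates are invariant to adding a constant to `Y`. Rows with missing
#' values in `X` are rejected; response columns containing missing values
#' yield `NA` estimates.
#'
#' @param y Numeric matrix (trials x points) or vector of responses.
#' @param x Numeric matrix (trials x regressors) with column names;
#'   regressors are expected to be z-scored.
#' @return Matrix of estimates (regressors x points), intercept excluded.
#' @export
fit_glm_trials <- function(y, x) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(y) != nrow(x)) abort("`y` and `x` must have the same number of rows.")
  if (nrow(x) < ncol(x) + 1 + 3) {
    abort("Need at least 3 more trials than design columns.")
  }
  if (anyNA(x)) abort("Design matrix contains missing values.")
  xf <- cbind(`(intercept)` = 1, x)
  qr_x <- qr(xf)
  if (qr_x$rank < ncol(xf)) {
    dropped <- colnames(xf)[qr_x$pivot[(qr_x$rank + 1):ncol(xf)]]
    abort(paste0(
      "Design is rank deficient; collinear column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  ok <- !apply(is.na(y), 2, any)
  beta <- matrix(NA_real_, ncol(xf), ncol(y))
  if (any(ok)) beta[, ok] <- qr.coef(qr_x, y[, ok, drop = FALSE])
  rownames(beta) <- colnames(xf)
  beta[-1, , drop = FALSE]
}

#' Trial-wise encoding model over a band time series
#'
#' Regresses each site's normalized band power, at every time point, on
#' z-scored model regressors across that patient's trials of one
#' condition (reward designs use expected value and outcome; cue- or
#' choice-locked designs typically use expected value only). Artifact
#' trials are excluded listwise; sites with fewer than `min_trials` usable
#' trials are dropped.
#'
#' @param bp A `band_power` time series (see [band_average()]).
#' @param condition Condition to fit (`"reward"` or `"punishment"`), or
#'   `NULL` to use all trials.
#' @param regressors Names of z-scored regressor columns in the trial table.
#' @param valid Optional per-site logical lists (from
#'   [reject_artifact_trials()]).
#' @param min_trials Minimum usable trials per site.
#' @return An `encoding_map`: `betas` array `[site, regressor, time]`,
#'   usable-trial counts, and axis metadata.
#' @export
encode_band <- function(bp, condition = "reward",
                        regressors = c("z_q", "z_r"), valid = NULL,
                        min_trials = 20) {
  trials <- bp$trials
  n_sites <- length(bp$series)
  betas <- array(NA_real_, c(n_sites, length(regressors), length(bp$times)),
    dimnames = list(NULL, regressors, NULL)
  )
  n_used <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    rows <- which(trials$patient_id == bp$sites$patient_id[i])
    keep <- rep(TRUE, length(rows))
    if (!is.null(condition)) keep <- trials$condition[rows] == condition
    if (!is.null(valid)) keep <- keep & valid[[i]]
    x <- as.matrix(trials[rows, regressors])
    keep <- keep & !apply(is.na(x), 1, any)
    n_used[i] <- sum(keep)
    if (n_used[i] < max(min_trials, ncol(x) + 4)) next
    y <- bp$series[[i]][keep, , drop = FALSE]
    betas[i, , ] <- fit_glm_trials(y, x[keep, , drop = FALSE])
  }
  structure(
    list(
      betas = betas, regressors = regressors, times = bp$times,
      condition = condition %||% "all", lock = bp$lock, band = bp$band,
      sites = bp$sites, n_used = n_used, min_trials = min_trials
    ),
    class = "encoding_map"
  )
}

#' @export
print.encoding_map <- function(x, ...) {
  cat(sprintf(
    "Encoding map (%s, %s-locked): %d sites x %d regressors x %d times\n",
    x$condition, x$lock, dim(x$betas)[1], dim(x$betas)[2], dim(x$betas)[3]
  ))
  invisible(x)
}

# t statistics across sites for a site x points estimate matrix
t_across_sites <- function(b) {
  ok <- is.finite(b)
  n <- colSums(ok)
  m <- colMeans(b, na.rm = TRUE)
  s <- sqrt(pmax(colMeans(b^2, na.rm = TRUE) - m^2, 0) * n / pmax(n - 1, 1))
  degenerate <- s < .Machine$double.eps^0.5
  t_stat <- ifelse(degenerate | n < 2, NA_real_, m / (s / sqrt(n)))
  list(t = t_stat, mean = m, n = n, degenerate = degenerate & n >= 2)
}

#' Across-site t-statistics for encoding estimates
#'
#' One-sample two-tailed t-test of the regression estimates against zero
#' across recording sites at every point, or a paired contrast between two
#' maps (e.g. reward versus punishment estimates). Points with zero
#' across-site variance are flagged degenerate and reported as `NA` rather
#' than infinite.
#'
#' @param map An `encoding_map`.
#' @param contrast Optional second `encoding_map` for a paired t-test
#'   (`map - contrast`).
#' @return An `encoding_ttest`: per-regressor t and uncorrected p vectors,
#'   the degrees of freedom (sites - 1), and metadata.
#' @export
group_ttest <- function(map, contrast = NULL) {
  b <- map$betas
  label <- map$condition
  if (!is.null(contrast)) {
    if (!identical(dim(b), dim(contrast$betas))) {
      abort("Maps must have identical dimensions for a paired contrast.")
    }
    b <- b - contrast$betas
    label <- paste0(map$condition, "-", contrast$condition)
  }
  site_ok <- apply(is.finite(b), 1, any)
  if (sum(site_ok) < 2) abort("Need at least 2 sites with estimates.")
  res <- lapply(seq_len(dim(b)[2]), function(r) t_across_sites(b[, r, ]))
  df <- sum(site_ok) - 1
  structure(
    list(
      t = lapply(res, `[[`, "t"),
      mean = lapply(res, `[[`, "mean"),
      degenerate = lapply(res, `[[`, "degenerate"),
      p = lapply(res, function(z) 2 * stats::pt(-abs(z$t), df)),
      df = df, regressors = map$regressors, times = map$times,
      condition = label, lock = map$lock
    ),
    class = "encoding_ttest"
  )
}

#' @export
print.encoding_ttest <- function(x, ...) {
  cat(sprintf(
    "Across-site t-map (%s, df = %d): regressors %s over %d time points\n",
    x$condition, x$df, paste(x$regressors, collapse = ", "), length(x$times)
  ))
  invisible(x)
}
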