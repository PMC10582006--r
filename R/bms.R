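#' Per-site regression of prediction errors on band power
#'
#' For each recording site, the z-scored prediction error is regressed on
#' the site's band power averaged over the post-outcome window
#' (`PE = a + b P + e`), and the slopes are tested against zero across
#' sites with a two-tailed one-sample t-test. Reward-condition trials give
#' the reward-prediction-error regression; punishment trials the
#' punishment counterpart.
#'
#' @param df A tibble with one row per site-trial: columns `site_id`,
#'   `power` (band power in the analysis window) and `pe` (prediction
#'   error; z-scored values are used as-is, raw values are z-scored per
#'   site).
#' @return A list of class `band_pe_fit`: per-site slopes, the across-site
#'   mean, t, df and p.
#' @export
band_pe_regression <- function(df) {
  req <- c("site_id", "power", "pe")
  if (!all(req %in% names(df))) {
    abort("`df` needs columns site_id, power, pe.")
  }
  per_site <- df |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      beta = {
        p <- .data$power
        y <- .data$pe
        if (stats::sd(p) < .Machine$double.eps^0.5 ||
          stats::sd(y) < .Machine$double.eps^0.5) {
          abort("Constant prediction error or power at a site.")
        }
        stats::cov(y, p) / stats::var(p)
      },
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  n <- nrow(per_site)
  if (n < 2) abort("Need at least 2 sites.")
  m <- mean(per_site$beta)
  s <- stats::sd(per_site$beta)
  if (is.finite(s) && s > .Machine$double.eps^0.5) {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), n - 1)
  } else {
    # identical slopes across sites: flag rather than report infinity
    t_stat <- NA_real_
    p <- NA_real_
  }
  structure(
    list(
      per_site = per_site, mean_beta = m,
      t = t_stat, df = n - 1, p = p
    ),
    class = "band_pe_fit"
  )
}

#' @export
print.band_pe_fit <- function(x, ...) {
  cat(sprintf(
    "PE ~ band power: mean slope %.3f across %d sites, t(%d) = %.2f, p = %.3g\n",
    x$mean_beta, nrow(x$per_site), x$df, x$t, x$p
  ))
  invisible(x)
}

#' Log marginal likelihood of a Bayesian linear regression
#'
#' Closed-form log evidence of the conjugate normal-inverse-gamma linear
#' model with a zero-mean g-prior on the coefficients (`g = n`,
#' unit-information scaling) and an `IG(a0, b0)` noise prior. Response and
#' predictors are standardized, and no intercept is included (the model
#' space compares standardized band predictors). Alternatively a
#' `-BIC / 2` approximation can be requested.
#'
#' @param y Response vector.
#' @param x Predictor matrix (columns are band powers).
#' @param g Prior scale; defaults to the number of observations.
#' @param a0,b0 Inverse-gamma noise-prior hyperparameters.
#' @param method `"conjugate"` (exact closed form) or `"bic"`.
#' @return Log evidence in nats.
#' @export
log_model_evidence <- function(y, x, g = NULL, a0 = 0.01, b0 = 0.01,
                               method = c("conjugate", "bic")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- length(y)
  if (nrow(x) != n) abort("`y` and `x` sizes differ.")
  y <- as.vector(scale(y))
  x <- apply(x, 2, function(col) as.vector(scale(col)))
  if (anyNA(y) || anyNA(x)) abort("Constant response or predictor column.")
  p <- ncol(x)
  if (qr(x)$rank < p) abort("Collinear design columns.")
  if (method == "bic") {
    rss <- sum(stats::lm.fit(x, y)$residuals^2)
    return(-0.5 * (n * log(rss / n) + p * log(n)))
  }
  g <- g %||% n
  xtx <- crossprod(x)
  xty <- crossprod(x, y)
  yty <- sum(y^2)
  fit_ss <- as.numeric(crossprod(xty, solve(xtx, xty)))
  an <- a0 + n / 2
  bn <- b0 + 0.5 * (yty - g / (g + 1) * fit_ss)
  -n / 2 * log(2 * pi) - p / 2 * log(g + 1) +
    a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
}

#' The eight-band model space for prediction-error regressions
#'
#' All models contain the LFO (4-12 Hz) band; the remaining models add
#' every combination of the delta, beta and gamma bands.
#' @return Named list of predictor-band character vectors.
#' @export
bms_model_space <- function() {
  extras <- c("delta", "beta", "gamma")
  combos <- unlist(
    lapply(0:3, function(k) utils::combn(extras, k, simplify = FALSE)),
    recursive = FALSE
  )
  models <- lapply(combos, function(cc) c("LFO", cc))
  names(models) <- vapply(models, paste, character(1), collapse = "+")
  models
}

#' Per-site log evidences for the band model space
#'
#' @param df A tibble with one row per site-trial: `site_id`, `pe`, and
#'   one `P_<band>` column per band (`P_LFO`, `P_delta`, `P_beta`,
#'   `P_gamma`).
#' @param models Model space (defaults to [bms_model_space()]).
#' @param ... Passed to [log_model_evidence()].
#' @return Matrix of log evidences, sites x models.
#' @export
band_lme_matrix <- function(df, models = bms_model_space(), ...) {
  sites <- unique(df$site_id)
  lme <- matrix(NA_real_, length(sites), length(models),
    dimnames = list(as.character(sites), names(models))
  )
  for (i in seq_along(sites)) {
    d <- df[df$site_id == sites[i], ]
    for (m in seq_along(models)) {
      x <- as.matrix(d[, paste0("P_", models[[m]])])
      lme[i, m] <- log_model_evidence(d$pe, x, ...)
    }
  }
  lme
}

#' Random-effects Bayesian model selection
#'
#' Treats the best model as a random effect across recording sites and
#' infers the population frequency of each model by a variational
#' Dirichlet scheme: starting from a uniform Dirichlet prior (concentration
#' 1 per model), posterior model assignments
#' `u_nk ~ exp(lme_nk + digamma(alpha_k) - digamma(sum(alpha)))` are
#' normalized per site and accumulated into the concentration updates
#' `alpha_k = 1 + sum_n g_nk` until convergence. Expected frequencies are
#' `Ef = alpha / sum(alpha)`; exceedance probabilities (the probability
#' that a model is the most frequent one) are estimated from seeded
#' Dirichlet Monte Carlo samples.
#'
#' @param lme Sites x models matrix of log evidences.
#' @param prior Dirichlet prior concentration per model.
#' @param n_samples Monte Carlo samples for the exceedance probabilities.
#' @param seed Seed for the Monte Carlo step.
#' @param tol Convergence tolerance on the concentration parameters.
#' @param max_iter Iteration cap (error when exceeded).
#' @return A `bms_result`: `alpha` (posterior concentrations), `ef`,
#'   `xp`, `winner` (model with the highest exceedance probability),
#'   assignment matrix `g`, and iteration count.
#' @export
rfx_bms <- function(lme, prior = 1, n_samples = 1e5, seed = 1L,
                    tol = 1e-6, max_iter = 1e4) {
  lme <- as.matrix(lme)
  if (anyNA(lme) || any(!is.finite(lme))) abort("`lme` must be finite.")
  n <- nrow(lme)
  k <- ncol(lme)
  if (k < 2) abort("Need at least 2 models.")
  alpha <- rep(prior, k)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    u <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- u - apply(u, 1, max)
    g <- exp(u)
    g <- g / rowSums(g)
    alpha_new <- prior + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "RFX-BMS did not converge in %d iterations (last change %.2g).",
      max_iter, delta
    ))
  }
  ef <- alpha / sum(alpha)
  xp <- with_seed(substream_seed(seed, "xp"), {
    draws <- matrix(rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
      n_samples, k
    )
    tabulate(max.col(draws), k) / n_samples
  })
  names(ef) <- names(xp) <- colnames(lme)
  structure(
    list(
      alpha = stats::setNames(alpha, colnames(lme)), ef = ef, xp = xp,
      winner = colnames(lme)[which.max(xp)] %||% which.max(xp),
      g = g, n_iter = iter, n_samples = n_samples
    ),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  tab <- tibble::tibble(
    model = names(x$ef) %||% seq_along(x$ef),
    ef = round(x$ef, 4), xp = round(x$xp, 4)
  )
  print(tab, n = nrow(tab))
  cat(sprintf("Winner: %s\n", as.character(x$winner)))
  invisible(x)
}
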