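#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Q-learning fit
#'
#' @param x A `qlearn_fit`.
#' @param ... Unused.
#' @return One row per parameter (`alpha`, `beta`) with the estimate.
#' @method tidy qlearn_fit
#' @export
tidy.qlearn_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta)
  )
}

#' @rdname tidy.qlearn_fit
#' @return `glance()`: one row with `nll`, `aic`, `aic_random`, `n_trials`.
#' @method glance qlearn_fit
#' @export
glance.qlearn_fit <- function(x, ...) {
  tibble::tibble(
    nll = x$nll, aic = x$aic, aic_random = x$aic_random,
    n_trials = x$n_trials
  )
}

#' Tidy group behavioral tests
#' @param x An `rl_behavior_summary`.
#' @param ... Unused.
#' @method tidy rl_behavior_summary
#' @export
tidy.rl_behavior_summary <- function(x, ...) x$tests

#' Tidy an across-site t-map into a long tibble
#' @param x An `encoding_ttest`.
#' @param ... Unused.
#' @method tidy encoding_ttest
#' @export
tidy.encoding_ttest <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$regressors), function(r) {
    tibble::tibble(
      regressor = x$regressors[r], time = x$times,
      mean_beta = x$mean[[r]], statistic = x$t[[r]], p_value = x$p[[r]],
      degenerate = x$degenerate[[r]]
    )
  }))
}

#' Tidy clusters from a permutation test
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$by_regressor), function(r) {
    cl <- x$by_regressor[[r]]$clusters
    if (!nrow(cl)) {
      return(NULL)
    }
    tibble::tibble(
      regressor = r, t_start = cl$t_start, t_end = cl$t_end,
      sign = cl$sign, stat = cl$stat, pc = cl$pc
    )
  }))
}

#' Tidy / glance a model-selection result
#' @param x A `bms_result`.
#' @param ... Unused.
#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(
    model = names(x$ef) %||% as.character(seq_along(x$ef)),
    alpha = unname(x$alpha), ef = unname(x$ef), xp = unname(x$xp)
  )
}

#' @rdname tidy.bms_result
#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  tibble::tibble(
    winner = as.character(x$winner),
    ef_winner = max(x$ef), xp_winner = max(x$xp), n_iter = x$n_iter
  )
}

#' Tidy per-site band slopes
#' @param x A `band_pe_fit`.
#' @param ... Unused.
#' @method tidy band_pe_fit
#' @export
tidy.band_pe_fit <- function(x, ...) x$per_site

#' @rdname tidy.band_pe_fit
#' @method glance band_pe_fit
#' @export
glance.band_pe_fit <- function(x, ...) {
  tibble::tibble(
    mean_beta = x$mean_beta, statistic = x$t, df = x$df, p_value = x$p
  )
}
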