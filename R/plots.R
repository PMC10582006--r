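#' Plot group behavioral accuracy and reaction times
#'
#' Accuracy per condition with individual patients overlaid, and mean
#' reaction times per condition.
#'
#' @param object An `rl_behavior_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rl_behavior_summary
#' @export
autoplot.rl_behavior_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$patients,
    cols = dplyr::starts_with("accuracy_") & !dplyr::contains("last4"),
    names_to = "condition", names_prefix = "accuracy_",
    values_to = "accuracy"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.4, width = 0.6) +
    ggplot2::geom_jitter(width = 0.08, height = 0) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      y = "correct choice rate", x = NULL,
      title = "Choice accuracy vs chance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an across-site encoding t-map time course
#'
#' Mean regression estimates over time with the cluster-forming threshold;
#' optionally shades the significant clusters of a matching
#' [cluster_correct()] result.
#'
#' @param object An `encoding_ttest`.
#' @param clusters Optional `cluster_result` to overlay (pc < 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot encoding_ttest
#' @export
autoplot.encoding_ttest <- function(object, clusters = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$statistic,
    colour = .data$regressor
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = sprintf("time from %s (s)", object$lock),
      y = sprintf("t(%d) across sites", object$df),
      title = sprintf("Encoding time course (%s)", object$condition)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    sig <- tidy(clusters)
    sig <- sig[sig$pc < 0.05, , drop = FALSE]
    if (nrow(sig)) {
      p <- p + ggplot2::geom_rect(
        data = sig,
        ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange",
        inherit.aes = FALSE
      )
    }
  }
  p
}

#' Plot expected frequencies and exceedance probabilities
#'
#' @param object A `bms_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("ef", "xp"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$model, y = .data$value,
    fill = .data$measure
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Random-effects Bayesian model selection"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot trial-averaged time-frequency power for one site
#'
#' @param object A `tf_power` object.
#' @param site Site index.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tf_power
#' @export
autoplot.tf_power <- function(object, site = 1, ...) {
  arr <- object$power[[site]]
  m <- apply(arr, c(2, 3), mean, na.rm = TRUE)
  df <- expand.grid(freq = object$freqs, time = object$times)
  df$power <- as.vector(m)
  ggplot2::ggplot(
    df[is.finite(df$power), ],
    ggplot2::aes(x = .data$time, y = .data$freq, fill = .data$power)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(
      x = sprintf("time from %s (s)", object$lock), y = "frequency (Hz)",
      fill = if (object$normalized) "z-power" else "power",
      title = sprintf("Site %d mean power", site)
    ) +
    ggplot2::theme_minimal()
}
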