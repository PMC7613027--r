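#' Plot a coefficient table
#'
#' Point estimates with 95% confidence intervals, the standard display for
#' the lagged-evidence regression pattern.
#'
#' @param object A `heist_coeftab`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heist_coeftab <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "fixed-effect estimate (log-odds)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-subject RSA difference scores by condition
#'
#' @param summaries A tibble with `subject`, `condition`, `difference`.
#' @return A ggplot object.
#' @export
plot_rsa_differences <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$condition, y = .data$difference)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject),
                       colour = "grey70", alpha = 0.6) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(y = "on - off diagonal similarity (Fisher z)",
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the encoding-model condition contrast across bin counts
#'
#' @param test A [encoding_condition_test()] tibble.
#' @return A ggplot object.
#' @export
plot_encoding_contrast <- function(test) {
  ggplot2::ggplot(test, ggplot2::aes(x = .data$n_bins, y = .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = unique(test$n_bins)) +
    ggplot2::labs(x = "number of probability bins",
                  y = "cross-entropy difference (dependent - independent)") +
    ggplot2::theme_minimal()
}

#' Plot a block's transition schedules
#'
#' @param schedule A [generate_transition_schedule()] tibble.
#' @return A ggplot object.
#' @export
plot_transition_schedule <- function(schedule) {
  long <- tidyr::pivot_longer(schedule, c("p_a", "p_b"),
                              names_to = "context", values_to = "p")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$p,
                                     colour = .data$context)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "trial", y = "p(dark door -> heist)") +
    ggplot2::theme_minimal()
}
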