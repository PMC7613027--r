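#' Tidy a hierarchical fit
#'
#' One row per subject with natural-scale MAP parameters and evidence.
#'
#' @param x A [em_fit()] result.
#' @param ... Unused.
#' @return A tibble: `subject`, `alpha`, `beta`, `w`, `log_marginal`,
#'   `flagged`.
#' @export
tidy.heist_em_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(subject = f$subject, alpha = f$params$alpha,
                   beta = f$params$beta, w = f$params$w,
                   log_marginal = f$log_marginal, flagged = f$flagged)
  })
}

#' Glance at a hierarchical fit
#'
#' Group-level summary: the prior mean mapped back to the natural scale,
#' iteration count and summed evidence.
#'
#' @inheritParams tidy.heist_em_fit
#' @return A one-row tibble.
#' @export
glance.heist_em_fit <- function(x, ...) {
  nat <- untransform_params(x$prior$mean)
  tibble::tibble(
    variant = x$variant, n_subjects = length(x$fits),
    alpha_group = nat$alpha, beta_group = nat$beta, w_group = nat$w,
    sum_log_marginal = x$trace[length(x$trace)],
    n_iter = x$n_iter, converged = x$converged
  )
}

#' @export
tidy.heist_model_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 mean_diff = x$mean_diff, conf_low = x$conf_low,
                 conf_high = x$conf_high, wins_a = x$wins_a,
                 wins_b = x$wins_b, n = x$n)
}

#' @export
tidy.heist_rsa_summary <- function(x, ...) {
  tibble::tibble(on_diag = x$on_diag, off_diag = x$off_diag,
                 difference = x$difference)
}

#' @export
tidy.heist_rsa_interaction <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 mean_dep = x$mean_dep, mean_indep = x$mean_indep, n = x$n)
}

#' @export
print.heist_em_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Hierarchical EM fit (%s model, %d subjects)\n", g$variant, g$n_subjects))
  cat(sprintf("  group means (natural): alpha=%.3f beta=%.3f w=%.3f\n",
              g$alpha_group, g$beta_group, g$w_group))
  cat(sprintf("  sum log marginal: %.2f after %d iterations (%s)\n",
              g$sum_log_marginal, g$n_iter,
              if (g$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
print.heist_model_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired model comparison: t(%d) = %.3f, p = %.4g\n  mean score difference (a - b) = %.4f; wins a/b: %d/%d of %d\n",
    x$df, x$statistic, x$p_value, x$mean_diff, x$wins_a, x$wins_b, x$n))
  invisible(x)
}

#' @export
print.heist_rsa_interaction <- function(x, ...) {
  cat(sprintf(
    "Condition x diagonal interaction: t(%d) = %.3f, p = %.4g\n  mean on-off difference: dependent %.4f, independent %.4f\n",
    x$df, x$statistic, x$p_value, x$mean_dep, x$mean_indep))
  invisible(x)
}
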