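#' Assign trials to probability bins
#'
#' `"fixed_quartiles"` uses the fixed edges 0-.25, .26-.50, .51-.75, .76-1.00
#' (generalised to `n_bins` equal-width bins); `"subject_quartiles"` computes
#' per-subject quantile edges over the supplied trials. Ties on an edge go to
#' the lower bin.
#'
#' @param p Per-trial probabilities in \[0, 1\] (e.g.
#'   `p(heist | door presented)`).
#' @param scheme `"subject_quartiles"` or `"fixed_quartiles"`.
#' @param n_bins Number of bins (4 for the quartile analyses).
#' @return An integer vector of bin labels 1..n_bins.
#' @examples
#' assign_probability_bins(c(0.1, 0.9), scheme = "fixed_quartiles")
#' @export
assign_probability_bins <- function(p, scheme = c("subject_quartiles",
                                                  "fixed_quartiles"),
                                    n_bins = 4L) {
  scheme <- match.arg(scheme)
  if (length(p) == 0L) abort("empty probability vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("probabilities must lie in [0, 1]")
  edges <- if (scheme == "fixed_quartiles") {
    seq(0, 1, length.out = n_bins + 1L)
  } else {
    unique(quantile(p, probs = seq(0, 1, length.out = n_bins + 1L)))
  }
  edges[1L] <- -Inf
  edges[length(edges)] <- Inf
  # right-closed intervals: a value equal to an edge falls in the lower bin
  bin <- findInterval(p, edges, left.open = TRUE, rightmost.closed = TRUE)
  pmin(pmax(bin, 1L), n_bins)
}

#' Choice-by-state combination bins
#'
#' The four combinations that drive the direction of belief updates:
#' 1 dark+heist, 2 dark+neutral, 3 light+heist, 4 light+neutral.
#'
#' @param choice,state Character vectors.
#' @return Integer bins 1..4.
#' @export
outcome_bins <- function(choice, state) {
  dplyr::case_when(
    choice == "dark" & state == "heist" ~ 1L,
    choice == "dark" & state == "neutral" ~ 2L,
    choice == "light" & state == "heist" ~ 3L,
    choice == "light" & state == "neutral" ~ 4L,
    TRUE ~ NA_integer_
  )
}

#' Bin-mean voxel patterns for one context
#'
#' Per-voxel mean over the context's trials in each bin, collapsing across
#' runs.
#'
#' @param dataset A [generate_voxel_dataset()] result.
#' @param bins Integer bin label per dataset row (defaults to the generator's
#'   own labels in `dataset$meta$bin`).
#' @param context Context id.
#' @param n_bins Number of bins expected.
#' @param runs Optional run subset.
#' @return A `n_bins x voxels` matrix; errors naming any empty (context, bin)
#'   cell.
#' @export
bin_mean_patterns <- function(dataset, bins = dataset$meta$bin, context,
                              n_bins = max(bins), runs = NULL) {
  sel_ctx <- dataset$meta$context == context
  if (!is.null(runs)) sel_ctx <- sel_ctx & dataset$meta$run %in% runs
  out <- matrix(NA_real_, n_bins, ncol(dataset$patterns))
  for (b in seq_len(n_bins)) {
    sel <- sel_ctx & bins == b
    if (!any(sel)) {
      abort(sprintf("no trials in cell (context %s, bin %d)", context, b))
    }
    out[b, ] <- colMeans(dataset$patterns[sel, , drop = FALSE])
  }
  out
}

fisher_z <- function(r, clip = 1 - 1e-6) atanh(pmin(pmax(r, -clip), clip))

#' Cross-context similarity contrast
#'
#' Correlates every bin-mean pattern of context A with every bin-mean pattern
#' of context B (a 4x4 matrix that is not symmetric and is used as-is),
#' Fisher-transforms the correlations (clipped at |r| <= 1 - 1e-6), and
#' averages the 4 diagonal (same-bin) and 12 off-diagonal (different-bin)
#' cells. `difference = on_diag - off_diag` measures whether identical
#' transition-probability bins are encoded more similarly across contexts
#' than different bins.
#'
#' @param means_a,means_b `bins x voxels` matrices from [bin_mean_patterns()].
#' @return A list of class `heist_rsa_summary`: `z_matrix`, `on_diag`,
#'   `off_diag`, `difference`.
#' @export
cross_context_contrast <- function(means_a, means_b) {
  if (ncol(means_a) != ncol(means_b)) abort("voxel dimensions differ")
  if (any(apply(means_a, 1, sd) == 0) || any(apply(means_b, 1, sd) == 0)) {
    abort("zero-variance bin pattern: correlation undefined")
  }
  r <- stats::cor(t(means_a), t(means_b))
  z <- fisher_z(r)
  summarise_z_matrix(z)
}

summarise_z_matrix <- function(z) {
  on_diag <- mean(diag(z))
  off_diag <- mean(z[row(z) != col(z)])
  structure(list(z_matrix = z, on_diag = on_diag, off_diag = off_diag,
                 difference = on_diag - off_diag),
            class = "heist_rsa_summary")
}

context_pair <- function(dataset, condition) {
  ctxs <- sort(unique(dataset$meta$context[dataset$meta$condition == condition]))
  if (length(ctxs) != 2L) {
    abort(sprintf("expected 2 contexts in the %s condition", condition))
  }
  ctxs
}

#' Condition-wise RSA summary for one subject
#'
#' Convenience wrapper: computes bin means for the condition's two contexts
#' (collapsing across runs) and runs [cross_context_contrast()].
#'
#' @inheritParams bin_mean_patterns
#' @param condition `"dependent"` or `"independent"`.
#' @return A `heist_rsa_summary`.
#' @export
rsa_condition_contrast <- function(dataset, condition,
                                   bins = dataset$meta$bin,
                                   n_bins = max(bins)) {
  ctxs <- context_pair(dataset, condition)
  cross_context_contrast(
    bin_mean_patterns(dataset, bins, ctxs[1L], n_bins),
    bin_mean_patterns(dataset, bins, ctxs[2L], n_bins)
  )
}

#' Cross-run cross-validated similarity contrast
#'
#' Bin means are computed per run and correlations taken only across run
#' pairs i != j. `"between_context"` correlates context A (run i) with
#' context B (run j); `"within_context"` stays inside one context across
#' runs (averaged over the condition's two contexts). Cells empty in a run
#' are dropped from the average with a warning.
#'
#' @inheritParams rsa_condition_contrast
#' @param mode `"between_context"` or `"within_context"`.
#' @return A `heist_rsa_summary` (the z matrix averaged over ordered run
#'   pairs).
#' @export
crossval_contrast <- function(dataset, condition,
                              mode = c("between_context", "within_context"),
                              bins = dataset$meta$bin, n_bins = max(bins)) {
  mode <- match.arg(mode)
  ctxs <- context_pair(dataset, condition)
  runs <- sort(unique(dataset$meta$run[dataset$meta$condition == condition]))
  if (length(runs) < 2L) abort("cross-validation needs >= 2 runs")

  run_means <- function(ctx, run) {
    tryCatch(bin_mean_patterns(dataset, bins, ctx, n_bins, runs = run),
             error = function(e) NULL)
  }
  pairs <- expand.grid(i = runs, j = runs)
  pairs <- pairs[pairs$i != pairs$j, ]
  ctx_sets <- if (mode == "between_context") {
    list(c(ctxs[1L], ctxs[2L]), c(ctxs[2L], ctxs[1L]))
  } else {
    list(c(ctxs[1L], ctxs[1L]), c(ctxs[2L], ctxs[2L]))
  }
  acc <- matrix(0, n_bins, n_bins)
  cnt <- matrix(0, n_bins, n_bins)
  dropped <- 0L
  for (cs in ctx_sets) {
    for (k in seq_len(nrow(pairs))) {
      ma <- run_means(cs[1L], pairs$i[k])
      mb <- run_means(cs[2L], pairs$j[k])
      if (is.null(ma) || is.null(mb)) { dropped <- dropped + 1L; next }
      ok_a <- apply(ma, 1, sd) > 0
      ok_b <- apply(mb, 1, sd) > 0
      z <- matrix(NA_real_, n_bins, n_bins)
      z[ok_a, ok_b] <- fisher_z(stats::cor(t(ma[ok_a, , drop = FALSE]),
                                           t(mb[ok_b, , drop = FALSE])))
      use <- !is.na(z)
      acc[use] <- acc[use] + z[use]
      cnt[use] <- cnt[use] + 1
    }
  }
  if (dropped > 0L) {
    warn(sprintf("%d run pair(s) dropped due to empty cells", dropped))
  }
  if (any(cnt == 0)) abort("some bin cells were empty in every run pair")
  summarise_z_matrix(acc / cnt)
}

#' Condition-by-diagonal interaction test
#'
#' Paired t-test across subjects of the on-minus-off-diagonal difference in
#' the dependent versus independent condition, plus one-sample tests of each
#' condition's difference against zero.
#'
#' @param summaries A tibble with columns `subject`, `condition` and
#'   `difference` (one row per subject and condition; see
#'   [rsa_condition_contrast()]).
#' @return A list of class `heist_rsa_interaction`: `statistic`, `df`,
#'   `p_value`, `conf_low`, `conf_high`, `mean_dep`, `mean_indep`, and the
#'   per-condition one-sample test results `test_dep`, `test_indep`.
#' @export
condition_interaction <- function(summaries) {
  wide <- tidyr::pivot_wider(summaries[c("subject", "condition", "difference")],
                             names_from = "condition",
                             values_from = "difference")
  if (nrow(wide) < 2L) abort("need at least 2 subjects")
  d <- wide$dependent - wide$independent
  if (sd(d) < 1e-12) {
    tt <- list(statistic = c(t = 0), parameter = c(df = nrow(wide) - 1L),
               p.value = 1, conf.int = c(0, 0))
  } else {
    tt <- t.test(wide$dependent, wide$independent, paired = TRUE)
  }
  one_sample <- function(x) {
    if (sd(x) < 1e-12) {
      if (abs(mean(x)) < 1e-12) {
        list(statistic = 0, p_value = 1)
      } else {
        list(statistic = sign(mean(x)) * Inf, p_value = 0)
      }
    } else {
      o <- t.test(x)
      list(statistic = unname(o$statistic), p_value = o$p.value)
    }
  }
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, conf_low = tt$conf.int[1],
         conf_high = tt$conf.int[2], mean_dep = mean(wide$dependent),
         mean_indep = mean(wide$independent),
         test_dep = one_sample(wide$dependent),
         test_indep = one_sample(wide$independent), n = nrow(wide)),
    class = "heist_rsa_interaction"
  )
}

#' Temporal-proximity control
#'
#' For each subject and condition, computes the mean absolute temporal
#' distance between cross-context trial pairs falling in the same bin
#' (diagonal) and in different bins (off-diagonal). The per-subject
#' `proximity_difference` (diagonal minus off-diagonal mean distance) is
#' correlated across subjects with the RSA `difference`, to check whether
#' apparent pattern similarity tracks temporal closeness rather than
#' probability coding.
#'
#' @param datasets A named list of per-subject `heist_voxel_dataset`s.
#' @param summaries As in [condition_interaction()] (same subjects).
#' @param condition Condition to test.
#' @return A list: `per_subject` tibble (`subject`, `proximity_difference`,
#'   `rsa_difference`), `estimate` (Pearson r), `p_value`.
#' @export
temporal_proximity_control <- function(datasets, summaries, condition) {
  per <- purrr::imap_dfr(datasets, function(vd, id) {
    m <- vd$meta[vd$meta$condition == condition, ]
    ctxs <- sort(unique(m$context))
    a <- m[m$context == ctxs[1L], ]
    b <- m[m$context == ctxs[2L], ]
    dt <- abs(outer(a$time, b$time, "-"))
    same <- outer(a$bin, b$bin, "==")
    tibble::tibble(subject = id,
                   proximity_difference = mean(dt[same]) - mean(dt[!same]))
  })
  rsa <- summaries[summaries$condition == condition, c("subject", "difference")]
  per$rsa_difference <- rsa$difference[match(per$subject, rsa$subject)]
  ok <- stats::complete.cases(per$proximity_difference, per$rsa_difference)
  if (sum(ok) < 3L) {
    return(list(per_subject = per, estimate = NA_real_, p_value = NA_real_))
  }
  ct <- cor.test(per$proximity_difference[ok], per$rsa_difference[ok])
  list(per_subject = per, estimate = unname(ct$estimate),
       p_value = ct$p.value)
}
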