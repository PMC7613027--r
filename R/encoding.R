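#' Binned probability design matrix
#'
#' Converts probabilities to log-odds, clips them to \[-2, 2\], and assigns
#' them to `n_bins` equal-width bins over that range. The `"one_hot"` basis
#' places a 1 in the trial's bin; the `"gaussian"` basis places a tuning
#' curve that is maximal in the trial's bin and tapers over neighbours
#' (unit-normalised columns). Probabilities of exactly 0 or 1 are clipped
#' with a warning before the log-odds transform.
#'
#' @param p Per-trial probabilities.
#' @param n_bins Number of bins, 1..10.
#' @param basis `"one_hot"` or `"gaussian"`.
#' @param width Gaussian tuning width in log-odds units (default: one bin
#'   width).
#' @return A list of class `heist_design`: `X` (`n_bins x n_trials`), `bins`
#'   (true bin per trial), `centres`, `basis`.
#' @examples
#' d <- probability_design(c(0.5, 0.9), n_bins = 5)
#' d$bins
#' @export
probability_design <- function(p, n_bins, basis = c("one_hot", "gaussian"),
                               width = NULL) {
  basis <- match.arg(basis)
  if (n_bins < 1L || n_bins > 10L) abort("n_bins must be between 1 and 10")
  if (any(p <= 0 | p >= 1)) {
    warn("probabilities at 0/1 clipped before the log-odds transform")
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  }
  lo <- pmin(pmax(log(p / (1 - p)), -2), 2)
  edges <- seq(-2, 2, length.out = n_bins + 1L)
  bins <- pmin(pmax(findInterval(lo, edges, left.open = TRUE,
                                 rightmost.closed = TRUE), 1L), n_bins)
  centres <- (edges[-1L] + edges[-length(edges)]) / 2
  n <- length(p)
  if (basis == "one_hot") {
    X <- matrix(0, n_bins, n)
    X[cbind(bins, seq_len(n))] <- 1
  } else {
    width <- width %||% (4 / n_bins)
    X <- vapply(seq_len(n), function(i) {
      v <- exp(-(centres - centres[bins[i]])^2 / (2 * width^2))
      v / sum(v)
    }, numeric(n_bins))
    X <- matrix(X, n_bins, n)
  }
  structure(list(X = X, bins = bins, centres = centres, basis = basis,
                 n_bins = n_bins),
            class = "heist_design")
}

#' Fit encoding weights by linear regression
#'
#' Least-squares regression of the design onto each voxel's responses,
#' `W = argmin ||Y - X' W'||^2`, with a tiny ridge for rank-deficient
#' designs (e.g. empty bins).
#'
#' @param design A [probability_design()] result (training trials).
#' @param Y `trials x voxels` pattern matrix (same trial order).
#' @param ridge Ridge added to the design Gram matrix.
#' @return A list of class `heist_encoding_weights`: `W` (`voxels x n_bins`),
#'   `n_bins`, `basis`.
#' @export
fit_encoding_weights <- function(design, Y, ridge = 1e-6) {
  stopifnot(inherits(design, "heist_design"))
  X <- design$X
  if (ncol(X) != nrow(Y)) abort("design and pattern trial counts differ")
  if (all(X == 0)) abort("design has no occupied bins")
  G <- X %*% t(X) + diag(ridge, nrow(X))
  B <- solve(G, X %*% Y) # n_bins x voxels
  structure(list(W = t(B), n_bins = design$n_bins, basis = design$basis),
            class = "heist_encoding_weights")
}

#' Decode held-out patterns and score by cross-entropy
#'
#' Recovers per-trial bin scores by least-squares inversion of the trained
#' weights against each held-out pattern, maps scores to a probability
#' distribution over bins with a softmax, and returns the mean cross-entropy
#' `-log p(true bin)`. Chance level is `log(n_bins)`.
#'
#' The softmax `temperature` is the readout gain of the equivalent
#' multinomial logistic regression; fit it on the *training* cell with
#' [fit_decoder_temperature()] so that uninformative patterns decode to a
#' near-uniform distribution (loss near `log(n_bins)`) rather than to
#' overconfident noise.
#'
#' @param weights A [fit_encoding_weights()] result.
#' @param Y_test `trials x voxels` held-out patterns.
#' @param true_bins Integer true bin per held-out trial.
#' @param ridge Ridge used in the inversion.
#' @param temperature Softmax gain applied to the recovered scores.
#' @return A list: `loss` (mean cross-entropy), `per_trial`, `probs`
#'   (`trials x n_bins`).
#' @export
decode_and_score <- function(weights, Y_test, true_bins, ridge = 1e-6,
                             temperature = 1) {
  probs <- decode_probs(weights, Y_test, ridge, temperature)
  per_trial <- -log(pmax(probs[cbind(seq_len(nrow(probs)), true_bins)], 1e-300))
  list(loss = mean(per_trial), per_trial = per_trial, probs = probs)
}

decode_probs <- function(weights, Y_test, ridge, temperature) {
  stopifnot(inherits(weights, "heist_encoding_weights"))
  W <- weights$W
  if (ncol(Y_test) != nrow(W)) abort("voxel dimensions differ")
  G <- crossprod(W) + diag(ridge, ncol(W))
  S <- temperature * solve(G, t(W) %*% t(Y_test)) # n_bins x trials
  S <- sweep(S, 2L, apply(S, 2L, max))
  P <- exp(S)
  P <- sweep(P, 2L, colSums(P), "/")
  t(P) # trials x n_bins
}

#' Fit the decoder's softmax temperature by cross-fitting the training cell
#'
#' Chooses the scalar readout gain of the equivalent multinomial logistic
#' regression: the training trials are split into interleaved folds, weights
#' fitted on the complement decode each fold, and the gain minimising the
#' pooled fold-wise cross-entropy is returned. No held-out (test) labels are
#' involved. At gain 0 the decoder outputs the uniform distribution, so on
#' uninformative patterns the fitted gain stays near 0 and held-out loss
#' near `log(n_bins)`.
#'
#' @param design A [probability_design()] for the training trials.
#' @param Y_train The training patterns (`trials x voxels`).
#' @param ridge Ridge used in fitting and inversion.
#' @param folds Number of interleaved cross-fitting folds.
#' @return The fitted temperature (a scalar in \[0, 100\]).
#' @export
fit_decoder_temperature <- function(design, Y_train, ridge = 1e-6,
                                    folds = 2L) {
  stopifnot(inherits(design, "heist_design"))
  n <- ncol(design$X)
  fold_id <- rep_len(seq_len(folds), n)
  S_all <- NULL
  bins_all <- integer(0)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (!any(tr) || !any(!tr)) next
    sub <- design
    sub$X <- design$X[, tr, drop = FALSE]
    if (all(sub$X == 0)) next
    w_k <- fit_encoding_weights(sub, Y_train[tr, , drop = FALSE], ridge)
    P <- decode_probs(w_k, Y_train[!tr, , drop = FALSE], ridge, 1)
    S_all <- rbind(S_all, log(pmax(P, 1e-300)))
    bins_all <- c(bins_all, design$bins[!tr])
  }
  if (is.null(S_all)) return(1)
  obj <- function(tau) {
    P <- exp(tau * S_all)
    P <- P / rowSums(P)
    mean(-log(pmax(P[cbind(seq_len(nrow(P)), bins_all)], 1e-300)))
  }
  stats::optimize(obj, c(0, 100))$minimum
}

#' Cross-context generalization of the encoding model
#'
#' For one subject's dataset: per condition, trains encoding weights on each
#' (context, run) cell and decodes (a) the paired context's trials in the
#' other runs (`cross_gem`) and (b) the same context's trials in the other
#' runs (`within_gem`), averaging the mean cross-entropy over train/test
#' pairs. Repeated over a grid of bin counts. Lower cross-gem loss in the
#' dependent than the independent condition indicates a transition-probability
#' code shared across that condition's contexts.
#'
#' @param dataset A `heist_voxel_dataset` in door mode (meta column `p`).
#' @param n_bins_grid Bin counts to evaluate (default 1..10).
#' @param basis `"one_hot"` or `"gaussian"`.
#' @param ridge Ridge for fitting and inversion.
#' @return A tibble: `n_bins`, `basis`, `condition`, `loss_cross_gem`,
#'   `loss_within_gem`, `chance` (`log(n_bins)`).
#' @export
generalization_contrast <- function(dataset, n_bins_grid = 1:10,
                                    basis = c("one_hot", "gaussian"),
                                    ridge = 1e-6) {
  basis <- match.arg(basis)
  meta <- dataset$meta
  if (!"p" %in% names(meta) || anyNA(meta$p)) {
    abort("encoding analysis needs door-mode datasets with per-trial p")
  }
  runs <- sort(unique(meta$run))
  if (length(runs) < 2L) abort("need >= 2 runs")
  purrr::map_dfr(n_bins_grid, function(nb) {
    design_all <- probability_design(meta$p, nb, basis)
    purrr::map_dfr(c("dependent", "independent"), function(cond) {
      ctxs <- context_pair(dataset, cond)
      cells <- expand.grid(ctx = ctxs, run = runs)
      losses_cross <- c(); losses_within <- c()
      for (k in seq_len(nrow(cells))) {
        tr <- which(meta$context == cells$ctx[k] & meta$run == cells$run[k])
        if (length(tr) <= nb) next
        Xtr <- probability_design(meta$p[tr], nb, basis)
        Ytr <- dataset$patterns[tr, , drop = FALSE]
        w <- fit_encoding_weights(Xtr, Ytr, ridge)
        tau <- if (nb > 1L) fit_decoder_temperature(Xtr, Ytr, ridge) else 1
        other_ctx <- setdiff(ctxs, cells$ctx[k])
        te_cross <- which(meta$context == other_ctx & meta$run != cells$run[k])
        te_within <- which(meta$context == cells$ctx[k] &
                             meta$run != cells$run[k])
        if (length(te_cross)) {
          losses_cross <- c(losses_cross,
            decode_and_score(w, dataset$patterns[te_cross, , drop = FALSE],
                             design_all$bins[te_cross], ridge,
                             temperature = tau)$loss)
        }
        if (length(te_within)) {
          losses_within <- c(losses_within,
            decode_and_score(w, dataset$patterns[te_within, , drop = FALSE],
                             design_all$bins[te_within], ridge,
                             temperature = tau)$loss)
        }
      }
      if (!length(losses_cross)) abort("no usable train/test pairs")
      tibble::tibble(n_bins = nb, basis = basis, condition = cond,
                     loss_cross_gem = mean(losses_cross),
                     loss_within_gem = mean(losses_within),
                     chance = log(nb))
    })
  })
}

#' Condition contrast of encoding losses across subjects
#'
#' Paired t-test (dependent minus independent cross-gem loss) per bin count.
#'
#' @param results Row-bound [generalization_contrast()] tibbles with a
#'   `subject` column.
#' @return A tibble: `n_bins`, `basis`, `mean_diff` (dependent - independent),
#'   `statistic`, `df`, `p_value`.
#' @export
encoding_condition_test <- function(results) {
  results |>
    dplyr::group_by(.data$n_bins, .data$basis) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df[c("subject", "condition", "loss_cross_gem")],
                                 names_from = "condition",
                                 values_from = "loss_cross_gem")
      d <- wide$dependent - wide$independent
      if (sd(d) < 1e-12) {
        return(tibble::tibble(mean_diff = mean(d), statistic = 0,
                              df = length(d) - 1, p_value = 1))
      }
      tt <- t.test(wide$dependent, wide$independent, paired = TRUE)
      tibble::tibble(mean_diff = unname(tt$estimate),
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value)
    }) |>
    dplyr::ungroup()
}
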