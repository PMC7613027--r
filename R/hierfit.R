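#' Parameter transforms for the Gaussian hierarchy
#'
#' The group-level Gaussian lives on unconstrained parameters: `alpha` and
#' `w` are logit-transformed, `beta` log-transformed. Boundary values (0, 1,
#' or `beta = 0`) map to infinity and are rejected; nudge them inside the
#' open interval first.
#'
#' @param params A [model_params()].
#' @return A named numeric 3-vector `(alpha_t, beta_t, w_t)`.
#' @examples
#' transform_params(model_params(0.65, 1.8, 0.61))
#' @export
transform_params <- function(params) {
  stopifnot(inherits(params, "heist_model_params"))
  if (params$alpha <= 0 || params$alpha >= 1 || params$w <= 0 ||
      params$w >= 1 || params$beta <= 0) {
    abort("boundary parameters transform to infinity; nudge them inside (0, 1) / beta > 0")
  }
  c(alpha_t = qlogis(params$alpha), beta_t = log(params$beta),
    w_t = qlogis(params$w))
}

#' @rdname transform_params
#' @param theta A transformed 3-vector.
#' @export
untransform_params <- function(theta) {
  model_params(alpha = plogis(theta[[1]]), beta = exp(theta[[2]]),
               w = plogis(theta[[3]]))
}

#' Group-level Gaussian prior
#'
#' Diagonal Gaussian over transformed parameters.
#'
#' @param mean,var Numeric 3-vectors; variances are floored at `1e-6`.
#' @return A list of class `heist_group_prior`.
#' @export
group_prior <- function(mean = c(0, 0, 0), var = c(6.25, 6.25, 6.25)) {
  stopifnot(length(mean) == 3L, length(var) == 3L, all(var > 0))
  structure(list(mean = as.numeric(mean), var = pmax(as.numeric(var), 1e-6)),
            class = "heist_group_prior")
}

neg_log_posterior_fn <- function(enc, prior, flexible) {
  function(theta) {
    nat_alpha <- plogis(theta[1]); nat_beta <- exp(theta[2])
    nat_w <- plogis(theta[3])
    nll <- model_negloglik_cpp(enc$condition, enc$context, enc$valence,
                               enc$trial_type, enc$choice, enc$state,
                               nat_alpha, nat_beta, nat_w, flexible)
    nll - sum(stats::dnorm(theta, prior$mean, sqrt(prior$var), log = TRUE))
  }
}

# Central finite-difference Hessian (step in transformed space). The step is
# ~eps^(1/4): second differences scale as H*h^2 and must clear the objective's
# numerical noise floor, which a much smaller step does not.
numeric_hessian <- function(fn, x, h = 1e-2) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h)
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

# Floor eigenvalues so the Laplace term and posterior covariance are defined.
# The posterior Hessian cannot fall below the prior precision in any
# direction, so flat or slightly negative finite-difference eigenvalues are
# floored there (with 1e-6 as an absolute backstop).
regularize_hessian <- function(H, prior_var) {
  floor <- max(1e-6, 1 / max(prior_var))
  e <- eigen(H, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  list(H = e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors),
       logdet = sum(log(vals)),
       inv_diag = diag(e$vectors %*% diag(1 / vals, length(vals)) %*% t(e$vectors)))
}

subject_map_enc <- function(enc, prior, flexible, n_restarts = 3L,
                            init = NULL) {
  fn <- neg_log_posterior_fn(enc, prior, flexible)
  sdv <- sqrt(prior$var)
  starts <- if (is.null(init)) list(prior$mean) else
    lapply(seq_len(ncol(as.matrix(init))), function(k) as.matrix(init)[, k])
  if (n_restarts > 1L) {
    n0 <- length(starts)
    for (r in seq_len(n_restarts - 1L)) {
      starts[[n0 + r]] <- prior$mean + rnorm(3L) * pmin(sdv, 1.5)
    }
  }
  best <- NULL
  flagged <- TRUE
  for (s in starts) {
    opt <- tryCatch(
      optim(s, fn, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (opt$convergence == 0) flagged <- FALSE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) abort("subject-level optimisation failed from all starts")
  H <- numeric_hessian(fn, best$par)
  reg <- regularize_hessian(H, prior$var)
  log_marginal <- -best$value + 1.5 * log(2 * pi) - 0.5 * reg$logdet
  list(theta = best$par, hessian = reg$H, posterior_var = reg$inv_diag,
       neg_log_post = best$value, log_marginal = log_marginal,
       flagged = flagged)
}

#' Maximum a posteriori fit of one subject
#'
#' Maximises the choice log likelihood plus the log density of a Gaussian
#' group prior in transformed parameter space, computes a central
#' finite-difference Hessian at the optimum (non-positive-definite Hessians
#' are eigenvalue-floored at 1e-6), and returns the Laplace-approximate log
#' marginal likelihood
#' `loglik + log prior + (3/2) log(2 pi) - (1/2) log det H`.
#'
#' @param trials The subject's trial table with filled choices.
#' @param prior A [group_prior()].
#' @param variant `"fixed"` or `"flexible"`.
#' @param n_restarts Optimiser restarts (first start at the prior mean, the
#'   rest jittered).
#' @param init Optional transformed-space starting point.
#' @return A list of class `heist_subject_fit`: `theta` (transformed MAP),
#'   `params` (natural scale), `hessian`, `log_marginal`, `flagged`.
#' @export
subject_map <- function(trials, prior = group_prior(),
                        variant = c("fixed", "flexible"),
                        n_restarts = 3L, init = NULL) {
  variant <- match.arg(variant)
  enc <- encode_trials(trials, require_choices = TRUE)
  fit <- subject_map_enc(enc, prior, flexible = (variant == "flexible"),
                         n_restarts = n_restarts, init = init)
  fit$params <- untransform_params(fit$theta)
  fit$variant <- variant
  class(fit) <- "heist_subject_fit"
  fit
}

#' Hierarchical EM fit of a cohort
#'
#' Alternates subject-level MAP fits (E-step) with moment updates of the
#' diagonal group Gaussian (M-step): the group mean is the mean of the MAP
#' estimates and the group variance the mean of `theta^2` plus the subjects'
#' posterior variances (from the inverse Hessian) minus the squared mean,
#' floored at 1e-6. Iterates until the summed Laplace log marginal changes by
#' less than `tol` (warning if `max_iter` is hit first). Subject fits are
#' warm-started from the previous iteration's MAP.
#'
#' @param cohort A list of trial tables (>= 2 subjects) or one long tibble
#'   with a `subject` column.
#' @param variant `"fixed"` or `"flexible"`.
#' @param prior Initial [group_prior()].
#' @param tol Convergence tolerance on the summed log marginal.
#' @param prior_tol Convergence tolerance on the group prior: the fit also
#'   stops once no element of the group mean or variance moved by more than
#'   this between M-steps (the Laplace evidence carries finite-difference
#'   noise larger than `tol` on realistic cohorts, so prior stability is the
#'   effective criterion there).
#' @param max_iter Maximum EM iterations.
#' @param n_restarts Optimiser restarts on the first EM iteration.
#' @return A list of class `heist_em_fit`: `prior`, per-subject `fits`,
#'   `trace` of summed log marginals, `n_iter`, `converged`, `variant`.
#' @examples
#' \donttest{
#' set.seed(1)
#' cohort <- lapply(1:4, function(i)
#'   simulate_subject(model_params(0.5, 2, 0.8), "flexible", subject = i))
#' fit <- em_fit(cohort, "flexible", max_iter = 10)
#' glance(fit)
#' }
#' @export
em_fit <- function(cohort, variant = c("fixed", "flexible"),
                   prior = group_prior(), tol = 1e-4, prior_tol = 1e-3,
                   max_iter = 200L, n_restarts = 3L) {
  variant <- match.arg(variant)
  cohort <- as_cohort(cohort)
  if (length(cohort) < 2L) abort("em_fit needs at least 2 subjects")
  flexible <- variant == "flexible"
  encs <- lapply(cohort, encode_trials, require_choices = TRUE)
  n <- length(encs)

  inits <- rep(list(NULL), n)
  anchors <- rep(list(NULL), n) # wide-prior MAPs, kept as candidate starts
  trace <- numeric(0)
  converged <- FALSE
  fits <- NULL
  for (iter in seq_len(max_iter)) {
    restarts <- if (iter == 1L) n_restarts else 1L
    fits <- purrr::map2(encs, seq_len(n), function(e, i) {
      ini <- if (is.null(inits[[i]])) NULL else
        cbind(inits[[i]], anchors[[i]])
      subject_map_enc(e, prior, flexible, n_restarts = restarts, init = ini)
    })
    inits <- purrr::map(fits, "theta")
    if (iter == 1L) anchors <- inits
    total <- sum(purrr::map_dbl(fits, "log_marginal"))
    trace <- c(trace, total)
    if (iter > 1L && abs(total - trace[iter - 1L]) < tol) {
      converged <- TRUE
    }
    theta <- do.call(rbind, inits)
    pvar <- do.call(rbind, purrr::map(fits, "posterior_var"))
    pvar <- sweep(pvar, 2L, prior$var, pmin) # posterior no wider than prior
    mu <- colMeans(theta)
    v <- pmax(colMeans(theta^2 + pvar) - mu^2, 1e-6)
    prior_change <- max(abs(mu - prior$mean), abs(v - prior$var))
    prior <- group_prior(mu, v)
    if (iter > 1L && prior_change < prior_tol) converged <- TRUE
    if (converged) break
  }
  if (!converged) {
    warn(sprintf("EM stopped at max_iter = %d without meeting tol = %g",
                 max_iter, tol))
  }
  fits <- purrr::imap(fits, function(f, i) {
    f$params <- untransform_params(f$theta)
    f$subject <- names(cohort)[i] %||% i
    class(f) <- "heist_subject_fit"
    f
  })
  structure(list(prior = prior, fits = fits, trace = trace,
                 n_iter = length(trace), converged = converged,
                 variant = variant),
            class = "heist_em_fit")
}

as_cohort <- function(cohort) {
  if (is.data.frame(cohort)) {
    cohort <- split(cohort, cohort$subject)
  }
  cohort
}

#' Subject-level leave-one-out cross-validation scores
#'
#' For each subject, fits the group hierarchy on the remaining subjects and
#' scores the held-out subject by the negative Laplace log marginal under the
#' resulting group prior. Lower scores indicate better out-of-sample
#' prediction of choices.
#'
#' @inheritParams em_fit
#' @param ... Passed on to [em_fit()] (e.g. `max_iter`, `n_restarts`).
#' @return A tibble with columns `subject`, `loocv` and `flagged`.
#' @export
loocv_scores <- function(cohort, variant = c("fixed", "flexible"), ...) {
  variant <- match.arg(variant)
  cohort <- as_cohort(cohort)
  n <- length(cohort)
  if (n < 3L) abort("loocv_scores needs at least 3 subjects")
  flexible <- variant == "flexible"
  purrr::map_dfr(seq_len(n), function(i) {
    em <- em_fit(cohort[-i], variant, ...)
    enc <- encode_trials(cohort[[i]], require_choices = TRUE)
    fit <- subject_map_enc(enc, em$prior, flexible, n_restarts = 2L)
    tibble::tibble(subject = names(cohort)[i] %||% i,
                   loocv = -fit$log_marginal, flagged = fit$flagged)
  })
}

#' Paired comparison of per-subject model scores
#'
#' Two-sided paired t-test of per-subject scores (lower is better), plus the
#' count of subjects favouring each model.
#'
#' @param scores_a,scores_b Equal-length numeric score vectors (e.g. LOOcv
#'   scores for two model variants), paired by subject.
#' @return A list of class `heist_model_comparison`: `statistic`, `df`,
#'   `p_value`, `mean_diff` (a minus b), `conf_low`, `conf_high`, `wins_a`,
#'   `wins_b`, `n`.
#' @export
compare_models <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) abort("scores must be paired")
  n <- length(scores_a)
  if (n < 2L) abort("need at least 2 paired scores")
  d <- scores_a - scores_b
  if (sd(d) < 1e-12) {
    if (max(abs(d)) < 1e-12) {
      res <- list(statistic = 0, df = n - 1L, p_value = 1,
                  mean_diff = 0, conf_low = 0, conf_high = 0)
    } else {
      abort("degenerate comparison: constant nonzero score differences")
    }
  } else {
    tt <- t.test(scores_a, scores_b, paired = TRUE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, mean_diff = unname(tt$estimate),
                conf_low = tt$conf.int[1], conf_high = tt$conf.int[2])
  }
  res$wins_a <- sum(d < 0)
  res$wins_b <- sum(d > 0)
  res$n <- n
  structure(res, class = "heist_model_comparison")
}

#' Reference group-level parameter distributions
#'
#' Group laws used by the synthetic cohort generators, expressed in the same
#' transformed space as the fitting hierarchy (logit for `alpha` and `w`,
#' log for `beta`) so that synthetic cohorts are draws from the model the
#' fitter assumes. The transformed means are the transforms of the
#' group-level fits reported for each model variant in the fMRI cohort
#' (n = 29): flexible `alpha = 0.56`, `beta = 1.59`, `w(dependent) = 0.85`;
#' fixed `alpha = 0.65`, `beta = 1.80`, `w = 0.61`. The reported confidence
#' intervals imply between-subject natural-scale SDs of roughly 0.4-0.5 for
#' the bounded parameters, which no unimodal law on \[0, 1\] can reach at
#' these means; the generator uses the closest feasible logit-normal
#' approximation (transformed SD 2.0 for `alpha` and `w`, natural SD about
#' 0.3) and the log-scale SD implied by the `beta` confidence interval.
#'
#' @param variant `"fixed"` or `"flexible"`.
#' @return A list with transformed-space numeric 3-vectors `mean_t` and
#'   `sd_t` named `alpha`, `beta`, `w`.
#' @export
default_group_params <- function(variant = c("flexible", "fixed")) {
  variant <- match.arg(variant)
  if (variant == "flexible") {
    list(mean_t = c(alpha = qlogis(0.56), beta = log(1.59), w = qlogis(0.85)),
         sd_t = c(alpha = 2.0, beta = 0.57, w = 2.0))
  } else {
    list(mean_t = c(alpha = qlogis(0.65), beta = log(1.80), w = qlogis(0.61)),
         sd_t = c(alpha = 2.0, beta = 0.56, w = 2.0))
  }
}

#' Sample a pool of subject-level parameters
#'
#' Draws transformed parameters from the Gaussian group law of
#' [default_group_params()] and maps them back to the natural scale,
#' clamping to \[0.02, 0.98\] (`alpha`, `w`) and \[0.05, 10\] (`beta`) to
#' keep later transforms finite.
#'
#' @param n Number of parameter sets.
#' @param variant `"fixed"` or `"flexible"`.
#' @return A tibble with columns `alpha`, `beta`, `w`.
#' @examples
#' set.seed(1)
#' sample_params_pool(5, "flexible")
#' @export
sample_params_pool <- function(n, variant = c("flexible", "fixed")) {
  variant <- match.arg(variant)
  g <- default_group_params(variant)
  tibble::tibble(
    alpha = pmin(pmax(plogis(rnorm(n, g$mean_t["alpha"], g$sd_t["alpha"])), 0.02), 0.98),
    beta = pmin(pmax(exp(rnorm(n, g$mean_t["beta"], g$sd_t["beta"])), 0.05), 10),
    w = pmin(pmax(plogis(rnorm(n, g$mean_t["w"], g$sd_t["w"])), 0.02), 0.98)
  )
}
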