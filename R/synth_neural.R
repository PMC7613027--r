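#' Coding scheme for synthetic multivoxel patterns
#'
#' Defines how trial-wise voxel patterns (stand-ins for single-trial BOLD
#' estimates) encode a binned quantity. Each (context, bin) cell gets a
#' voxel-length prototype drawn i.i.d. standard normal. With `"shared"`
#' coding a condition's two contexts use identical prototypes; with
#' `"separate"` coding they are drawn independently. `"smooth"` tuning
#' correlates adjacent-bin prototypes (first-order autoregressive mixing),
#' giving patterns that vary gradually along the binned axis.
#'
#' @param n_voxels Number of voxels (default 200, the scale of a small ROI).
#' @param n_bins Number of bins in the planted code (default 4).
#' @param sharing_dep,sharing_indep `"shared"` or `"separate"` coding for the
#'   dependent and independent condition's context pair.
#' @param noise_sd SD of the i.i.d. Gaussian trial noise added per voxel.
#' @param run_effect_sd SD of a per-run voxel offset (drawn once per run so
#'   that cross-run cross-validation is non-trivial).
#' @param tuning `"discrete"` (independent bin prototypes) or `"smooth"`.
#' @param smooth_cor Adjacent-bin correlation under smooth tuning.
#' @return A list of class `heist_coding_scheme` with a
#'   `prototypes[context, bin, voxel]` array.
#' @examples
#' set.seed(1)
#' sc <- make_coding_scheme(sharing_dep = "shared", sharing_indep = "separate")
#' @export
make_coding_scheme <- function(n_voxels = 200L, n_bins = 4L,
                               sharing_dep = c("shared", "separate"),
                               sharing_indep = c("separate", "shared"),
                               noise_sd = 8, run_effect_sd = 0.5,
                               tuning = c("discrete", "smooth"),
                               smooth_cor = 0.5) {
  sharing_dep <- match.arg(sharing_dep)
  sharing_indep <- match.arg(sharing_indep)
  tuning <- match.arg(tuning)
  if (n_voxels < 1L || n_bins < 1L) abort("counts must be >= 1")

  draw_proto <- function() {
    m <- matrix(rnorm(n_bins * n_voxels), n_bins, n_voxels)
    if (tuning == "smooth" && n_bins > 1L) {
      for (b in 2:n_bins) {
        m[b, ] <- smooth_cor * m[b - 1L, ] +
          sqrt(1 - smooth_cor^2) * m[b, ]
      }
    }
    m
  }
  proto <- array(NA_real_, dim = c(4L, n_bins, n_voxels))
  sharing <- c(dependent = sharing_dep, independent = sharing_indep)
  pairs <- list(dependent = c(1L, 2L), independent = c(3L, 4L))
  for (cond in names(pairs)) {
    ctxs <- pairs[[cond]]
    proto[ctxs[1L], , ] <- draw_proto()
    proto[ctxs[2L], , ] <- if (sharing[[cond]] == "shared") {
      proto[ctxs[1L], , ]
    } else {
      draw_proto()
    }
  }
  structure(
    list(n_voxels = as.integer(n_voxels), n_bins = as.integer(n_bins),
         prototypes = proto, sharing_dep = sharing_dep,
         sharing_indep = sharing_indep, noise_sd = noise_sd,
         run_effect_sd = run_effect_sd, tuning = tuning),
    class = "heist_coding_scheme"
  )
}

#' Generate a synthetic trial-by-voxel dataset
#'
#' Emits one voxel pattern per trial: the prototype of the trial's
#' (context, bin) cell, plus a per-run offset and i.i.d. Gaussian noise. In
#' `"door"` mode the bin is the fixed-quartile bin of
#' `p(heist | door presented)` (`p_hat` when the dark door is presented,
#' `1 - p_hat` otherwise), the quantity considered at planning time. In
#' `"outcome"` mode the bin is the choice-by-state combination re-encoded at
#' update time (1 dark+heist, 2 dark+neutral, 3 light+heist, 4 light+neutral).
#'
#' @param trials A simulated subject (trial table with trajectory columns;
#'   see [simulate_subject()]); door mode needs `p_hat`, outcome mode needs
#'   filled `choice` and `state`. Sessions are used as scanner runs.
#' @param scheme A [make_coding_scheme()] (outcome mode requires
#'   `n_bins = 4`).
#' @param mode `"door"` or `"outcome"`.
#' @return A list of class `heist_voxel_dataset`: `patterns` (trials x voxels
#'   matrix) and `meta` (tibble with `trial`, `context`, `condition`, `run`,
#'   `bin`, `p`, `time`).
#' @examples
#' set.seed(1)
#' sub <- simulate_subject(model_params(0.5, 2, 0.85), "flexible")
#' vd <- generate_voxel_dataset(sub, make_coding_scheme(n_voxels = 50))
#' dim(vd$patterns)
#' @export
generate_voxel_dataset <- function(trials, scheme, mode = c("door", "outcome")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "heist_coding_scheme"))
  keep <- !is.na(trials$choice) & trials$choice != "missed"
  df <- trials[keep, ]
  if (mode == "door") {
    if (!"p_hat" %in% names(df) || anyNA(df$p_hat)) {
      abort("door mode needs a p_hat column without missing values")
    }
    p <- ifelse(df$door_presented == "dark", df$p_hat, 1 - df$p_hat)
    bin <- assign_probability_bins(p, scheme = "fixed_quartiles",
                                   n_bins = scheme$n_bins)
  } else {
    if (scheme$n_bins != 4L) abort("outcome mode needs a 4-bin coding scheme")
    p <- rep(NA_real_, nrow(df))
    bin <- outcome_bins(df$choice, df$state)
  }
  runs <- sort(unique(df$session))
  run_offsets <- matrix(rnorm(length(runs) * scheme$n_voxels,
                              sd = scheme$run_effect_sd),
                        length(runs), scheme$n_voxels)
  n <- nrow(df)
  patterns <- matrix(NA_real_, n, scheme$n_voxels)
  for (i in seq_len(n)) {
    patterns[i, ] <- scheme$prototypes[df$context[i], bin[i], ] +
      run_offsets[match(df$session[i], runs), ]
  }
  patterns <- patterns +
    matrix(rnorm(n * scheme$n_voxels, sd = scheme$noise_sd),
           n, scheme$n_voxels)
  meta <- tibble::tibble(
    trial = df$trial, context = df$context, condition = df$condition,
    run = match(df$session, runs), bin = bin, p = p, time = df$trial
  )
  structure(list(patterns = patterns, meta = meta, mode = mode),
            class = "heist_voxel_dataset")
}

#' Simulate a cohort of subjects with synthetic voxel patterns
#'
#' Draws agent parameters from `pool`, simulates each subject's behaviour,
#' generates voxel patterns under a fresh coding scheme per subject, and
#' computes the per-condition cross-context RSA summary. Subjects whose
#' trajectories leave an analysis cell empty (so that a bin mean is
#' undefined) are replaced by a fresh draw, mirroring the exclusion of
#' unanalysable participants; the number of replacements is reported.
#'
#' @param n_subjects Number of analysable subjects to return.
#' @param variant Agent model variant.
#' @param pool Parameter pool (rows resampled per subject).
#' @param config Task configuration.
#' @param mode `"door"` (probability bins) or `"outcome"` (choice-by-state
#'   bins).
#' @param bin_scheme Binning for door mode: `"subject_quartiles"` or
#'   `"fixed_quartiles"`.
#' @param n_bins Number of probability bins (door mode).
#' @param ... Passed to [make_coding_scheme()] (e.g. `sharing_dep`,
#'   `sharing_indep`, `noise_sd`).
#' @return A list: `summaries` (tibble subject x condition with `on_diag`,
#'   `off_diag`, `difference`), `datasets` (named list of voxel datasets),
#'   `subjects` (list of simulated trial tables), `n_replaced`.
#' @export
simulate_neural_cohort <- function(n_subjects = 29L,
                                   variant = c("flexible", "fixed"),
                                   pool = NULL,
                                   config = task_config("fmri"),
                                   mode = c("door", "outcome"),
                                   bin_scheme = "subject_quartiles",
                                   n_bins = 4L, ...) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  pool <- pool %||% sample_params_pool(n_subjects, variant)
  datasets <- list()
  subjects <- list()
  summaries <- list()
  n_replaced <- 0L
  i <- 0L
  while (i < n_subjects) {
    pp <- pool[sample(nrow(pool), 1L), ]
    sub <- simulate_subject(model_params(pp$alpha, pp$beta, pp$w), variant,
                            config, subject = i + 1L)
    scheme <- make_coding_scheme(n_bins = if (mode == "door") n_bins else 4L,
                                 ...)
    vd <- generate_voxel_dataset(sub, scheme, mode = mode)
    bins <- if (mode == "door") {
      assign_probability_bins(vd$meta$p, scheme = bin_scheme, n_bins = n_bins)
    } else {
      vd$meta$bin
    }
    res <- tryCatch(
      purrr::map_dfr(c("dependent", "independent"), function(cond) {
        s <- rsa_condition_contrast(vd, cond, bins = bins, n_bins = n_bins)
        tibble::tibble(subject = i + 1L, condition = cond,
                       on_diag = s$on_diag, off_diag = s$off_diag,
                       difference = s$difference)
      }),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_replaced <- n_replaced + 1L
      if (n_replaced > 10L * n_subjects) {
        abort("too many subjects without analysable bin coverage")
      }
      next
    }
    i <- i + 1L
    datasets[[i]] <- vd
    subjects[[i]] <- sub
    summaries[[i]] <- res
  }
  names(datasets) <- seq_len(n_subjects)
  list(summaries = dplyr::bind_rows(summaries), datasets = datasets,
       subjects = subjects, n_replaced = n_replaced)
}
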