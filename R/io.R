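trial_table_cols <- c("subject", "session", "block", "condition", "context",
                      "trial", "trial_type", "valence", "door_presented",
                      "choice", "state", "outcome", "p_true")

trial_table_enums <- list(
  condition = c("dependent", "independent"),
  trial_type = c("forced", "free"),
  valence = c("gain", "loss"),
  door_presented = c("dark", "light"),
  choice = c("dark", "light", "missed"),
  state = c("heist", "neutral")
)

#' Validate a trial table
#'
#' Checks the column set, enum values (lower-case strings) and the
#' outcome/state/valence consistency rules; `choice`, `state` and `outcome`
#' may be `NA` (design-only tables).
#'
#' @param trials A data frame.
#' @return The input, invisibly, or an error naming the violation.
#' @export
validate_trial_table <- function(trials) {
  missing <- setdiff(trial_table_cols, names(trials))
  if (length(missing)) {
    abort(paste0("trial table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  for (col in names(trial_table_enums)) {
    bad <- setdiff(unique(trials[[col]][!is.na(trials[[col]])]),
                   trial_table_enums[[col]])
    if (length(bad)) {
      abort(sprintf("column `%s` has invalid values: %s", col,
                    paste(bad, collapse = ", ")))
    }
  }
  filled <- !is.na(trials$state) & !is.na(trials$outcome)
  ok <- with(trials[filled, ],
             (state == "neutral" & outcome == 0L) |
               (state == "heist" & valence == "gain" & outcome == 1L) |
               (state == "heist" & valence == "loss" & outcome == -1L))
  if (any(!ok)) abort("outcome is inconsistent with state and valence")
  forced <- !is.na(trials$choice) & trials$choice != "missed" &
    trials$trial_type == "forced"
  if (any(trials$choice[forced] != trials$door_presented[forced])) {
    abort("forced-trial choices must equal the presented door")
  }
  invisible(trials)
}

#' Read and write trial tables as CSV
#'
#' Column names follow the trial-record schema; enum values are lower-case
#' strings and the on-disk `trial` index is 0-based.
#'
#' @param trials A trial table.
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns a validated tibble.
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  out <- trials[trial_table_cols]
  out$trial <- out$trial - 1L
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tt <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          condition = "c", context = "i", trial = "i",
                          trial_type = "c", valence = "c",
                          door_presented = "c", choice = "c", state = "c",
                          outcome = "i", p_true = "d", session = "i",
                          block = "i"))
  tt$trial <- tt$trial + 1L
  validate_trial_table(tt)
  tt
}

#' Map an external behavioural table onto the trial-record schema
#'
#' Thin adapter for deposited data whose columns or value codes differ from
#' this package's schema: renames columns via `mapping`, recodes values via
#' `value_maps`, drops missed trials if requested, and validates.
#'
#' @param df External data frame.
#' @param mapping Named character vector `c(internal = "external", ...)`.
#' @param value_maps Named list of named vectors recoding column values,
#'   e.g. `list(choice = c("1" = "dark", "2" = "light"))`.
#' @param drop_missed Drop rows whose mapped `choice` is `"missed"`
#'   (excluded from all analyses).
#' @return A validated trial table.
#' @export
as_trial_table <- function(df, mapping, value_maps = list(),
                           drop_missed = TRUE) {
  for (internal in names(mapping)) {
    ext <- mapping[[internal]]
    if (!ext %in% names(df)) {
      abort(sprintf("mapped column `%s` (for `%s`) not found", ext, internal))
    }
    df[[internal]] <- df[[ext]]
  }
  for (col in names(value_maps)) {
    vm <- value_maps[[col]]
    df[[col]] <- unname(vm[as.character(df[[col]])])
  }
  df <- tibble::as_tibble(df)[trial_table_cols]
  if (drop_missed) {
    df <- df[is.na(df$choice) | df$choice != "missed", ]
  }
  validate_trial_table(df)
  df
}

#' Read and write model trajectories as CSV
#'
#' Trajectories align row-by-row with a trial table.
#'
#' @param trajectory A [run_model()] result.
#' @param path File path.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_csv(
    trajectory[c("p_hat", "q_dark", "q_light", "choice_prob_dark", "delta",
                 "loglik_contribution")], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write voxel datasets
#'
#' The pattern matrix is written as TSV (one row per trial) and the trial
#' metadata as a CSV sharing its row order; reading checks that the two row
#' counts agree.
#'
#' @param dataset A `heist_voxel_dataset`.
#' @param patterns_path,meta_path File paths.
#' @export
write_voxel_dataset <- function(dataset, patterns_path, meta_path) {
  utils::write.table(dataset$patterns, patterns_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  readr::write_csv(dataset$meta, meta_path)
  invisible(patterns_path)
}

#' @rdname write_voxel_dataset
#' @export
read_voxel_dataset <- function(patterns_path, meta_path) {
  patterns <- as.matrix(utils::read.table(patterns_path, sep = "\t",
                                          header = FALSE))
  dimnames(patterns) <- NULL
  meta <- readr::read_csv(meta_path, show_col_types = FALSE)
  if (nrow(patterns) != nrow(meta)) {
    abort(sprintf("pattern rows (%d) and metadata rows (%d) differ",
                  nrow(patterns), nrow(meta)))
  }
  structure(list(patterns = patterns, meta = meta, mode = "unknown"),
            class = "heist_voxel_dataset")
}

#' Export a hierarchical fit as JSON
#'
#' Stores the group prior, per-subject natural parameters and Laplace
#' evidences (and LOOcv scores if supplied).
#'
#' @param fit A [em_fit()] result.
#' @param path File path.
#' @param loocv Optional [loocv_scores()] tibble.
#' @export
write_fit_json <- function(fit, path, loocv = NULL) {
  stopifnot(inherits(fit, "heist_em_fit"))
  subjects <- purrr::map(fit$fits, function(f) {
    list(subject = f$subject, alpha = f$params$alpha, beta = f$params$beta,
         w = f$params$w, log_marginal = f$log_marginal, flagged = f$flagged)
  })
  obj <- list(
    variant = fit$variant,
    prior = list(mean = fit$prior$mean, var = fit$prior$var),
    n_iter = fit$n_iter, converged = fit$converged,
    subjects = subjects
  )
  if (!is.null(loocv)) obj$loocv <- loocv
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
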