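test_that("fixed quartile bins use the printed edges with ties going down", {
  p <- c(0.10, 0.25, 0.26, 0.50, 0.51, 0.75, 0.76, 0.90, 0, 1)
  bins <- assign_probability_bins(p, "fixed_quartiles")
  expect_equal(bins, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 1L, 4L))
  expect_error(assign_probability_bins(numeric(0)), "empty")
  expect_error(assign_probability_bins(c(0.2, 1.4)), "0, 1")
})

test_that("subject quartiles give near-equal bin counts", {
  set.seed(50)
  p <- runif(201)
  bins <- assign_probability_bins(p, "subject_quartiles")
  counts <- tabulate(bins, 4)
  expect_lte(max(counts) - min(counts), 2L)
})

test_that("outcome bins enumerate the four choice-state combinations", {
  expect_equal(outcome_bins(c("dark", "dark", "light", "light"),
                            c("heist", "neutral", "heist", "neutral")),
               1:4)
  expect_true(is.na(outcome_bins("missed", "heist")))
})

test_that("bin means are per-voxel averages and empty cells error by name", {
  patterns <- rbind(c(1, 2, 3), c(3, 4, 5), c(10, 10, 10))
  vd <- structure(list(
    patterns = patterns,
    meta = tibble::tibble(context = c(1L, 1L, 1L), run = 1L, bin = c(1L, 1L, 2L),
                          condition = "dependent")
  ), class = "heist_voxel_dataset")
  m <- bin_mean_patterns(vd, context = 1, n_bins = 2)
  expect_equal(m[1, ], c(2, 3, 4))
  expect_equal(m[2, ], c(10, 10, 10))
  expect_error(bin_mean_patterns(vd, context = 1, n_bins = 3),
               "context 1, bin 3")
})

test_that("cross-context contrast uses 4 diagonal and 12 off-diagonal cells", {
  set.seed(51)
  A <- matrix(rnorm(4 * 50), 4)
  s_id <- cross_context_contrast(A, A)
  expect_equal(dim(s_id$z_matrix), c(4L, 4L))
  expect_equal(s_id$on_diag, atanh(1 - 1e-6)) # clipped r = 1
  expect_gt(s_id$difference, 5)

  B <- matrix(rnorm(4 * 50), 4)
  s_ab <- cross_context_contrast(A, B)
  expect_equal(s_ab$difference, s_ab$on_diag - s_ab$off_diag)
  # the 4x4 block is used as-is, not symmetrized
  expect_false(isTRUE(all.equal(s_ab$z_matrix, t(s_ab$z_matrix))))
  expect_equal(s_ab$off_diag,
               mean(s_ab$z_matrix[row(s_ab$z_matrix) != col(s_ab$z_matrix)]))

  # independent random patterns: difference ~ 0 in expectation
  diffs <- replicate(200, {
    cross_context_contrast(matrix(rnorm(4 * 30), 4),
                           matrix(rnorm(4 * 30), 4))$difference
  })
  expect_lt(abs(mean(diffs)), 0.05)

  expect_error(cross_context_contrast(A, B[, 1:10]), "voxel")
  Az <- A; Az[2, ] <- 1
  expect_error(cross_context_contrast(Az, B), "zero-variance")
})

test_that("cross-validated contrast equals the plain contrast on run-identical data", {
  set.seed(52)
  sub <- simulate_subject(model_params(0.6, 2, 0.85), "flexible")
  sc <- make_coding_scheme(n_voxels = 40, noise_sd = 0, run_effect_sd = 0)
  vd <- generate_voxel_dataset(sub, sc, mode = "outcome")
  plain <- rsa_condition_contrast(vd, "dependent")
  cv <- crossval_contrast(vd, "dependent", "between_context")
  expect_equal(cv$on_diag, plain$on_diag, tolerance = 1e-10)
  expect_equal(cv$off_diag, plain$off_diag, tolerance = 1e-10)
})

test_that("cross-validated contrasts separate shared from separate codes", {
  set.seed(53)
  sub <- simulate_subject(model_params(0.6, 2, 0.85), "flexible")
  sc <- make_coding_scheme(n_voxels = 150, sharing_dep = "shared",
                           sharing_indep = "separate", noise_sd = 2)
  vd <- generate_voxel_dataset(sub, sc, mode = "outcome")
  between_dep <- crossval_contrast(vd, "dependent", "between_context")
  between_ind <- crossval_contrast(vd, "independent", "between_context")
  within_ind <- crossval_contrast(vd, "independent", "within_context")
  expect_gt(between_dep$difference, 0.3)
  expect_lt(abs(between_ind$difference), 0.2)
  expect_gt(within_ind$difference, 0.3) # the separate code is stable within context
})

test_that("condition interaction flips sign under label swap and nulls on ties", {
  set.seed(54)
  summaries <- tibble::tibble(
    subject = rep(1:10, each = 2),
    condition = rep(c("dependent", "independent"), 10),
    difference = rnorm(20, rep(c(0.3, 0.0), 10), 0.05)
  )
  ci <- condition_interaction(summaries)
  swapped <- summaries
  swapped$condition <- ifelse(swapped$condition == "dependent",
                              "independent", "dependent")
  ci_sw <- condition_interaction(swapped)
  expect_equal(ci$statistic, -ci_sw$statistic, tolerance = 1e-10)

  tied <- summaries
  tied$difference <- rep(c(0.2, 0.2), 10)
  ci0 <- condition_interaction(tied)
  expect_equal(ci0$statistic, 0)
  expect_equal(ci0$p_value, 1)
})

test_that("temporal proximity control detects planted clustering and not chance", {
  set.seed(55)
  make_vd <- function(bins, times) {
    structure(list(
      patterns = matrix(rnorm(80), 40),
      meta = tibble::tibble(context = rep(c(1L, 2L), each = 20),
                            condition = "dependent",
                            bin = rep(bins, 2),
                            run = 1L, time = times)
    ), class = "heist_voxel_dataset")
  }
  # bins cycling uniformly through time: proximity difference ~ 0
  even <- make_vd(rep(1:4, 5), c(seq(1, 78, 4), seq(3, 80, 4)))
  # same-bin trials clustered in time across contexts
  clustered <- make_vd(rep(1:4, each = 5),
                       c(rep(1:4, each = 5) * 100 + runif(20),
                         rep(1:4, each = 5) * 100 + runif(20)))
  vds <- list(a = even, b = clustered)
  sums <- tibble::tibble(subject = c("a", "b"), condition = "dependent",
                         difference = c(0.1, 0.2))
  res <- temporal_proximity_control(vds, sums, "dependent")
  prox <- res$per_subject$proximity_difference
  expect_lt(abs(prox[1]), 5)
  expect_lt(prox[2], -100) # same-bin pairs much closer in time

  # shuffled timestamps: proximity difference ~ 0 on average
  set.seed(56)
  shuffled <- replicate(100, {
    vd <- make_vd(rep(1:4, 5), sample(1:40))
    m <- vd$meta
    a <- m[m$context == 1, ]; b <- m[m$context == 2, ]
    dt <- abs(outer(a$time, b$time, "-"))
    same <- outer(a$bin, b$bin, "==")
    mean(dt[same]) - mean(dt[!same])
  })
  expect_lt(abs(mean(shuffled)), 1.5)
})
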