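test_that("lambda_max matches the closed-form gradient bound", {
  set.seed(21)
  n <- 30
  y <- factor(rep(c("NH", "HI"), each = 15), levels = c("NH", "HI"))
  x <- as.numeric(y) - 1 + stats::rnorm(n, 0, 0.1)
  X <- matrix(x, ncol = 1)
  y01 <- as.numeric(y) - 1
  expect_equal(lambda_max(X, y),
               abs(sum(x * (y01 - mean(y01)))) / n)

  # homogeneity: scaling X scales lambda_max by the same factor
  expect_equal(lambda_max(3.7 * X, y), 3.7 * lambda_max(X, y))

  # duplicated features do not change the maximum
  expect_equal(lambda_max(cbind(X, X), y), lambda_max(X, y))

  expect_error(lambda_max(matrix(0, 10, 2), rep(0:1, 5)), "zero")
})

test_that("randomized L1 fit has the expected degenerate limits", {
  set.seed(33)
  n <- 60; p <- 5
  X <- matrix(stats::rnorm(n * p), n)
  y <- factor(rep(c("NH", "HI"), each = n / 2), levels = c("NH", "HI"))
  X[, 2] <- X[, 2] + 2 * (as.numeric(y) - 1)
  X[, 4] <- X[, 4] - 2 * (as.numeric(y) - 1)
  Xz <- scale(X)

  lmax <- lambda_max(Xz, y)
  # at or above lambda_max with no randomization: the null model
  null_fit <- randomized_l1_fit(Xz, y, lambda = lmax * 1.01, weakness = 1)
  expect_length(null_fit$selected, 0)

  # near-unpenalized limit with n >= p: informative features selected
  low_fit <- randomized_l1_fit(Xz, y, lambda = lmax * 1e-4, weakness = 1)
  expect_true(all(c(1L, 3L) %in% low_fit$selected))

  # weakness 1 reduces to the plain L1 path
  grid <- erpdecode:::lambda_path(lmax, 10, 1e-3)
  plain <- glmnet::glmnet(Xz, y, family = "binomial", lambda = grid,
                          standardize = FALSE, thresh = 0.01, maxit = 1e5)
  ours <- randomized_l1_fit(Xz, y, lambda = grid, weakness = 1)
  expect_identical(ours$selected,
                   unname(which(rowSums(as.matrix(plain$beta) != 0) > 0)) - 1L)

  expect_error(randomized_l1_fit(Xz, y, lmax, weights = 1:3), "per feature")
})

test_that("stability scores separate a planted feature from noise", {
  # selective regime: more features than subsampled rows, one label copy
  set.seed(55)
  n <- 60; p <- 60
  y <- factor(rep(c("NH", "HI"), each = n / 2), levels = c("NH", "HI"))
  X <- cbind(as.numeric(y) - 1 + stats::rnorm(n, 0, 0.1),
             matrix(stats::rnorm(n * (p - 1)), n))
  Xz <- scale(X)
  sc <- suppressWarnings(
    stability_scores(Xz, y, stability_params(n_resamples = 200, seed = 77)))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gte(sc[1], 0.9)               # the label-copy feature is stable
  expect_gte(mean(sc[-1] < 0.25), 0.9) # pure-noise features score low

  # restricting the path to its sparse upper half isolates the planted
  # feature completely on an easy instance
  Xs <- scale(cbind(Xz[, 1], matrix(stats::rnorm(n * 5), n)))
  scs <- suppressWarnings(
    stability_scores(Xs, y, stability_params(n_resamples = 100, seed = 78,
                                             lambda_min_ratio = 0.5)))
  expect_gte(scs[1], 0.95)
  expect_true(all(scs[-1] <= 0.1))

  # seeded determinism of the whole resampling schedule
  sc2 <- suppressWarnings(
    stability_scores(Xz, y, stability_params(n_resamples = 200, seed = 77)))
  expect_identical(as.numeric(sc), as.numeric(sc2))
})

test_that("threshold sweep is nested, flags the optimum, and matches the
           all-feature SVM at threshold zero", {
  fm <- planted_features()
  stab <- planted_stability()
  scores <- stab$scores

  # nestedness of selected sets across increasing thresholds
  th <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  sel <- lapply(th, function(t) which(scores >= t))
  for (i in seq_len(length(th) - 1))
    expect_true(all(sel[[i + 1]] %in% sel[[i]]))

  sw <- threshold_sweep(scores, fm, thresholds = c(0, 0.5, 0.99),
                        grid = unit_grid(), seed = 99)
  expect_identical(sw$n_selected_features[1], length(scores))
  # a threshold above every score selects nothing, metrics missing
  expect_identical(sw$n_selected_features[3], 0L)
  expect_true(is.na(sw$accuracy[3]))
  expect_true(all(sw$n_unique_rois <= sw$n_selected_features))
  ok <- !is.na(sw$accuracy)
  expect_identical(sum(sw$optimal), 1L)
  expect_equal(sw$accuracy[sw$optimal], max(sw$accuracy[ok]))

  # threshold 0 = the plain all-feature SVM evaluation under the same
  # split/normalization policy, recomputed independently here
  sp <- split_data(fm, 0.8, "pseudo_trial", seed = 99)
  nz <- zscore_fit_apply(sp$train, list(sp$test))
  gs <- grid_search_svm(nz$train$X, nz$train$y, unit_grid(), 5, seed = 100)
  pr <- erpdecode:::svm_fit_predict(nz$train$X, nz$train$y, nz$others[[1]]$X,
                                    gs$C, gs$gamma)
  m <- classification_metrics(nz$others[[1]]$y, pr$pred, pr$decision)
  expect_equal(sw$accuracy[1], m$accuracy)
  expect_equal(sw$auc[1], m$auc)
})

test_that("region aggregation takes per-ROI maxima and ranks by score", {
  atlas <- make_atlas()
  meta <- data.frame(feature_index = 0:5,
                     roi_index = c(0L, 0L, 1L, 1L, 40L, 40L),
                     window_index = rep(0:1, 3),
                     window_start_ms = rep(c(-10, 0), 3),
                     window_end_ms = rep(c(0, 10), 3),
                     hemisphere = c("L", "L", "L", "L", "R", "R"),
                     abbrev = NA)
  scores <- c(0.4, 0.6, 0.2, 0.1, 0.6, 0.55)

  reg <- select_regions(scores, meta, atlas, threshold = 0.5)
  expect_identical(nrow(reg), 2L)
  # max aggregation: ROI 0 appears once with its best window's score
  expect_equal(reg$stability_score, c(0.6, 0.6))
  # tie broken by ROI index
  expect_identical(reg$roi_index, c(0L, 40L))
  expect_identical(reg$hemisphere, c("L", "R"))
  expect_identical(reg$rank, 1:2)

  none <- select_regions(scores, meta, atlas, threshold = 0.95)
  expect_identical(nrow(none), 0L)

  # hemisphere summary is consistent with the table it summarizes
  ls <- lateralization_summary(reg)
  expect_equal(sum(ls$by_hemisphere$n), nrow(reg))
  expect_equal(ls$by_hemisphere$fraction, c(0.5, 0.5))
})
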