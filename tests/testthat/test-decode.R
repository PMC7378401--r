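test_that("classification metrics match hand-computed values", {
  # perfect prediction
  m <- classification_metrics(c("NH", "NH", "HI", "HI"),
                              c("NH", "NH", "HI", "HI"), c(-2, -1, 1, 2))
  expect_equal(unlist(m), c(accuracy = 1, auc = 1, f1 = 1))

  # contingency 3 TP / 1 FP / 1 FN / 5 TN: accuracy 0.8, F1 0.75
  y_true <- c(rep("HI", 4), rep("NH", 6))
  y_pred <- c("HI", "HI", "HI", "NH", "HI", rep("NH", 5))
  m <- classification_metrics(y_true, y_pred, seq_along(y_true))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.75)

  # constant decision values carry no ranking information
  m <- classification_metrics(c("NH", "HI", "NH", "HI"),
                              c("NH", "NH", "NH", "NH"), rep(0, 4))
  expect_equal(m$auc, 0.5)

  expect_error(classification_metrics(rep("HI", 4), rep("HI", 4), 1:4),
               "single class")

  # AUC agrees with an independent ROC implementation
  set.seed(14)
  yt <- sample(c("NH", "HI"), 40, replace = TRUE)
  dv <- stats::rnorm(40) + (yt == "HI")
  ours <- classification_metrics(yt, yt, dv)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = yt, predictor = dv,
                                        levels = c("NH", "HI"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("stratified splits respect proportions, units and seeds", {
  cohort <- tiny_cohort()
  fm <- build_feature_matrix(cohort, "clear", n_per_average = 2, seed = 4)
  expect_identical(nrow(fm$X), 48L)   # 4 subjects x 12 averages

  sp <- split_data(fm, 0.75, seed = 3)
  expect_identical(nrow(sp$train$X), 36L)
  expect_identical(nrow(sp$test$X), 12L)
  expect_equal(as.numeric(table(sp$train$y)), c(18, 18))  # stratified

  # subject unit: no subject on both sides
  sps <- split_data(fm, 0.5, unit = "subject", seed = 3)
  expect_length(intersect(unique(sps$train$subject_of),
                          unique(sps$test$subject_of)), 0)

  expect_identical(split_data(fm, 0.75, seed = 3)$train_rows, sp$train_rows)
  expect_error(split_data(fm, 1.2, seed = 1), "train_fraction")
})

test_that("grid search solves separable data and prefers simpler ties", {
  set.seed(61)
  X <- rbind(matrix(stats::rnorm(40, -3), 20), matrix(stats::rnorm(40, 3), 20))
  y <- factor(rep(c("NH", "HI"), each = 20), levels = c("NH", "HI"))
  gs <- grid_search_svm(X, y, grid_spec(C_values = c(1, 10),
                                        gamma_values = c(0.05, 0.5)),
                        folds = 4, seed = 2)
  expect_equal(gs$cv_accuracy, 1)
  # every combo separates this set perfectly, so the tie-break picks the
  # smallest C then smallest gamma
  expect_equal(gs$C, 1)
  expect_equal(gs$gamma, 0.05)

  # singleton grid returns its parameter pair without searching
  g1 <- grid_search_svm(X, y, grid_spec(C_values = 7, gamma_values = 0.3),
                        folds = 4, seed = 2)
  expect_equal(c(g1$C, g1$gamma), c(7, 0.3))

  # permuted labels: CV accuracy hovers at chance
  accs <- replicate(20, {
    yp <- sample(y)
    grid_search_svm(X, yp, grid_spec(C_values = 1, gamma_values = c(0.05, 0.5)),
                    folds = 4, seed = 5)$cv_accuracy
  })
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)

  expect_error(grid_search_svm(X, factor(rep("HI", 40)), test_grid(), 4),
               "single class")
})

test_that("peak accuracy is monotone in the planted effect size", {
  accs <- vapply(c(1, 1.5, 2.5), function(eff) {
    cfg <- latency_config(seed = 808)
    cfg$group_effect <- eff
    cfg$n_nh <- 4L; cfg$n_hi <- 4L; cfg$n_trials <- 150L
    cohort <- simulate_cohort(cfg, conditions = "clear")
    fm <- build_feature_matrix(cohort, "clear", n_per_average = 15, seed = 6)
    decode_windows(fm, "whole", grid = unit_grid(), seed = 13)$best$accuracy
  }, 0)
  tol <- 0.1
  expect_true(accs[2] >= accs[1] - tol)
  expect_true(accs[3] >= accs[2] - tol)
  expect_gt(accs[3], accs[1])   # strong effect clearly beats none
})

test_that("whole-brain peak accuracy is not worse than either hemisphere", {
  whole <- latency_decode("clear_whole")$best$accuracy
  lh <- latency_decode("clear_lh")$best$accuracy
  rh <- latency_decode("clear_rh")$best$accuracy
  expect_gte(whole, max(lh, rh) - 0.1)
})

test_that("decoding results expose consistent structure and methods", {
  dr <- latency_decode("clear_whole")
  expect_s3_class(dr, "decoding_result")
  expect_identical(nrow(dr$per_window), 21L)
  expect_true(all(dr$per_window$accuracy >= 0 & dr$per_window$accuracy <= 1))
  expect_true(all(dr$per_window$auc >= 0 & dr$per_window$auc <= 1))
  expect_equal(dr$best$accuracy, max(dr$per_window$accuracy))
  b <- which.max(dr$per_window$accuracy)
  expect_equal(dr$best$latency_ms, dr$per_window$window_start_ms[b])
  expect_output(print(dr), "peak accuracy")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(dr))
})
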