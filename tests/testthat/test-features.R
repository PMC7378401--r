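test_that("subsample averaging draws disjoint subsets and preserves means", {
  block <- tiny_cohort()[[1]]   # 24 trials x 6 ROIs
  n_trials <- dim(block$data)[1]

  # full average equals the grand mean
  full <- subsample_average(block, n_trials, 1, seed = 1)
  expect_equal(full[1, , ], colMeans(block$data, dims = 1))

  # size-1 averages are a permutation-subset of raw trials
  ones <- subsample_average(block, 1, 5, seed = 2)
  sets <- attr(ones, "trial_sets")
  for (i in 1:5)
    expect_equal(ones[i, , ], block$data[sets[[i]], , ])

  # disjointness: no trial is reused across pseudo-trials
  pt <- subsample_average(block, 4, 6, seed = 3)
  idx <- unlist(attr(pt, "trial_sets"))
  expect_identical(anyDuplicated(idx), 0L)
  expect_length(idx, 24)

  # over-requesting disjoint draws fails; overlapping mode permits it
  expect_error(subsample_average(block, 4, 7, seed = 3), "insufficient")
  over <- subsample_average(block, 4, 7, seed = 3, overlapping = TRUE)
  expect_identical(dim(over)[1], 7L)

  # seeded determinism
  expect_equal(subsample_average(block, 4, 6, seed = 3), pt)
})

test_that("baseline correction removes constants, idempotently", {
  tb <- seq(-10, 198, by = 2)
  waves <- array(stats::rnorm(2 * 3 * length(tb)), c(2, 3, length(tb)))

  const <- array(7, dim(waves))
  expect_equal(baseline_correct(const, tb), array(0, dim(waves)))

  bc <- baseline_correct(waves, tb)
  expect_equal(baseline_correct(bc, tb), bc)                  # idempotent
  expect_equal(baseline_correct(waves + 3, tb), bc)           # shift invariant
  base_sel <- tb >= -10 & tb < 0
  expect_equal(apply(bc[, , base_sel], c(1, 2), mean),
               matrix(0, 2, 3))
  expect_error(baseline_correct(waves, tb, baseline_ms = c(-500, -400)),
               "no samples")
})

test_that("window features tile the span in row-major ROI x window order", {
  tb <- seq(-10, 198, by = 2)
  waves <- array(stats::rnorm(4 * 3 * length(tb)), c(4, 3, length(tb)))
  wf <- window_features(waves, tb, window_ms = 10)
  expect_identical(ncol(wf$X), 3L * 21L)
  expect_identical(nrow(wf$meta), 63L)
  # index arithmetic and tiling
  expect_identical(wf$meta$feature_index,
                   wf$meta$roi_index * 21L + wf$meta$window_index)
  w0 <- wf$meta[wf$meta$roi_index == 0, ]
  expect_equal(w0$window_start_ms, seq(-10, 190, by = 10))
  expect_equal(w0$window_end_ms, w0$window_start_ms + 10)

  # piecewise-constant waveform: feature equals the constant
  waves2 <- array(0, c(1, 1, length(tb)))
  waves2[1, 1, tb >= 40 & tb < 50] <- 4.5
  wf2 <- window_features(waves2, tb, window_ms = 10)
  win_40 <- which(wf2$meta$window_start_ms == 40)
  expect_equal(wf2$X[1, win_40], 4.5)
  expect_equal(sum(wf2$X[1, -win_40]), 0)

  expect_error(window_features(waves, tb, window_ms = 500), "larger")
})

test_that("windowing commutes with trial averaging", {
  tb <- seq(-10, 198, by = 2)
  waves <- array(stats::rnorm(6 * 2 * length(tb)), c(6, 2, length(tb)))
  avg <- array(colMeans(waves, dims = 1), c(1, 2, length(tb)))
  f_avg <- window_features(avg, tb)$X
  f_all <- window_features(waves, tb)$X
  expect_equal(as.numeric(f_avg), colMeans(f_all), tolerance = 1e-12)
})

test_that("z-scoring is fitted on the training matrix only", {
  cohort <- tiny_cohort()
  fm <- build_feature_matrix(cohort, "clear", n_per_average = 6, seed = 4)
  sp <- split_data(fm, 0.75, seed = 8)
  nz <- zscore_fit_apply(sp$train, list(sp$test))
  expect_equal(colMeans(nz$train$X), numeric(ncol(fm$X)), tolerance = 1e-10)
  expect_equal(apply(nz$train$X, 2, sd), rep(1, ncol(fm$X)),
               tolerance = 1e-10)
  # test set transformed with train parameters, not its own
  expect_false(isTRUE(all.equal(colMeans(nz$others[[1]]$X),
                                numeric(ncol(fm$X)), tolerance = 1e-3)))
  # re-applying the *stored* affine map to already-normalized data is not
  # the identity (z-scoring is not idempotent as a fixed transform)
  pars <- nz$train$norm_params
  twice <- sweep(sweep(nz$train$X, 2, pars$mean, `-`), 2, pars$sd, `/`)
  expect_false(isTRUE(all.equal(twice, nz$train$X)))

  # constant feature: zeros plus a warning
  fmc <- fm; fmc$X[, 3] <- 2
  expect_warning(nzc <- zscore_fit_apply(fmc), "zero-variance")
  expect_equal(nzc$X[, 3], numeric(nrow(fmc$X)))
})

test_that("feature matrix construction stacks subjects with labels", {
  cohort <- tiny_cohort()
  fm <- build_feature_matrix(cohort, "clear", n_per_average = 6, seed = 4)
  expect_identical(nrow(fm$X), 4L * 4L)      # 4 subjects x 24/6 averages
  expect_identical(ncol(fm$X), 6L * 21L)
  expect_identical(as.character(unique(fm$y)), c("NH", "HI"))
  expect_identical(length(unique(fm$subject_of)), 4L)
  expect_identical(levels(fm$y), c("NH", "HI"))
})

test_that("feature matrix round-trips through CSV", {
  cohort <- tiny_cohort()
  fm <- build_feature_matrix(cohort, "clear", n_per_average = 12, seed = 4)
  stem <- tempfile()
  write_feature_matrix(fm, stem)
  back <- read_feature_matrix(stem)
  expect_equal(back$X, fm$X, tolerance = 1e-12)
  expect_identical(back$y, fm$y)
  expect_identical(back$subject_of, fm$subject_of)
  expect_equal(back$meta$window_start_ms, fm$meta$window_start_ms)
})
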