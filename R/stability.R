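#' Largest useful L1 penalty
#'
#' Smallest penalty at which an L1-penalized (logistic or linear) model
#' keeps every coefficient at zero: the maximum absolute gradient of the
#' unpenalized loss at the null model, `max_j |x_j' (y - mean(y))| / n`.
#' The regularization path used by stability selection is anchored at this
#' data-driven value, the same entry point the least-angle-regression
#' path starts from.
#'
#' @param X Numeric matrix (rows = samples), typically z-scored.
#' @param y Two-level factor or 0/1 vector.
#' @return Positive scalar.
#' @export
lambda_max <- function(X, y) {
  y01 <- if (is.factor(y)) as.numeric(y) - 1 else as.numeric(y)
  if (all(X == 0)) stop("X is all zero")
  max(abs(crossprod(X, y01 - mean(y01)))) / nrow(X)
}

# Log-spaced penalty path from lambda_max down to lambda_max * min_ratio.
lambda_path <- function(lmax, n_lambda = 25, min_ratio = 1e-3) {
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Stability-selection parameters
#'
#' Configuration of the resampling scheme: subsample fraction 0.75, 1000
#' resamples and solver tolerance 0.01 by default, with randomization
#' weakness 0.5 (each feature's penalty is divided by an independent
#' uniform draw from `[weakness, 1]`, the randomized-lasso device that
#' decorrelates selection among correlated features).
#'
#' @param sample_fraction Fraction of rows drawn (without replacement) per
#'   resample, in (0, 1).
#' @param n_resamples Number of resamples.
#' @param weakness Randomization strength in (0, 1]; 1 disables the
#'   penalty randomization.
#' @param lambda_grid Optional explicit penalty grid; when `NULL` it is
#'   derived from the data as [lambda_path()] of [lambda_max()].
#' @param n_lambda,lambda_min_ratio Grid shape when derived from data.
#' @param tol Convergence tolerance of the coordinate-descent solver.
#' @param family `"binomial"` (L1 logistic, default) or `"gaussian"`
#'   (lasso regression on the 0/1 labels).
#' @param seed Integer seed; resample `b` uses seed `seed + b`.
#' @return List of class `stability_params`.
#' @export
stability_params <- function(sample_fraction = 0.75, n_resamples = 1000L,
                             weakness = 0.5, lambda_grid = NULL,
                             n_lambda = 25L, lambda_min_ratio = 1e-3,
                             tol = 0.01,
                             family = c("binomial", "gaussian"),
                             seed = 1L) {
  family <- match.arg(family)
  if (sample_fraction <= 0 || sample_fraction >= 1)
    stop("sample_fraction must be in (0, 1)")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  if (weakness <= 0 || weakness > 1) stop("weakness must be in (0, 1]")
  structure(list(sample_fraction = sample_fraction,
                 n_resamples = as.integer(n_resamples), weakness = weakness,
                 lambda_grid = lambda_grid, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, tol = tol,
                 family = family, seed = as.integer(seed)),
            class = "stability_params")
}

#' Randomized L1-penalized fit
#'
#' One randomized-lasso fit: an L1-penalized logistic (or linear) model in
#' which feature `j`'s penalty is `lambda / w_j` with `w_j` drawn
#' independently from `U[weakness, 1]` (supply `weights` to fix the draw).
#' With `weakness = 1` this reduces to the plain L1-penalized fit.
#'
#' @param X Numeric matrix with at least two columns, typically z-scored.
#' @param y Two-level factor or 0/1 vector.
#' @param lambda Penalty value(s); a decreasing grid is fitted in one
#'   solver path.
#' @param weakness Randomization strength in (0, 1].
#' @param weights Optional fixed randomization weights in `[weakness, 1]`
#'   (length = ncol(X)).
#' @param tol Solver convergence tolerance.
#' @param family `"binomial"` or `"gaussian"`.
#' @return List with `selected` (0-based indices of features active at any
#'   `lambda`), `active` (p x n_lambda logical matrix) and `weights`.
#' @export
randomized_l1_fit <- function(X, y, lambda, weakness = 0.5, weights = NULL,
                              tol = 0.01, family = "binomial") {
  p <- ncol(X)
  if (is.null(weights)) weights <- stats::runif(p, weakness, 1)
  if (length(weights) != p) stop("weights must have one entry per feature")
  yv <- if (family == "binomial") factor(y)
        else if (is.factor(y)) as.numeric(y) - 1 else as.numeric(y)
  lambda <- sort(lambda, decreasing = TRUE)
  fit <- glmnet::glmnet(x = X, y = yv, family = family, lambda = lambda,
                        penalty.factor = 1 / weights, standardize = FALSE,
                        thresh = tol, maxit = 1e5)
  beta <- as.matrix(fit$beta)
  # glmnet may return fewer path points than requested on degenerate fits
  active <- matrix(FALSE, nrow = p, ncol = length(lambda))
  active[, seq_len(ncol(beta))] <- beta != 0
  list(selected = which(rowSums(active) > 0) - 1L, active = active,
       weights = weights)
}

#' Stability scores by resampled randomized-lasso selection
#'
#' The selection-frequency scores at the heart of stability selection.
#' For each of `n_resamples` resamples, `floor(sample_fraction * n)` rows
#' are drawn without replacement, a randomized L1-penalized model is
#' fitted across the whole penalty grid, and a feature counts as selected
#' if it is active at any grid point. The score of a feature is its
#' selection frequency across resamples, a number in [0, 1] (0 =
#' irrelevant, 1 = always selected).
#'
#' Reproducibility contract: resample `b` seeds the RNG with
#' `params$seed + b`, then draws the row subset (`sample.int`) followed by
#' the randomization weights (`runif`). Solver failures skip the resample
#' with a warning and shrink the denominator.
#'
#' @param X Numeric matrix, typically z-scored training data.
#' @param y Two-level factor or 0/1 vector.
#' @param params A [stability_params()].
#' @return Numeric vector of length `ncol(X)` with attributes
#'   `lambda_grid`, `n_ok` (resamples that converged) and
#'   `per_resample_n_selected`.
#' @export
stability_scores <- function(X, y, params = stability_params()) {
  n <- nrow(X); p <- ncol(X)
  m <- floor(params$sample_fraction * n)
  if (m < 2) stop("too few rows for the requested sample_fraction")
  grid <- params$lambda_grid %||%
    lambda_path(lambda_max(X, y), params$n_lambda, params$lambda_min_ratio)
  counts <- numeric(p); n_ok <- 0L
  n_sel <- integer(params$n_resamples)
  with_seed(params$seed, {
    for (b in seq_len(params$n_resamples)) {
      set.seed(params$seed + b)
      idx <- sample.int(n, m)
      w <- stats::runif(p, params$weakness, 1)
      res <- tryCatch(
        randomized_l1_fit(X[idx, , drop = FALSE], y[idx], grid,
                          weights = w, tol = params$tol,
                          family = params$family),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning("resample ", b, " skipped: ", conditionMessage(res))
        n_sel[b] <- NA_integer_
        next
      }
      counts[res$selected + 1L] <- counts[res$selected + 1L] + 1
      n_sel[b] <- length(res$selected)
      n_ok <- n_ok + 1L
    }
  })
  if (n_ok == 0L) stop("no resample converged")
  scores <- counts / n_ok
  attr(scores, "lambda_grid") <- grid
  attr(scores, "n_ok") <- n_ok
  attr(scores, "per_resample_n_selected") <- n_sel
  scores
}

#' Default stability-threshold sweep grid
#'
#' Thresholds 0.05..0.95 in steps of 0.05; the grid always contains the
#' 0.1, 0.5 and 0.7 operating points used in reported summaries.
#'
#' @return Numeric vector of thresholds in (0, 1).
#' @export
default_thresholds <- function() {
  sort(unique(c(seq(0.05, 0.95, by = 0.05), 0.1, 0.5, 0.7)))
}

#' Threshold sweep with coupled SVM evaluation
#'
#' For each stability threshold, keeps the features scoring at or above
#' it, retrains the grid-searched RBF SVM on the training partition
#' restricted to those features, and evaluates on the held-out test set
#' (same split/CV policy as [decode_windows()]). Thresholds selecting no
#' features yield a row with missing metrics.
#'
#' @param scores Stability scores (one per feature of `fm`).
#' @param fm A raw `feature_matrix`.
#' @param thresholds Thresholds in (0, 1).
#' @param grid,folds,train_fraction,split_unit,seed SVM evaluation policy;
#'   the split seed must match the one the scores were computed under to
#'   keep the test set untouched.
#' @return Data frame with columns threshold, n_selected_features,
#'   n_unique_rois, accuracy, auc, f1. The row maximizing accuracy (ties:
#'   AUC, then F1, then larger threshold = sparser model) is flagged in
#'   the `optimal` column.
#' @export
threshold_sweep <- function(scores, fm, thresholds = default_thresholds(),
                            grid = grid_spec(), folds = 5,
                            train_fraction = 0.8,
                            split_unit = c("pseudo_trial", "subject"),
                            seed = 1L) {
  split_unit <- match.arg(split_unit)
  # threshold 0 is allowed: it selects every feature and reproduces the
  # all-feature SVM evaluation
  if (any(thresholds < 0 | thresholds >= 1))
    stop("thresholds must be in [0, 1)")
  sp <- split_data(fm, train_fraction, split_unit, seed = seed)
  nz <- zscore_fit_apply(sp$train, list(sp$test))
  train <- nz$train; test <- nz$others[[1]]
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    t_i <- thresholds[i]
    cols <- which(scores >= t_i)
    n_roi <- length(unique(fm$meta$roi_index[cols]))
    if (!length(cols)) {
      rows[[i]] <- data.frame(threshold = t_i, n_selected_features = 0L,
                              n_unique_rois = 0L, accuracy = NA_real_,
                              auc = NA_real_, f1 = NA_real_)
      next
    }
    gs <- grid_search_svm(train$X[, cols, drop = FALSE], train$y, grid,
                          folds, seed = seed + 1L)
    pr <- svm_fit_predict(train$X[, cols, drop = FALSE], train$y,
                          test$X[, cols, drop = FALSE], gs$C, gs$gamma)
    m <- classification_metrics(test$y, pr$pred, pr$decision)
    rows[[i]] <- data.frame(threshold = t_i,
                            n_selected_features = length(cols),
                            n_unique_rois = n_roi, accuracy = m$accuracy,
                            auc = m$auc, f1 = m$f1)
  }
  sweep_tab <- do.call(rbind, rows)
  ok <- which(!is.na(sweep_tab$accuracy))
  optimal <- rep(FALSE, nrow(sweep_tab))
  if (length(ok)) {
    o <- ok[order(-sweep_tab$accuracy[ok], -sweep_tab$auc[ok],
                  -sweep_tab$f1[ok], -sweep_tab$threshold[ok])][1]
    optimal[o] <- TRUE
  }
  sweep_tab$optimal <- optimal
  sweep_tab
}

#' Ranked ROI network at a stability threshold
#'
#' Aggregates feature-level stability scores to regions (per-ROI score =
#' maximum over that region's time-window features) and returns the
#' regions reaching the threshold, ranked by score (ties broken by ROI
#' index), with hemisphere and lobe labels for lateralization and lobe
#' summaries.
#'
#' @param scores Stability scores (one per row of `meta`).
#' @param meta Feature metadata (from a `feature_matrix`).
#' @param atlas An atlas table from [make_atlas()].
#' @param threshold Stability threshold in (0, 1).
#' @return Data frame: rank, roi_index, name, abbrev, hemisphere, lobe,
#'   stability_score, n_features_selected.
#' @export
select_regions <- function(scores, meta, atlas = make_atlas(),
                           threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  rois <- sort(unique(meta$roi_index))
  roi_score <- vapply(rois, function(r)
    max(scores[meta$roi_index == r]), 0)
  n_feat <- vapply(rois, function(r)
    sum(scores[meta$roi_index == r] >= threshold), 0L)
  keep <- roi_score >= threshold
  ord <- order(-roi_score[keep], rois[keep])
  sel <- rois[keep][ord]
  m <- match(sel, atlas$roi_index)
  data.frame(rank = seq_along(sel), roi_index = sel,
             name = atlas$name[m], abbrev = atlas$abbrev[m],
             hemisphere = atlas$hemisphere[m], lobe = atlas$lobe[m],
             stability_score = roi_score[keep][ord],
             n_features_selected = n_feat[keep][ord],
             stringsAsFactors = FALSE)
}

#' Stability selection of discriminative brain regions
#'
#' The package's region-selection estimator. Fits stability scores on the
#' training partition (randomized L1-penalized logistic regression over
#' resamples and a data-driven penalty path), sweeps stability thresholds
#' with a coupled SVM evaluated on the held-out test set, and extracts the
#' ranked ROI network at `report_threshold`.
#'
#' @param fm A raw `feature_matrix`.
#' @param params A [stability_params()].
#' @param thresholds Sweep grid (default [default_thresholds()]).
#' @param report_threshold Threshold of the reported ROI network (default
#'   0.5, the interpretable operating point; the sweep's `optimal` flag
#'   marks the accuracy-maximizing threshold).
#' @param grid,folds,train_fraction,split_unit SVM policy shared with
#'   [decode_windows()].
#' @param scores_on `"train"` (default, leakage-safe) or `"all"` (strict
#'   replication mode: scores computed on all rows).
#' @param atlas Atlas for region labels.
#' @return Object of class `stability_report`: `scores`, `params`,
#'   `sweep`, `optimal_threshold`, `chosen` (threshold, selected 0-based
#'   feature indices, ranked `regions` table).
#' @export
stability_selection <- function(fm, params = stability_params(),
                                thresholds = default_thresholds(),
                                report_threshold = 0.5,
                                grid = grid_spec(), folds = 5,
                                train_fraction = 0.8,
                                split_unit = c("pseudo_trial", "subject"),
                                scores_on = c("train", "all"),
                                atlas = NULL) {
  split_unit <- match.arg(split_unit)
  scores_on <- match.arg(scores_on)
  if (is.null(atlas) && all(fm$meta$roi_index %in% 0:67) &&
        length(unique(fm$meta$roi_index)) == 68)
    atlas <- make_atlas()
  sp <- split_data(fm, train_fraction, split_unit, seed = params$seed)
  if (scores_on == "train") {
    train <- zscore_fit_apply(sp$train)
    scores <- stability_scores(train$X, train$y, params)
  } else {
    all_z <- zscore_fit_apply(fm)
    scores <- stability_scores(all_z$X, all_z$y, params)
  }
  sweep_tab <- threshold_sweep(scores, fm, thresholds, grid = grid,
                               folds = folds,
                               train_fraction = train_fraction,
                               split_unit = split_unit, seed = params$seed)
  opt <- sweep_tab$threshold[sweep_tab$optimal][1]
  regions <- if (!is.null(atlas))
    select_regions(scores, fm$meta, atlas, report_threshold) else NULL
  structure(list(scores = scores, params = params, sweep = sweep_tab,
                 optimal_threshold = opt,
                 chosen = list(threshold = report_threshold,
                               features = which(scores >=
                                                  report_threshold) - 1L,
                               regions = regions),
                 condition = fm$condition),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability selection (%s condition): %d features, %d resamples (%d ok)\n",
              x$condition %||% "?", length(x$scores),
              x$params$n_resamples, attr(x$scores, "n_ok")))
  cat(sprintf("  score range [%.2f, %.2f]; %.0f%% of features score < 0.1\n",
              min(x$scores), max(x$scores), 100 * mean(x$scores < 0.1)))
  opt_row <- x$sweep[x$sweep$optimal, , drop = FALSE]
  if (nrow(opt_row))
    cat(sprintf("  optimal threshold %.2f: %d features / %d ROIs, accuracy %.1f%%\n",
                opt_row$threshold, opt_row$n_selected_features,
                opt_row$n_unique_rois, 100 * opt_row$accuracy))
  if (!is.null(x$chosen$regions)) {
    cat(sprintf("  network at threshold %.2f: %d ROIs\n",
                x$chosen$threshold, nrow(x$chosen$regions)))
    print(utils::head(x$chosen$regions, 12), row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.stability_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$scores, breaks = seq(0, 1, by = 0.1),
                 main = "Stability scores", xlab = "Score",
                 col = "grey80")
  ok <- !is.na(x$sweep$accuracy)
  plot(x$sweep$threshold[ok], 100 * x$sweep$accuracy[ok], type = "b",
       pch = 16, xlab = "Stability threshold",
       ylab = "Held-out accuracy (%)", main = "Threshold sweep")
  graphics::lines(x$sweep$threshold[ok], 100 * x$sweep$auc[ok], lty = 2)
  graphics::abline(v = x$chosen$threshold, lty = 3)
  invisible(x)
}
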