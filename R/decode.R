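#' SVM hyperparameter grid
#'
#' Log-spaced grid for the RBF support vector machine: cost `C` spanning
#' 1e-2..1e2 and kernel width `gamma` spanning 7e-4..1e-2 by default.
#'
#' @param C_values Positive costs.
#' @param gamma_values Positive RBF widths.
#' @return List of class `grid_spec` with a `combos` data frame ordered by
#'   increasing `C` then `gamma` (the tie-breaking order: simpler models
#'   first).
#' @export
grid_spec <- function(C_values = 10^seq(-2, 2, by = 1),
                      gamma_values = exp(seq(log(7e-4), log(1e-2),
                                             length.out = 7))) {
  if (!length(C_values) || !length(gamma_values) ||
        any(C_values <= 0) || any(gamma_values <= 0))
    stop("grid values must be positive and non-empty")
  combos <- expand.grid(gamma = sort(gamma_values), C = sort(C_values),
                        KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  combos <- combos[order(combos$C, combos$gamma), ]
  rownames(combos) <- NULL
  structure(list(C_values = sort(C_values),
                 gamma_values = sort(gamma_values),
                 kernel = "RBF", combos = combos),
            class = "grid_spec")
}

#' Classification metrics
#'
#' Accuracy, F1 and AUC from predictions and continuous decision values.
#' F1 defaults to the binary score for the positive (HI) class; AUC is the
#' rank statistic (probability that a positive outranks a negative) of the
#' decision values, so constant decision values give exactly 0.5.
#'
#' @param y_true,y_pred Factors or vectors with the same two levels.
#' @param decision_values Numeric scores, larger = more positive-class.
#' @param positive Positive class label (default `"HI"`).
#' @param f1 `"binary"` (positive class) or `"weighted"`
#'   (support-weighted mean of per-class F1).
#' @return Named list `(accuracy, auc, f1)`.
#' @examples
#' classification_metrics(c("NH","NH","HI","HI"), c("NH","HI","HI","HI"),
#'                        c(-2, 1, 2, 3))
#' @export
classification_metrics <- function(y_true, y_pred, decision_values,
                                   positive = "HI",
                                   f1 = c("binary", "weighted")) {
  f1 <- match.arg(f1)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(unique(y_true)) < 2)
    stop("y_true contains a single class; AUC undefined")
  acc <- mean(y_true == y_pred)
  pos <- y_true == positive
  r <- rank(decision_values)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  f1_one <- function(cls) {
    tp <- sum(y_pred == cls & y_true == cls)
    fp <- sum(y_pred == cls & y_true != cls)
    fn <- sum(y_pred != cls & y_true == cls)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  f1v <- if (f1 == "binary") f1_one(positive) else {
    cls <- unique(y_true)
    sum(vapply(cls, function(cl) f1_one(cl) * mean(y_true == cl), 0))
  }
  list(accuracy = acc, auc = auc, f1 = f1v)
}

#' Stratified train/test split
#'
#' Random split stratified by class. With `unit = "subject"` whole
#' subjects are assigned to one side only (leakage-safe evaluation); with
#' the default `unit = "pseudo_trial"` individual pseudo-trials are split.
#'
#' @param fm A `feature_matrix`.
#' @param train_fraction Fraction of rows (or subjects per group) in the
#'   training set, in (0, 1).
#' @param unit `"pseudo_trial"` or `"subject"`.
#' @param seed Integer seed.
#' @return List `(train, test)` of `feature_matrix` objects plus the row
#'   indices used (`train_rows`, `test_rows`).
#' @export
split_data <- function(fm, train_fraction = 0.8,
                       unit = c("pseudo_trial", "subject"), seed = NULL) {
  unit <- match.arg(unit)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  with_seed(seed, {
    train_rows <- integer()
    if (unit == "pseudo_trial") {
      for (cl in levels(fm$y)) {
        idx <- which(fm$y == cl)
        n_tr <- max(1L, min(length(idx) - 1L,
                            round(train_fraction * length(idx))))
        train_rows <- c(train_rows, sample(idx, n_tr))
      }
    } else {
      for (cl in levels(fm$y)) {
        subj <- unique(fm$subject_of[fm$y == cl])
        n_tr <- max(1L, min(length(subj) - 1L,
                            round(train_fraction * length(subj))))
        keep <- sample(subj, n_tr)
        train_rows <- c(train_rows, which(fm$subject_of %in% keep))
      }
    }
    train_rows <- sort(train_rows)
    test_rows <- setdiff(seq_along(fm$y), train_rows)
    train <- fm_subset(fm, train_rows)
    test <- fm_subset(fm, test_rows)
    if (nlevels(droplevels(train$y)) < 2 || nlevels(droplevels(test$y)) < 2)
      stop("a class is absent from one partition")
    list(train = train, test = test,
         train_rows = train_rows, test_rows = test_rows)
  })
}

# Fit an RBF SVM and score a test matrix; decision values oriented so
# larger = more `positive`.
svm_fit_predict <- function(Xtr, ytr, Xte, C, gamma, positive = "HI") {
  fit <- e1071::svm(x = Xtr, y = droplevels(ytr), kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  pr <- stats::predict(fit, Xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # column name "A/B": positive values vote for class A
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  dv <- if (first == positive) dv[, 1] else -dv[, 1]
  list(pred = as.character(pr), decision = as.numeric(dv))
}

#' Grid search for RBF SVM hyperparameters
#'
#' Stratified k-fold cross-validation over the `(C, gamma)` grid on the
#' training set; returns the pair maximizing mean CV accuracy, ties broken
#' toward smaller `C` then smaller `gamma` (the simpler model).
#'
#' @param X Numeric training matrix.
#' @param y Two-level factor of labels.
#' @param grid A [grid_spec()].
#' @param folds Number of CV folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return List `(C, gamma, cv_accuracy, cv_table)`.
#' @export
grid_search_svm <- function(X, y, grid = grid_spec(), folds = 5,
                            seed = NULL) {
  if (folds < 2) stop("folds must be >= 2")
  if (nrow(X) < folds) stop("fewer rows than folds")
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("training set contains a single class")
  combos <- grid$combos
  if (nrow(combos) == 1L) {
    return(list(C = combos$C[1], gamma = combos$gamma[1],
                cv_accuracy = NA_real_, cv_table = combos))
  }
  with_seed(seed, {
    fold_id <- stratified_folds(y, folds)
    acc <- numeric(nrow(combos))
    for (i in seq_len(nrow(combos))) {
      fold_acc <- numeric(folds)
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        if (nlevels(droplevels(y[tr])) < 2) { fold_acc[f] <- NA; next }
        fit <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr],
                          kernel = "radial", cost = combos$C[i],
                          gamma = combos$gamma[i], scale = FALSE)
        pred <- stats::predict(fit, X[!tr, , drop = FALSE])
        fold_acc[f] <- mean(as.character(pred) == as.character(y[!tr]))
      }
      acc[i] <- mean(fold_acc, na.rm = TRUE)
    }
    best <- which.max(acc)  # combos pre-ordered: first max = simplest
    cv_table <- cbind(combos, cv_accuracy = acc)
    list(C = combos$C[best], gamma = combos$gamma[best],
         cv_accuracy = acc[best], cv_table = cv_table)
  })
}

# Resolve a scope argument to a set of 0-based ROI indices.
resolve_scope <- function(scope, meta) {
  rois <- sort(unique(meta$roi_index))
  if (is.numeric(scope)) return(list(name = "custom", rois = as.integer(scope)))
  scope <- match.arg(scope, c("whole", "LH", "RH"))
  if (scope == "whole") return(list(name = "whole", rois = rois))
  hemi <- if (scope == "LH") "L" else "R"
  sel <- unique(meta$roi_index[!is.na(meta$hemisphere) &
                                 meta$hemisphere == hemi])
  if (!length(sel)) stop("no ROIs with hemisphere ", hemi, " in metadata")
  list(name = scope, rois = sort(sel))
}

#' Sliding-window SVM decoding of group membership
#'
#' The package's time-resolved decoder. The feature matrix is split once
#' into stratified train/test sets, z-scored with parameters fitted on the
#' training set, and then one RBF SVM is trained per time window on that
#' window's ROI features (all 68 ROIs for `scope = "whole"`, 34 for a
#' single hemisphere). Per window the held-out accuracy, AUC and F1 are
#' recorded; the peak window defines the decoder's best accuracy and its
#' latency (reported as the window start time).
#'
#' @param fm A `feature_matrix` (raw; normalization is handled internally).
#' @param scope `"whole"`, `"LH"`, `"RH"`, or an integer vector of 0-based
#'   ROI indices.
#' @param grid A [grid_spec()] searched per window (default) or once
#'   globally.
#' @param folds CV folds for the grid search.
#' @param train_fraction,split_unit Passed to [split_data()].
#' @param per_window_grid If `FALSE`, `(C, gamma)` is searched once on the
#'   full-epoch scope features and reused for every window.
#' @param seed Integer seed controlling split and fold assignment.
#' @return An object of class `decoding_result` with `per_window` (data
#'   frame: window_start_ms, accuracy, auc, f1, C, gamma), `best`
#'   (accuracy, auc, f1, latency_ms, C, gamma), `scope`, `condition`,
#'   `split`, `seed`.
#' @export
decode_windows <- function(fm, scope = "whole", grid = grid_spec(),
                           folds = 5, train_fraction = 0.8,
                           split_unit = c("pseudo_trial", "subject"),
                           per_window_grid = TRUE, seed = 1L) {
  split_unit <- match.arg(split_unit)
  sc <- resolve_scope(scope, fm$meta)
  roi_ok <- fm$meta$roi_index %in% sc$rois
  if (!any(roi_ok)) stop("scope selects no features")
  sp <- split_data(fm, train_fraction, split_unit, seed = seed)
  nz <- zscore_fit_apply(sp$train, list(sp$test))
  train <- nz$train; test <- nz$others[[1]]

  win <- sort(unique(fm$meta$window_index))
  global <- NULL
  if (!per_window_grid) {
    cols <- which(roi_ok)
    global <- grid_search_svm(train$X[, cols, drop = FALSE], train$y,
                              grid, folds, seed = seed + 1L)
  }
  rows <- vector("list", length(win))
  for (k in seq_along(win)) {
    cols <- which(roi_ok & fm$meta$window_index == win[k])
    if (!length(cols)) stop("empty feature set for window ", win[k])
    gs <- global %||% grid_search_svm(train$X[, cols, drop = FALSE],
                                      train$y, grid, folds,
                                      seed = seed + 1L)
    pr <- svm_fit_predict(train$X[, cols, drop = FALSE], train$y,
                          test$X[, cols, drop = FALSE], gs$C, gs$gamma)
    m <- classification_metrics(test$y, pr$pred, pr$decision)
    rows[[k]] <- data.frame(
      window_index = win[k],
      window_start_ms = fm$meta$window_start_ms[cols[1]],
      accuracy = m$accuracy, auc = m$auc, f1 = m$f1,
      C = gs$C, gamma = gs$gamma)
  }
  per_window <- do.call(rbind, rows)
  b <- which.max(per_window$accuracy)  # earliest window wins ties
  res <- structure(list(
    scope = sc$name, condition = fm$condition, per_window = per_window,
    best = list(accuracy = per_window$accuracy[b], auc = per_window$auc[b],
                f1 = per_window$f1[b],
                latency_ms = per_window$window_start_ms[b],
                C = per_window$C[b], gamma = per_window$gamma[b]),
    split = list(train_fraction = train_fraction, cv_folds = folds,
                 split_unit = split_unit,
                 n_train = nrow(train$X), n_test = nrow(test$X)),
    seed = seed), class = "decoding_result")
  res
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Sliding-window decoding (%s features, %s condition)\n",
              x$scope, x$condition))
  cat(sprintf("  peak accuracy %.1f%% (AUC %.1f%%, F1 %.1f%%) at %g ms (C=%g, gamma=%g)\n",
              100 * x$best$accuracy, 100 * x$best$auc, 100 * x$best$f1,
              x$best$latency_ms, x$best$C, x$best$gamma))
  cat(sprintf("  split: %d train / %d test (%s unit), %d-fold CV grid search\n",
              x$split$n_train, x$split$n_test, x$split$split_unit,
              x$split$cv_folds))
  invisible(x)
}

#' @export
summary.decoding_result <- function(object, ...) {
  print(object)
  cat("\nPer-window held-out performance:\n")
  pw <- object$per_window
  pw[, c("accuracy", "auc", "f1")] <-
    round(100 * pw[, c("accuracy", "auc", "f1")], 1)
  print(pw, row.names = FALSE)
  invisible(object)
}

#' @export
plot.decoding_result <- function(x, ...) {
  pw <- x$per_window
  plot(pw$window_start_ms, 100 * pw$accuracy, type = "b", pch = 16,
       xlab = "Window start (ms)", ylab = "Held-out accuracy (%)",
       main = sprintf("Group decoding over time (%s, %s)",
                      x$scope, x$condition), ...)
  graphics::abline(h = 50, lty = 3)
  graphics::points(x$best$latency_ms, 100 * x$best$accuracy, col = 2,
                   pch = 8, cex = 1.5)
  invisible(x)
}
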