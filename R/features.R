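#' Pseudo-trials by random trial averaging without replacement
#'
#' Draws random subsets of single trials and averages each subset into one
#' pseudo-trial ERP, the standard device for trading trial count against
#' SNR before decoding. By default the subsets are mutually disjoint (a
#' trial contributes to at most one pseudo-trial); with
#' `overlapping = TRUE` draws are without replacement only within each
#' pseudo-trial.
#'
#' @param epochs A `source_epochs` block.
#' @param n_per_average Trials averaged into each pseudo-trial.
#' @param n_averages Number of pseudo-trials to form.
#' @param seed Integer seed; draws are reproducible.
#' @param overlapping If `FALSE` (default) the index sets are disjoint.
#' @return Array (pseudo_trial x roi x sample) with attribute
#'   `"trial_sets"`, the list of drawn trial index sets.
#' @examples
#' cfg <- simulation_config(n_nh = 1, n_hi = 1, n_trials = 12, n_rois = 4,
#'                          discriminative_rois = integer(), seed = 3)
#' ep <- simulate_cohort(cfg, conditions = "clear")[[1]]
#' pt <- subsample_average(ep, n_per_average = 4, n_averages = 3, seed = 5)
#' dim(pt)   # 3 x 4 x 105
#' @export
subsample_average <- function(epochs, n_per_average, n_averages,
                              seed = NULL, overlapping = FALSE) {
  n_trials <- dim(epochs$data)[1]
  if (n_per_average < 1) stop("n_per_average must be >= 1")
  if (!overlapping && n_per_average * n_averages > n_trials)
    stop("insufficient trials for ", n_averages, " disjoint averages of ",
         n_per_average, " (have ", n_trials, ")")
  if (overlapping && n_per_average > n_trials)
    stop("n_per_average exceeds available trials")
  with_seed(seed, {
    if (overlapping) {
      sets <- lapply(seq_len(n_averages),
                     function(i) sort(sample.int(n_trials, n_per_average)))
    } else {
      perm <- sample.int(n_trials)
      sets <- lapply(seq_len(n_averages), function(i)
        sort(perm[((i - 1) * n_per_average + 1):(i * n_per_average)]))
    }
    out <- array(0, dim = c(n_averages, dim(epochs$data)[2],
                            dim(epochs$data)[3]))
    for (i in seq_len(n_averages)) {
      sub <- epochs$data[sets[[i]], , , drop = FALSE]
      out[i, , ] <- colMeans(sub, dims = 1)
    }
    attr(out, "trial_sets") <- sets
    out
  })
}

#' Baseline correction
#'
#' Subtracts, per pseudo-trial and ROI, the mean amplitude over the
#' prestimulus baseline window. Idempotent and invariant to constant
#' offsets.
#'
#' @param waves Array (pseudo_trial x roi x sample).
#' @param timebase_ms Sample times in ms (length = third dim of `waves`).
#' @param baseline_ms Length-2 window; samples with
#'   `baseline_ms[1] <= t < baseline_ms[2]` form the baseline.
#' @return Array of the same shape with zero-mean baseline.
#' @export
baseline_correct <- function(waves, timebase_ms, baseline_ms = c(-10, 0)) {
  sel <- timebase_ms >= baseline_ms[1] & timebase_ms < baseline_ms[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(waves[, , sel, drop = FALSE], c(1, 2), mean)
  sweep(waves, c(1, 2), base, `-`)
}

#' Non-overlapping time-window mean-amplitude features
#'
#' Tiles the analysis span with half-open windows `[start, start + w)` ms
#' and takes the mean amplitude per ROI and window. A 68-ROI epoch of
#' 210 ms with 10-ms windows yields 68 x 21 = 1428 features. Feature order
#' is row-major: `feature_index = roi * n_windows + window` (0-based).
#'
#' @param waves Array (pseudo_trial x roi x sample).
#' @param timebase_ms Sample times in ms.
#' @param window_ms Window length in ms (default 10).
#' @param span_ms Length-2 analysis span; defaults to the full timebase
#'   extent. Must be a whole number of windows (within one sample).
#' @param roi_indices 0-based atlas indices of the ROI axis (defaults to
#'   `0:(n_roi - 1)`), recorded in the feature metadata.
#' @param atlas Atlas table for hemisphere lookup; `NULL` leaves
#'   hemisphere `NA` (useful for toy ROI counts).
#' @return List with `X` (matrix pseudo_trial x feature) and `meta` (data
#'   frame: feature_index, roi_index, window_index, window_start_ms,
#'   window_end_ms, hemisphere, abbrev).
#' @examples
#' cfg <- simulation_config(n_nh = 1, n_hi = 1, n_trials = 8, n_rois = 68,
#'                          seed = 3)
#' ep <- simulate_cohort(cfg, conditions = "clear")[[1]]
#' pt <- subsample_average(ep, 8, 1, seed = 1)
#' wf <- window_features(pt, epochs_timebase(ep), atlas = make_atlas())
#' ncol(wf$X)   # 1428
#' @export
window_features <- function(waves, timebase_ms, window_ms = 10,
                            span_ms = NULL, roi_indices = NULL,
                            atlas = NULL) {
  n_roi <- dim(waves)[2]
  dt <- if (length(timebase_ms) > 1) diff(timebase_ms[1:2]) else window_ms
  if (is.null(span_ms))
    span_ms <- c(timebase_ms[1], timebase_ms[length(timebase_ms)] + dt)
  span <- diff(span_ms)
  if (window_ms > span + dt / 2) stop("window larger than analysis span")
  n_win <- round(span / window_ms)
  if (abs(n_win * window_ms - span) > dt / 2)
    stop("analysis span is not a whole number of windows")
  if (is.null(roi_indices)) roi_indices <- seq_len(n_roi) - 1L
  starts <- span_ms[1] + (seq_len(n_win) - 1) * window_ms
  X <- matrix(NA_real_, nrow = dim(waves)[1], ncol = n_roi * n_win)
  for (w in seq_len(n_win)) {
    sel <- timebase_ms >= starts[w] & timebase_ms < starts[w] + window_ms
    if (!any(sel)) stop("window ", w, " contains no samples")
    wm <- apply(waves[, , sel, drop = FALSE], c(1, 2), mean)
    # columns for window w across all ROIs (row-major feature order)
    X[, (seq_len(n_roi) - 1) * n_win + w] <- wm
  }
  hemi <- rep(NA_character_, n_roi); abbrev <- rep(NA_character_, n_roi)
  if (!is.null(atlas)) {
    m <- match(roi_indices, atlas$roi_index)
    hemi <- atlas$hemisphere[m]; abbrev <- atlas$abbrev[m]
  }
  meta <- data.frame(
    feature_index = seq_len(n_roi * n_win) - 1L,
    roi_index = rep(roi_indices, each = n_win),
    window_index = rep(seq_len(n_win) - 1L, times = n_roi),
    window_start_ms = rep(starts, times = n_roi),
    window_end_ms = rep(starts + window_ms, times = n_roi),
    hemisphere = rep(hemi, each = n_win),
    abbrev = rep(abbrev, each = n_win),
    stringsAsFactors = FALSE)
  list(X = X, meta = meta)
}

#' Build the decoding feature matrix for one condition
#'
#' Runs the full feature pipeline over a simulated (or imported) cohort:
#' per subject, draw disjoint pseudo-trial averages, baseline-correct, and
#' take windowed mean amplitudes; rows from all subjects are stacked with
#' group labels. Normalization is deliberately left to the decoding stage
#' so that scaling can be fitted on training data only.
#'
#' @param cohort List of `source_epochs` blocks.
#' @param condition Condition to extract (`"clear"` or `"noise"`).
#' @param n_per_average,n_averages Passed to [subsample_average()]; the
#'   per-subject seed is derived from `seed` and the subject position.
#' @param window_ms Window length in ms.
#' @param baseline_ms Baseline window in ms.
#' @param atlas Atlas for feature metadata (default [make_atlas()] when
#'   the blocks have 68 ROIs, else `NULL`).
#' @param seed Integer seed.
#' @param overlapping Passed to [subsample_average()].
#' @return A list of class `feature_matrix`: `X` (rows = pseudo-trials),
#'   `y` (factor NH/HI), `subject_of`, `condition`, `meta`, `normalized`,
#'   `norm_params`.
#' @export
build_feature_matrix <- function(cohort, condition = "clear",
                                 n_per_average = 100, n_averages = NULL,
                                 window_ms = 10, baseline_ms = c(-10, 0),
                                 atlas = NULL, seed = 1L,
                                 overlapping = FALSE) {
  blocks <- Filter(function(b) b$condition == condition, cohort)
  if (!length(blocks)) stop("no blocks for condition ", condition)
  n_roi <- dim(blocks[[1]]$data)[2]
  if (is.null(atlas) && n_roi == 68L) atlas <- make_atlas()
  Xs <- list(); ys <- character(); subj <- character()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    n_avg <- n_averages %||% (dim(b$data)[1] %/% n_per_average)
    pt <- subsample_average(b, n_per_average, n_avg,
                            seed = seed + 97L * i, overlapping = overlapping)
    tb <- epochs_timebase(b)
    pt <- baseline_correct(pt, tb, baseline_ms)
    wf <- window_features(pt, tb, window_ms = window_ms, atlas = atlas)
    Xs[[i]] <- wf$X
    ys <- c(ys, rep(b$group, n_avg))
    subj <- c(subj, rep(b$subject_id, n_avg))
    if (i == 1) meta <- wf$meta
  }
  structure(list(X = do.call(rbind, Xs),
                 y = factor(ys, levels = c("NH", "HI")),
                 subject_of = subj, condition = condition, meta = meta,
                 normalized = FALSE, norm_params = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix (%s): %d pseudo-trials x %d features (%s)\n",
              x$condition, nrow(x$X), ncol(x$X),
              if (x$normalized) "normalized" else "raw"))
  print(table(x$y))
  invisible(x)
}

#' Fit z-scoring on one feature matrix and apply to others
#'
#' Per-feature standardization `(x - mean) / sd` with parameters fitted on
#' `train` only, then applied unchanged to `train` and every matrix in
#' `others` — the fold-safe normalization policy used throughout decoding.
#' Zero-variance features get sd 1 (they carry no information) with a
#' warning.
#'
#' @param train A `feature_matrix` to fit scaling on.
#' @param others List of further `feature_matrix` objects to transform
#'   with the fitted parameters.
#' @return If `others` is empty, the normalized `train`; otherwise a list
#'   `(train, others)` of normalized matrices. Fitted parameters are
#'   stored in `$norm_params` (`mean`, `sd` per feature).
#' @export
zscore_fit_apply <- function(train, others = list()) {
  if (nrow(train$X) < 2) stop("need >= 2 rows to fit scaling")
  mu <- colMeans(train$X)
  sd_ <- apply(train$X, 2, stats::sd)
  zero <- !is.finite(sd_) | sd_ <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s); sd set to 1")
    sd_[zero] <- 1
  }
  apply_one <- function(fm) {
    fm$X <- sweep(sweep(fm$X, 2, mu, `-`), 2, sd_, `/`)
    fm$normalized <- TRUE
    fm$norm_params <- list(mean = mu, sd = sd_)
    fm
  }
  train <- apply_one(train)
  if (!length(others)) return(train)
  list(train = train, others = lapply(others, apply_one))
}

# Row subset of a feature_matrix, keeping metadata consistent.
fm_subset <- function(fm, rows) {
  fm$X <- fm$X[rows, , drop = FALSE]
  fm$y <- fm$y[rows]
  fm$subject_of <- fm$subject_of[rows]
  fm
}

#' Write / read a feature matrix as CSV
#'
#' Plain-text round-trip: `<stem>_X.csv` holds the data matrix with a
#' leading `group` and `subject` column; `<stem>_meta.csv` the per-feature
#' metadata.
#'
#' @param fm A `feature_matrix`.
#' @param stem Path stem (files `<stem>_X.csv`, `<stem>_meta.csv`).
#' @return `write_feature_matrix` returns `stem` invisibly;
#'   `read_feature_matrix` the reconstructed `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, stem) {
  df <- data.frame(group = as.character(fm$y), subject = fm$subject_of,
                   condition = fm$condition, fm$X, check.names = FALSE)
  utils::write.csv(df, paste0(stem, "_X.csv"), row.names = FALSE)
  utils::write.csv(fm$meta, paste0(stem, "_meta.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(stem) {
  df <- utils::read.csv(paste0(stem, "_X.csv"), check.names = FALSE)
  meta <- utils::read.csv(paste0(stem, "_meta.csv"), stringsAsFactors = FALSE)
  X <- as.matrix(df[, -(1:3), drop = FALSE])
  dimnames(X) <- NULL
  structure(list(X = X, y = factor(df$group, levels = c("NH", "HI")),
                 subject_of = df$subject, condition = df$condition[1],
                 meta = meta, normalized = FALSE, norm_params = NULL),
            class = "feature_matrix")
}
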