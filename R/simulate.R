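#' ERP component specification
#'
#' One deflection of the evoked waveform template. Amplitude signs follow
#' the usual polarity convention: P1 and P2 are non-negative, N1
#' non-positive. `width_ms` is the Gaussian standard deviation of the
#' deflection.
#'
#' @param label One of `"P1"`, `"N1"`, `"P2"`.
#' @param latency_ms Peak latency in ms post-stimulus.
#' @param width_ms Gaussian SD of the deflection in ms; must be positive.
#' @param amplitude Signed peak amplitude in arbitrary source units.
#' @return A list of class `erp_component`.
#' @export
erp_component <- function(label = c("P1", "N1", "P2"), latency_ms, width_ms,
                          amplitude) {
  label <- match.arg(label)
  if (!is.finite(width_ms) || width_ms <= 0)
    stop("width_ms must be positive")
  if (label %in% c("P1", "P2") && amplitude < 0)
    stop(label, " amplitude must be >= 0")
  if (label == "N1" && amplitude > 0)
    stop("N1 amplitude must be <= 0")
  structure(list(label = label, latency_ms = latency_ms,
                 width_ms = width_ms, amplitude = amplitude),
            class = "erp_component")
}

# Canonical P1-N1-P2 morphology used as the simulator default.  Peak
# latencies/amplitudes are free template parameters of the generator (not
# estimates from any dataset); see the methods vignette for the rationale.
default_components <- function() {
  list(erp_component("P1", latency_ms = 60, width_ms = 20, amplitude = 1.0),
       erp_component("N1", latency_ms = 100, width_ms = 30, amplitude = -1.5),
       erp_component("P2", latency_ms = 170, width_ms = 40, amplitude = 1.2))
}

#' Evaluate an evoked-response kernel on a timebase
#'
#' Sums Gaussian-windowed deflections, one per component. With an empty
#' component list the kernel is identically zero.
#'
#' @param components List of [erp_component()] objects.
#' @param timebase_ms Numeric vector of sample times in ms.
#' @return Numeric vector, one value per sample.
#' @examples
#' tb <- seq(-10, 198, by = 2)
#' k <- erp_kernel(default_components(), tb)
#' tb[which.max(k)]   # near the P1 latency
#' @export
erp_kernel <- function(components, timebase_ms) {
  out <- numeric(length(timebase_ms))
  for (comp in components) {
    if (comp$width_ms <= 0) stop("width_ms must be positive")
    out <- out + comp$amplitude *
      exp(-0.5 * ((timebase_ms - comp$latency_ms) / comp$width_ms)^2)
  }
  out
}

#' Synthetic cohort configuration
#'
#' Parameters of the source-level ERP cohort generator. Defaults follow the
#' study design the package targets: 13 normal-hearing (NH) and 19
#' hearing-impaired (HI) listeners, ~6000 single trials per subject and
#' condition, 68 atlas ROIs, epochs from -10 to 200 ms at 500 Hz with a
#' -10..0 ms prestimulus baseline. The HI group carries a multiplicative
#' amplitude effect (default 1.5 on the P1 component) inside
#' `discriminative_rois`; the noise-degraded condition scales all component
#' amplitudes by `amplitude_scale` and delays them by `latency_shift_ms`.
#'
#' @param n_nh,n_hi Subjects per group.
#' @param n_trials Single trials per subject per condition.
#' @param n_rois Number of ROIs (68 matches the shipped atlas).
#' @param sampling_rate_hz Sampling rate; 500 Hz makes a 10-ms analysis
#'   window exactly 5 samples.
#' @param epoch_ms Length-2 epoch limits in ms (start < 0 < end).
#' @param baseline_ms Length-2 prestimulus baseline limits in ms.
#' @param components List of [erp_component()] shared by both groups.
#' @param discriminative_rois 0-based ROI indices carrying the group
#'   effect; default the 12-region stable clear-speech network
#'   ([default_discriminative_rois()]).
#' @param group_effect Multiplier applied to `effect_components` amplitudes
#'   for HI subjects inside `discriminative_rois`; 1 means no group
#'   difference.
#' @param effect_components Labels of components carrying the group effect.
#' @param amplitude_scale,latency_shift_ms Noise-condition degradation:
#'   amplitudes scaled by `amplitude_scale` (in (0, 1]) and latencies
#'   delayed by `latency_shift_ms` (>= 0).
#' @param white_sd Per-sample white noise SD.
#' @param pink_sd SD of the 1/f^beta background.
#' @param pink_exponent Spectral exponent beta of the background (1 = pink).
#' @param trial_jitter_ms_sd SD of the per-trial latency jitter.
#' @param subject_amp_sd SD of the per-subject multiplicative amplitude
#'   factor (mean 1), modelling between-subject gain variability.
#' @param roi_gain_sd SD of the per-subject, per-ROI multiplicative gain
#'   (mean 1, fixed across conditions), modelling regional expression
#'   variability: different subjects express the evoked response (and any
#'   group effect) more strongly in different regions, so discriminative
#'   regions carry partially independent signal rather than identical
#'   copies.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_nh = 13L, n_hi = 19L, n_trials = 6000L,
                              n_rois = 68L, sampling_rate_hz = 500,
                              epoch_ms = c(-10, 200),
                              baseline_ms = c(-10, 0),
                              components = default_components(),
                              discriminative_rois = default_discriminative_rois(),
                              group_effect = 1.5,
                              effect_components = "P1",
                              amplitude_scale = 0.7,
                              latency_shift_ms = 20,
                              white_sd = 1.5, pink_sd = 1.0,
                              pink_exponent = 1,
                              trial_jitter_ms_sd = 5,
                              subject_amp_sd = 0.1,
                              roi_gain_sd = 0.2,
                              seed = 1L) {
  if (!(epoch_ms[1] < baseline_ms[2] && baseline_ms[2] <= 0 &&
          0 < epoch_ms[2]))
    stop("need epoch start < baseline end <= 0 < epoch end")
  if (length(discriminative_rois) &&
        (min(discriminative_rois) < 0 || max(discriminative_rois) >= n_rois))
    stop("discriminative_rois must lie in 0..n_rois-1")
  if (amplitude_scale <= 0 || amplitude_scale > 1)
    stop("amplitude_scale must be in (0, 1]")
  if (latency_shift_ms < 0) stop("latency_shift_ms must be >= 0")
  if (n_trials < 1 || n_nh < 1 || n_hi < 1) stop("counts must be positive")
  structure(list(n_nh = as.integer(n_nh), n_hi = as.integer(n_hi),
                 n_trials = as.integer(n_trials), n_rois = as.integer(n_rois),
                 sampling_rate_hz = sampling_rate_hz, epoch_ms = epoch_ms,
                 baseline_ms = baseline_ms, components = components,
                 discriminative_rois = as.integer(discriminative_rois),
                 group_effect = group_effect,
                 effect_components = effect_components,
                 amplitude_scale = amplitude_scale,
                 latency_shift_ms = latency_shift_ms,
                 white_sd = white_sd, pink_sd = pink_sd,
                 pink_exponent = pink_exponent,
                 trial_jitter_ms_sd = trial_jitter_ms_sd,
                 subject_amp_sd = subject_amp_sd,
                 roi_gain_sd = roi_gain_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Sample times in ms for a config: epoch start inclusive, end exclusive,
# so 500 Hz over -10..200 ms gives exactly 105 samples (21 x 5).
config_timebase <- function(config) {
  n <- round(diff(config$epoch_ms) / 1000 * config$sampling_rate_hz)
  config$epoch_ms[1] + (seq_len(n) - 1) / config$sampling_rate_hz * 1000
}

# Group- and condition-specific component list: HI multiplies the effect
# components; the noise condition scales amplitudes and delays latencies.
adjust_components <- function(config, group, condition,
                              apply_group_effect = TRUE) {
  comps <- config$components
  for (i in seq_along(comps)) {
    c_i <- comps[[i]]
    if (apply_group_effect && group == "HI" &&
          c_i$label %in% config$effect_components)
      c_i$amplitude <- c_i$amplitude * config$group_effect
    if (condition == "noise") {
      c_i$amplitude <- c_i$amplitude * config$amplitude_scale
      c_i$latency_ms <- c_i$latency_ms + config$latency_shift_ms
    }
    comps[[i]] <- c_i
  }
  comps
}

#' Noiseless group-mean kernels for a configuration
#'
#' Evaluates the expected (noise-free) evoked waveform for a group and
#' condition, inside and outside the discriminative ROI set. Used to state
#' generator-level properties (e.g. the noise condition has a smaller,
#' later P1) without simulating trials.
#'
#' @param config A [simulation_config()].
#' @param group `"NH"` or `"HI"`.
#' @param condition `"clear"` or `"noise"`.
#' @param discriminative Evaluate the waveform of a discriminative ROI
#'   (`TRUE`) or a background ROI (`FALSE`).
#' @return Numeric waveform on [config_timebase] of the config.
#' @export
expected_kernel <- function(config, group = c("NH", "HI"),
                            condition = c("clear", "noise"),
                            discriminative = TRUE) {
  group <- match.arg(group); condition <- match.arg(condition)
  comps <- adjust_components(config, group, condition,
                             apply_group_effect = discriminative)
  erp_kernel(comps, config_timebase(config))
}

# 1/f^beta background: filter white noise columns in the frequency domain
# (mvfft is column-vectorised), amplitude response normalised to unit
# output variance, DC removed.
pink_noise <- function(n_samples, n_series, exponent) {
  w <- matrix(stats::rnorm(n_samples * n_series), nrow = n_samples)
  freq_idx <- pmin(seq_len(n_samples) - 1, n_samples - seq_len(n_samples) + 1)
  amp <- c(0, freq_idx[-1]^(-exponent / 2))
  amp <- amp / sqrt(mean(amp^2))
  spec <- stats::mvfft(w) * amp
  Re(stats::mvfft(spec, inverse = TRUE)) / n_samples
}

#' Simulate a cohort of single-trial source epochs
#'
#' Generates one epoch block per subject and condition. Each single trial
#' is the subject's evoked kernel (group/condition-adjusted, latency
#' jittered per trial) plus 1/f^beta background and white noise. ROIs
#' outside `discriminative_rois` share an identical expected waveform
#' across groups, so any group separation found there is noise.
#'
#' @param config A [simulation_config()].
#' @param conditions Conditions to generate (subset of
#'   `c("clear", "noise")`). Both by default.
#' @return A list of `source_epochs` objects (one per subject x condition),
#'   each with fields `subject_id`, `group`, `condition`, `data` (array
#'   trial x roi x sample), `sampling_rate_hz`, `epoch_start_ms`.
#' @examples
#' cfg <- simulation_config(n_nh = 2, n_hi = 2, n_trials = 20, n_rois = 8,
#'                          discriminative_rois = 0:1, seed = 7)
#' cohort <- simulate_cohort(cfg, conditions = "clear")
#' length(cohort)            # 4 blocks
#' dim(cohort[[1]]$data)     # 20 x 8 x 105
#' @export
simulate_cohort <- function(config, conditions = c("clear", "noise")) {
  stopifnot(inherits(config, "simulation_config"))
  conditions <- match.arg(conditions, c("clear", "noise"), several.ok = TRUE)
  timebase <- config_timebase(config)
  n_samp <- length(timebase)
  groups <- c(rep("NH", config$n_nh), rep("HI", config$n_hi))
  ids <- c(sprintf("NH%02d", seq_len(config$n_nh)),
           sprintf("HI%02d", seq_len(config$n_hi)))
  disc <- config$discriminative_rois + 1L  # to 1-based

  with_seed(config$seed, {
    subj_amp <- pmax(0.1, stats::rnorm(length(ids), 1, config$subject_amp_sd))
    # regional gains are a per-subject trait, shared across conditions
    roi_gain <- matrix(pmax(0.1, stats::rnorm(length(ids) * config$n_rois,
                                              1, config$roi_gain_sd)),
                       nrow = length(ids))
    out <- vector("list", length(ids) * length(conditions))
    k <- 0L
    for (s in seq_along(ids)) {
      for (cond in conditions) {
        comps_bg <- adjust_components(config, groups[s], cond,
                                      apply_group_effect = FALSE)
        comps_fg <- adjust_components(config, groups[s], cond,
                                      apply_group_effect = TRUE)
        jitter <- stats::rnorm(config$n_trials, 0, config$trial_jitter_ms_sd)
        data <- array(0, dim = c(config$n_trials, config$n_rois, n_samp))
        for (tr in seq_len(config$n_trials)) {
          bg <- erp_kernel(comps_bg, timebase - jitter[tr]) * subj_amp[s]
          sig <- matrix(bg, nrow = config$n_rois, ncol = n_samp,
                        byrow = TRUE)
          if (length(disc) && groups[s] == "HI") {
            fg <- erp_kernel(comps_fg, timebase - jitter[tr]) * subj_amp[s]
            sig[disc, ] <- matrix(fg, nrow = length(disc), ncol = n_samp,
                                  byrow = TRUE)
          }
          data[tr, , ] <- roi_gain[s, ] * sig
        }
        noise <- config$pink_sd *
          pink_noise(n_samp, config$n_trials * config$n_rois,
                     config$pink_exponent) +
          matrix(stats::rnorm(n_samp * config$n_trials * config$n_rois,
                              0, config$white_sd), nrow = n_samp)
        data <- data + aperm(array(noise,
                                   dim = c(n_samp, config$n_trials,
                                           config$n_rois)),
                             c(2, 3, 1))
        k <- k + 1L
        out[[k]] <- structure(
          list(subject_id = ids[s], group = groups[s], condition = cond,
               data = data, sampling_rate_hz = config$sampling_rate_hz,
               epoch_start_ms = config$epoch_ms[1]),
          class = "source_epochs")
      }
    }
    out
  })
}

#' @export
print.source_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("source_epochs: %s (%s, %s) - %d trials x %d ROIs x %d samples @ %g Hz\n",
              x$subject_id, x$group, x$condition, d[1], d[2], d[3],
              x$sampling_rate_hz))
  invisible(x)
}

# Timebase in ms of an epochs block.
epochs_timebase <- function(epochs) {
  n <- dim(epochs$data)[3]
  epochs$epoch_start_ms + (seq_len(n) - 1) / epochs$sampling_rate_hz * 1000
}

#' Write / read a source_epochs block as plain text
#'
#' Serialization for epoch blocks: a small header of `# key value` lines
#' followed by a tab-separated (trial x roi) by sample matrix. Plain text
#' keeps blocks portable and diffable; round-trips exactly at full double
#' precision.
#'
#' @param epochs A `source_epochs` object.
#' @param path Output file path (`write_source_epochs`) or input file path
#'   (`read_source_epochs`).
#' @return `write_source_epochs` returns `path` invisibly;
#'   `read_source_epochs` returns a `source_epochs` object.
#' @export
write_source_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# subject_id", epochs$subject_id),
    paste("# group", epochs$group),
    paste("# condition", epochs$condition),
    paste("# sampling_rate_hz", format(epochs$sampling_rate_hz, digits = 17)),
    paste("# epoch_start_ms", format(epochs$epoch_start_ms, digits = 17)),
    paste("# dim", d[1], d[2], d[3])), con)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[3])
  utils::write.table(format(t(flat), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_source_epochs
#' @export
read_source_epochs <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(sub("^# ", "", hdr), " ")
  meta <- stats::setNames(lapply(kv, `[`, -1), vapply(kv, `[`, "", 1))
  d <- as.integer(meta$dim)
  flat <- as.matrix(utils::read.table(path, skip = 6, sep = "\t"))
  dimnames(flat) <- NULL
  data <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  structure(list(subject_id = meta$subject_id[[1]], group = meta$group[[1]],
                 condition = meta$condition[[1]], data = data,
                 sampling_rate_hz = as.numeric(meta$sampling_rate_hz[[1]]),
                 epoch_start_ms = as.numeric(meta$epoch_start_ms[[1]])),
            class = "source_epochs")
}
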