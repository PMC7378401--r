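# Shared fixtures, built once per test run and cached.  The two cohort
# fixtures are the expensive objects: a planted-network cohort for
# region-recovery and null-calibration checks, and a clean narrow-P1
# cohort (subject traits and jitter off) for latency/lateralization
# recovery, where the group effect must stay confined to one time window.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small grid keeping SVM search affordable in tests
test_grid <- function() grid_spec(C_values = c(1, 10),
                                  gamma_values = c(1e-3, 1e-2))

# single (C, gamma): no search, used where only evaluation matters
unit_grid <- function() grid_spec(C_values = 1, gamma_values = 1 / 68)

# 8 + 8 subjects, 600 trials, default planted 12-ROI network with
# subject-trait variability; clear condition; 25-trial pseudo-trials.
planted_features <- function() fixture("fm_planted", function() {
  cfg <- simulation_config(n_nh = 8, n_hi = 8, n_trials = 600, seed = 4242)
  cohort <- simulate_cohort(cfg, conditions = "clear")
  fm <- build_feature_matrix(cohort, "clear", n_per_average = 25, seed = 7)
  rm(cohort); gc(verbose = FALSE)
  fm
})

planted_stability <- function() fixture("stab_planted", function() {
  stability_selection(planted_features(),
                      params = stability_params(n_resamples = 100, seed = 99),
                      thresholds = c(0.1, 0.5, 0.7),
                      grid = test_grid())
})

# narrow P1 (65 ms, 3 ms SD) so the group effect lives in the window
# starting at 60 ms; planted only in left-hemisphere regions; no subject
# traits or trial jitter, so no subject-fingerprint leakage.
latency_config <- function(seed = 777) {
  comps <- list(erp_component("P1", 65, 3, 1),
                erp_component("N1", 100, 30, -1.5),
                erp_component("P2", 170, 40, 1.2))
  atlas <- make_atlas()
  lh_planted <- intersect(default_discriminative_rois(),
                          hemisphere_mask(atlas, "L"))
  simulation_config(n_nh = 8, n_hi = 8, n_trials = 600, components = comps,
                    discriminative_rois = lh_planted,
                    trial_jitter_ms_sd = 0, subject_amp_sd = 0,
                    roi_gain_sd = 0, seed = seed)
}

latency_features <- function() fixture("fm_latency", function() {
  cohort <- simulate_cohort(latency_config())
  out <- list(
    clear = build_feature_matrix(cohort, "clear", n_per_average = 25,
                                 seed = 11),
    noise = build_feature_matrix(cohort, "noise", n_per_average = 25,
                                 seed = 11))
  rm(cohort); gc(verbose = FALSE)
  out
})

latency_decode <- function(which) {
  fms <- latency_features()
  key <- paste0("dec_", which)
  fixture(key, function() {
    switch(which,
      clear_whole = decode_windows(fms$clear, "whole", grid = test_grid(),
                                   seed = 21),
      clear_lh = decode_windows(fms$clear, "LH", grid = test_grid(),
                                seed = 21),
      clear_rh = decode_windows(fms$clear, "RH", grid = test_grid(),
                                seed = 21),
      noise_whole = decode_windows(fms$noise, "whole", grid = test_grid(),
                                   seed = 21))
  })
}

# tiny cohort for structural unit tests
tiny_cohort <- function(seed = 5) {
  cfg <- simulation_config(n_nh = 2, n_hi = 2, n_trials = 24, n_rois = 6,
                           discriminative_rois = 0:1, seed = seed)
  simulate_cohort(cfg, conditions = "clear")
}
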