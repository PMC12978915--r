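# Shared fixtures: scaled-down configurations used across the suite.
# All sizes are fixed here once; tests never tune them.

scaled_pre <- function(...) {
  preprocess_params(trim_s = 0.5, band_high_hz = 245, ...)
}

scaled_psd <- function(...) {
  psd_params(band_high_hz = 245, ...)
}

# equal control/compression durations so WFL (total variation) is
# commensurable between the segments a contrast compares
scaled_cfg <- function(seed, n_participants = 25, ...) {
  sim_config(n_participants = n_participants, fs = 512,
             control_duration_s = 3, compression_duration_s = 3,
             seed = seed, ...)
}

null_map <- function() {
  activation_map(gain = stats::setNames(rep(1, 7), emg_muscles()),
                 spectral_mix = 0)
}

# one small preprocessed session + its features
scaled_session <- function(seed = 7, map = activation_map()) {
  simulate_session("P01", scaled_cfg(seed), map)
}

scaled_pipeline <- function(seed = 7, map = activation_map()) {
  ses <- scaled_session(seed, map)
  norm <- preprocess_session(ses, scaled_pre())
  list(raw = ses, session = norm$session, scales = norm$scales,
       features = extract_features(norm$session, scaled_pre(),
                                   scaled_psd()))
}

cohort_features <- function(cfg, map, pre = scaled_pre(),
                            psd = scaled_psd()) {
  coh <- simulate_cohort(cfg, map)
  norm <- emg_cohort(lapply(coh$sessions,
                            function(s) preprocess_session(s, pre)$session))
  extract_cohort_features(norm, pre, psd)
}
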