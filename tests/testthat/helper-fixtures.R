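# Shared fixtures, all built in code.

# Single- or multi-tone recording.
tone_recording <- function(freqs, amps = rep(1, length(freqs)), fs = 512,
                           duration_s = 60) {
  t <- (0:(duration_s * fs - 1)) / fs
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * cos(2 * pi * freqs[i] * t),
                      numeric(length(t))))
  lfp_recording(list(OB = x), fs = fs)
}

white_noise_recording <- function(duration_s = 60, fs = 512, seed = 1) {
  set.seed(seed)
  lfp_recording(list(OB = rnorm(duration_s * fs)), fs = fs)
}

# fepsp_features object with chosen values (for criteria tests).
make_features <- function(latency_ms = 8, amplitude_uV = 2000,
                          slope_uV_per_ms = -600) {
  structure(list(latency_ms = latency_ms, amplitude_uV = amplitude_uV,
                 slope_uV_per_ms = slope_uV_per_ms, artifact_end_ms = 1,
                 fit_window = c(1.5, 7.5)),
            class = "fepsp_features")
}

# Sweep whose linear descent starts exactly at the blanking end, so the
# central-80% fit window lies entirely inside the descent.
recoverable_sweep_config <- function(slope, peak_amp = 2000, blank_ms = 1,
                                     noise_sd = 0, seed = 1) {
  sweep_sim_config(latency_ms = blank_ms + peak_amp / abs(slope),
                   peak_amp = peak_amp, slope = slope,
                   artifact_dur_ms = 0.8, noise_sd = noise_sd, seed = seed)
}

# Restricted PAC grids used throughout the tests (f_L <= 20, f_H <= 100).
test_pac_params <- function(...) {
  pac_params(fL_grid = seq(1, 19, 2), fH_grid = seq(10, 100, 5), ...)
}
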