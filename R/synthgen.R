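# Synthetic LFPs with controllable theta-gamma coupling and synthetic
# evoked fEPSP sweeps/experiments. All generators are deterministic given
# the seed in their config; RNG state of the session is left untouched.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Configuration for a synthetic cross-frequency-coupled LFP
#'
#' Describes a single-channel LFP as 1/f^a background noise plus a slow
#' carrier sinusoid (phase provider, e.g. theta) plus a fast sinusoid
#' (e.g. gamma) whose amplitude envelope is modulated by the carrier phase:
#' `envelope = gamma_amp * (1 + mod_depth * cos(phase)) / (1 + mod_depth)`,
#' so the envelope peaks at the carrier's phase zero and the peak envelope
#' equals `gamma_amp` at every depth.
#'
#' @param duration_s recording duration, seconds.
#' @param fs sampling rate, Hz.
#' @param phase_freq slow carrier frequency, Hz.
#' @param amp_freq fast (modulated) band center, Hz.
#' @param mod_depth modulation depth in `[0, 1]`; 0 means no coupling.
#' @param carrier_amp,gamma_amp component amplitudes, microvolts.
#' @param noise_exponent spectral slope `a` of the 1/f^a background.
#' @param noise_sd background noise standard deviation, microvolts.
#' @param seed integer RNG seed.
#' @return A validated `lfp_sim_config` list.
#' @export
lfp_sim_config <- function(duration_s = 60, fs = 512, phase_freq = 7,
                           amp_freq = 60, mod_depth = 0.5, carrier_amp = 50,
                           gamma_amp = 20, noise_exponent = 1, noise_sd = 15,
                           seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (!(phase_freq > 0 && phase_freq < amp_freq && amp_freq < fs / 2))
    stop("need 0 < phase_freq < amp_freq < fs/2", call. = FALSE)
  if (mod_depth < 0 || mod_depth > 1)
    stop("mod_depth must be in [0, 1]", call. = FALSE)
  structure(list(duration_s = duration_s, fs = fs, phase_freq = phase_freq,
                 amp_freq = amp_freq, mod_depth = mod_depth,
                 carrier_amp = carrier_amp, gamma_amp = gamma_amp,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "lfp_sim_config")
}

# Gaussian 1/f^a noise by spectral shaping of white noise.
pink_noise <- function(n, exponent, sd) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)            # symmetric bin index, preserves Hermitian symmetry
  g <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

#' Generate a synthetic cross-frequency-coupled LFP
#'
#' @param config an [lfp_sim_config].
#' @return An [lfp_recording] with one channel `"OB"` of
#'   `duration_s * fs` samples. Identical config (including seed) yields
#'   bit-identical output.
#' @export
gen_coupled_lfp <- function(config) {
  stopifnot(inherits(config, "lfp_sim_config"))
  n <- round(config$duration_s * config$fs)
  t <- (0:(n - 1)) / config$fs
  ph <- 2 * pi * config$phase_freq * t
  carrier <- config$carrier_amp * cos(ph)
  env <- config$gamma_amp * (1 + config$mod_depth * cos(ph)) / (1 + config$mod_depth)
  gam <- env * cos(2 * pi * config$amp_freq * t)
  noise <- with_seed(config$seed,
                     pink_noise(n, config$noise_exponent, config$noise_sd))
  rec <- lfp_recording(list(OB = carrier + gam + noise), fs = config$fs)
  rec$sim_config <- config
  rec
}

#' Configuration for a synthetic evoked fEPSP sweep
#'
#' The sweep is flat at zero before the stimulus; at `stim_time_s` a brief
#' biphasic stimulus artifact (one-sample spike of alternating sign with an
#' exponential ring-down shorter than `artifact_dur_ms`) is inserted; the
#' negative field EPSP deflection then descends linearly at `slope` to
#' `-peak_amp`, reached `latency_ms` after the stimulus, and recovers
#' exponentially. Gaussian noise of `noise_sd` is added throughout.
#'
#' The linear descent starts at `latency_ms - peak_amp/|slope|` after the
#' stimulus; this onset must fall after the artifact ends, otherwise the
#' descent cannot reach the peak in time and the config is rejected.
#'
#' @param fs sampling rate, Hz (nominal 3000).
#' @param pre_ms,post_ms flat pre-stimulus and total post-stimulus
#'   durations, ms.
#' @param stim_time_s stimulus time from sweep start, seconds.
#' @param artifact_amp,artifact_dur_ms artifact size (uV) and duration (ms).
#' @param latency_ms stimulus to negative-peak latency, ms.
#' @param peak_amp magnitude of the negative deflection, uV (positive number).
#' @param slope descent rate, uV/ms (negative).
#' @param recovery_tau_ms time constant of the post-peak recovery, ms.
#' @param noise_sd additive Gaussian noise, uV.
#' @param seed integer RNG seed.
#' @return A validated `sweep_sim_config` list.
#' @export
sweep_sim_config <- function(fs = 3000, pre_ms = 10, post_ms = 40,
                             stim_time_s = NULL, artifact_amp = 4000,
                             artifact_dur_ms = 0.8, latency_ms = 8,
                             peak_amp = 2000, slope = -500,
                             recovery_tau_ms = 6, noise_sd = 0, seed = 1L) {
  if (is.null(stim_time_s)) stim_time_s <- pre_ms / 1000
  if (peak_amp <= 0) stop("peak_amp must be > 0", call. = FALSE)
  if (slope >= 0) stop("slope must be negative (descending deflection)", call. = FALSE)
  if (latency_ms <= artifact_dur_ms)
    stop("latency_ms must exceed artifact_dur_ms", call. = FALSE)
  onset_ms <- latency_ms - peak_amp / abs(slope)
  if (onset_ms < artifact_dur_ms - 1e-9)
    stop(sprintf(paste("descent cannot reach -%g uV by %g ms at %g uV/ms:",
                       "onset %0.2f ms falls inside the artifact"),
                 peak_amp, latency_ms, slope, onset_ms), call. = FALSE)
  structure(list(fs = fs, pre_ms = pre_ms, post_ms = post_ms,
                 stim_time_s = stim_time_s, artifact_amp = artifact_amp,
                 artifact_dur_ms = artifact_dur_ms, latency_ms = latency_ms,
                 peak_amp = peak_amp, slope = slope,
                 recovery_tau_ms = recovery_tau_ms, noise_sd = noise_sd,
                 seed = as.integer(seed), onset_ms = onset_ms),
            class = "sweep_sim_config")
}

#' Generate a synthetic evoked fEPSP sweep
#'
#' @param config a [sweep_sim_config].
#' @return A [sweep_record]. In the noiseless limit the slope fitted by
#'   [extract_features] over a window inside the descent equals the
#'   configured slope exactly.
#' @export
gen_fepsp_sweep <- function(config) {
  stopifnot(inherits(config, "sweep_sim_config"))
  fs <- config$fs
  n <- round((config$stim_time_s * 1000 + config$post_ms) * fs / 1000)
  t_ms <- (0:(n - 1)) / fs * 1000          # ms from sweep start
  rel <- t_ms - config$stim_time_s * 1000  # ms from stimulus
  x <- numeric(n)

  in_art <- rel >= 0 & rel < config$artifact_dur_ms
  if (any(in_art)) {
    k <- seq_len(sum(in_art)) - 1
    x[in_art] <- config$artifact_amp * (-1)^k * exp(-k / max(1, fs * 2e-4))
  }
  onset <- config$onset_ms
  desc <- rel >= onset & rel <= config$latency_ms
  x[desc] <- config$slope * (rel[desc] - onset)
  rec <- rel > config$latency_ms
  x[rec] <- -config$peak_amp * exp(-(rel[rec] - config$latency_ms) / config$recovery_tau_ms)

  if (config$noise_sd > 0)
    x <- x + with_seed(config$seed, stats::rnorm(n, sd = config$noise_sd))
  sweep_record(x, fs = fs, stim_time_s = config$stim_time_s,
               meta = list(sim_config = config))
}

#' Generate a synthetic input/output series of evoked sweeps
#'
#' Emulates an I/O protocol: stimulation at 1--8 V in 1 V steps, three
#' sweeps per voltage. The expected fEPSP descent rate at voltage `v`
#' follows a sigmoid, `max_slope / (1 + exp(-steepness * (v - v50)))`,
#' i.e. half-maximal at `v50` and saturating at `max_slope`. Each sweep's
#' peak amplitude scales with its slope at a fixed descent duration so the
#' waveform geometry is voltage-invariant.
#'
#' @param sweep_base a [sweep_sim_config] supplying everything except
#'   slope/peak/latency (noise, sampling, artifact).
#' @param v50 half-maximum voltage, volts.
#' @param max_slope plateau descent rate magnitude, uV/ms.
#' @param voltages stimulation voltages, volts.
#' @param n_per_voltage sweeps per voltage.
#' @param steepness sigmoid steepness, 1/V.
#' @param descent_ms descent duration (peak amplitude = slope * descent_ms).
#' @return Named list of [sweep_record]s; each carries `meta$voltage_V`.
#' @export
gen_io_series <- function(sweep_base = sweep_sim_config(), v50 = 4,
                          max_slope = 800, voltages = 1:8,
                          n_per_voltage = 3, steepness = 1.5,
                          descent_ms = 4) {
  out <- list()
  for (v in voltages) {
    s_v <- max_slope / (1 + exp(-steepness * (v - v50)))
    for (j in seq_len(n_per_voltage)) {
      cfg <- sweep_sim_config(
        fs = sweep_base$fs, pre_ms = sweep_base$pre_ms,
        post_ms = sweep_base$post_ms, stim_time_s = sweep_base$stim_time_s,
        artifact_amp = sweep_base$artifact_amp,
        artifact_dur_ms = sweep_base$artifact_dur_ms,
        latency_ms = 1 + descent_ms,      # descent spans blanking end to peak
        peak_amp = s_v * descent_ms, slope = -s_v,
        recovery_tau_ms = sweep_base$recovery_tau_ms,
        noise_sd = sweep_base$noise_sd,
        seed = sweep_base$seed + 101L * v + j)
      sw <- gen_fepsp_sweep(cfg)
      sw$meta$voltage_V <- v
      out[[sprintf("v%d_s%d", v, j)]] <- sw
    }
  }
  out
}

#' Configuration for a synthetic two-phase LTP experiment
#'
#' Describes per-subject fEPSP-slope time courses around a tetanization:
#' `baseline_points` points at 100% in expectation, then `post_points`
#' points at 2.5 min spacing whose group profile is `induction_pct` at the
#' first post point, then decays exponentially from `stp_pct` toward
#' `ltp_pct` with time constant `stp_decay_min`. Subject-level offsets are
#' drawn once per subject (`between_subject_sd`), point-level noise per
#' time point (`within_subject_sd`), both in percent of baseline.
#'
#' @param n_subjects_per_group subjects per group.
#' @param baseline_points number of pre-tetanization points (averaged as
#'   the 100% reference).
#' @param post_points post-tetanization points (36 = 90 min at 2.5 min).
#' @param point_spacing_min minutes between points.
#' @param induction_pct,stp_pct,ltp_pct group profile, percent of baseline.
#' @param stp_decay_min decay time constant, minutes.
#' @param between_subject_sd,within_subject_sd noise, percent.
#' @param base_slope mean raw baseline slope, uV/ms (scale only).
#' @param seed integer RNG seed.
#' @return A validated `ltp_experiment_config` list.
#' @export
ltp_experiment_config <- function(n_subjects_per_group = 8, baseline_points = 6,
                                  post_points = 36, point_spacing_min = 2.5,
                                  induction_pct = 180, stp_pct = 150,
                                  ltp_pct = 130, stp_decay_min = 10,
                                  between_subject_sd = 8, within_subject_sd = 6,
                                  base_slope = 600, seed = 1L) {
  pcts <- c(induction_pct, stp_pct, ltp_pct)
  if (any(pcts <= 0)) stop("all profile percentages must be > 0", call. = FALSE)
  if (baseline_points < 1 || post_points < 1)
    stop("need at least one baseline and one post point", call. = FALSE)
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 baseline_points = baseline_points, post_points = post_points,
                 point_spacing_min = point_spacing_min,
                 induction_pct = induction_pct, stp_pct = stp_pct,
                 ltp_pct = ltp_pct, stp_decay_min = stp_decay_min,
                 between_subject_sd = between_subject_sd,
                 within_subject_sd = within_subject_sd,
                 base_slope = base_slope, seed = as.integer(seed)),
            class = "ltp_experiment_config")
}

ltp_profile <- function(cfg, t_min) {
  p <- cfg$ltp_pct + (cfg$stp_pct - cfg$ltp_pct) *
    exp(-(t_min - t_min[1]) / cfg$stp_decay_min)
  p[1] <- cfg$induction_pct
  p
}

#' Generate a synthetic two-group LTP experiment
#'
#' Simulates raw slope series for two groups under their configs, then
#' baseline-normalizes each subject with [ltp_timecourse_from_slopes]
#' (mean of the last six baseline points = 100%).
#'
#' @param config_a,config_b [ltp_experiment_config] for groups A and B.
#'   Group B reuses A's structural fields when only percentages differ.
#' @return List with elements `A` and `B`, each a list of [ltp_timecourse]
#'   objects (one per subject).
#' @export
gen_ltp_experiment <- function(config_a, config_b = config_a) {
  stopifnot(inherits(config_a, "ltp_experiment_config"),
            inherits(config_b, "ltp_experiment_config"))
  gen_group <- function(cfg, seed_off) with_seed(cfg$seed + seed_off, {
    t_post <- seq_len(cfg$post_points) * cfg$point_spacing_min
    prof <- ltp_profile(cfg, t_post)
    lapply(seq_len(cfg$n_subjects_per_group), function(s) {
      subj_base <- cfg$base_slope *
        (1 + stats::rnorm(1, sd = cfg$between_subject_sd / 100))
      base_pts <- subj_base *
        (1 + stats::rnorm(cfg$baseline_points, sd = cfg$within_subject_sd / 100))
      post_pts <- subj_base * prof / 100 *
        (1 + stats::rnorm(cfg$post_points, sd = cfg$within_subject_sd / 100))
      ltp_timecourse_from_slopes(
        baseline_slopes = base_pts, post_slopes = post_pts,
        point_spacing_min = cfg$point_spacing_min)
    })
  })
  list(A = gen_group(config_a, 0L), B = gen_group(config_b, 5000L))
}
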