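# Evoked fEPSP quantification: slope/latency/amplitude extraction,
# inclusion criteria, input/output curves, and baseline-normalized LTP
# time courses.

#' Construct an evoked sweep record
#'
#' @param samples microvolt series.
#' @param fs sampling rate, Hz (nominal 3000).
#' @param stim_time_s stimulus time from sweep start, seconds.
#' @param stim_duration_us stimulus pulse duration, microseconds (metadata).
#' @param meta list of labels (subject, group, voltage, timestamp, ...).
#' @return A `sweep_record`.
#' @export
sweep_record <- function(samples, fs = 3000, stim_time_s = 0,
                         stim_duration_us = 200, meta = list()) {
  samples <- as.numeric(samples)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (stim_time_s < 0 || stim_time_s >= length(samples) / fs)
    stop("stim_time_s must lie within the sweep", call. = FALSE)
  structure(list(samples = samples, fs = fs, stim_time_s = stim_time_s,
                 stim_duration_us = stim_duration_us, meta = meta),
            class = "sweep_record")
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf("<sweep_record> %d samples @ %g Hz, stimulus at %g ms\n",
              length(x$samples), x$fs, x$stim_time_s * 1000))
  invisible(x)
}

#' Extract fEPSP features from a sweep
#'
#' The stimulus artifact is blanked for `blank_ms` after the stimulus
#' (artifact end = stimulus time + `blank_ms`). The negative peak is the
#' minimum sample in the 15 ms following the artifact end; latency is
#' measured from the stimulus to that peak, amplitude is the peak's
#' magnitude relative to the pre-stimulus mean, and the slope is the
#' least-squares line fitted over the central 80% of the span from
#' artifact end to peak (10% of the span dropped at each end, avoiding
#' onset and peak curvature).
#'
#' @param sweep a [sweep_record].
#' @param blank_ms artifact blanking after the stimulus, ms (default 1:
#'   200 us pulse plus ring-down margin).
#' @param search_ms negative-peak search window after artifact end, ms.
#' @return An `fepsp_features` list: `latency_ms`, `amplitude_uV`,
#'   `slope_uV_per_ms` (signed; negative for the descending fEPSP),
#'   `artifact_end_ms`, `fit_window` (ms from stimulus).
#' @export
extract_features <- function(sweep, blank_ms = 1, search_ms = 15) {
  stopifnot(inherits(sweep, "sweep_record"))
  fs <- sweep$fs
  rel_ms <- ((seq_along(sweep$samples) - 1) / fs - sweep$stim_time_s) * 1000
  if (max(rel_ms) < blank_ms + search_ms)
    stop(sprintf("sweep ends %0.1f ms post-stimulus; need %g ms",
                 max(rel_ms), blank_ms + search_ms), call. = FALSE)
  pre <- sweep$samples[rel_ms < 0]
  pre_mean <- if (length(pre)) mean(pre) else 0
  pre_sd <- if (length(pre) > 1) stats::sd(pre) else 0

  win <- which(rel_ms > blank_ms & rel_ms <= blank_ms + search_ms)
  pk <- win[which.min(sweep$samples[win])]
  peak_val <- sweep$samples[pk]
  if (peak_val >= pre_mean - 3 * pre_sd)
    stop("no negative deflection below baseline - 3 sd: feature absent",
         call. = FALSE)
  latency_ms <- rel_ms[pk]
  amplitude <- abs(peak_val - pre_mean)

  span <- latency_ms - blank_ms
  f0 <- blank_ms + 0.1 * span
  f1 <- blank_ms + 0.9 * span
  fit_idx <- which(rel_ms >= f0 & rel_ms <= f1)
  if (length(fit_idx) < 2)
    stop("fit window contains fewer than 2 samples", call. = FALSE)
  co <- stats::lm.fit(cbind(1, rel_ms[fit_idx]), sweep$samples[fit_idx])$coefficients
  structure(list(latency_ms = latency_ms, amplitude_uV = amplitude,
                 slope_uV_per_ms = unname(co[2]),
                 artifact_end_ms = blank_ms, fit_window = c(f0, f1)),
            class = "fepsp_features")
}

#' @export
print.fepsp_features <- function(x, ...) {
  cat(sprintf("<fepsp_features> latency %.2f ms, amplitude %.0f uV, slope %.1f uV/ms (fit %0.2f-%0.2f ms)\n",
              x$latency_ms, x$amplitude_uV, x$slope_uV_per_ms,
              x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Apply fEPSP inclusion/exclusion criteria
#'
#' A response is included when, with all bounds inclusive, latency to the
#' negative peak is within 6--10 ms, amplitude within 1500--2500 uV, and
#' slope magnitude within 400--900 uV/ms. Every violated bound is listed.
#'
#' @param f an `fepsp_features`.
#' @param latency_bounds,amplitude_bounds,slope_bounds inclusive bounds.
#' @return A `criteria_result` with `included` (logical) and `reasons`
#'   (character vector among `latency_low`, `latency_high`,
#'   `amplitude_low`, `amplitude_high`, `slope_low`, `slope_high`).
#' @export
apply_inclusion_criteria <- function(f, latency_bounds = c(6, 10),
                                     amplitude_bounds = c(1500, 2500),
                                     slope_bounds = c(400, 900)) {
  stopifnot(inherits(f, "fepsp_features"))
  if (!all(is.finite(c(f$latency_ms, f$amplitude_uV, f$slope_uV_per_ms))))
    stop("features must be finite", call. = FALSE)
  s <- abs(f$slope_uV_per_ms)
  reasons <- character(0)
  if (f$latency_ms < latency_bounds[1]) reasons <- c(reasons, "latency_low")
  if (f$latency_ms > latency_bounds[2]) reasons <- c(reasons, "latency_high")
  if (f$amplitude_uV < amplitude_bounds[1]) reasons <- c(reasons, "amplitude_low")
  if (f$amplitude_uV > amplitude_bounds[2]) reasons <- c(reasons, "amplitude_high")
  if (s < slope_bounds[1]) reasons <- c(reasons, "slope_low")
  if (s > slope_bounds[2]) reasons <- c(reasons, "slope_high")
  structure(list(included = length(reasons) == 0L, reasons = reasons),
            class = "criteria_result")
}

#' Build an input/output curve from sweeps grouped by voltage
#'
#' Per-voltage mean of the slope magnitude across sweeps (three responses
#' expected per voltage; fewer are accepted with a warning).
#'
#' @param sweeps list of [sweep_record]s, each carrying `meta$voltage_V`.
#' @param blank_ms passed to [extract_features].
#' @param expect_voltages protocol voltages; absent ones are warned about
#'   and the curve is built over the available voltages (`NULL` disables).
#' @return An `io_curve` with `voltages` (ascending), `mean_slopes`
#'   (uV/ms magnitudes), `max_slope`.
#' @export
build_io_curve <- function(sweeps, blank_ms = 1, expect_voltages = 1:8) {
  if (length(sweeps) == 0) stop("no sweeps supplied", call. = FALSE)
  v <- vapply(sweeps, function(s) {
    if (is.null(s$meta$voltage_V)) stop("sweep lacks meta$voltage_V", call. = FALSE)
    as.numeric(s$meta$voltage_V)
  }, numeric(1))
  slopes <- vapply(sweeps, function(s)
    abs(extract_features(s, blank_ms = blank_ms)$slope_uV_per_ms), numeric(1))
  volts <- sort(unique(v))
  if (!is.null(expect_voltages) && length(setdiff(expect_voltages, volts)))
    warning(sprintf("missing voltage(s): %s",
                    paste(setdiff(expect_voltages, volts), collapse = ", ")))
  counts <- table(factor(v, levels = volts))
  if (any(counts < 3))
    warning(sprintf("fewer than 3 sweeps at voltage(s): %s",
                    paste(volts[counts < 3], collapse = ", ")))
  means <- vapply(volts, function(vi) mean(slopes[v == vi]), numeric(1))
  structure(list(voltages = volts, mean_slopes = means,
                 max_slope = max(means)),
            class = "io_curve")
}

#' @export
print.io_curve <- function(x, ...) {
  cat("<io_curve>\n")
  print(data.frame(voltage_V = x$voltages,
                   mean_slope_uV_per_ms = round(x$mean_slopes, 1)))
  invisible(x)
}

#' Select the test stimulus from an I/O curve
#'
#' Returns the tested voltage whose mean slope is nearest 50% of the
#' maximum response; ties break toward the lower voltage. With
#' `interpolate = TRUE` the half-maximum voltage is instead located by
#' linear interpolation between the bracketing tested voltages.
#'
#' @param curve an `io_curve`.
#' @param interpolate allow an untested (interpolated) voltage.
#' @return Selected voltage (V).
#' @export
select_test_stimulus <- function(curve, interpolate = FALSE) {
  stopifnot(inherits(curve, "io_curve"))
  if (length(curve$voltages) == 0) stop("empty I/O curve", call. = FALSE)
  if (curve$max_slope <= 0) stop("all slopes zero; cannot select", call. = FALSE)
  half <- 0.5 * curve$max_slope
  if (interpolate) {
    return(stats::approx(curve$mean_slopes, curve$voltages, xout = half,
                         ties = min)$y)
  }
  d <- abs(curve$mean_slopes - half)
  curve$voltages[which.min(d)]   # which.min takes the first (lower) on ties
}

#' Baseline-normalized LTP time course from per-point slopes
#'
#' Normalizes an already point-averaged slope series: the mean of the
#' last six baseline points defines 100%, and every point is expressed as
#' a percentage of it. Baseline points are placed at negative times
#' ending at 0; post points at `point_spacing_min` intervals after it.
#'
#' @param baseline_slopes ordered baseline point slopes, uV/ms (>= 6).
#' @param post_slopes ordered post-tetanization point slopes, uV/ms.
#' @param point_spacing_min minutes between points (default 2.5).
#' @param n_baseline_for_ref baseline points averaged as the reference
#'   (default 6, taken from the end of the baseline).
#' @return An `ltp_timecourse` with `times_min` (tetanization at 0),
#'   `pct_baseline`, `baseline_mean_slope`, `n_baseline`,
#'   `n_sweeps_per_point`.
#' @export
ltp_timecourse_from_slopes <- function(baseline_slopes, post_slopes,
                                       point_spacing_min = 2.5,
                                       n_baseline_for_ref = 6,
                                       n_sweeps_per_point = 5) {
  nb <- length(baseline_slopes)
  if (nb < n_baseline_for_ref)
    stop(sprintf("need >= %d baseline points, got %d", n_baseline_for_ref, nb),
         call. = FALSE)
  ref <- mean(utils::tail(baseline_slopes, n_baseline_for_ref))
  if (ref <= 0) stop("nonpositive baseline mean slope", call. = FALSE)
  times <- c(-rev(seq_len(nb) - 1) * point_spacing_min - point_spacing_min,
             seq_along(post_slopes) * point_spacing_min)
  structure(list(times_min = times,
                 pct_baseline = 100 * c(baseline_slopes, post_slopes) / ref,
                 baseline_mean_slope = ref, n_baseline = nb,
                 n_sweeps_per_point = n_sweeps_per_point),
            class = "ltp_timecourse")
}

#' Baseline-normalized LTP time course from sweep streams
#'
#' Implements the point protocol: consecutive non-overlapping blocks of
#' `sweeps_per_point` evoked responses (delivered at 0.033 Hz, i.e. one
#' point per 2.5 min) are averaged into one slope per point; an
#' incomplete final block is dropped with a warning. The mean of the last
#' six baseline points is the 100% reference.
#'
#' @param baseline_sweeps,post_sweeps time-ordered lists of
#'   [sweep_record]s.
#' @param sweeps_per_point sweeps averaged per point (default 5).
#' @param point_spacing_min minutes per point (default 2.5).
#' @param blank_ms passed to [extract_features].
#' @return An `ltp_timecourse` (see [ltp_timecourse_from_slopes]).
#' @export
ltp_timecourse <- function(baseline_sweeps, post_sweeps,
                           sweeps_per_point = 5, point_spacing_min = 2.5,
                           blank_ms = 1) {
  block_slopes <- function(sweeps, phase) {
    n_pts <- length(sweeps) %/% sweeps_per_point
    if (n_pts * sweeps_per_point < length(sweeps))
      warning(sprintf("dropping incomplete final %s block (%d sweep(s))",
                      phase, length(sweeps) - n_pts * sweeps_per_point))
    if (n_pts == 0) return(numeric(0))
    s <- vapply(sweeps[seq_len(n_pts * sweeps_per_point)], function(sw)
      abs(extract_features(sw, blank_ms = blank_ms)$slope_uV_per_ms),
      numeric(1))
    colMeans(matrix(s, nrow = sweeps_per_point))
  }
  base <- block_slopes(baseline_sweeps, "baseline")
  if (length(base) < 6)
    stop(sprintf("need >= 6 baseline points, got %d", length(base)), call. = FALSE)
  post <- block_slopes(post_sweeps, "post")
  ltp_timecourse_from_slopes(base, post, point_spacing_min,
                             n_sweeps_per_point = sweeps_per_point)
}

#' @export
print.ltp_timecourse <- function(x, ...) {
  post <- x$pct_baseline[x$times_min > 0]
  cat(sprintf("<ltp_timecourse> %d baseline + %d post points; baseline slope %.1f uV/ms; last post point %.1f%%\n",
              x$n_baseline, length(post), x$baseline_mean_slope,
              if (length(post)) post[length(post)] else NA_real_))
  invisible(x)
}

#' Mean percentage over a time window of an LTP time course
#'
#' Each point's timestamp marks the end of its sweep block, so a window
#' narrower than the point spacing (e.g. the first-minute induction
#' window `c(0, 1)`) contains no timestamps; in that case the points
#' whose covering block `(t - spacing, t]` overlaps the window are used
#' instead (for `c(0, 1)` at 2.5-min spacing: the first post point).
#'
#' @param tc an `ltp_timecourse`.
#' @param window inclusive window `c(lo, hi)` in minutes relative to
#'   tetanization (e.g. `c(0, 10)` for STP, `c(70, 90)` for LTP).
#' @return List with `mean_pct`, `values` (per-point percentages) and
#'   `times_min` of the included points.
#' @export
window_stats <- function(tc, window) {
  stopifnot(inherits(tc, "ltp_timecourse"))
  sel <- tc$times_min >= window[1] & tc$times_min <= window[2]
  if (!any(sel)) {
    spacing <- stats::median(diff(tc$times_min))
    sel <- (tc$times_min - spacing) < window[2] & tc$times_min > window[1]
  }
  if (!any(sel))
    stop(sprintf("window [%g, %g] min contains no time points",
                 window[1], window[2]), call. = FALSE)
  list(mean_pct = mean(tc$pct_baseline[sel]), values = tc$pct_baseline[sel],
       times_min = tc$times_min[sel])
}

#' Write an LTP time course to CSV
#' @param tc an `ltp_timecourse`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  utils::write.csv(data.frame(time_min = tc$times_min,
                              pct_baseline = tc$pct_baseline),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
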