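test_that("slope fit is exact on noiseless piecewise-linear sweeps", {
  for (s in c(-400, -500, -650, -900)) {
    sw <- gen_fepsp_sweep(recoverable_sweep_config(s))
    f <- extract_features(sw, blank_ms = 1)
    expect_equal(f$slope_uV_per_ms, s, tolerance = 1e-3)
  }
})

test_that("features scale linearly with the sweep and latency is invariant", {
  sw <- gen_fepsp_sweep(recoverable_sweep_config(-500))
  f1 <- extract_features(sw)
  sw2 <- sw
  sw2$samples <- sw$samples * 2
  f2 <- extract_features(sw2)
  expect_equal(f2$amplitude_uV, 2 * f1$amplitude_uV)
  expect_equal(f2$slope_uV_per_ms, 2 * f1$slope_uV_per_ms)
  expect_equal(f2$latency_ms, f1$latency_ms)
})

test_that("flat and too-short sweeps raise feature errors", {
  short <- sweep_record(rep(0, 40), fs = 3000, stim_time_s = 0.01)
  expect_error(extract_features(short), "ends")
  set.seed(2)
  flat <- sweep_record(rnorm(200, sd = 1e-3), fs = 3000, stim_time_s = 0.01)
  expect_error(extract_features(flat), "feature absent")
})

test_that("features extracted from synthetic sweeps match their configuration", {
  cfg <- recoverable_sweep_config(-650, peak_amp = 1950)
  f <- extract_features(gen_fepsp_sweep(cfg), blank_ms = 1)
  expect_equal(f$latency_ms, cfg$latency_ms, tolerance = 1 / 3)   # one sample
  expect_equal(f$amplitude_uV, 1950, tolerance = 1950 * 0.001)
  expect_equal(f$slope_uV_per_ms, -650, tolerance = 0.65)
})

test_that("inclusion criteria: interior, boundary, and one-unit excursions", {
  ok <- apply_inclusion_criteria(make_features(8, 2000, -600))
  expect_true(ok$included)
  expect_length(ok$reasons, 0)

  # all bounds inclusive: the nine boundary fixtures are included
  bounds <- list(c(6, 2000, 600), c(10, 2000, 600),
                 c(8, 1500, 600), c(8, 2500, 600),
                 c(8, 2000, 400), c(8, 2000, 900),
                 c(6, 1500, 400), c(10, 2500, 900), c(8, 2000, 600))
  for (b in bounds) {
    r <- apply_inclusion_criteria(make_features(b[1], b[2], -b[3]))
    expect_true(r$included, info = paste(b, collapse = "/"))
  }

  # one-unit excursions beyond each bound are excluded with the right reason
  cases <- list(list(make_features(5, 2000, -600), "latency_low"),
                list(make_features(11, 2000, -600), "latency_high"),
                list(make_features(8, 1499, -600), "amplitude_low"),
                list(make_features(8, 2501, -600), "amplitude_high"),
                list(make_features(8, 2000, -399), "slope_low"),
                list(make_features(8, 2000, -950), "slope_high"))
  for (cs in cases) {
    r <- apply_inclusion_criteria(cs[[1]])
    expect_false(r$included)
    expect_identical(r$reasons, cs[[2]])
  }

  # included XOR nonempty reasons, on arbitrary features
  set.seed(1)
  for (i in 1:20) {
    r <- apply_inclusion_criteria(make_features(runif(1, 3, 13),
                                                runif(1, 1000, 3000),
                                                -runif(1, 200, 1100)))
    expect_identical(r$included, length(r$reasons) == 0L)
  }
})

test_that("I/O curve averages three responses per voltage", {
  sweeps <- gen_io_series(sweep_sim_config(noise_sd = 0), v50 = 4, max_slope = 800)
  curve <- build_io_curve(sweeps)
  expect_equal(curve$voltages, 1:8)
  expect_equal(curve$max_slope, max(curve$mean_slopes))
  # three identical sweeps: point equals the single-sweep slope
  one <- abs(extract_features(sweeps[["v4_s1"]])$slope_uV_per_ms)
  expect_equal(curve$mean_slopes[4], one, tolerance = 1e-9)
  # missing voltage handled with a warning
  partial <- sweeps[!vapply(sweeps, function(s) s$meta$voltage_V == 8, TRUE)]
  expect_warning(c7 <- build_io_curve(partial), "missing voltage")
  expect_equal(c7$voltages, 1:7)
  expect_error(build_io_curve(list()), "no sweeps")
})

test_that("test-stimulus selection finds 50% of maximum with lower-voltage ties", {
  lin <- structure(list(voltages = 1:8, mean_slopes = 100 * (1:8),
                        max_slope = 800), class = "io_curve")
  expect_equal(select_test_stimulus(lin), 4)
  tie <- structure(list(voltages = c(2, 4, 5, 8),
                        mean_slopes = c(100, 400, 401, 800),
                        max_slope = 800), class = "io_curve")
  expect_equal(select_test_stimulus(tie), 4)     # 400 and 401 tie region: lower V
  for (v50 in c(3, 4, 5)) {
    curve <- build_io_curve(gen_io_series(sweep_sim_config(noise_sd = 0),
                                          v50 = v50, max_slope = 800))
    expect_lte(abs(select_test_stimulus(curve) - v50), 1)
  }
  # interpolation mode returns the exact half-max crossing on a linear curve
  expect_equal(select_test_stimulus(lin, interpolate = TRUE), 4)
  zero <- structure(list(voltages = 1:3, mean_slopes = c(0, 0, 0), max_slope = 0),
                    class = "io_curve")
  expect_error(select_test_stimulus(zero), "zero")
})

test_that("LTP normalization: identity, ratio, and the six-point baseline rule", {
  tc <- ltp_timecourse_from_slopes(rep(500, 8), rep(500, 36))
  expect_true(all(tc$pct_baseline == 100))
  tc2 <- ltp_timecourse_from_slopes(rep(500, 6), rep(750, 36))
  expect_true(all(tc2$pct_baseline[tc2$times_min > 0] == 150))
  # reference is the mean of the LAST six baseline points
  tc3 <- ltp_timecourse_from_slopes(c(1000, rep(500, 6)), rep(500, 10))
  expect_equal(tc3$baseline_mean_slope, 500)
  expect_error(ltp_timecourse_from_slopes(rep(500, 5), rep(500, 10)), ">= 6")
  expect_error(ltp_timecourse_from_slopes(rep(0, 6), rep(1, 3)), "nonpositive")
})

test_that("sweep-stream time course blocks five sweeps per point", {
  mk <- function(slope, n) lapply(seq_len(n), function(i)
    gen_fepsp_sweep(recoverable_sweep_config(slope)))
  base <- mk(-500, 30)   # 6 points
  post <- mk(-750, 21)   # 4 points + incomplete block
  expect_warning(tc <- ltp_timecourse(base, post), "incomplete")
  expect_equal(sum(tc$times_min < 0), 6)
  expect_equal(sum(tc$times_min > 0), 4)
  expect_equal(unname(tc$pct_baseline[tc$times_min > 0]), rep(150, 4),
               tolerance = 1e-6)
  expect_error(ltp_timecourse(mk(-500, 25), post), ">= 6 baseline")
})

test_that("window statistics select inclusive windows on the 2.5-min grid", {
  tc <- ltp_timecourse_from_slopes(rep(500, 6), rep(500, 36))
  expect_equal(window_stats(tc, c(0, 90))$mean_pct, 100)
  w <- window_stats(tc, c(70, 90))
  expect_equal(w$times_min, seq(70, 90, 2.5))
  # sub-spacing induction window resolves to the first post point's block
  ind <- window_stats(tc, c(0, 1))
  expect_equal(ind$times_min, 2.5)
  expect_length(ind$values, 1)
  expect_error(window_stats(tc, c(200, 300)), "no time points")
})
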