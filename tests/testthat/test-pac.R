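test_that("analytic signal of a tone has constant envelope and linear phase", {
  fs <- 512
  t <- (0:(60 * fs - 1)) / fs
  x <- 3.2 * cos(2 * pi * 12 * t)
  ab <- analytic_band(x, fs, 12, 4)
  expect_equal(mean(ab$envelope), 3.2, tolerance = 1e-3)
  expect_lt(sd(ab$envelope) / mean(ab$envelope), 1e-3)
  dph <- diff(ab$phase)
  dph <- dph[dph > -pi]                     # unwrap
  expect_equal(mean(dph), 2 * pi * 12 / fs, tolerance = 1e-4)
  expect_true(all(ab$envelope >= 0))
  expect_true(all(ab$phase > -pi & ab$phase <= pi))
})

test_that("envelope recovers amplitude modulation when sidebands pass", {
  fs <- 512; fL <- 7; fH <- 60; m <- 0.8
  t <- (0:(60 * fs - 1)) / fs
  x <- (1 + m * cos(2 * pi * fL * t)) * cos(2 * pi * fH * t)
  true_env <- 1 + m * cos(2 * pi * fL * t)
  keep <- (fs + 1):(length(t) - fs)
  wide <- analytic_band(x, fs, fH, bandwidth = 2 * fL + 4)
  expect_gt(cor(wide$envelope, true_env[keep]), 0.99)
  # bandwidth below 2*fL excludes the sidebands: modulation attenuated
  narrow <- analytic_band(x, fs, fH, bandwidth = fL)
  expect_lt(sd(narrow$envelope), 0.25 * sd(wide$envelope))
})

test_that("modulation index matches closed-form and linearity properties", {
  n <- 200000
  phase <- seq(-pi, pi, length.out = n + 1)[-1]    # uniform over full cycles
  # constant envelope, uniform phase: symmetric phasors cancel
  expect_lt(modulation_index(phase, rep(2, n)), 1e-9)
  # envelope 1 + cos(phase): dense numerical integration oracle
  env <- 1 + cos(phase)
  oracle_raw <- Mod(sum(env * exp(1i * phase)) / n)        # -> 0.5
  oracle_norm <- oracle_raw / mean(env)                     # -> 0.5
  expect_equal(modulation_index(phase, env, normalize = FALSE), oracle_raw)
  expect_equal(modulation_index(phase, env), oracle_norm)
  expect_equal(oracle_norm, 0.5, tolerance = 1e-4)
  # doubling the envelope doubles raw MI, leaves normalized MI unchanged
  expect_equal(modulation_index(phase, 2 * env, normalize = FALSE),
               2 * modulation_index(phase, env, normalize = FALSE))
  expect_equal(modulation_index(phase, 2 * env), modulation_index(phase, env))
  expect_error(modulation_index(numeric(0), numeric(0)), "non-empty")
  expect_error(modulation_index(c(1, NA), c(1, 1)), "NA")
})

test_that("comodulogram flags non-estimable cells as NA, never zero", {
  rec <- gen_coupled_lfp(lfp_sim_config(duration_s = 20, seed = 1))
  par <- pac_params(fL_grid = c(1, 7, 50), fH_grid = c(20, 60, 240, 254))
  cm <- comodulogram(rec, params = par)
  expect_true(all(is.na(cm$mi["1", ])))          # phase band would reach 0 Hz
  expect_true(all(is.na(cm$mi[, "254"])))        # 254 + bw/2 >= Nyquist for all rows
  expect_true(is.na(cm$mi["50", "240"]))         # bw = 104 Hz pushes past Nyquist
  expect_false(is.na(cm$mi["7", "240"]))         # bw = 18 Hz still fits
  expect_true(is.na(cm$mi["50", "20"]))          # f_H <= f_L
  expect_false(anyNA(cm$mi["7", c("20", "60")]))
  expect_true(all(cm$mi["7", c("20", "60")] >= 0))
})

test_that("comodulogram recovers synthetic coupling at (7, 60)", {
  rec <- gen_coupled_lfp(lfp_sim_config(duration_s = 60, phase_freq = 7,
                                        amp_freq = 60, mod_depth = 1, seed = 3))
  cm <- comodulogram(rec, params = test_pac_params())
  pk <- comod_peak(cm)
  expect_lte(abs(pk$fL - 7), 2)
  expect_lte(abs(pk$fH - 60), 5)
  expect_true(all(cm$mi <= 1, na.rm = TRUE))     # normalized MI bounded
})

test_that("theta-gamma summary averages exactly the in-band cells", {
  rec <- gen_coupled_lfp(lfp_sim_config(duration_s = 20, seed = 2))
  cm <- comodulogram(rec, params = pac_params(fL_grid = c(3, 5, 7, 9, 11),
                                              fH_grid = seq(30, 110, 10)))
  cm0 <- cm
  cm0$mi[] <- 0
  expect_equal(theta_gamma_pac(cm0), 0)
  cmc <- cm
  cmc$mi[] <- 0.37
  expect_equal(theta_gamma_pac(cmc), 0.37)
  # manual band membership: fL in {5,7}? no - 4..8 inclusive -> {5,7}; fH 40..100
  manual <- mean(cm$mi[cm$fL_grid %in% c(5, 7), cm$fH_grid >= 40 & cm$fH_grid <= 100])
  expect_equal(theta_gamma_pac(cm), manual)
  expect_error(theta_gamma_pac(cm, phase_band = c(200, 300)), "do not intersect")
})

test_that("coupling at (7,60) raises the theta-gamma summary more than (7,150)", {
  par <- pac_params(fL_grid = seq(3, 11, 2), fH_grid = seq(40, 160, 10))
  cm_in <- comodulogram(gen_coupled_lfp(lfp_sim_config(
    duration_s = 30, amp_freq = 60, mod_depth = 1, seed = 6)), params = par)
  cm_out <- comodulogram(gen_coupled_lfp(lfp_sim_config(
    duration_s = 30, amp_freq = 150, mod_depth = 1, seed = 6)), params = par)
  expect_gt(theta_gamma_pac(cm_in), theta_gamma_pac(cm_out))
})

test_that("surrogate null separates coupled from uncoupled stochastic signals", {
  # A drifting (random-walk) phase, as in real theta, so that circular
  # time shifts genuinely destroy phase-amplitude alignment. (For a
  # strictly periodic carrier a shift only rotates the composite vector
  # and the time-shift null is blind by construction.)
  set.seed(8)
  n <- 30000
  dphi <- 2 * pi * 7 / 512 * (1 + 0.5 * rnorm(n))
  phase <- ((cumsum(dphi) + pi) %% (2 * pi)) - pi
  env <- 1 + cos(phase) + 0.1 * rnorm(n)
  mi <- modulation_index(phase, env)
  nul <- surrogate_null(phase, env, n_surrogates = 99, seed = 1)
  expect_gt(mi, nul$threshold)
  expect_equal(nul$null, sort(nul$null))

  # uncoupled: observed MI sits inside its own null distribution
  env0 <- 1 + 0.3 * abs(rnorm(n))
  mi0 <- modulation_index(phase, env0)
  nul0 <- surrogate_null(phase, env0, n_surrogates = 99, seed = 2)
  expect_lt(mi0, max(nul0$null) * 1.5)

  expect_error(surrogate_null(phase, env, n_surrogates = 0), ">= 19")
  expect_error(surrogate_null(1, 1, n_surrogates = 20), ">= 2 samples")
})

test_that("normalized theta-gamma MI increases with modulation depth", {
  par <- pac_params(fL_grid = c(5, 7, 9), fH_grid = seq(40, 100, 10))
  mi_at_depth <- function(d) mean(vapply(1:5, function(s) {
    rec <- gen_coupled_lfp(lfp_sim_config(duration_s = 30, mod_depth = d,
                                          seed = 100 + s))
    theta_gamma_pac(comodulogram(rec, params = par))
  }, numeric(1)))
  mis <- vapply(c(0, 0.5, 1), mi_at_depth, numeric(1))
  expect_true(all(diff(mis) > 0))
})
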