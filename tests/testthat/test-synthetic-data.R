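test_that("session parameter validation rejects degenerate settings", {
  expect_error(session_params(duration_s = 30), "exceed 60")
  expect_error(session_params(eeg_fs = 0), "positive")
  expect_error(session_params(hr_bpm = 20), "30, 200")
  expect_error(session_params(alpha_gain_cp = 0), "> 0")
  expect_error(generate_eeg(session_params(), channels = c("Cz", "NOPE")),
               "unknown channel")
})

test_that("identical seed and parameters give bit-identical streams", {
  p <- quick_params(seed = 42)
  a <- simulate_session(p, channels = c("Cz", "Pz"))
  b <- simulate_session(p, channels = c("Cz", "Pz"))
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$ecg, b$ecg)
  expect_identical(a$eog, b$eog)
  expect_identical(a$fnirs, b$fnirs)
  expect_identical(a$ground_truth$blink_times_s, b$ground_truth$blink_times_s)
  d <- simulate_session(quick_params(seed = 43), channels = c("Cz", "Pz"))
  expect_false(identical(a$eeg, d$eeg))
})

test_that("a pure 10 Hz tone yields alpha RPL ~ 1 downstream", {
  p <- quick_params(eeg_band_amps = c(delta = 0, theta = 0, alpha = 0,
                                      beta = 0, gamma = 0),
                    eeg_noise_sd = 0, eeg_tone_hz = 10, eeg_tone_amp = 20)
  ee <- generate_eeg(p, channels = "Cz")
  psd <- compute_psd(ee$eeg[1:(10 * 128), 1], 128)
  rpl <- compute_rpl(psd)
  expect_gt(rpl$rpl[rpl$band == "alpha"], 0.99)
  expect_lt(max(rpl$rpl[rpl$band != "alpha"]), 0.01)
})

test_that("white-noise-only EEG has RPLs near the flat-spectrum bandwidth ratios", {
  # analytic oracle: flat PSD over the five bands -> RPL_b = bandwidth_b / 49
  p <- session_params(duration_s = 300, eeg_fs = 128,
                      eeg_band_amps = c(delta = 0, theta = 0, alpha = 0,
                                        beta = 0, gamma = 0),
                      eeg_noise_sd = 5, seed = 11)
  ee <- generate_eeg(p, channels = "Cz")
  trials <- segment_trials(300)
  rpl <- channel_rpl(ee$eeg, 128, trials)
  mean_rpl <- tapply(rpl$rpl, rpl$band, mean)
  expected <- c(delta = 3, theta = 4, alpha = 5, beta = 17, gamma = 20) / 49
  expect_equal(mean_rpl[names(expected)], expected, tolerance = 0.06,
               ignore_attr = TRUE)
})

test_that("regional alpha gain strictly raises alpha RPL on gained channels", {
  p <- quick_params(ctor = sleep_deprived_params, alpha_gain_cp = 2, seed = 5)
  ee <- generate_eeg(p, channels = c("CP4", "Fp1"))  # gained vs plain channel
  trials <- segment_trials(120)
  rpl <- channel_rpl(ee$eeg, 128, trials)
  alpha <- tapply(rpl$rpl[rpl$band == "alpha"], rpl$channel[rpl$band == "alpha"],
                  mean)
  expect_gt(alpha[["CP4"]], alpha[["Fp1"]])
})

test_that("noiseless ECG produces the exact expected ground-truth peak counts", {
  p1 <- quick_params(hr_bpm = 60, hr_slope_bpm_per_min = 0, ecg_noise_sd = 0,
                     ecg_jitter_sd = 0, duration_s = 61)
  g1 <- generate_ecg(p1)
  expect_equal(sum(g1$r_peak_times_s < 60), 60)
  expect_true(all(diff(g1$r_peak_times_s) > 0))

  p2 <- quick_params(hr_bpm = 70, hr_slope_bpm_per_min = 0, ecg_noise_sd = 0,
                     ecg_jitter_sd = 0)
  g2 <- generate_ecg(p2)
  expect_equal(sum(g2$r_peak_times_s < 60), 70)
})

test_that("the detector recovers the generated heart rate within 1 bpm under noise", {
  p <- quick_params(hr_bpm = 70, ecg_noise_sd = 0.05, seed = 9)
  g <- generate_ecg(p)
  rec_hr <- ecg_heart_rate(cbind(ECG1 = g$ecg[, 1], ECG2 = g$ecg[, 2]),
                           128, 120)
  truth_per_min <- c(sum(g$r_peak_times_s < 60),
                     sum(g$r_peak_times_s >= 60 & g$r_peak_times_s < 120))
  expect_true(all(abs(rec_hr$bpm - truth_per_min) <= 1))
})

test_that("blink generation matches its Poisson specification and determinism", {
  p0 <- quick_params(blink_rate_per_min = 0)
  expect_length(generate_eog(p0)$blink_times_s, 0)

  p <- session_params(duration_s = 1800, eeg_fs = 32, blink_rate_per_min = 15,
                      seed = 21)
  bt <- generate_eog(p)$blink_times_s
  # Poisson mean 450, sd ~21; 4 sd window
  expect_gt(length(bt), 450 - 85)
  expect_lt(length(bt), 450 + 85)
  expect_true(all(diff(bt) > 0))
  expect_true(all(bt >= 0 & bt < 1800))
  expect_identical(bt, generate_eog(p)$blink_times_s)
})

test_that("noiseless fNIRS intensities are constant at baseline", {
  p <- quick_params(hbo_trend_mM_per_min = 0, hbo_noise_sd = 0,
                    hbo_osc_amp = 0, fnirs_noise_sd = 0, fnirs_drift_amp = 0)
  fn <- generate_fnirs_intensities(p)
  for (ch in c("ch1_735", "ch5_850")) {
    expect_lt(diff(range(fn$intensity[[ch]])), 1e-9)
  }
})

test_that("a positive HbO trend increases 850 nm attenuation over time", {
  # epsilon_HbO(850) = 1.1596 > epsilon_HbR(850) = 0.7861, so HbO up /
  # HbR down must dim the 850 nm channel
  p <- quick_params(hbo_trend_mM_per_min = 0.02, hbo_noise_sd = 0,
                    hbo_osc_amp = 0, fnirs_noise_sd = 0, fnirs_drift_amp = 0)
  fn <- generate_fnirs_intensities(p)
  x <- fn$intensity$ch1_850
  expect_lt(mean(tail(x, 100)), mean(head(x, 100)))
})

test_that("an overwhelming trend raises a non-positive-intensity error", {
  p <- quick_params(hbo_trend_mM_per_min = 0.02, fnirs_noise_sd = 600)
  expect_error(generate_fnirs_intensities(p), "non-positive")
})

test_that("condition presets order every DCL feature in the fatigue direction", {
  pw <- quick_params(well_rested_params, duration_s = 300, seed = 31)
  ps <- quick_params(sleep_deprived_params, duration_s = 300, seed = 131)
  ch <- c("CP4", "P4", "FCz", "Cz")
  w <- generate_eeg(pw, ch)
  s <- generate_eeg(ps, ch)
  trials <- segment_trials(300)
  regions <- region_spec(alpha_region = c("CP4", "P4"),
                         beta_region = c("FCz", "Cz"))
  fw <- region_features(channel_rpl(w$eeg, 128, trials), regions)
  fsd <- region_features(channel_rpl(s$eeg, 128, trials), regions)
  expect_gt(mean(fsd$alpha_cp), mean(fw$alpha_cp))   # alpha up when deprived
  expect_gt(mean(fw$beta_fc), mean(fsd$beta_fc))     # beta down when deprived
  expect_gt(mean(fw$beta_over_alpha), mean(fsd$beta_over_alpha))
  expect_gt(length(generate_ecg(pw)$r_peak_times_s),
            length(generate_ecg(ps)$r_peak_times_s))
  expect_gt(mean(generate_fnirs_intensities(pw)$true_hbo),
            mean(generate_fnirs_intensities(ps)$true_hbo))
})
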