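test_that("baseline is the mean over the first 30 s only", {
  tbl <- constant_intensity(n = 600)
  b <- compute_baseline(tbl)
  expect_equal(nrow(b), 16)
  expect_true(all(b$baseline == 1000))

  # ramp 1000 -> 1060 over the 30 s window: mean 1030
  ramp <- constant_intensity(n = 600)
  ramp$ch1_735 <- seq(1000, 1000 + 60 / 299 * 599, length.out = 600)
  b2 <- compute_baseline(ramp)
  expect_equal(b2$baseline[b2$channel == "ch1" & b2$wavelength_nm == 735],
               mean(seq(1000, 1060, length.out = 300)), tolerance = 1e-9)

  # data after t = 30 s cannot move the baseline
  late <- constant_intensity(n = 600)
  late$ch1_735[400:600] <- 5000
  expect_equal(compute_baseline(late)$baseline,
               compute_baseline(constant_intensity(n = 600))$baseline)

  expect_error(compute_baseline(constant_intensity(n = 100)), "at least 30")
})

test_that("mBLL conversion reproduces the worked two-wavelength example", {
  baseline <- compute_baseline(constant_intensity(n = 400))  # clean 1000 a.u.
  tbl <- constant_intensity(n = 400)
  tbl[2, paste0("ch", 1:8, "_735")] <- 900
  tbl[2, paste0("ch", 1:8, "_850")] <- 800
  h <- mbll_convert(tbl, baseline)
  at0 <- h[h$time_s == 0 & h$channel == "ch1", ]
  expect_equal(at0$dhbo, 0)
  expect_equal(at0$dhbr, 0)
  at1 <- h[h$time_s == 0.1 & h$channel == "ch1", ]
  # independent oracle: solve OD = d * E %*% c for c
  od <- c(log10(1000 / 900), log10(1000 / 800))
  E <- rbind(c(0.4646, 1.2959), c(1.1596, 0.7861))
  conc <- solve(3 * E, od)
  expect_equal(at1$dhbo, conc[1], tolerance = 1e-12)
  expect_equal(at1$dhbr, conc[2], tolerance = 1e-12)
  expect_equal(round(c(at1$dhbo, at1$dhbr), 4), c(0.0263, 0.0024))
})

test_that("mBLL closed form equals the 2x2 linear-solve oracle on random inputs", {
  set.seed(99)
  mp <- mbll_params()
  E <- rbind(mp$eps_hbo, mp$eps_hbr)    # 2x2, columns = wavelengths
  worst <- 0
  for (i in 1:1000) {
    ib <- runif(2, 500, 2000)
    it <- ib * exp(runif(2, -0.3, 0.3))
    tbl <- constant_intensity(n = 301)
    tbl$ch1_735[301] <- it[1]
    tbl$ch1_850[301] <- it[2]
    bl <- compute_baseline(tbl)
    bl$baseline[bl$channel == "ch1"] <- ib
    h <- mbll_convert(tbl, bl)
    got <- unlist(h[h$channel == "ch1" & h$time_s == 30,
                    c("dhbo", "dhbr")])
    od <- log10(ib / it)
    want <- solve(mp$d_cm * t(E), od)
    # relative to the solution scale (a per-component ratio is meaningless
    # when cancellation drives one component to ~0)
    worst <- max(worst, max(abs(got - want)) / max(sqrt(sum(want^2)), 1e-12))
  }
  expect_lt(worst, 1e-12)
})

test_that("conversion is linear in optical density and validates inputs", {
  tbl <- constant_intensity(n = 400)
  tbl$ch1_735[5] <- 1000 * 10^(-0.05)
  tbl$ch1_850[5] <- 1000 * 10^(-0.08)
  tbl2 <- constant_intensity(n = 400)
  tbl2$ch1_735[5] <- 1000 * 10^(-0.10)
  tbl2$ch1_850[5] <- 1000 * 10^(-0.16)
  b <- compute_baseline(constant_intensity(n = 400))   # clean baseline
  h1 <- mbll_convert(tbl, b)[5, c("dhbo", "dhbr")]
  h2 <- mbll_convert(tbl2, b)[5, c("dhbo", "dhbr")]
  expect_equal(unlist(h2), 2 * unlist(h1), tolerance = 1e-9)

  bad <- constant_intensity(n = 400)
  bad$ch1_735[10] <- -1
  expect_error(mbll_convert(bad, b), "non-positive")
  expect_error(mbll_params(eps_hbo = c(1, 1), eps_hbr = c(1, 1)), "singular")
})

test_that("the forward model round-trips through mbll_convert to 1e-9", {
  p <- quick_params(hbo_trend_mM_per_min = 0.02, hbo_noise_sd = 0,
                    fnirs_noise_sd = 0, fnirs_drift_amp = 0, seed = 12)
  fn <- generate_fnirs_intensities(p)
  h <- mbll_convert(fn$intensity, baseline_from_truth(fn$baseline))
  for (ch in c(1, 5, 8)) {
    hc <- h[h$channel == paste0("ch", ch), ]
    expect_lt(max(abs(hc$dhbo - fn$true_hbo[, ch])), 1e-9)
    expect_lt(max(abs(hc$dhbr - fn$true_hbr[, ch])), 1e-9)
  }
})

test_that("a drop at 850 nm alone reads as HbO up, HbR down", {
  tbl <- constant_intensity(n = 400)
  tbl$ch1_850[50:400] <- 950
  h <- mbll_convert(tbl, compute_baseline(tbl))
  at <- h[h$channel == "ch1" & h$time_s == 10, ]
  expect_gt(at$dhbo, 0)
  expect_lt(at$dhbr, 0)
})

test_that("drift high-pass attenuates slow drift and passes 0.1 Hz", {
  fs <- 10
  tt <- (0:5999) / fs
  slow <- sin(2 * pi * 0.001 * tt)
  expect_lt(sd(drift_highpass(slow, fs)) / sd(slow), 0.2)
  fast <- sin(2 * pi * 0.1 * tt)
  expect_equal(sd(drift_highpass(fast, fs)) / sd(fast), 1, tolerance = 0.1)
})

test_that("overlapping-window smoothing preserves means and kills fast ripple", {
  fs <- 10
  n <- 1200
  expect_equal(smooth_overlap(rep(2.5, n), fs), rep(2.5, n))
  tt <- (0:(n - 1)) / fs
  ripple <- sin(2 * pi * 1 * tt)
  expect_lt(sqrt(mean(smooth_overlap(ripple, fs)^2)) / sqrt(mean(ripple^2)),
            0.1)
  ramp <- seq(0, 10, length.out = n)
  sm <- smooth_overlap(ramp, fs)
  mid <- 100:1100
  expect_lt(max(abs(sm[mid] - ramp[mid])), 0.01 * diff(range(ramp)))
  expect_error(smooth_overlap(rnorm(50), fs), "shorter than one smoothing")
})

test_that("per-trial hemodynamic amplitudes track the generating trend", {
  trials <- segment_trials(1800)
  hemo <- tidyr::expand_grid(channel = paste0("ch", 1:2),
                             time_s = seq(0, 1799.9, 0.1)) %>%
    dplyr::mutate(dhbo = 0.5, dhbr = -0.2)
  amp <- hbo_trial_amplitude(hemo, trials)
  expect_equal(nrow(amp), 180)
  expect_true(all(abs(amp$hbo - 0.5) < 1e-12))

  p <- quick_params(duration_s = 300, hbo_trend_mM_per_min = 0.01,
                    hbo_noise_sd = 0, hbo_osc_amp = 0, fnirs_noise_sd = 0,
                    fnirs_drift_amp = 0, seed = 13)
  fn <- generate_fnirs_intensities(p)
  h <- mbll_convert(fn$intensity, baseline_from_truth(fn$baseline))
  amp2 <- hbo_trial_amplitude(h, segment_trials(300))
  expect_true(all(diff(amp2$hbo) > 0))

  expect_error(hbo_trial_amplitude(h, segment_trials(900)), "beyond")
})
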