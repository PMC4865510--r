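#' Parameters of a synthetic driving session
#'
#' Bundles every knob of the multimodal signal generator: session geometry
#' (duration, sampling rates), the condition-dependent physiology (heart rate
#' and its drift, regional alpha/beta band gains, the hemodynamic trend,
#' blink rate) and per-stream noise/drift levels. Use
#' [well_rested_params()] / [sleep_deprived_params()] for the two study
#' presets; `session_params()` is the fully explicit constructor.
#'
#' @param condition `"well_rested"` or `"sleep_deprived"`.
#' @param duration_s Session length in seconds (> 60).
#' @param eeg_fs Electrophysiology sampling rate in Hz (EEG/EOG/ECG share it).
#' @param fnirs_fs fNIRS sampling rate in Hz.
#' @param hr_bpm Mean heart rate at session start, beats/min (30-200).
#' @param hr_slope_bpm_per_min Linear heart-rate drift, beats/min per minute.
#' @param alpha_gain_cp Multiplier on alpha-band amplitude over the
#'   centro-parietal region channels (dimensionless, > 0).
#' @param beta_gain_fc Multiplier on beta-band amplitude over the
#'   fronto-central region channels (> 0).
#' @param hbo_trend_mM_per_min Linear trend of the true oxy-hemoglobin change,
#'   mM/DPF per minute.
#' @param blink_rate_per_min Mean blink rate (Poisson), events/min (>= 0).
#' @param eeg_band_amps Named numeric: per-band RMS amplitude (uV) of the
#'   band-limited noise processes summed into each EEG channel. Set all to 0
#'   for a noise- or tone-only channel.
#' @param eeg_noise_sd White sensor noise added to each EEG channel, uV.
#' @param eeg_tone_hz,eeg_tone_amp Optional pure sinusoid mixed into every EEG
#'   channel (amplitude in uV); `eeg_tone_amp = 0` disables it.
#' @param ecg_noise_sd Additive ECG noise, relative to the 1 mV R amplitude.
#' @param ecg_jitter_sd Beat-to-beat timing jitter, seconds.
#' @param eog_noise_sd Additive EOG noise, uV.
#' @param eog_drift_amp Amplitude of the slow EOG baseline wander, uV.
#' @param blink_amp_uV Blink waveform amplitude on the vertical channel, uV.
#' @param fnirs_baseline Baseline light intensity, arbitrary units (> 0).
#' @param fnirs_noise_sd Additive intensity sensor noise, a.u.
#' @param fnirs_drift_amp Log-amplitude of the multiplicative slow exponential
#'   intensity drift (dimensionless).
#' @param fnirs_drift_tau_s Drift time constant, seconds (>= 600).
#' @param hbo_noise_sd Sample-to-sample noise on the true HbO series, mM/DPF.
#' @param hbo_osc_amp,hbo_osc_hz Slow sinusoidal physiological component of
#'   the true HbO series (mM/DPF, Hz).
#' @param regions A [region_spec()] naming the gained channels.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output. Per-modality substreams are derived deterministically.
#' @return A list of class `session_params`.
#' @export
session_params <- function(condition = c("well_rested", "sleep_deprived"),
                           duration_s = 1800,
                           eeg_fs = 512,
                           fnirs_fs = 10,
                           hr_bpm = 70,
                           hr_slope_bpm_per_min = 0,
                           alpha_gain_cp = 1,
                           beta_gain_fc = 1,
                           hbo_trend_mM_per_min = 0,
                           blink_rate_per_min = 12,
                           eeg_band_amps = c(delta = 5, theta = 4, alpha = 6,
                                             beta = 3.5, gamma = 1.5),
                           eeg_noise_sd = 2,
                           eeg_tone_hz = 10,
                           eeg_tone_amp = 0,
                           ecg_noise_sd = 0.02,
                           ecg_jitter_sd = 0.01,
                           eog_noise_sd = 5,
                           eog_drift_amp = 30,
                           blink_amp_uV = 200,
                           fnirs_baseline = 1000,
                           fnirs_noise_sd = 0.5,
                           fnirs_drift_amp = 0.05,
                           fnirs_drift_tau_s = 600,
                           hbo_noise_sd = 0.003,
                           hbo_osc_amp = 0.02,
                           hbo_osc_hz = 0.02,
                           regions = region_spec(),
                           seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(duration_s), is.numeric(eeg_fs), is.numeric(fnirs_fs))
  if (duration_s <= 60) stop("duration_s must exceed 60 s", call. = FALSE)
  if (eeg_fs <= 0 || fnirs_fs <= 0) stop("sampling rates must be positive", call. = FALSE)
  if (hr_bpm < 30 || hr_bpm > 200) stop("hr_bpm must lie in [30, 200]", call. = FALSE)
  if (alpha_gain_cp <= 0 || beta_gain_fc <= 0) stop("band gains must be > 0", call. = FALSE)
  if (blink_rate_per_min < 0) stop("blink_rate_per_min must be >= 0", call. = FALSE)
  if (fnirs_baseline <= 0) stop("fnirs_baseline must be > 0", call. = FALSE)
  if (!all(c("delta", "theta", "alpha", "beta", "gamma") %in% names(eeg_band_amps))) {
    stop("eeg_band_amps must name all five bands", call. = FALSE)
  }
  if (!inherits(regions, "region_spec")) stop("regions must be a region_spec", call. = FALSE)
  structure(
    list(condition = condition, duration_s = duration_s, eeg_fs = eeg_fs,
         fnirs_fs = fnirs_fs, hr_bpm = hr_bpm,
         hr_slope_bpm_per_min = hr_slope_bpm_per_min,
         alpha_gain_cp = alpha_gain_cp, beta_gain_fc = beta_gain_fc,
         hbo_trend_mM_per_min = hbo_trend_mM_per_min,
         blink_rate_per_min = blink_rate_per_min,
         eeg_band_amps = eeg_band_amps[c("delta", "theta", "alpha", "beta", "gamma")],
         eeg_noise_sd = eeg_noise_sd, eeg_tone_hz = eeg_tone_hz,
         eeg_tone_amp = eeg_tone_amp, ecg_noise_sd = ecg_noise_sd,
         ecg_jitter_sd = ecg_jitter_sd, eog_noise_sd = eog_noise_sd,
         eog_drift_amp = eog_drift_amp, blink_amp_uV = blink_amp_uV,
         fnirs_baseline = fnirs_baseline, fnirs_noise_sd = fnirs_noise_sd,
         fnirs_drift_amp = fnirs_drift_amp, fnirs_drift_tau_s = fnirs_drift_tau_s,
         hbo_noise_sd = hbo_noise_sd, hbo_osc_amp = hbo_osc_amp,
         hbo_osc_hz = hbo_osc_hz, regions = regions, seed = as.integer(seed)),
    class = "session_params"
  )
}

#' Condition presets for the two driving sessions
#'
#' `well_rested_params()` encodes the alert-driver physiology: heart rate
#' near 70 bpm that eases down over the half hour, a positive prefrontal HbO
#' trend (cerebral blood flow rising while attending to the task) and a
#' fronto-central beta gain above 1. `sleep_deprived_params()` encodes the
#' fatigued driver: heart rate near 62 bpm, an essentially flat/slightly
#' negative HbO trend, and a centro-parietal alpha gain above 1. With unit
#' DCL weights these presets order every index component the same way the
#' two conditions order in real recordings.
#'
#' @param ... Overrides forwarded to [session_params()].
#' @param seed Integer seed.
#' @return A `session_params` object.
#' @export
well_rested_params <- function(..., seed = 1L) {
  defaults <- list(condition = "well_rested", hr_bpm = 70,
                   hr_slope_bpm_per_min = -0.15, alpha_gain_cp = 1,
                   beta_gain_fc = 1.4, hbo_trend_mM_per_min = 0.015,
                   blink_rate_per_min = 12, seed = seed)
  do.call(session_params, utils::modifyList(defaults, list(...)))
}

#' @rdname well_rested_params
#' @export
sleep_deprived_params <- function(..., seed = 1L) {
  defaults <- list(condition = "sleep_deprived", hr_bpm = 62,
                   hr_slope_bpm_per_min = 0, alpha_gain_cp = 1.5,
                   beta_gain_fc = 1, hbo_trend_mM_per_min = -0.002,
                   blink_rate_per_min = 15, seed = seed)
  do.call(session_params, utils::modifyList(defaults, list(...)))
}

# band-limited noise with unit RMS: white noise -> 4th-order Butterworth
# band-pass (zero phase), rescaled to sd 1
band_noise <- function(n, fs, lo, hi) {
  hi <- min(hi, fs / 2 * 0.99)
  if (lo >= hi) return(numeric(n))
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

#' Generate synthetic multichannel EEG
#'
#' Each channel is a sum of five band-limited noise processes (one per
#' canonical band, 4th-order Butterworth band-passed white noise) plus white
#' sensor noise and an optional calibration tone. Channels in the
#' centro-parietal region have their alpha amplitude multiplied by
#' `alpha_gain_cp` and fronto-central channels their beta amplitude by
#' `beta_gain_fc`, reproducing the regional band-power contrasts between the
#' two driving conditions.
#'
#' @param params A [session_params()] object.
#' @param channels Channel labels to synthesize (default: full 64-channel
#'   montage). Unknown labels are an error.
#' @return List with `eeg` (samples x channels matrix, uV, labeled columns)
#'   and `band_amplitudes` (tibble channel/band/amplitude of the generating
#'   RMS amplitudes, the spectral ground truth).
#' @export
generate_eeg <- function(params, channels = montage_channels()) {
  stopifnot(inherits(params, "session_params"))
  unknown <- setdiff(channels, .montage_64)
  if (length(unknown) > 0) {
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- round(params$duration_s * params$eeg_fs)
  fs <- params$eeg_fs
  bands <- .eeg_bands
  with_substream(params$seed, 101L, {
    eeg <- matrix(0, nrow = n, ncol = length(channels),
                  dimnames = list(NULL, channels))
    truth <- vector("list", length(channels))
    tone <- if (params$eeg_tone_amp > 0) {
      params$eeg_tone_amp * sin(2 * pi * params$eeg_tone_hz * (seq_len(n) - 1) / fs)
    } else NULL
    for (j in seq_along(channels)) {
      ch <- channels[j]
      amps <- params$eeg_band_amps
      if (ch %in% params$regions$alpha_region) {
        amps["alpha"] <- amps["alpha"] * params$alpha_gain_cp
      }
      if (ch %in% params$regions$beta_region) {
        amps["beta"] <- amps["beta"] * params$beta_gain_fc
      }
      x <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        if (amps[[bands$band[b]]] > 0) {
          x <- x + amps[[bands$band[b]]] *
            band_noise(n, fs, bands$lo_hz[b], bands$hi_hz[b])
        }
      }
      if (params$eeg_noise_sd > 0) x <- x + rnorm(n, sd = params$eeg_noise_sd)
      if (!is.null(tone)) x <- x + tone
      eeg[, j] <- x
      truth[[j]] <- tibble(channel = ch, band = bands$band,
                           amplitude = unname(amps))
    }
    list(eeg = eeg, band_amplitudes = bind_rows(truth))
  })
}

# Mexican-hat (Ricker) QRS template sampled at fs; width ~80 ms
qrs_template <- function(fs, width_s = 0.08, amp_mV = 1) {
  sigma <- width_s / 5
  t <- seq(-width_s, width_s, by = 1 / fs)
  amp_mV * (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))
}

#' Generate synthetic ECG with ground-truth R-peak times
#'
#' A Mexican-hat QRS-like template train whose instantaneous rate is
#' `hr_bpm + hr_slope_bpm_per_min * t`, with optional beat-timing jitter and
#' additive sensor noise. Two chest channels are returned (the second is a
#' slightly attenuated copy with independent noise, as a contralateral
#' electrode would record).
#'
#' @param params A [session_params()] object.
#' @return List with `ecg` (samples x 2 matrix, mV, columns ECG1/ECG2) and
#'   `r_peak_times_s` (strictly increasing ground-truth peak times).
#' @export
generate_ecg <- function(params) {
  stopifnot(inherits(params, "session_params"))
  fs <- params$eeg_fs
  n <- round(params$duration_s * fs)
  with_substream(params$seed, 202L, {
    # beat times from the instantaneous rate, first beat at 0.5 s
    times <- numeric(0)
    t <- 0.5
    while (t < params$duration_s) {
      times <- c(times, t)
      rate <- params$hr_bpm + params$hr_slope_bpm_per_min * t / 60
      rate <- max(rate, 30)
      dt <- 60 / rate
      if (params$ecg_jitter_sd > 0) dt <- dt + rnorm(1, sd = params$ecg_jitter_sd)
      t <- t + max(dt, 0.25)
    }
    tmpl <- qrs_template(fs)
    half <- (length(tmpl) - 1) %/% 2
    x <- numeric(n)
    idx <- round(times * fs) + 1L
    for (i in idx) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      x[lo:hi] <- x[lo:hi] + tmpl[(lo - i + half + 1L):(hi - i + half + 1L)]
    }
    ecg <- cbind(ECG1 = x, ECG2 = 0.9 * x)
    if (params$ecg_noise_sd > 0) {
      ecg <- ecg + matrix(rnorm(2 * n, sd = params$ecg_noise_sd), ncol = 2)
    }
    list(ecg = ecg, r_peak_times_s = (idx - 1L) / fs)
  })
}

#' Generate synthetic EOG with ground-truth blink times
#'
#' Baseline wander plus stereotyped blink waveforms (250 ms raised-cosine
#' bumps on the vertical channel, with a small projection onto the horizontal
#' channel) at Poisson-distributed times with the configured rate.
#'
#' @param params A [session_params()] object.
#' @return List with `eog` (samples x 2 matrix, uV, columns EOGh/EOGv) and
#'   `blink_times_s` (strictly increasing, in `[0, duration_s)`).
#' @export
generate_eog <- function(params) {
  stopifnot(inherits(params, "session_params"))
  fs <- params$eeg_fs
  n <- round(params$duration_s * fs)
  with_substream(params$seed, 303L, {
    n_blinks <- rpois(1, params$blink_rate_per_min * params$duration_s / 60)
    blink_times <- sort(runif(n_blinks, min = 0.5, max = params$duration_s - 0.5))
    # enforce strict increase with a 300 ms minimum gap
    if (length(blink_times) > 1) {
      keep <- c(TRUE, diff(blink_times) > 0.3)
      blink_times <- blink_times[keep]
    }
    tt <- (seq_len(n) - 1) / fs
    drift <- params$eog_drift_amp * sin(2 * pi * 0.01 * tt + runif(1, 0, 2 * pi))
    v <- drift + rnorm(n, sd = params$eog_noise_sd)
    h <- 0.5 * drift + rnorm(n, sd = params$eog_noise_sd)
    # raised-cosine blink, 0.25 s
    bl <- round(0.25 * fs)
    bump <- params$blink_amp_uV * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = bl)))
    for (bt in blink_times) {
      i <- round(bt * fs) + 1L
      hi <- min(n, i + bl - 1L)
      seg <- seq.int(i, hi)
      v[seg] <- v[seg] + bump[seq_along(seg)]
      h[seg] <- h[seg] + 0.15 * bump[seq_along(seg)]
    }
    list(eog = cbind(EOGh = h, EOGv = v), blink_times_s = blink_times)
  })
}

#' Generate synthetic two-wavelength fNIRS intensities
#'
#' A ground-truth oxy-hemoglobin time course (linear trend per
#' `hbo_trend_mM_per_min`, a slow sinusoidal physiological component and
#' optional noise; the deoxy course is its scaled mirror, `-0.4 * HbO`) is
#' mapped *forward* through the Beer-Lambert attenuation model with the same
#' extinction coefficients, emitter-detector distance and DPF convention the
#' inverse conversion uses, then overlaid with a multiplicative slow
#' exponential drift and additive sensor noise.
#'
#' @param params A [session_params()] object.
#' @param mbll A [mbll_params()] object (forward-model constants).
#' @return List with `intensity` (wide tibble: `time_s`, `ch{1..8}_735`,
#'   `ch{1..8}_850`), `true_hbo` / `true_hbr` (samples x 8 matrices, mM/DPF)
#'   and `baseline` (per channel/wavelength baseline intensities).
#' @export
generate_fnirs_intensities <- function(params, mbll = mbll_params()) {
  stopifnot(inherits(params, "session_params"))
  fs <- params$fnirs_fs
  n <- round(params$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  with_substream(params$seed, 404L, {
    gains <- runif(8, 0.9, 1.1)              # channel-specific responsiveness
    phase <- runif(1, 0, 2 * pi)
    base_shape <- params$hbo_trend_mM_per_min * tt / 60 +
      params$hbo_osc_amp * sin(2 * pi * params$hbo_osc_hz * tt + phase)
    hbo <- sapply(gains, function(g) {
      g * base_shape + if (params$hbo_noise_sd > 0)
        rnorm(n, sd = params$hbo_noise_sd) else 0
    })
    hbr <- -0.4 * hbo
    drift <- exp(params$fnirs_drift_amp * (1 - exp(-tt / params$fnirs_drift_tau_s)))
    ib <- params$fnirs_baseline * matrix(runif(16, 0.95, 1.05), nrow = 8,
                                         dimnames = list(paste0("ch", 1:8),
                                                         c("735", "850")))
    inten <- matrix(0, nrow = n, ncol = 16)
    cols <- c(paste0("ch", 1:8, "_735"), paste0("ch", 1:8, "_850"))
    for (ch in 1:8) {
      for (w in 1:2) {
        od <- mbll$d_cm * mbll$dpf *
          (mbll$eps_hbo[w] * hbo[, ch] + mbll$eps_hbr[w] * hbr[, ch])
        x <- ib[ch, w] * drift * 10^(-od)
        if (params$fnirs_noise_sd > 0) x <- x + rnorm(n, sd = params$fnirs_noise_sd)
        inten[, (w - 1) * 8 + ch] <- x
      }
    }
    if (any(inten <= 0)) {
      stop("hemodynamic trend/noise too large: non-positive light intensity",
           call. = FALSE)
    }
    intensity <- as_tibble(inten, .name_repair = "minimal")
    names(intensity) <- cols
    intensity <- dplyr::bind_cols(tibble(time_s = tt), intensity)
    list(intensity = intensity, true_hbo = hbo, true_hbr = hbr, baseline = ib)
  })
}

#' Simulate a complete multimodal driving session
#'
#' Runs all four generators with deterministically derived RNG substreams and
#' assembles a `multimodal_recording` carrying the raw streams, the trigger
#' times and the generator's ground truth (R-peak times, blink times, true
#' hemodynamics, per-channel band amplitudes).
#'
#' @param params A [session_params()] object.
#' @param channels EEG channels to synthesize (default full montage).
#' @return A list of class `multimodal_recording` with elements `eeg`, `eog`,
#'   `ecg` (matrices at `eeg_fs`), `fnirs` (wide intensity tibble at
#'   `fnirs_fs`), `fs_eeg`, `fs_fnirs`, `triggers`, `condition`,
#'   `bad_channels`, `params` and `ground_truth`.
#' @export
simulate_session <- function(params, channels = montage_channels()) {
  stopifnot(inherits(params, "session_params"))
  ee <- generate_eeg(params, channels)
  ec <- generate_ecg(params)
  eo <- generate_eog(params)
  fn <- generate_fnirs_intensities(params)
  structure(
    list(
      eeg = ee$eeg, eog = eo$eog, ecg = ec$ecg,
      fnirs = fn$intensity,
      fs_eeg = params$eeg_fs, fs_fnirs = params$fnirs_fs,
      triggers = list(ephys = c(start = 0, end = params$duration_s),
                      fnirs = c(start = 0, end = params$duration_s)),
      condition = params$condition,
      bad_channels = character(0),
      params = params,
      ground_truth = list(
        r_peak_times_s = ec$r_peak_times_s,
        blink_times_s = eo$blink_times_s,
        true_hbo = fn$true_hbo,
        true_hbr = fn$true_hbr,
        fnirs_baseline = fn$baseline,
        band_amplitudes = ee$band_amplitudes
      )
    ),
    class = "multimodal_recording"
  )
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat("<multimodal_recording> condition:", x$condition, "\n")
  cat("  eeg:", ncol(x$eeg), "ch x", nrow(x$eeg), "samples @", x$fs_eeg, "Hz\n")
  cat("  eog/ecg: 2+2 ch; fnirs: 8 ch x 2 wavelengths x",
      nrow(x$fnirs), "samples @", x$fs_fnirs, "Hz\n")
  invisible(x)
}
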