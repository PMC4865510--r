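#' Constants of the modified Beer-Lambert conversion
#'
#' Wavelengths, hemoglobin extinction coefficients, emitter-detector
#' separation and the differential path length factor (DPF) used to convert
#' two-wavelength optical-density changes into oxy-/deoxy-hemoglobin
#' concentration changes. The DPF is unknown in continuous-wave fNIRS and is
#' conventionally folded into the concentration unit, so it defaults to 1 and
#' outputs carry the unit mM/DPF. The optical-density logarithm is base 10
#' (configurable).
#'
#' @param wavelengths_nm Two wavelengths, nm.
#' @param eps_hbo Extinction coefficients of HbO at the two wavelengths,
#'   mM^-1 cm^-1.
#' @param eps_hbr Extinction coefficients of HbR, mM^-1 cm^-1.
#' @param d_cm Emitter-detector separation, cm.
#' @param dpf Differential path length factor (dimensionless).
#' @param log_base Base of the optical-density logarithm (10 or `exp(1)`).
#' @return A list of class `mbll_params`.
#' @export
mbll_params <- function(wavelengths_nm = c(735, 850),
                        eps_hbo = c(0.4646, 1.1596),
                        eps_hbr = c(1.2959, 0.7861),
                        d_cm = 3, dpf = 1, log_base = 10) {
  stopifnot(length(wavelengths_nm) == 2, length(eps_hbo) == 2,
            length(eps_hbr) == 2, d_cm > 0, dpf > 0, log_base > 1)
  det <- eps_hbo[1] * eps_hbr[2] - eps_hbo[2] * eps_hbr[1]
  if (abs(det) < 1e-12) stop("extinction coefficient matrix is singular", call. = FALSE)
  structure(list(wavelengths_nm = wavelengths_nm, eps_hbo = eps_hbo,
                 eps_hbr = eps_hbr, d_cm = d_cm, dpf = dpf,
                 log_base = log_base, det = det),
            class = "mbll_params")
}

fnirs_channel_cols <- function() {
  c(paste0("ch", 1:8, "_735"), paste0("ch", 1:8, "_850"))
}

#' Baseline light intensities
#'
#' Per-channel, per-wavelength mean intensity over the first `window_s`
#' seconds of the recording (half-open window `[0, window_s)`). These serve
#' as the reference intensities of the Beer-Lambert conversion.
#'
#' @param intensity Wide intensity tibble with columns `time_s` and
#'   `ch{1..8}_{735,850}`.
#' @param window_s Baseline window length, seconds (default 30).
#' @return Tibble with columns `channel`, `wavelength_nm`, `baseline`.
#' @export
compute_baseline <- function(intensity, window_s = 30) {
  stopifnot(is.data.frame(intensity), "time_s" %in% names(intensity))
  if (max(intensity$time_s) < window_s) {
    stop("need at least ", window_s, " s of data for the baseline", call. = FALSE)
  }
  idx <- intensity$time_s < window_s
  out <- tidyr::pivot_longer(intensity[idx, , drop = FALSE], -"time_s",
                             names_to = c("channel", "wavelength_nm"),
                             names_pattern = "(ch\\d+)_(\\d+)",
                             values_to = "intensity") %>%
    mutate(wavelength_nm = as.numeric(.data$wavelength_nm)) %>%
    group_by(.data$channel, .data$wavelength_nm) %>%
    summarise(baseline = mean(.data$intensity), .groups = "drop")
  if (any(out$baseline <= 0)) stop("non-positive baseline intensity", call. = FALSE)
  out
}

#' Convert light intensities to hemoglobin concentration changes
#'
#' Applies the modified Beer-Lambert law: the optical-density change at each
#' wavelength, `OD = log(I_baseline / I_transient)`, is inverted through the
#' 2x2 extinction system to per-sample oxy- and deoxy-hemoglobin
#' concentration changes,
#' \deqn{\Delta HbO = \frac{OD_{\lambda 1}\,\varepsilon_{HbR,\lambda 2} -
#'   OD_{\lambda 2}\,\varepsilon_{HbR,\lambda 1}}{d \cdot DPF\,
#'   (\varepsilon_{HbO,\lambda 1}\varepsilon_{HbR,\lambda 2} -
#'    \varepsilon_{HbO,\lambda 2}\varepsilon_{HbR,\lambda 1})}}
#' and analogously for \eqn{\Delta HbR} with the HbO coefficients. With
#' `dpf = 1` the outputs carry the unit mM/DPF.
#'
#' @param intensity Wide intensity tibble (`time_s`, `ch{1..8}_{735,850}`),
#'   all values positive.
#' @param baseline Baseline tibble from [compute_baseline()] (or `NULL` to
#'   compute it from the first 30 s).
#' @param params A [mbll_params()] object.
#' @return Tidy hemodynamics tibble: `time_s`, `channel`, `dhbo`, `dhbr`
#'   (mM/DPF).
#' @export
mbll_convert <- function(intensity, baseline = NULL, params = mbll_params()) {
  stopifnot(inherits(params, "mbll_params"), is.data.frame(intensity))
  cols <- fnirs_channel_cols()
  missing_cols <- setdiff(c("time_s", cols), names(intensity))
  if (length(missing_cols) > 0) {
    stop("intensity table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(as.matrix(intensity[cols]) <= 0)) {
    stop("non-positive transient intensity", call. = FALSE)
  }
  if (is.null(baseline)) baseline <- compute_baseline(intensity)
  ib <- matrix(NA_real_, nrow = 8, ncol = 2,
               dimnames = list(paste0("ch", 1:8), c("735", "850")))
  for (i in seq_len(nrow(baseline))) {
    ib[baseline$channel[i], as.character(baseline$wavelength_nm[i])] <-
      baseline$baseline[i]
  }
  if (any(is.na(ib)) || any(ib <= 0)) stop("invalid baseline table", call. = FALSE)
  lb <- log(params$log_base)
  denom <- params$d_cm * params$dpf * params$det
  out <- vector("list", 8)
  for (ch in 1:8) {
    od1 <- log(ib[ch, "735"] / intensity[[paste0("ch", ch, "_735")]]) / lb
    od2 <- log(ib[ch, "850"] / intensity[[paste0("ch", ch, "_850")]]) / lb
    dhbo <- (od1 * params$eps_hbr[2] - od2 * params$eps_hbr[1]) / denom
    dhbr <- (od2 * params$eps_hbo[1] - od1 * params$eps_hbo[2]) / denom
    out[[ch]] <- tibble(time_s = intensity$time_s,
                        channel = paste0("ch", ch), dhbo = dhbo, dhbr = dhbr)
  }
  bind_rows(out)
}

#' Remove slow hemodynamic drift
#'
#' Zero-phase 0.01 Hz Butterworth high-pass applied per channel to a tidy
#' hemodynamics tibble (or to any numeric vector), removing baseline drifts
#' while leaving task-related fluctuations above ~0.01 Hz intact.
#'
#' @param hemo Tidy hemodynamics tibble from [mbll_convert()], or a numeric
#'   vector.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz High-pass cutoff (default 0.01 Hz).
#' @return Same shape as the input, filtered.
#' @export
drift_highpass <- function(hemo, fs, cutoff_hz = 0.01) {
  spec <- filter_spec("highpass", lo_hz = cutoff_hz, order = 4)
  if (is.numeric(hemo)) return(apply_filter(hemo, fs, spec))
  stopifnot(is.data.frame(hemo))
  hemo %>%
    group_by(.data$channel) %>%
    mutate(dhbo = apply_filter(.data$dhbo, fs, spec),
           dhbr = apply_filter(.data$dhbr, fs, spec)) %>%
    ungroup()
}

#' Smooth a series with overlapping temporal windows
#'
#' Window means over `window_s`-second windows hopped by
#' `window_s * (1 - overlap)` seconds, linearly interpolated back onto the
#' original sample grid. With the defaults (10-s windows, 50% overlap) this
#' suppresses fluctuations faster than ~0.1 Hz while preserving trends.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
smooth_overlap <- function(x, fs, window_s = 10, overlap = 0.5) {
  stopifnot(is.numeric(x), fs > 0, window_s > 0, overlap >= 0, overlap < 1)
  n <- length(x)
  wlen <- round(window_s * fs)
  if (n < wlen) stop("series shorter than one smoothing window", call. = FALSE)
  hop <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq(1L, n - wlen + 1L, by = hop)
  centers <- (starts + (wlen - 1) / 2 - 1) / fs
  means <- vapply(starts, function(s) mean(x[s:(s + wlen - 1L)]), numeric(1))
  tt <- (seq_len(n) - 1) / fs
  approx(centers, means, xout = tt, rule = 2)$y
}

#' Smooth a tidy hemodynamics tibble
#'
#' Convenience wrapper applying [smooth_overlap()] to the `dhbo` and `dhbr`
#' columns per channel.
#'
#' @inheritParams drift_highpass
#' @inheritParams smooth_overlap
#' @return Tibble of the same shape, smoothed.
#' @export
smooth_hemo <- function(hemo, fs, window_s = 10, overlap = 0.5) {
  stopifnot(is.data.frame(hemo))
  hemo %>%
    group_by(.data$channel) %>%
    mutate(dhbo = smooth_overlap(.data$dhbo, fs, window_s, overlap),
           dhbr = smooth_overlap(.data$dhbr, fs, window_s, overlap)) %>%
    ungroup()
}

#' Per-trial hemodynamic amplitudes
#'
#' Mean concentration change within each 10-s trial per channel, then
#' averaged over the 8 prefrontal channels: one HbO and one HbR amplitude
#' per trial, the fNIRS classification features.
#'
#' @param hemo Tidy hemodynamics tibble (`time_s`, `channel`, `dhbo`, `dhbr`).
#' @param trials A [segment_trials()] trial set.
#' @return Tibble with columns `trial`, `hbo`, `hbr` (mM/DPF).
#' @export
hbo_trial_amplitude <- function(hemo, trials) {
  stopifnot(is.data.frame(hemo), inherits(trials, "trial_set"))
  t_end <- max(hemo$time_s)
  last_needed <- trials$onsets_s[trials$n_trials] + trials$trial_len_s
  if (last_needed > t_end + 1 / 2) {
    stop("trial grid extends beyond the hemodynamic series", call. = FALSE)
  }
  hemo %>%
    mutate(trial = trial_of(.data$time_s, trials)) %>%
    filter(!is.na(.data$trial)) %>%
    group_by(.data$trial) %>%
    summarise(hbo = mean(.data$dhbo), hbr = mean(.data$dhbr), .groups = "drop") %>%
    arrange(.data$trial)
}
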