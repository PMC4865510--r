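#' Detect R-peaks by statistical thresholding
#'
#' Finds local maxima exceeding `mean + k_sd * sd` of the trace, enforcing a
#' refractory period between accepted peaks (larger peaks win within a
#' refractory window). Because the threshold is built from the trace's own
#' statistics, detection is invariant to amplitude scaling. The trace should
#' be band-pass filtered (0.1-30 Hz) and detrended first.
#'
#' @param x Numeric ECG vector, mV.
#' @param fs Sampling rate, Hz.
#' @param k_sd Threshold in SD units above the mean (default 2.5).
#' @param refractory_s Minimum peak spacing, seconds (default 0.3, a ~200
#'   beats/min ceiling).
#' @return A tibble of class `peak_train` with column `peak_time_s`
#'   (strictly increasing) and attribute `source = "ecg"`.
#' @export
detect_r_peaks <- function(x, fs, k_sd = 2.5, refractory_s = 0.3) {
  stopifnot(is.numeric(x), fs > 0, refractory_s >= 0)
  thr <- mean(x) + k_sd * sd(x)
  peaks <- find_peaks(x, thr, round(refractory_s * fs))
  if (length(peaks) == 0) stop("no R-peaks found above threshold", call. = FALSE)
  out <- tibble(peak_time_s = (peaks - 1) / fs)
  class(out) <- c("peak_train", class(out))
  attr(out, "source") <- "ecg"
  out
}

# local maxima above thr with a minimum spacing (in samples); when two
# candidates collide within the refractory window the larger amplitude wins
find_peaks <- function(x, thr, min_gap) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] > thr) + 1L
  if (length(cand) <= 1 || min_gap <= 0) return(cand)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord) {
    if (length(taken) == 0 || all(abs(taken - i) >= min_gap)) {
      taken <- c(taken, i)
    }
  }
  sort(taken)
}

#' Heart rate per minute from a peak train
#'
#' Counts R-peaks in half-open minute windows `[m, m+1)` minutes. Minutes
#' without any peak are flagged missing and excluded from the session mean.
#'
#' @param peaks A `peak_train` (or numeric vector of peak times, seconds).
#' @param duration_s Session duration, seconds.
#' @return A tibble of class `hr_series` with columns `minute` (1-based) and
#'   `bpm` (`NA` for empty minutes); the session mean is the attribute
#'   `mean_hr` and is also returned by [glance.hr_series()].
#' @export
heart_rate <- function(peaks, duration_s) {
  tms <- if (is.data.frame(peaks)) peaks$peak_time_s else peaks
  stopifnot(is.numeric(tms), duration_s > 0)
  n_min <- floor(duration_s / 60)
  if (n_min < 1) stop("need at least one full minute", call. = FALSE)
  counts <- vapply(seq_len(n_min), function(m) {
    sum(tms >= (m - 1) * 60 & tms < m * 60)
  }, numeric(1))
  counts[counts == 0] <- NA_real_
  out <- tibble(minute = seq_len(n_min), bpm = counts)
  class(out) <- c("hr_series", class(out))
  attr(out, "mean_hr") <- mean(counts, na.rm = TRUE)
  out
}

#' @rdname heart_rate
#' @param x An `hr_series`.
#' @param ... Unused.
#' @export
glance.hr_series <- function(x, ...) {
  tibble(mean_hr = attr(x, "mean_hr"),
         n_minutes = nrow(x),
         n_missing = sum(is.na(x$bpm)))
}

#' Mean RR interval per trial
#'
#' Averages the successive R-peak intervals falling inside each 10-s trial;
#' trials with fewer than two peaks get a missing value. A full 30-minute
#' session yields 180 interval features.
#'
#' @param peaks A `peak_train` or numeric vector of peak times, seconds.
#' @param trials A [segment_trials()] trial set.
#' @return Tibble with columns `trial`, `mean_rr_s`.
#' @export
rr_features <- function(peaks, trials) {
  tms <- if (is.data.frame(peaks)) peaks$peak_time_s else peaks
  stopifnot(inherits(trials, "trial_set"))
  idx <- trial_of(tms, trials)
  out <- map_dbl(seq_len(trials$n_trials), function(tr) {
    tt <- tms[!is.na(idx) & idx == tr]
    if (length(tt) < 2) return(NA_real_)
    mean(diff(tt))
  })
  tibble(trial = seq_len(trials$n_trials), mean_rr_s = out)
}

#' Blink rate per minute from EOG
#'
#' Band-passes the vertical EOG channel (0.1-10 Hz by default, removing
#' baseline wander), thresholds at `mean + k_sd * sd`, and counts detected
#' peaks in half-open minute windows. Zero counts are legitimate.
#'
#' @param eog_v Numeric vertical-EOG vector, uV.
#' @param fs Sampling rate, Hz.
#' @param k_sd Threshold in SD units (default 3).
#' @param refractory_s Minimum blink spacing, seconds (default 0.2).
#' @param window_s Counting window, seconds (default 60).
#' @param prefilter Apply the 0.1-10 Hz band-pass first (default TRUE).
#' @param min_amp_uV Absolute floor on the detection threshold (default 50
#'   uV); blinks are stereotyped large deflections, and the floor keeps a
#'   blink-free noise trace from yielding spurious statistical-threshold
#'   crossings.
#' @return Tibble with columns `minute`, `blinks` (counts per window).
#' @export
blink_rate <- function(eog_v, fs, k_sd = 3, refractory_s = 0.2,
                       window_s = 60, prefilter = TRUE, min_amp_uV = 50) {
  stopifnot(is.numeric(eog_v), fs > 0)
  x <- if (prefilter) {
    apply_filter(eog_v, fs, filter_spec("bandpass", 0.1, min(10, fs / 2 * 0.9)))
  } else eog_v
  thr <- max(mean(x) + k_sd * sd(x), min_amp_uV)
  peaks <- find_peaks(x, thr, round(refractory_s * fs))
  tms <- (peaks - 1) / fs
  n_win <- floor(length(eog_v) / fs / window_s)
  counts <- vapply(seq_len(n_win), function(m) {
    sum(tms >= (m - 1) * window_s & tms < m * window_s)
  }, numeric(1))
  tibble(minute = seq_len(n_win), blinks = counts)
}

#' Heart rate from a two-channel ECG recording
#'
#' Convenience wrapper: filters (0.1-30 Hz) and detrends each chest channel,
#' detects R-peaks independently on both, and averages the two per-minute
#' heart-rate series to reduce detection error and bias.
#'
#' @param ecg Samples-by-2 ECG matrix, mV.
#' @param fs Sampling rate, Hz.
#' @param duration_s Session duration, seconds.
#' @param k_sd,refractory_s Passed to [detect_r_peaks()].
#' @return An `hr_series` tibble (averaged over channels) with attribute
#'   `peaks` holding the per-channel peak trains.
#' @export
ecg_heart_rate <- function(ecg, fs, duration_s = nrow(ecg) / fs,
                           k_sd = 2.5, refractory_s = 0.3) {
  stopifnot(is.matrix(ecg), ncol(ecg) == 2)
  spec <- filter_spec("bandpass", 0.1, min(30, fs / 2 * 0.9))
  trains <- lapply(1:2, function(j) {
    v <- detrend_linear(apply_filter(ecg[, j], fs, spec))
    detect_r_peaks(v, fs, k_sd, refractory_s)
  })
  hrs <- lapply(trains, heart_rate, duration_s = duration_s)
  out <- tibble(minute = hrs[[1]]$minute,
                bpm = rowMeans(cbind(hrs[[1]]$bpm, hrs[[2]]$bpm)))
  class(out) <- c("hr_series", class(out))
  attr(out, "mean_hr") <- mean(out$bpm, na.rm = TRUE)
  attr(out, "peaks") <- trains
  out
}
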