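#' Segment a session into fixed-length trials
#'
#' Maximal non-overlapping cover of `[0, duration_s)` by `trial_len_s`-second
#' trials starting at t = 0; any remainder is dropped. A 30-minute session at
#' the default 10 s per trial yields 180 trials.
#'
#' @param duration_s Session duration, seconds (>= `trial_len_s`).
#' @param trial_len_s Trial length, seconds (default 10).
#' @return A list of class `trial_set` with `trial_len_s`, `onsets_s`,
#'   `n_trials`.
#' @export
segment_trials <- function(duration_s, trial_len_s = 10) {
  stopifnot(trial_len_s > 0)
  if (duration_s < trial_len_s) {
    stop("duration shorter than one trial", call. = FALSE)
  }
  n <- floor(duration_s / trial_len_s)
  structure(list(trial_len_s = trial_len_s,
                 onsets_s = (seq_len(n) - 1) * trial_len_s,
                 n_trials = as.integer(n)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set>", x$n_trials, "trials of", x$trial_len_s, "s\n")
  invisible(x)
}

#' Trial index of time points
#'
#' Maps times (seconds) to 1-based trial indices under the half-open
#' convention `[onset, onset + trial_len)`; times outside every trial map to
#' `NA`.
#'
#' @param time_s Numeric vector of times, seconds.
#' @param trials A [segment_trials()] trial set.
#' @return Integer vector of trial indices (or `NA`).
#' @export
trial_of <- function(time_s, trials) {
  stopifnot(inherits(trials, "trial_set"))
  idx <- floor(time_s / trials$trial_len_s) + 1
  idx[time_s < 0 | idx > trials$n_trials] <- NA
  as.integer(idx)
}

#' Welch power spectral density
#'
#' Welch's averaged-periodogram estimate with Hamming-windowed segments
#' (default 2 s, 50% overlap), one-sided scaling so that the integral of the
#' PSD over frequency equals the signal variance. The frequency grid
#' resolution is `1/seg_s` Hz (0.5 Hz at the defaults).
#'
#' @param x Numeric vector (one trial of one channel) or samples-by-channels
#'   matrix.
#' @param fs Sampling rate, Hz.
#' @param seg_s Welch segment length, seconds.
#' @param overlap Fractional segment overlap.
#' @return For a vector: tibble `freq_hz`, `power` (uV^2/Hz). For a matrix:
#'   tibble `freq_hz` plus one power column per input column.
#' @export
compute_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  stopifnot(fs > 0, seg_s > 0)
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(xm)
  nseg <- round(seg_s * fs)
  if (n < nseg) stop("trial shorter than one Welch segment", call. = FALSE)
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  scale <- fs * sum(w^2)
  nfreq <- nseg %/% 2 + 1L
  acc <- matrix(0, nrow = nfreq, ncol = ncol(xm))
  for (s in starts) {
    seg <- xm[s:(s + nseg - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    ft <- stats::mvfft(seg * w)
    p <- (Mod(ft[seq_len(nfreq), , drop = FALSE])^2) / scale
    # one-sided: double everything except DC (and Nyquist for even nseg)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  acc <- acc / length(starts)
  freq <- (seq_len(nfreq) - 1) * fs / nseg
  out <- as_tibble(acc, .name_repair = "minimal")
  names(out) <- if (!is.matrix(x)) "power"
    else if (!is.null(colnames(x))) colnames(x)
    else paste0("power", seq_len(ncol(xm)))
  dplyr::bind_cols(tibble(freq_hz = freq), out)
}

band_power <- function(freq, power, lo, hi) {
  df <- freq[2] - freq[1]
  sum(power[freq >= lo & freq < hi]) * df
}

#' Relative power levels over the five canonical bands
#'
#' Integrates the PSD over each half-open band `[lo, hi)` and normalizes by
#' the summed power of all five bands, reducing session/subject variability.
#' The five values are in `[0, 1]` and sum to 1.
#'
#' @param psd A tibble from [compute_psd()] with columns `freq_hz`, `power`.
#' @return Tibble with columns `band`, `rpl` (rows ordered
#'   delta/theta/alpha/beta/gamma).
#' @export
compute_rpl <- function(psd) {
  stopifnot(is.data.frame(psd), all(c("freq_hz", "power") %in% names(psd)))
  if (max(psd$freq_hz) < 50) {
    warning("PSD grid does not reach 50 Hz; gamma band truncated", call. = FALSE)
  }
  bp <- map_dbl(seq_len(nrow(.eeg_bands)), function(b) {
    band_power(psd$freq_hz, psd$power, .eeg_bands$lo_hz[b], .eeg_bands$hi_hz[b])
  })
  tot <- sum(bp)
  if (tot <= 0) stop("total band power is zero", call. = FALSE)
  tibble(band = .eeg_bands$band, rpl = bp / tot)
}

#' Per-trial, per-channel relative power levels
#'
#' Segments the EEG into trials, runs the Welch estimator per trial on all
#' channels at once, and returns the tidy RPL table downstream feature and
#' classification steps consume.
#'
#' @param eeg Samples-by-channels matrix with channel labels as column names.
#' @param fs Sampling rate, Hz.
#' @param trials A [segment_trials()] trial set.
#' @param channels Channel subset to compute (default: all columns).
#' @return Tibble with columns `trial`, `channel`, `band`, `rpl`.
#' @export
channel_rpl <- function(eeg, fs, trials, channels = colnames(eeg)) {
  stopifnot(is.matrix(eeg), inherits(trials, "trial_set"))
  if (is.null(colnames(eeg))) stop("eeg matrix must have channel names", call. = FALSE)
  missing_ch <- setdiff(channels, colnames(eeg))
  if (length(missing_ch) > 0) {
    stop("channels not present: ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  nper <- round(trials$trial_len_s * fs)
  out <- vector("list", trials$n_trials)
  for (tr in seq_len(trials$n_trials)) {
    i0 <- round(trials$onsets_s[tr] * fs) + 1L
    seg <- eeg[i0:(i0 + nper - 1L), channels, drop = FALSE]
    psd <- compute_psd(seg, fs)
    freq <- psd$freq_hz
    rpls <- lapply(channels, function(ch) {
      bp <- map_dbl(seq_len(nrow(.eeg_bands)), function(b) {
        band_power(freq, psd[[ch]], .eeg_bands$lo_hz[b], .eeg_bands$hi_hz[b])
      })
      tibble(trial = tr, channel = ch, band = .eeg_bands$band, rpl = bp / sum(bp))
    })
    out[[tr]] <- bind_rows(rpls)
  }
  bind_rows(out)
}

#' Region-averaged alpha/beta features
#'
#' Averages per-channel RPLs spatially over the centro-parietal channels for
#' alpha and the fronto-central channels for beta, and forms the beta/alpha
#' ratio that enters the Driving Condition Level.
#'
#' @param rpl_tbl Tidy RPL tibble from [channel_rpl()].
#' @param regions A [region_spec()].
#' @return Tibble with columns `trial`, `alpha_cp`, `beta_fc`,
#'   `beta_over_alpha`.
#' @export
region_features <- function(rpl_tbl, regions = region_spec()) {
  stopifnot(is.data.frame(rpl_tbl), inherits(regions, "region_spec"))
  have <- unique(rpl_tbl$channel)
  need <- unique(c(regions$alpha_region, regions$beta_region))
  if (!all(need %in% have)) {
    stop("region channels missing from RPL table: ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  }
  a <- rpl_tbl %>%
    filter(.data$band == "alpha", .data$channel %in% regions$alpha_region) %>%
    group_by(.data$trial) %>%
    summarise(alpha_cp = mean(.data$rpl), .groups = "drop")
  b <- rpl_tbl %>%
    filter(.data$band == "beta", .data$channel %in% regions$beta_region) %>%
    group_by(.data$trial) %>%
    summarise(beta_fc = mean(.data$rpl), .groups = "drop")
  out <- left_join(a, b, by = "trial")
  if (any(out$alpha_cp == 0)) stop("zero alpha RPL in region average", call. = FALSE)
  out %>% mutate(beta_over_alpha = .data$beta_fc / .data$alpha_cp)
}
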