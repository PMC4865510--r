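#' Write an fNIRS intensity table
#'
#' Tab-delimited, header `time_s`, `ch{1..8}_735`, `ch{1..8}_850`, one row
#' per sample.
#'
#' @param intensity Wide intensity tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fnirs_table <- function(intensity, path) {
  stopifnot(is.data.frame(intensity))
  need <- c("time_s", fnirs_channel_cols())
  if (!identical(names(intensity), need)) {
    stop("intensity table columns must be exactly: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  readr::write_tsv(intensity, path)
  invisible(path)
}

#' Read an fNIRS intensity table
#'
#' Validates the documented dialect: exact header
#' `time_s, ch{1..8}_735, ch{1..8}_850` and a strictly increasing time
#' vector.
#'
#' @param path File path.
#' @return Wide intensity tibble.
#' @export
read_fnirs_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", fnirs_channel_cols())
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    stop("fNIRS table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(tbl$time_s) <= 0)) {
    stop("fNIRS time vector is not strictly increasing", call. = FALSE)
  }
  tbl[need]
}

#' Synchronize the electrophysiology and fNIRS streams
#'
#' Crops every stream to its own `[start, end]` trigger interval and resets
#' time zero to the start trigger, so that both acquisition computers' data
#' live on a common session clock. The aligned durations must agree within
#' 1 s and overlap by at least 60 s.
#'
#' @param rec A `multimodal_recording`.
#' @return The recording, cropped and with triggers reset to
#'   `(0, duration)`.
#' @export
align_streams <- function(rec) {
  stopifnot(inherits(rec, "multimodal_recording"))
  te <- rec$triggers$ephys
  tf <- rec$triggers$fnirs
  if (is.null(te) || is.null(tf) || anyNA(c(te, tf))) {
    stop("missing start/end trigger", call. = FALSE)
  }
  dur_e <- te["end"] - te["start"]
  dur_f <- tf["end"] - tf["start"]
  common <- min(dur_e, dur_f)
  if (common < 60) stop("stream overlap shorter than 60 s", call. = FALSE)
  if (abs(dur_e - dur_f) > 1) {
    warning("ephys and fNIRS trigger intervals differ by more than 1 s",
            call. = FALSE)
  }
  fs <- rec$fs_eeg
  keep_e <- seq(round(te["start"] * fs) + 1L, round((te["start"] + common) * fs))
  keep_e <- keep_e[keep_e <= nrow(rec$eeg)]
  rec$eeg <- rec$eeg[keep_e, , drop = FALSE]
  rec$eog <- rec$eog[keep_e, , drop = FALSE]
  rec$ecg <- rec$ecg[keep_e, , drop = FALSE]
  keep_f <- rec$fnirs$time_s >= tf["start"] &
    rec$fnirs$time_s < tf["start"] + common
  rec$fnirs <- rec$fnirs[keep_f, , drop = FALSE]
  rec$fnirs$time_s <- rec$fnirs$time_s - tf["start"]
  rec$triggers <- list(ephys = c(start = 0, end = unname(common)),
                       fnirs = c(start = 0, end = unname(common)))
  rec
}

#' Write a session to disk
#'
#' Electrophysiology (EEG + EOGh/EOGv + ECG1/ECG2) goes to one EDF+ file
#' with `session_start`/`session_end` annotations, fNIRS intensities to a
#' tab-delimited table, and the generator's ground truth to a sidecar JSON.
#'
#' @param rec A `multimodal_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(rec, dir) {
  stopifnot(inherits(rec, "multimodal_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig <- cbind(rec$eeg, rec$eog, rec$ecg)
  ann <- tibble(onset_s = c(rec$triggers$ephys[["start"]],
                            rec$triggers$ephys[["end"]] - 1e-9),
                text = c("session_start", "session_end"))
  write_edf(sig, rec$fs_eeg, file.path(dir, "session.edf"), annotations = ann)
  write_fnirs_table(rec$fnirs, file.path(dir, "fnirs.tsv"))
  gt <- rec$ground_truth
  gt_json <- list(
    condition = rec$condition,
    fs_eeg = rec$fs_eeg, fs_fnirs = rec$fs_fnirs,
    r_peak_times_s = gt$r_peak_times_s,
    blink_times_s = gt$blink_times_s,
    true_hbo_mean = if (!is.null(gt$true_hbo)) rowMeans(gt$true_hbo) else NULL
  )
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from disk
#'
#' Inverse of [write_session()]: reads the EDF (requiring the session
#' triggers), partitions channels by label, reads the fNIRS table and, if
#' present, the ground-truth sidecar.
#'
#' @param dir Session directory.
#' @return A `multimodal_recording`.
#' @export
read_session <- function(dir) {
  edf <- read_edf(file.path(dir, "session.edf"), require_triggers = TRUE)
  fnirs <- read_fnirs_table(file.path(dir, "fnirs.tsv"))
  g <- edf$groups
  gt <- NULL
  condition <- NA_character_
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    condition <- raw$condition %||% NA_character_
    gt <- list(r_peak_times_s = raw$r_peak_times_s,
               blink_times_s = raw$blink_times_s,
               true_hbo_mean = raw$true_hbo_mean)
  }
  starts <- edf$annotations$onset_s[edf$annotations$text == "session_start"]
  ends <- edf$annotations$onset_s[edf$annotations$text == "session_end"]
  structure(
    list(eeg = edf$signals[, g$eeg, drop = FALSE],
         eog = edf$signals[, g$eog, drop = FALSE],
         ecg = edf$signals[, g$ecg, drop = FALSE],
         fnirs = fnirs, fs_eeg = edf$fs, fs_fnirs = {
           dt <- median(diff(fnirs$time_s)); 1 / dt
         },
         triggers = list(ephys = c(start = starts[1], end = ends[1]),
                         fnirs = c(start = min(fnirs$time_s),
                                   end = max(fnirs$time_s))),
         condition = condition, bad_channels = character(0),
         params = NULL, ground_truth = gt),
    class = "multimodal_recording"
  )
}

#' Drop bad channels from a recording
#'
#' Removes the listed EEG channels (a config-supplied stand-in for visual
#' inspection) before feature extraction.
#'
#' @param rec A `multimodal_recording`.
#' @param bad Character vector of channel labels.
#' @return The recording without those channels, with `bad_channels`
#'   recorded.
#' @export
drop_bad_channels <- function(rec, bad) {
  stopifnot(inherits(rec, "multimodal_recording"))
  unknown <- setdiff(bad, colnames(rec$eeg))
  if (length(unknown) > 0) {
    stop("bad channels not in recording: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rec$eeg <- rec$eeg[, setdiff(colnames(rec$eeg), bad), drop = FALSE]
  rec$bad_channels <- union(rec$bad_channels, bad)
  rec
}
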