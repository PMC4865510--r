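# Minimal EDF+C (European Data Format) writer/reader: fixed-width ASCII
# header, int16 little-endian data records of 1 s, one TAL annotation signal.
# Covers exactly what this pipeline needs: uniform sampling rate across data
# signals, integer fs, onset-only annotations.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x, call. = FALSE)
  formatC(x, width = -width)
}

fmt_num <- function(x, width = 8) {
  s <- formatC(signif(x, 7), format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = width - 4)
  pad_field(s, width)
}

# render a physical-range bound in <= 8 characters, rounded outward
# (dir = -1 floors a minimum, dir = +1 ceils a maximum) so every data value
# stays inside the printed range
fmt_bound <- function(x, dir) {
  if (x == 0) return("0")
  for (d in 6:1) {
    scale <- 10^(ceiling(log10(abs(x))) - d)
    v <- if (dir < 0) floor(x / scale) * scale else ceiling(x / scale) * scale
    s <- formatC(v, format = "g", digits = 7)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot render physical range bound ", x, " in 8 characters",
       call. = FALSE)
}

#' Write signals to an EDF+ file
#'
#' Writes a samples-by-channels matrix as 16-bit EDF+C with 1-second data
#' records and a text-annotation signal. Physical min/max are taken from the
#' data per channel, so quantization error is at most 1/65535 of each
#' channel's range. The duration is truncated to whole seconds.
#'
#' @param signals Samples-by-channels numeric matrix; column names become
#'   channel labels.
#' @param fs Integer sampling rate shared by all channels, Hz.
#' @param path Output file path.
#' @param annotations Tibble/data.frame with columns `onset_s`, `text`
#'   (may be empty).
#' @param phys_dim Physical dimension string per channel (recycled).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, annotations = NULL, phys_dim = "uV") {
  stopifnot(is.matrix(signals), fs > 0, fs == round(fs))
  nch <- ncol(signals)
  labels <- colnames(signals)
  if (is.null(labels)) stop("signal matrix must have column names", call. = FALSE)
  n_rec <- floor(nrow(signals) / fs)
  if (n_rec < 1) stop("less than one second of data", call. = FALSE)
  signals <- signals[seq_len(n_rec * fs), , drop = FALSE]
  phys_dim <- rep_len(phys_dim, nch)

  pmin <- apply(signals, 2, min)
  pmax <- apply(signals, 2, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # the header renders the physical range in 8 ASCII characters; digitize
  # against that rendering (rounded outward so all samples stay inside) or
  # the reader's rescaling would disagree with the writer's
  pmin_str <- vapply(pmin, fmt_bound, character(1), dir = -1)
  pmax_str <- vapply(pmax, fmt_bound, character(1), dir = 1)
  pmin <- as.numeric(pmin_str)
  pmax <- as.numeric(pmax_str)
  dmin <- -32768; dmax <- 32767

  # digital conversion
  dig <- matrix(0L, nrow(signals), nch)
  for (j in seq_len(nch)) {
    dig[, j] <- as.integer(round((signals[, j] - pmin[j]) /
                                   (pmax[j] - pmin[j]) * (dmax - dmin) + dmin))
  }

  # annotation TALs per record
  if (is.null(annotations)) {
    annotations <- tibble(onset_s = numeric(0), text = character(0))
  }
  tal_of <- function(rec) {
    s <- sprintf("+%d\x14\x14", rec - 1L)
    sel <- which(floor(annotations$onset_s) == rec - 1L)
    for (i in sel) {
      s <- paste0(s, sprintf("+%g\x14%s\x14", annotations$onset_s[i],
                             annotations$text[i]))
    }
    s
  }
  tals <- vapply(seq_len(n_rec), tal_of, character(1))
  ann_bytes <- max(60L, max(nchar(tals, type = "bytes")) + 2L)
  if (ann_bytes %% 2 == 1) ann_bytes <- ann_bytes + 1L
  ann_samples <- ann_bytes %/% 2L

  ns <- nch + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate 01-JAN-2026 X X X", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("EDF+C", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4),
    paste(vapply(c(labels, "EDF Annotations"), pad_field, character(1), width = 16),
          collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(vapply(c(phys_dim, ""), pad_field, character(1), width = 8), collapse = ""),
    paste(c(vapply(pmin_str, pad_field, character(1), width = 8),
            pad_field("-1", 8)), collapse = ""),
    paste(c(vapply(pmax_str, pad_field, character(1), width = 8),
            pad_field("1", 8)), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(vapply(c(rep(fs, nch), ann_samples), pad_field, character(1), width = 8),
          collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  ), con, eos = NULL)

  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
    tal_raw <- charToRaw(tals[r])
    writeBin(c(tal_raw, raw(ann_bytes - length(tal_raw))), con)
  }
  invisible(path)
}

read_header_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, decodes the 16-bit records back to physical units, and
#' extracts text annotations from the EDF+ annotation signal if present.
#' Only files whose ordinary signals share one sampling rate are supported
#' (which is how this package writes them); no resampling is performed.
#'
#' @param path EDF file path.
#' @param require_triggers If `TRUE`, error unless `session_start` and
#'   `session_end` annotations are present.
#' @return List with `signals` (samples x channels matrix, labeled),
#'   `labels`, `fs`, `annotations` (tibble `onset_s`, `text`) and `groups`
#'   (labels partitioned into `eeg`/`eog`/`ecg` by naming convention).
#' @export
read_edf <- function(path, require_triggers = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  if (length(hdr) < 256) stop("malformed EDF header (truncated)", call. = FALSE)
  version <- read_header_field(hdr, 0, 8)
  if (version != "0") stop("malformed EDF header: bad version", call. = FALSE)
  n_rec <- as.integer(read_header_field(hdr, 236, 8))
  rec_dur <- as.numeric(read_header_field(hdr, 244, 8))
  ns <- as.integer(read_header_field(hdr, 252, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) {
    stop("malformed EDF header", call. = FALSE)
  }
  shdr <- readBin(con, "raw", 256 * ns)
  fieldv <- function(off0, width) {
    vapply(seq_len(ns), function(i) {
      read_header_field(shdr, off0 * ns + (i - 1) * width, width)
    }, character(1))
  }
  labels <- fieldv(0, 16)
  # per-field byte offsets within the signal header block (grouped by field):
  # labels 0, transducer 16, phys dim 96, phys min 104, phys max 112,
  # dig min 120, dig max 128, prefilter 136, samples/record 216
  pmin <- as.numeric(fieldv(104, 8))
  pmax <- as.numeric(fieldv(112, 8))
  dmin <- as.numeric(fieldv(120, 8))
  dmax <- as.numeric(fieldv(128, 8))
  nsamp <- as.integer(fieldv(216, 8))
  if (any(is.na(nsamp))) stop("malformed EDF signal header", call. = FALSE)

  ann_idx <- which(labels == "EDF Annotations")
  data_idx <- setdiff(seq_len(ns), ann_idx)
  fs_all <- nsamp[data_idx] / rec_dur
  if (length(unique(fs_all)) != 1) {
    stop("mixed sampling rates are not supported", call. = FALSE)
  }
  fs <- fs_all[1]

  rec_bytes <- sum(nsamp) * 2L
  expected <- 256 + 256 * ns + n_rec * rec_bytes
  if (sz < expected) stop("malformed EDF file: truncated records", call. = FALSE)
  body <- readBin(con, "raw", n_rec * rec_bytes)

  offs <- c(0L, cumsum(nsamp * 2L))
  sig <- matrix(0, nrow = n_rec * nsamp[data_idx[1]], ncol = length(data_idx),
                dimnames = list(NULL, labels[data_idx]))
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * rec_bytes
    for (k in seq_along(data_idx)) {
      i <- data_idx[k]
      raw_i <- body[(base + offs[i] + 1L):(base + offs[i + 1L])]
      d <- readBin(raw_i, "integer", n = nsamp[i], size = 2, endian = "little")
      rows <- ((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])
      sig[rows, k] <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
    for (i in ann_idx) {
      raw_i <- body[(base + offs[i] + 1L):(base + offs[i + 1L])]
      ann_text <- c(ann_text, rawToChar(raw_i[raw_i != as.raw(0)]))
    }
  }

  # walk the TAL token stream: a token parseable as a signed number opens a
  # TAL (its onset); subsequent non-empty tokens are its annotation texts
  # (durations, \x15, are never written by this package)
  onsets <- numeric(0); texts <- character(0)
  for (rec_str in ann_text) {
    tokens <- strsplit(rec_str, "\x14", fixed = TRUE)[[1]]
    cur_onset <- NA_real_
    for (tok in tokens) {
      num <- suppressWarnings(as.numeric(tok))
      if (grepl("^[+-]", tok) && !is.na(num)) {
        cur_onset <- num
      } else if (nzchar(tok) && !is.na(cur_onset)) {
        onsets <- c(onsets, cur_onset)
        texts <- c(texts, tok)
      }
    }
  }
  annotations <- tibble(onset_s = onsets, text = texts)
  if (require_triggers &&
      !all(c("session_start", "session_end") %in% annotations$text)) {
    stop("missing session_start/session_end annotation", call. = FALSE)
  }
  list(signals = sig, labels = labels[data_idx], fs = fs,
       annotations = annotations, groups = partition_channels(labels[data_idx]))
}

#' Partition channel labels into modality groups
#'
#' Labels `EOGh`/`EOGv` are ocular, `ECG1`/`ECG2` cardiac, everything else
#' EEG.
#'
#' @param labels Character vector of channel labels.
#' @return List with elements `eeg`, `eog`, `ecg`.
#' @export
partition_channels <- function(labels) {
  eog <- labels[labels %in% c("EOGh", "EOGv")]
  ecg <- labels[labels %in% c("ECG1", "ECG2")]
  list(eeg = setdiff(labels, c(eog, ecg)), eog = eog, ecg = ecg)
}
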