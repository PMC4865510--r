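#' Configure the end-to-end fatigue pipeline
#'
#' Collects every parameter the pipeline needs: the session geometry shared
#' by both conditions, per-condition generator overrides, region
#' definitions, preprocessing switches and the split scheme. All randomness
#' derives from `seed` (the well-rested session uses `seed`, the
#' sleep-deprived one `seed + 1000`).
#'
#' @param seed Integer master seed.
#' @param duration_s Session duration, seconds.
#' @param eeg_fs,fnirs_fs Sampling rates, Hz.
#' @param well_overrides,sleep_overrides Named lists forwarded to
#'   [well_rested_params()] / [sleep_deprived_params()].
#' @param regions A [region_spec()].
#' @param bad_channels EEG labels to drop before feature extraction.
#' @param use_ica Run infomax ICA EOG cleaning on the EEG (slower; the
#'   synthetic EEG carries no ocular leakage by default).
#' @param ica_threshold Absolute-correlation rejection threshold.
#' @param n_reps Split repetitions (default 30).
#' @param dcl_weights DCL component weights (default unit).
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, duration_s = 1800, eeg_fs = 512,
                            fnirs_fs = 10, well_overrides = list(),
                            sleep_overrides = list(),
                            regions = region_spec(),
                            bad_channels = character(0),
                            use_ica = FALSE, ica_threshold = 0.7,
                            n_reps = 30, dcl_weights = c(1, 1, 1),
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 eeg_fs = eeg_fs, fnirs_fs = fnirs_fs,
                 well_overrides = well_overrides,
                 sleep_overrides = sleep_overrides, regions = regions,
                 bad_channels = bad_channels, use_ica = use_ica,
                 ica_threshold = ica_threshold, n_reps = n_reps,
                 dcl_weights = dcl_weights, out_dir = out_dir),
            class = "pipeline_config")
}

# per-session feature extraction: trials, region RPLs, HR, RR, hemodynamics
extract_session_features <- function(rec, config) {
  fs <- rec$fs_eeg
  duration <- nrow(rec$eeg) / fs
  trials <- segment_trials(duration)
  regions <- config$regions

  eeg <- rec$eeg
  if (length(config$bad_channels) > 0) {
    rec <- drop_bad_channels(rec, config$bad_channels)
    eeg <- rec$eeg
  }
  if (isTRUE(config$use_ica)) {
    ica <- fit_infomax_ica(t(eeg), seed = config$seed)
    eeg <- t(remove_eog_components(t(eeg), ica, t(rec$eog),
                                   r_threshold = config$ica_threshold))
  }
  eeg <- apply_filter(eeg, fs, filter_spec("bandpass", 1, min(50, fs / 2 * 0.98)))

  region_ch <- unique(c(regions$alpha_region, regions$beta_region))
  region_ch <- intersect(region_ch, colnames(eeg))
  rpl <- channel_rpl(eeg, fs, trials, channels = region_ch)
  eeg_feat <- region_features(rpl, regions)

  hr <- ecg_heart_rate(rec$ecg, fs, duration_s = duration)
  peaks_avg <- attr(hr, "peaks")[[1]]   # RR features from channel 1 peaks
  rr <- rr_features(peaks_avg, trials)

  blinks <- blink_rate(rec$eog[, "EOGv"], fs)

  baseline <- compute_baseline(rec$fnirs)
  hemo <- mbll_convert(rec$fnirs, baseline) %>%
    drift_highpass(fs = rec$fs_fnirs) %>%
    smooth_hemo(fs = rec$fs_fnirs)
  hemo_feat <- hbo_trial_amplitude(hemo, trials)

  minutes <- tibble(minute = seq_len(floor(duration / 60))) %>%
    mutate(
      ratio = map_dbl(.data$minute, function(m) {
        tr <- ((m - 1) * 6 + 1):(m * 6)
        sel <- eeg_feat[eeg_feat$trial %in% tr, ]
        mean(sel$beta_fc) / mean(sel$alpha_cp)
      }),
      hbo = map_dbl(.data$minute, function(m) {
        tr <- ((m - 1) * 6 + 1):(m * 6)
        mean(hemo_feat$hbo[hemo_feat$trial %in% tr])
      }),
      hr = hr$bpm[.data$minute]
    )

  list(trials = trials, eeg = eeg_feat, rr = rr, hr = hr, blinks = blinks,
       hemo = hemo_feat, minutes = minutes)
}

#' Run the full multimodal fatigue pipeline
#'
#' Simulates one well-rested and one sleep-deprived session, preprocesses
#' every stream, extracts the per-trial and per-minute features, computes
#' the Driving Condition Level (per minute and per session), the relative
#' DCL, the modality contribution decomposition and the weighted-DCL grid
#' search, and classifies the two conditions per modality and with stacked
#' fusion over the time-ordered sliding splits. Deterministic given the
#' config seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `fatigue_report`; see the elements `dcl`
#'   (per-minute tibble), `summary` (session DCLs and rDCL),
#'   `contributions`, `best_weights`, `classification` (fusion summary +
#'   per-repetition accuracies), `hr_test` (paired per-minute heart-rate
#'   Wilcoxon test) and `features`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  mk <- function(ctor, overrides, seed) {
    do.call(ctor, utils::modifyList(
      list(duration_s = config$duration_s, eeg_fs = config$eeg_fs,
           fnirs_fs = config$fnirs_fs, regions = config$regions, seed = seed),
      overrides))
  }
  rec_w <- simulate_session(mk(well_rested_params, config$well_overrides,
                               config$seed))
  rec_s <- simulate_session(mk(sleep_deprived_params, config$sleep_overrides,
                               config$seed + 1000L))
  rec_w <- align_streams(rec_w)
  rec_s <- align_streams(rec_s)

  feat_w <- extract_session_features(rec_w, config)
  feat_s <- extract_session_features(rec_s, config)

  comp <- build_dcl_components(feat_w$minutes, feat_s$minutes)
  dcl_w <- compute_dcl(comp$well, config$dcl_weights, "well_rested")
  dcl_s <- compute_dcl(comp$sleep, config$dcl_weights, "sleep_deprived")
  rdcl <- compute_rdcl(dcl_w, dcl_s)
  contrib <- modality_contributions(comp$well, comp$sleep)
  best_w <- grid_search_weights(comp$well, comp$sleep)

  features_of <- function(f, cond) {
    list(
      eeg = f$eeg %>% select("trial", "alpha_cp", "beta_fc") %>%
        mutate(condition = cond),
      ecg = f$rr %>% mutate(condition = cond),
      fnirs = f$hemo %>% mutate(condition = cond)
    )
  }
  fw <- features_of(feat_w, "well_rested")
  fs_ <- features_of(feat_s, "sleep_deprived")
  features_list <- lapply(c(eeg = "eeg", ecg = "ecg", fnirs = "fnirs"),
                          function(m) bind_rows(fw[[m]], fs_[[m]]))
  splits <- make_splits(n_trials = feat_w$trials$n_trials,
                        n_reps = config$n_reps)
  fusion <- fuse_classifiers(features_list, splits)

  n_hr <- min(nrow(feat_w$minutes), 50L)
  hr_test <- wilcoxon_signed_rank_exact(feat_w$minutes$hr[seq_len(n_hr)],
                                        feat_s$minutes$hr[seq_len(n_hr)])

  dcl_tbl <- bind_rows(
    dcl_w %>% mutate(condition = "well_rested"),
    dcl_s %>% mutate(condition = "sleep_deprived")
  )
  report <- structure(
    list(
      config = config,
      dcl = as_tibble(dcl_tbl),
      summary = tibble(dcl_well = attr(dcl_w, "dcl_session"),
                       dcl_sleep = attr(dcl_s, "dcl_session"),
                       rdcl_percent = rdcl),
      contributions = contrib,
      best_weights = best_w,
      classification = fusion,
      hr_test = hr_test,
      components = comp,
      features = list(well = feat_w, sleep = feat_s)
    ),
    class = "fatigue_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.fatigue_report <- function(x, ...) {
  cat("<fatigue_report>\n  session DCL: well-rested",
      sprintf("%.2f", x$summary$dcl_well), "/ sleep-deprived",
      sprintf("%.2f", x$summary$dcl_sleep), "\n  rDCL:",
      sprintf("%.1f%%", x$summary$rdcl_percent), "\n")
  cat("  classification accuracy (mean over",
      attr(x$classification$single[[1]], "n_reps") %||%
        nrow(x$classification$fused), "repetitions):\n")
  print(x$classification$summary)
  invisible(x)
}

#' Write pipeline artifacts
#'
#' CSV tables (per-minute DCL, contributions, per-repetition accuracies)
#' plus one JSON report with every scalar result and the resolved
#' parameters.
#'
#' @param report A `fatigue_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "fatigue_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$dcl, file.path(dir, "dcl_per_minute.csv"))
  readr::write_csv(report$contributions, file.path(dir, "contributions.csv"))
  acc <- bind_rows(
    bind_rows(imap(report$classification$single, function(ev, nm) {
      tibble(modality = nm, repetition = ev$repetition, accuracy = ev$accuracy)
    })),
    as_tibble(report$classification$fused) %>%
      mutate(modality = "fused", .before = 1)
  )
  readr::write_csv(acc, file.path(dir, "accuracies.csv"))
  json <- list(
    seed = report$config$seed,
    duration_s = report$config$duration_s,
    summary = as.list(report$summary),
    best_weights = as.list(report$best_weights[c("a", "b", "c",
                                                 "dcl_difference")]),
    accuracy_summary = report$classification$summary,
    hr_test = list(V = unname(report$hr_test$statistic),
                   p_value = report$hr_test$p.value)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
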