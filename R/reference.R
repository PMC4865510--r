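# Published per-subject summary tables from the original 11-subject driving
# study. These printed values are *inputs* for worked arithmetic (relative
# DCL, group means, significance tests); the study's raw recordings were
# never deposited.

#' Published per-subject mean heart rates
#'
#' Mean (SD) heart rate over the 30-minute drive for each of the 11
#' subjects, in both conditions.
#'
#' @return Tibble with columns `subject`, `condition`, `mean_hr`, `sd_hr`.
#' @export
reference_heart_rates <- function() {
  subj <- paste0("S", 1:11)
  bind_rows(
    tibble(subject = subj, condition = "well_rested",
           mean_hr = c(71.6, 65.3, 78.5, 76.2, 71, 68.2, 68.1, 76.8, 66.7,
                       65.7, 60.9),
           sd_hr = c(2.0, 2.2, 2.3, 2.5, 2.8, 1.4, 2.3, 2.2, 3.1, 1.9, 2.9)),
    tibble(subject = subj, condition = "sleep_deprived",
           mean_hr = c(62, 58.2, 61.3, 55.7, 62.3, 64.2, 63, 67.3, 64.2,
                       62.4, 59.2),
           sd_hr = c(0.5, 2.7, 2.1, 2.6, 2.2, 1.1, 2.2, 3.7, 3.8, 1.4, 1.9))
  )
}

#' Published per-subject Driving Condition Levels
#'
#' Session-level DCL (0-3 scale) for each of the 11 subjects in the two
#' conditions, together with the published relative DCL row.
#'
#' @return Tibble with columns `subject`, `dcl_well`, `dcl_sleep`,
#'   `rdcl_printed`.
#' @export
reference_dcl <- function() {
  tibble(
    subject = paste0("S", 1:11),
    dcl_well = c(2.52, 2.48, 2.31, 2.04, 2.24, 2.75, 1.94, 2.80, 1.94,
                 2.01, 2),
    dcl_sleep = c(1.47, 1.17, 1.44, 1.07, 1.11, 1.73, 1.42, 1.88, 1.54,
                  1.19, 1.21),
    rdcl_printed = c(41.7, 52.8, 37.7, 47.5, 50.2, 37.1, 26.7, 32.9, 21,
                     40.8, 39.5)
  )
}
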