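#' Fit min-max normalization bounds with outlier shrinkage
#'
#' Values deemed outliers — each value is tested against the mean plus/minus
#' 2 standard deviations of the *remaining* values (leave-one-out, so a
#' single extreme value cannot mask itself by inflating the spread) — are
#' shrunk to the minimum/maximum of the non-outlying values. The
#' normalization bounds are the min and max of the shrunk set.
#'
#' @param values Numeric vector (>= 3 finite values, not all identical).
#' @param k_sd Outlier multiplier on the SD (default 2).
#' @return A list of class `norm_bounds` with `min_x`, `max_x`, `mean`,
#'   `sd`, `n_outliers`.
#' @export
fit_bounds <- function(values, k_sd = 2) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("need at least 3 finite values", call. = FALSE)
  if (max(v) - min(v) < 1e-300) {
    stop("all values identical: zero normalization range", call. = FALSE)
  }
  n <- length(v)
  s_all <- sum(v); ss_all <- sum(v^2)
  is_out <- vapply(seq_len(n), function(i) {
    m <- (s_all - v[i]) / (n - 1)
    varr <- (ss_all - v[i]^2 - (n - 1) * m^2) / (n - 2)
    varr <- max(varr, 0)
    abs(v[i] - m) > k_sd * sqrt(varr)
  }, logical(1))
  if (all(is_out)) stop("every value flagged as outlier", call. = FALSE)
  keep <- v[!is_out]
  lo <- min(keep); hi <- max(keep)
  if (hi - lo < 1e-300) {
    stop("zero normalization range after outlier shrinkage", call. = FALSE)
  }
  structure(list(min_x = lo, max_x = hi, mean = mean(v), sd = sd(v),
                 n_outliers = sum(is_out)),
            class = "norm_bounds")
}

#' Min-max normalize against fitted bounds
#'
#' `(x - min) / (max - min)`, clipped to `[0, 1]` so that shrunk outliers
#' land exactly on the bounds.
#'
#' @param x Numeric vector.
#' @param bounds A [fit_bounds()] object.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_feature <- function(x, bounds) {
  stopifnot(inherits(bounds, "norm_bounds"))
  pmin(pmax((x - bounds$min_x) / (bounds$max_x - bounds$min_x), 0), 1)
}

#' Assemble normalized per-minute DCL components for a session pair
#'
#' Takes the raw per-minute feature series of the two conditions
#' (beta/alpha RPL ratio, HbO amplitude, heart rate), fits one set of
#' normalization bounds per feature on the *pooled* minutes of both
#' conditions (so the two sessions are scaled commonly, which the relative
#' DCL requires), and returns the normalized component tibbles.
#'
#' @param well,sleep Tibbles with columns `minute`, `ratio`, `hbo`, `hr`
#'   (equal length).
#' @param k_sd Outlier multiplier passed to [fit_bounds()].
#' @return List with `well` and `sleep` component tibbles (`minute`,
#'   `norm_ratio`, `norm_hbo`, `norm_hr`) and the fitted `bounds`.
#' @export
build_dcl_components <- function(well, sleep, k_sd = 2) {
  need <- c("minute", "ratio", "hbo", "hr")
  stopifnot(all(need %in% names(well)), all(need %in% names(sleep)))
  if (nrow(well) != nrow(sleep)) {
    stop("the two sessions have different numbers of minutes", call. = FALSE)
  }
  bounds <- list(ratio = fit_bounds(c(well$ratio, sleep$ratio), k_sd),
                 hbo = fit_bounds(c(well$hbo, sleep$hbo), k_sd),
                 hr = fit_bounds(c(well$hr, sleep$hr), k_sd))
  normalize_one <- function(df) {
    tibble(minute = df$minute,
           norm_ratio = normalize_feature(df$ratio, bounds$ratio),
           norm_hbo = normalize_feature(df$hbo, bounds$hbo),
           norm_hr = normalize_feature(df$hr, bounds$hr))
  }
  list(well = normalize_one(well), sleep = normalize_one(sleep),
       bounds = bounds)
}

#' Compute the Driving Condition Level
#'
#' Per-minute weighted sum of the three normalized components,
#' `DCL = a * norm(beta/alpha RPL) + b * norm(HbO) + c * norm(HR)`, bounded
#' by `a + b + c` (3 at the unit default, where higher means more alert).
#' The session-level DCL is the mean over minutes.
#'
#' @param components Tibble with columns `minute`, `norm_ratio`, `norm_hbo`,
#'   `norm_hr`, each in `[0, 1]`.
#' @param weights Numeric `(a, b, c)` (default equal unit weights).
#' @param condition Optional condition label carried into the result.
#' @return A tibble of class `dcl_record` with columns `minute`, `dcl`;
#'   attributes `dcl_session` (mean), `weights`, `condition`.
#' @export
compute_dcl <- function(components, weights = c(1, 1, 1), condition = NA_character_) {
  need <- c("minute", "norm_ratio", "norm_hbo", "norm_hr")
  stopifnot(all(need %in% names(components)), length(weights) == 3)
  comp <- components[c("norm_ratio", "norm_hbo", "norm_hr")]
  if (any(unlist(comp) < -1e-9 | unlist(comp) > 1 + 1e-9)) {
    stop("components must lie in [0, 1]", call. = FALSE)
  }
  dcl <- weights[1] * components$norm_ratio + weights[2] * components$norm_hbo +
    weights[3] * components$norm_hr
  out <- tibble(minute = components$minute, dcl = dcl)
  class(out) <- c("dcl_record", class(out))
  attr(out, "dcl_session") <- mean(dcl)
  attr(out, "weights") <- weights
  attr(out, "condition") <- condition
  out
}

#' @rdname compute_dcl
#' @param x A `dcl_record`.
#' @param ... Unused.
#' @export
glance.dcl_record <- function(x, ...) {
  tibble(dcl_session = attr(x, "dcl_session"),
         n_minutes = nrow(x),
         condition = attr(x, "condition"))
}

#' Relative DCL between the two conditions
#'
#' `rDCL (%) = 100 - 100 * DCL_sleep_deprived / DCL_well_rested`: the
#' percentage drop of the fatigued session's DCL relative to the alert
#' session's. Higher rDCL means greater fatigue.
#'
#' @param dcl_well Session DCL in the well-rested condition (> 0); a
#'   `dcl_record` or a bare number.
#' @param dcl_sleep Session DCL in the sleep-deprived condition.
#' @return rDCL in percent.
#' @export
compute_rdcl <- function(dcl_well, dcl_sleep) {
  w <- if (inherits(dcl_well, "dcl_record")) attr(dcl_well, "dcl_session") else dcl_well
  s <- if (inherits(dcl_sleep, "dcl_record")) attr(dcl_sleep, "dcl_session") else dcl_sleep
  stopifnot(is.numeric(w), is.numeric(s))
  if (any(w <= 0)) stop("well-rested DCL must be positive", call. = FALSE)
  100 - s / w * 100
}

#' Modality-wise decomposition of the DCL difference
#'
#' Splits the session DCL difference (well-rested minus sleep-deprived) into
#' the three additive per-modality contributions,
#' `contribution_m = mean(norm_m, well) - mean(norm_m, sleep)`; the
#' contributions sum exactly to the DCL difference under unit weights.
#'
#' @param components_well,components_sleep Component tibbles as produced by
#'   [build_dcl_components()], equal length.
#' @return Tibble with columns `modality` (`eeg`, `fnirs`, `ecg`) and
#'   `contribution`.
#' @export
modality_contributions <- function(components_well, components_sleep) {
  need <- c("norm_ratio", "norm_hbo", "norm_hr")
  stopifnot(all(need %in% names(components_well)),
            all(need %in% names(components_sleep)))
  if (nrow(components_well) != nrow(components_sleep)) {
    stop("component series lengths differ", call. = FALSE)
  }
  tibble(
    modality = c("eeg", "fnirs", "ecg"),
    contribution = c(
      mean(components_well$norm_ratio) - mean(components_sleep$norm_ratio),
      mean(components_well$norm_hbo) - mean(components_sleep$norm_hbo),
      mean(components_well$norm_hr) - mean(components_sleep$norm_hr)
    )
  )
}

#' Grid search over DCL component weights
#'
#' Exhaustive search over the 11^3 grid `a, b, c` in `{0, 0.1, ..., 1}` for
#' the weighting that maximizes the session DCL difference (well-rested
#' minus sleep-deprived). Ties break deterministically to the
#' lexicographically smallest `(a, b, c)`.
#'
#' @inheritParams modality_contributions
#' @return A one-row tibble `a`, `b`, `c`, `dcl_difference`, with the full
#'   grid in attribute `grid`.
#' @export
grid_search_weights <- function(components_well, components_sleep) {
  if (nrow(components_well) != nrow(components_sleep)) {
    stop("component series lengths differ", call. = FALSE)
  }
  d <- modality_contributions(components_well, components_sleep)$contribution
  grid <- tidyr::expand_grid(a = seq(0, 1, 0.1), b = seq(0, 1, 0.1),
                             c = seq(0, 1, 0.1)) %>%
    mutate(dcl_difference = .data$a * d[1] + .data$b * d[2] + .data$c * d[3])
  best <- grid %>%
    arrange(dplyr::desc(.data$dcl_difference), .data$a, .data$b, .data$c) %>%
    dplyr::slice(1)
  attr(best, "grid") <- grid
  best
}
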