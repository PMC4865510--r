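#' Specify a zero-phase Butterworth filter
#'
#' @param kind `"bandpass"` or `"highpass"`.
#' @param lo_hz Lower edge (high-pass cutoff), Hz.
#' @param hi_hz Upper edge, Hz (band-pass only).
#' @param order Butterworth order (>= 2; applied forward-backward, so the
#'   effective attenuation is doubled).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "highpass"), lo_hz, hi_hz = NULL,
                        order = 4) {
  kind <- match.arg(kind)
  if (order < 2) stop("filter order must be >= 2", call. = FALSE)
  if (kind == "bandpass") {
    if (is.null(hi_hz) || !(lo_hz > 0 && lo_hz < hi_hz)) {
      stop("bandpass needs 0 < lo_hz < hi_hz", call. = FALSE)
    }
  } else {
    if (lo_hz <= 0) stop("highpass cutoff must be > 0", call. = FALSE)
    hi_hz <- NULL
  }
  structure(list(kind = kind, lo_hz = lo_hz, hi_hz = hi_hz, order = order),
            class = "filter_spec")
}

#' Apply a zero-phase filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, preserving length and
#' timing of transient features such as R-peaks and blinks. The series mean
#' is removed before filtering; since DC lies in the stop-band of every
#' filter this package uses, it is not added back.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered data, same shape as `x`.
#' @export
apply_filter <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"), fs > 0)
  nyq <- fs / 2
  hi_ok <- is.null(spec$hi_hz) || spec$hi_hz < nyq
  if (spec$lo_hz >= nyq || !hi_ok) {
    stop("filter edges invalid for sampling rate ", fs, " Hz", call. = FALSE)
  }
  bf <- if (spec$kind == "bandpass") {
    signal::butter(spec$order, c(spec$lo_hz, spec$hi_hz) / nyq, type = "pass")
  } else {
    signal::butter(spec$order, spec$lo_hz / nyq, type = "high")
  }
  run1 <- function(v) signal::filtfilt(bf, v - mean(v))
  if (is.matrix(x)) {
    out <- apply(x, 2, run1)
    dimnames(out) <- dimnames(x)
    out
  } else {
    run1(x)
  }
}

#' Remove a least-squares linear trend
#'
#' @param x Numeric vector (length >= 2) or samples-by-channels matrix.
#' @return Detrended data, same shape.
#' @export
detrend_linear <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, detrend_linear))
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to detrend", call. = FALSE)
  t <- seq_len(n)
  tc <- t - mean(t)
  beta <- sum(tc * x) / sum(tc^2)
  x - mean(x) - beta * tc
}

#' Fit a logistic infomax ICA model
#'
#' Blind source separation by the natural-gradient logistic infomax rule.
#' Data are centred and whitened, then the unmixing matrix is updated block
#' by block over randomly permuted sample blocks,
#' \eqn{W \leftarrow W + \eta\,(N_b I + (1-2g(u))u^\top)\,W} with
#' \eqn{u = WX_b} and logistic \eqn{g}; the learning rate anneals whenever
#' the update direction swings by more than 60 degrees, and iteration stops
#' when the relative weight change over one full pass falls below `tol`.
#' The logistic nonlinearity targets super-Gaussian sources (spiky
#' artifacts such as blinks); strongly sub-Gaussian sources separate less
#' sharply. The returned unmixing matrix includes the whitening transform,
#' so `unmixing %*% mixing` is the identity by construction.
#'
#' @param X Channels-by-samples matrix (full rank, samples >> channels).
#' @param max_iter Maximum number of full passes over the data.
#' @param tol Relative weight-change stopping threshold.
#' @param lrate Initial learning rate (default `0.00065 / log(nch + 2)`).
#' @param seed Integer seed for the block permutations.
#' @return A list of class `ica_model` with `unmixing`, `mixing`, `center`,
#'   `converged`, `iterations`.
#' @export
fit_infomax_ica <- function(X, max_iter = 512, tol = 1e-6, lrate = NULL,
                            seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) >= 2, ncol(X) > nrow(X))
  nch <- nrow(X)
  nT <- ncol(X)
  center <- rowMeans(X)
  Xc <- X - center
  eg <- eigen(tcrossprod(Xc) / (nT - 1), symmetric = TRUE)
  if (min(eg$values) <= max(eg$values) * 1e-10) {
    stop("data matrix is rank-deficient after centering", call. = FALSE)
  }
  sphere <- eg$vectors %*% diag(1 / sqrt(eg$values), nch) %*% t(eg$vectors)
  Xw <- sphere %*% Xc
  if (is.null(lrate)) lrate <- 0.00065 / log(nch + 2)
  block <- as.integer(ceiling(min(5 * log(nT), 0.3 * nT)))
  W <- diag(nch)
  converged <- FALSE
  iter <- 0L
  with_substream(seed, 0L, {
    old_W <- W
    old_delta <- NULL
    old_change <- 0
    while (iter < max_iter) {
      iter <- iter + 1L
      perm <- sample.int(nT)
      blowup <- FALSE
      for (bi in seq_len(nT %/% block)) {
        idx <- perm[((bi - 1L) * block + 1L):(bi * block)]
        u <- W %*% Xw[, idx, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        W <- W + lrate * (block * diag(nch) + (1 - 2 * y) %*% t(u)) %*% W
        if (max(abs(W)) > 1e8) { blowup <- TRUE; break }
      }
      if (blowup) {   # restart with a halved rate, as runica does
        lrate <- lrate / 2
        W <- diag(nch); old_W <- W; old_delta <- NULL
        next
      }
      delta <- as.vector(W - old_W)
      change <- sum(delta^2)
      if (!is.null(old_delta)) {
        ang <- sum(delta * old_delta) / sqrt(change * old_change + 1e-300)
        if (ang < cos(60 / 180 * pi)) lrate <- lrate * 0.9
      }
      old_delta <- delta; old_change <- change; old_W <- W
      if (sqrt(change) / sqrt(sum(W^2)) < tol) { converged <- TRUE; break }
    }
  })
  if (!converged) {
    warning("infomax ICA did not converge in ", max_iter,
            " passes; returning partial model", call. = FALSE)
  }
  unmixing <- W %*% sphere
  structure(list(unmixing = unmixing, mixing = solve(unmixing),
                 center = center, converged = converged, iterations = iter),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat("<ica_model>", nrow(x$unmixing), "components,",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Component sources of an ICA model
#'
#' @param ica An `ica_model`.
#' @param X Channels-by-samples data matrix the model applies to.
#' @return Components-by-samples source matrix.
#' @export
ica_sources <- function(ica, X) {
  stopifnot(inherits(ica, "ica_model"), is.matrix(X))
  ica$unmixing %*% (X - ica$center)
}

#' Remove ocular components from EEG
#'
#' Projects the data onto the fitted independent components, zeroes every
#' component whose absolute Pearson correlation with either EOG channel
#' exceeds `r_threshold`, and reconstructs the channel data from the
#' remaining components.
#'
#' @param X Channels-by-samples EEG matrix the ICA was fitted on.
#' @param ica An `ica_model` fitted on `X`.
#' @param eog 2-by-samples EOG matrix (horizontal, vertical).
#' @param r_threshold Absolute-correlation rejection threshold (default 0.7).
#' @return Cleaned channels-by-samples matrix, with attributes
#'   `removed_components` (indices) and `component_correlations`
#'   (components x 2 matrix of |r| against the EOG channels).
#' @export
remove_eog_components <- function(X, ica, eog, r_threshold = 0.7) {
  stopifnot(inherits(ica, "ica_model"), is.matrix(X), is.matrix(eog),
            ncol(eog) == ncol(X), nrow(eog) == 2)
  S <- ica_sources(ica, X)
  rr <- abs(cor(t(S), t(eog)))      # components x 2
  drop_idx <- which(apply(rr, 1, max) > r_threshold)
  if (length(drop_idx) == nrow(S)) {
    stop("all components exceed the EOG correlation threshold; ",
         "nothing would remain", call. = FALSE)
  }
  S[drop_idx, ] <- 0
  cleaned <- ica$mixing %*% S + ica$center
  dimnames(cleaned) <- dimnames(X)
  attr(cleaned, "removed_components") <- drop_idx
  attr(cleaned, "component_correlations") <- rr
  cleaned
}
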