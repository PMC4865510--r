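# shared fixtures: small/fast sessions and oracle utilities

# short low-rate session parameters for fast tests
quick_params <- function(ctor = well_rested_params, ..., seed = 1L) {
  args <- utils::modifyList(list(duration_s = 120, eeg_fs = 128, seed = seed),
                            list(...))
  do.call(ctor, args)
}

# unit-variance Laplacian deviates (super-Gaussian test sources for ICA)
rlaplace <- function(n) {
  u <- runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

# Amari separation index of a permutation-scaled matrix (0 = perfect)
amari_index <- function(P) {
  k <- nrow(P)
  P <- abs(P)
  s1 <- sum(rowSums(P / apply(P, 1, max)) - 1)
  s2 <- sum(colSums(P / matrix(apply(P, 2, max), k, k, byrow = TRUE)) - 1)
  (s1 + s2) / (2 * k * (k - 1))
}

# worst off-diagonal dominance of a (row-normalized) permutation-like matrix
max_crosstalk <- function(P) {
  Pn <- abs(P) / apply(abs(P), 1, max)
  max(apply(Pn, 1, function(r) sort(r, decreasing = TRUE)[2]))
}

# wide constant-intensity fNIRS table for mBLL unit tests
constant_intensity <- function(n = 400, fs = 10, value = 1000) {
  tbl <- as.data.frame(matrix(value, nrow = n, ncol = 16))
  names(tbl) <- c(paste0("ch", 1:8, "_735"), paste0("ch", 1:8, "_850"))
  dplyr::bind_cols(tibble::tibble(time_s = (seq_len(n) - 1) / fs),
                   tibble::as_tibble(tbl))
}

# baseline tibble straight from a generator's ground-truth baseline matrix
baseline_from_truth <- function(ib) {
  tibble::tibble(channel = rep(paste0("ch", 1:8), 2),
                 wavelength_nm = rep(c(735, 850), each = 8),
                 baseline = c(ib[, "735"], ib[, "850"]))
}

# brute-force exact Wilcoxon signed-rank p over all 2^n sign assignments
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  p_le <- mean(ws <= v + 1e-9)
  p_ge <- mean(ws >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Gaussian two-class feature tibble with given per-feature mean separation
gaussian_features <- function(n_trials, delta, n_features = 1, sd = 1) {
  mk <- function(cond, mu) {
    x <- matrix(rnorm(n_trials * n_features, mean = mu, sd = sd),
                nrow = n_trials)
    colnames(x) <- paste0("f", seq_len(n_features))
    dplyr::bind_cols(tibble::tibble(trial = seq_len(n_trials),
                                    condition = cond),
                     tibble::as_tibble(x))
  }
  dplyr::bind_rows(mk("well_rested", delta), mk("sleep_deprived", 0))
}
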