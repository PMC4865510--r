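#' Time-ordered sliding train/test splits
#'
#' Repetition `r` (0-based) circularly shifts the trial order by
#' `r * shift_trials`, takes the first 70% of trials as the training block
#' and the remainder as the test block, then drops the last
#' `buffer_trials` trials of each block so that no training trial lies
#' within one minute of a test trial. At the defaults (180 trials) every
#' repetition has 120 training and 48 test trials per condition, temporal
#' adjacency is kept within blocks but excluded between them, and 30
#' repetitions slide the window by one minute each.
#'
#' @param n_trials Number of trials per condition (default 180).
#' @param train_frac Training fraction (default 0.7; `n_trials * train_frac`
#'   must be integral).
#' @param buffer_trials Trials dropped from the end of each block (default
#'   6, one minute).
#' @param n_reps Number of repetitions (default 30).
#' @param shift_trials Circular shift per repetition (default 6).
#' @return A list of class `split_scheme`; each element has 1-based `train`
#'   and `test` trial-index vectors.
#' @export
make_splits <- function(n_trials = 180, train_frac = 0.7, buffer_trials = 6,
                        n_reps = 30, shift_trials = 6) {
  n_train_blk <- n_trials * train_frac
  if (abs(n_train_blk - round(n_train_blk)) > 1e-9) {
    stop("n_trials * train_frac must be integral", call. = FALSE)
  }
  n_train_blk <- as.integer(round(n_train_blk))
  n_test_blk <- n_trials - n_train_blk
  if (n_train_blk <= buffer_trials || n_test_blk <= buffer_trials) {
    stop("buffer_trials leaves an empty train or test block", call. = FALSE)
  }
  shift_trials <- as.integer(shift_trials)
  splits <- lapply(seq_len(n_reps) - 1L, function(r) {
    ord <- ((seq_len(n_trials) - 1L + r * shift_trials) %% as.integer(n_trials)) + 1L
    list(train = ord[seq_len(n_train_blk - buffer_trials)],
         test = ord[(n_train_blk + 1L):(n_trials - buffer_trials)])
  })
  structure(splits, class = "split_scheme",
            n_trials = n_trials, n_reps = n_reps)
}

#' Fit a Fisher linear discriminant
#'
#' Two-class FLDA with the closed-form weight vector
#' `w = (S_pooled + lambda I)^-1 (mu_1 - mu_0)` and the bias placing the
#' decision boundary at the projected midpoint of the class means. A small
#' ridge `lambda = shrink * trace(S)/p` keeps the pooled covariance
#' invertible. Scores are positive toward the second factor level; exact
#' zeros (boundary ties) classify as the first level.
#'
#' @param x Numeric matrix or data frame of features (rows = trials).
#' @param y Class labels with exactly two levels; the first level is the
#'   reference (class 0).
#' @param shrink Ridge fraction of the mean covariance eigenvalue (default
#'   1e-3).
#' @return A list of class `flda` with `w`, `b`, `means`, `levels`,
#'   `lambda`.
#' @export
fit_flda <- function(x, y, shrink = 1e-3) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("need exactly two classes", call. = FALSE)
  lev <- levels(y)
  x0 <- x[y == lev[1], , drop = FALSE]
  x1 <- x[y == lev[2], , drop = FALSE]
  if (nrow(x0) < 2 || nrow(x1) < 2) stop("need >= 2 samples per class", call. = FALSE)
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  p <- ncol(x)
  sp <- (crossprod(sweep(x0, 2, mu0)) + crossprod(sweep(x1, 2, mu1))) /
    (nrow(x0) + nrow(x1) - 2)
  lambda <- shrink * sum(diag(sp)) / p
  w <- solve(sp + diag(lambda, p), mu1 - mu0)
  b <- -sum(w * (mu0 + mu1) / 2)
  structure(list(w = as.numeric(w), b = b,
                 means = rbind(mu0 = mu0, mu1 = mu1),
                 pooled_cov = sp, levels = lev, lambda = lambda,
                 n = c(nrow(x0), nrow(x1)),
                 features = colnames(x) %||% paste0("x", seq_len(p))),
            class = "flda")
}

#' @export
print.flda <- function(x, ...) {
  cat("<flda>", length(x$w), "feature(s);", x$levels[1], "vs", x$levels[2], "\n")
  invisible(x)
}

#' @rdname fit_flda
#' @param x A fitted `flda` model (for `tidy`/`glance`).
#' @param ... Unused.
#' @export
tidy.flda <- function(x, ...) {
  tibble(term = x$features, estimate = x$w)
}

#' @rdname fit_flda
#' @export
glance.flda <- function(x, ...) {
  tibble(bias = x$b, lambda = x$lambda, n_class0 = x$n[1], n_class1 = x$n[2])
}

#' Predict from a fitted FLDA
#'
#' @param object A fitted `flda`.
#' @param newdata Feature matrix/data frame with matching columns.
#' @param ... Unused.
#' @return Tibble with `score` (signed discriminant, positive toward the
#'   second level) and `label` (factor); a score of exactly 0 ties to the
#'   first level.
#' @export
predict.flda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$w)) {
    stop("feature dimension mismatch: model has ", length(object$w),
         ", data has ", ncol(x), call. = FALSE)
  }
  score <- as.numeric(x %*% object$w + object$b)
  tibble(score = score,
         label = factor(ifelse(score > 0, object$levels[2], object$levels[1]),
                        levels = object$levels))
}

# internal: rows of `features` for the given trial indices, both conditions
split_rows <- function(features, trial_idx) {
  features[features$trial %in% trial_idx, , drop = FALSE]
}

feature_cols <- function(features) {
  setdiff(names(features), c("trial", "condition"))
}

#' Classification accuracy of one modality over all repetitions
#'
#' For every repetition of the split scheme: fit an FLDA on the training
#' trials of both conditions and score accuracy on the held-out test trials.
#' Rows with missing features are dropped before fitting.
#'
#' @param features Tibble with columns `trial`, `condition` (two-level
#'   factor/character) and one or more feature columns.
#' @param splits A [make_splits()] scheme.
#' @return A tibble of class `modality_eval` with columns `repetition`,
#'   `accuracy`; `glance()` gives mean and sd.
#' @export
evaluate_modality <- function(features, splits) {
  stopifnot(inherits(splits, "split_scheme"), is.data.frame(features))
  fcols <- feature_cols(features)
  if (length(fcols) == 0) stop("no feature columns", call. = FALSE)
  features <- features[stats::complete.cases(features), , drop = FALSE]
  acc <- map_dbl(seq_along(splits), function(r) {
    tr <- split_rows(features, splits[[r]]$train)
    te <- split_rows(features, splits[[r]]$test)
    m <- fit_flda(tr[fcols], tr$condition)
    pred <- predict(m, te[fcols])
    mean(as.character(pred$label) == as.character(te$condition))
  })
  out <- tibble(repetition = seq_along(splits), accuracy = acc)
  class(out) <- c("modality_eval", class(out))
  out
}

#' @rdname evaluate_modality
#' @param x A `modality_eval`.
#' @param ... Unused.
#' @export
glance.modality_eval <- function(x, ...) {
  tibble(mean_accuracy = mean(x$accuracy), sd_accuracy = sd(x$accuracy),
         n_reps = nrow(x))
}

# out-of-fold level-1 scores on the training block via contiguous k-fold
oof_scores <- function(train_tbl, fcols, n_folds) {
  n <- nrow(train_tbl)
  # folds contiguous in trial order (both conditions of a trial share a fold)
  fold <- cut(rank(train_tbl$trial, ties.method = "min"), n_folds,
              labels = FALSE)
  score <- numeric(n)
  for (k in seq_len(n_folds)) {
    hold <- fold == k
    m <- fit_flda(train_tbl[!hold, fcols, drop = FALSE],
                  train_tbl$condition[!hold])
    score[hold] <- predict(m, train_tbl[hold, fcols, drop = FALSE])$score
  }
  score
}

#' Stacked fusion of per-modality classifiers
#'
#' Within each repetition, the first-level FLDA of every modality produces
#' discriminant scores; a second-level FLDA fit on those scores makes the
#' final call. To avoid training-on-training leakage, the second level is
#' trained on *out-of-fold* first-level scores (contiguous 5-fold within the
#' training block); at test time the first-level models are refit on the
#' full training block.
#'
#' @param features_list Named list (>= 2) of per-modality feature tibbles as
#'   in [evaluate_modality()], aligned on `trial`/`condition`.
#' @param splits A [make_splits()] scheme.
#' @param n_folds Internal folds for the out-of-fold scores (default 5).
#' @return A list of class `fusion_result`: `fused` (per-repetition accuracy
#'   tibble), `single` (per-modality `modality_eval`s), `summary` (tibble of
#'   mean/sd accuracy per modality and fused).
#' @export
fuse_classifiers <- function(features_list, splits, n_folds = 5) {
  stopifnot(is.list(features_list), inherits(splits, "split_scheme"))
  if (length(features_list) < 2) {
    stop("need at least two modalities to fuse", call. = FALSE)
  }
  if (is.null(names(features_list))) {
    names(features_list) <- paste0("modality", seq_along(features_list))
  }
  features_list <- lapply(features_list, function(f) {
    f[stats::complete.cases(f), , drop = FALSE]
  })
  common <- Reduce(intersect, lapply(features_list, function(f) {
    paste(f$condition, f$trial)
  }))
  features_list <- lapply(features_list, function(f) {
    f[paste(f$condition, f$trial) %in% common, , drop = FALSE] %>%
      arrange(.data$condition, .data$trial)
  })
  fused_acc <- map_dbl(seq_along(splits), function(r) {
    tr_idx <- splits[[r]]$train
    te_idx <- splits[[r]]$test
    lvl1_scores_tr <- NULL
    lvl1_scores_te <- NULL
    ref <- NULL
    for (f in features_list) {
      fcols <- feature_cols(f)
      tr <- split_rows(f, tr_idx)
      te <- split_rows(f, te_idx)
      if (is.null(ref)) ref <- list(tr = tr, te = te)
      s_tr <- oof_scores(tr, fcols, n_folds)
      m_full <- fit_flda(tr[fcols], tr$condition)
      s_te <- predict(m_full, te[fcols])$score
      lvl1_scores_tr <- cbind(lvl1_scores_tr, s_tr)
      lvl1_scores_te <- cbind(lvl1_scores_te, s_te)
    }
    colnames(lvl1_scores_tr) <- names(features_list)
    colnames(lvl1_scores_te) <- names(features_list)
    m2 <- fit_flda(lvl1_scores_tr, ref$tr$condition)
    pred <- predict(m2, lvl1_scores_te)
    mean(as.character(pred$label) == as.character(ref$te$condition))
  })
  single <- lapply(features_list, evaluate_modality, splits = splits)
  single_summary <- bind_rows(imap(single, function(ev, nm) {
    glance(ev) %>% mutate(modality = nm, .before = 1)
  }))
  summary <- bind_rows(
    single_summary,
    tibble(modality = "fused", mean_accuracy = mean(fused_acc),
           sd_accuracy = sd(fused_acc), n_reps = length(fused_acc))
  )
  structure(list(fused = tibble(repetition = seq_along(splits),
                                accuracy = fused_acc),
                 single = single, summary = summary),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>\n")
  print(x$summary)
  invisible(x)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact test for paired samples. Zero differences are dropped
#' (documented convention); ties in the absolute differences get average
#' ranks. The null distribution of the positive-rank sum is computed exactly
#' over all `2^n` sign assignments via a shift convolution on the (doubled,
#' hence integer) ranks, so it is valid with ties and cheap for any
#' practical `n` (capped at 50).
#'
#' @param a,b Paired numeric vectors.
#' @return An object of class `htest` with the rank-sum statistic `V` and
#'   the exact two-sided p-value
#'   `min(1, 2 * min(P(W <= V), P(W >= V)))`.
#' @export
wilcoxon_signed_rank_exact <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) stop("fewer than 2 non-zero differences", call. = FALSE)
  if (n > 50) stop("n > 50 not supported; use wilcox.test", call. = FALSE)
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled ranks are integers
  v2 <- sum(r2[d > 0])
  # counts over the doubled rank-sum support, all 2^n sign assignments
  tot <- sum(r2)
  cnt <- numeric(tot + 1)      # index i-1 = doubled rank sum
  cnt[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), cnt[seq_len(tot + 1 - r)])
    cnt <- cnt + shifted
  }
  p_le <- sum(cnt[seq_len(v2 + 1)]) / 2^n
  p_ge <- sum(cnt[(v2 + 1):(tot + 1)]) / 2^n
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(statistic = c(V = v2 / 2), p.value = p,
                 method = "Exact Wilcoxon signed-rank test (two-sided)",
                 data.name = paste(deparse(substitute(a)), "vs",
                                   deparse(substitute(b))),
                 n = n),
            class = "htest")
}
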