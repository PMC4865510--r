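test_that("sliding splits have the published block sizes, gaps and coverage", {
  sp <- make_splits()
  expect_length(sp, 30)
  for (r in seq_along(sp)) {
    tr <- sp[[r]]$train
    te <- sp[[r]]$test
    expect_length(tr, 120)
    expect_length(te, 48)
    expect_length(intersect(tr, te), 0)
    # 6-trial buffer: no train trial within 6 slots of a test trial in the
    # circularly shifted order
    shift <- (r - 1) * 6
    pos <- function(i) ((i - 1 - shift) %% 180) + 1
    expect_true(min(abs(outer(pos(tr), pos(te), "-"))) >= 6)
  }
  expect_identical(sp[[1]]$train, 1:120)
  expect_identical(sp[[1]]$test, 127:174)
  expect_error(make_splits(n_trials = 100, train_frac = 0.715), "integral")
  expect_error(make_splits(n_trials = 20, buffer_trials = 6), "empty")
})

test_that("FLDA matches the closed-form discriminant and MASS::lda direction", {
  set.seed(61)
  n <- 500
  x <- rbind(matrix(rnorm(n), ncol = 1), matrix(rnorm(n, 3), ncol = 1))
  colnames(x) <- "f1"
  y <- rep(c("a", "b"), each = n)
  m <- fit_flda(x, y)
  expect_gt(m$w[1], 0)
  boundary <- -m$b / m$w[1]
  expect_equal(boundary, 1.5, tolerance = 0.2)

  # uninformative second feature gets a near-zero weight
  set.seed(62)
  x2 <- cbind(x, f2 = rnorm(2 * n))
  m2 <- fit_flda(x2, y)
  expect_lt(abs(m2$w[2]) / abs(m2$w[1]), 0.1)

  # closed form w = Sp^-1 (mu1 - mu0) on a small instance, against a direct
  # computation and against MASS::lda's scaling direction
  set.seed(63)
  x3 <- matrix(rnorm(1800), ncol = 3)
  x3[301:600, ] <- x3[301:600, ] + rep(c(1, -0.5, 0.25), each = 300)
  colnames(x3) <- paste0("f", 1:3)
  y3 <- rep(c("a", "b"), each = 300)
  m3 <- fit_flda(x3, y3, shrink = 0)
  mu0 <- colMeans(x3[1:300, ]); mu1 <- colMeans(x3[301:600, ])
  sp <- (crossprod(sweep(x3[1:300, ], 2, mu0)) +
           crossprod(sweep(x3[301:600, ], 2, mu1))) / 598
  expect_equal(m3$w, as.numeric(solve(sp, mu1 - mu0)), tolerance = 1e-9)
  lda_dir <- as.numeric(MASS::lda(x3, y3)$scaling)
  cosine <- sum(m3$w * lda_dir) / sqrt(sum(m3$w^2) * sum(lda_dir^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-6)

  # label swap flips the discriminant
  m3r <- fit_flda(x3, factor(y3, levels = c("b", "a")), shrink = 0)
  expect_equal(m3r$w, -m3$w, tolerance = 1e-9)
  expect_error(fit_flda(x3, rep("a", 600)), "two classes")
})

test_that("prediction scores are affine and ties go to the first class", {
  m <- list(w = c(1, 0), b = -1, levels = c("c0", "c1"),
            features = c("f1", "f2"))
  class(m) <- "flda"
  p <- predict(m, cbind(f1 = c(0, 1, 2), f2 = 0))
  expect_equal(p$score, c(-1, 0, 1))
  expect_equal(as.character(p$label), c("c0", "c0", "c1"))
  # affine in the inputs: score(2x) = 2 score(x) - b
  p2 <- predict(m, cbind(f1 = c(0, 2, 4), f2 = 0))
  expect_equal(p2$score, 2 * p$score + 1)
  expect_error(predict(m, cbind(f1 = 1)), "dimension mismatch")

  set.seed(64)
  tr <- gaussian_features(100, delta = 2)
  model <- fit_flda(tr[c("f1")], tr$condition)
  td <- tidy(model)
  expect_named(td, c("term", "estimate"))
  expect_equal(glance(model)$n_class0, 100)
})

test_that("modality evaluation is near chance without signal and high with d'=3", {
  set.seed(65)
  splits <- make_splits()
  null_feat <- gaussian_features(180, delta = 0)
  ev0 <- evaluate_modality(null_feat, splits)
  expect_equal(nrow(ev0), 30)
  expect_gt(glance(ev0)$mean_accuracy, 0.40)
  expect_lt(glance(ev0)$mean_accuracy, 0.60)

  sep_feat <- gaussian_features(180, delta = 3)  # d' = 3
  ev3 <- evaluate_modality(sep_feat, splits)
  expect_gte(glance(ev3)$mean_accuracy, 0.90)

  perfect <- gaussian_features(180, delta = 100)
  expect_equal(glance(evaluate_modality(perfect, splits))$mean_accuracy, 1)
})

test_that("stacked fusion behaves sensibly on informative and redundant inputs", {
  set.seed(66)
  splits <- make_splits()
  strong <- gaussian_features(180, delta = 3)
  noise <- gaussian_features(180, delta = 0)
  fr <- fuse_classifiers(list(strong = strong, noise = noise), splits)
  acc_strong <- glance(evaluate_modality(strong, splits))$mean_accuracy
  fused <- fr$summary$mean_accuracy[fr$summary$modality == "fused"]
  expect_gte(fused, acc_strong - 0.02)

  # three identical copies add nothing
  fr3 <- fuse_classifiers(list(a = strong, b = strong, c = strong), splits)
  fused3 <- fr3$summary$mean_accuracy[fr3$summary$modality == "fused"]
  expect_equal(fused3, acc_strong, tolerance = 0.02)

  expect_error(fuse_classifiers(list(a = strong), splits), "at least two")
})

test_that("three weak independent modalities fuse above the best single one", {
  set.seed(67)
  splits <- make_splits()
  weak <- replicate(3, gaussian_features(180, delta = 0.77), simplify = FALSE)
  names(weak) <- c("eeg", "ecg", "fnirs")
  fr <- fuse_classifiers(weak, splits)
  singles <- fr$summary$mean_accuracy[fr$summary$modality != "fused"]
  fused <- fr$summary$mean_accuracy[fr$summary$modality == "fused"]
  expect_gt(fused, max(singles))
})

test_that("exact Wilcoxon matches the brute-force enumeration oracle", {
  set.seed(68)
  for (n in c(3, 5, 8, 10)) {
    for (rep in 1:3) {
      a <- rnorm(n)
      b <- rnorm(n)
      got <- wilcoxon_signed_rank_exact(a, b)
      expect_equal(got$p.value, wilcoxon_enum_oracle(a, b), tolerance = 1e-12,
                   label = paste0("n=", n, " rep=", rep))
    }
  }
  # agreement with R's exact implementation when there are no ties
  a <- c(2.1, 0.4, 3.3, -0.7, 1.8, 0.9, -1.2)
  b <- c(1.0, 0.1, 2.0, 0.3, 0.2, 0.8, -0.5)
  expect_equal(wilcoxon_signed_rank_exact(a, b)$p.value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("all-positive differences give the extreme two-sided p-value", {
  w <- wilcoxon_signed_rank_exact(2:12, 1:11)
  expect_equal(w$p.value, 2 / 2^11, tolerance = 1e-15)
  expect_equal(unname(w$statistic), sum(1:11))

  # perfectly symmetric differences sit at the distribution center
  a <- c(1, 2, 3, 4)
  b <- c(2, 1, 5, 2)   # d = -1, 1, -2, 2
  expect_equal(wilcoxon_signed_rank_exact(a, b)$p.value, 1)
  expect_error(wilcoxon_signed_rank_exact(1:3, 1:3), "non-zero")
})
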