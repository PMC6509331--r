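test_that("feature window geometry and lag counts follow the configuration", {
  cfg <- feature_window_config(length = 1.4, spacing = 0.2)
  expect_equal(cfg$n_lags, 8)
  expect_equal(feature_window_config(length = 0)$n_lags, 1)
  # center alignment straddles t_ref; causal alignment ends at t_ref
  expect_equal(lag_times(cfg, 1), seq(1 - 0.7, 1 + 0.7, by = 0.2))
  ccfg <- feature_window_config(length = 1.4, alignment = "causal")
  expect_equal(lag_times(ccfg, 2), seq(2 - 1.4, 2, by = 0.2))
})

test_that("feature extraction is channel-major over the good EEG channels", {
  # 61 good EEG channels x 8 lags = 488 features
  mont <- standard_montage()
  set.seed(1)
  dat <- array(rnorm(3 * nrow(mont) * 1280), c(3, nrow(mont), 1280))
  ep <- epoch_set(dat, -2, 256, mont, letters[1:3])
  X <- extract_features(ep, 0, feature_window_config())
  expect_equal(ncol(X), 61 * 8)
  # zero-length window: one sample per channel
  X0 <- extract_features(ep, 0, feature_window_config(length = 0))
  expect_equal(ncol(X0), 61)
  # identical epochs give identical rows
  ep$data[2, , ] <- ep$data[1, , ]
  X2 <- extract_features(ep, 0, feature_window_config())
  expect_equal(X2[1, ], X2[2, ])
  # values sit at the lag grid of the named channel
  cz_row <- which(mont$name == "Cz")
  i_lag <- round((lag_times(feature_window_config(), 0)[1] + 2) * 256) + 1
  expect_equal(unname(X[1, grep("^Cz@", colnames(X))[1]]),
               ep$data[1, cz_row, i_lag])
  # lags outside the epoch are refused by name
  expect_error(extract_features(ep, -1.9, feature_window_config()),
               "lag outside")
})

test_that("shrinkage LDA separates well-separated Gaussian classes", {
  set.seed(5)
  d <- 20; n <- 60
  X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, mean = 10), n))
  y <- rep(c("a", "b"), each = n)
  te <- c(1:15, n + 1:15)
  m <- fit_slda(X[-te, ], y[-te])
  expect_gt(mean(predict(m, X[te, ], type = "class") == y[te]), 0.99)
  expect_gte(m$lambda, 0); expect_lte(m$lambda, 1)
})

test_that("lambda = 0 reproduces the direct-inversion LDA oracle", {
  set.seed(8)
  d <- 5; n <- 80
  X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, 1), n),
             matrix(rnorm(n * d, -1), n))
  y <- rep(c("a", "b", "c"), each = n)
  m0 <- fit_slda(X, y, lambda = 0)
  # independent oracle: explicit pooled-covariance inversion
  cls <- sort(unique(y))
  mu <- sapply(cls, function(cl) colMeans(X[y == cl, ]))
  Sp <- Reduce(`+`, lapply(cls, function(cl)
    crossprod(scale(X[y == cl, ], center = TRUE, scale = FALSE)))) /
    (3 * n - 3)
  sc <- sapply(cls, function(cl) {
    w <- solve(Sp, mu[, cl])
    X %*% w - 0.5 * sum(mu[, cl] * w) + log(1 / 3)
  })
  p_or <- exp(sc - apply(sc, 1, max)); p_or <- p_or / rowSums(p_or)
  expect_equal(unname(predict(m0, X)), unname(p_or), tolerance = 1e-10)
  # singular covariance at lambda = 0 instructs shrinkage
  Xs <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(fit_slda(Xs, y, lambda = 0), "lambda > 0")
})

test_that("lambda = 1 collapses to nearest class mean under the scaled identity", {
  set.seed(9)
  X <- rbind(matrix(rnorm(100 * 3), 100), matrix(rnorm(100 * 3, 1.5), 100))
  y <- rep(c("a", "b"), each = 100)
  m1 <- fit_slda(X, y, lambda = 1, priors = "uniform")
  mu <- sapply(c("a", "b"), function(cl) colMeans(X[y == cl, ]))
  nearest <- c("a", "b")[apply(X, 1, function(x)
    which.min(colSums((x - mu)^2)))]
  expect_equal(as.character(predict(m1, X, type = "class")), nearest)
})

test_that("softmax probabilities are proper and tie/shift invariant", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40 * 4), 40), matrix(rnorm(40 * 4, 2), 40))
  y <- rep(c("a", "b"), each = 40)
  m <- fit_slda(X, y, priors = "uniform")
  p <- predict(m, X)
  expect_equal(rowSums(p), rep(1, 80), tolerance = 1e-9)
  # a sample at a class mean takes that class
  mu_a <- colMeans(X[y == "a", , drop = FALSE])
  expect_equal(as.character(predict(m, rbind(mu_a), type = "class")), "a")
  # equidistant sample: exactly (0.5, 0.5)
  mid <- rbind((mu_a + colMeans(X[y == "b", , drop = FALSE])) / 2)
  expect_equal(unname(predict(m, mid)[1, ]), c(0.5, 0.5), tolerance = 1e-9)
  # adding a constant to all scores leaves probabilities unchanged
  m_shift <- m; m_shift$b <- m$b + 13.7
  expect_equal(unname(predict(m_shift, X)), unname(p), tolerance = 1e-9)
})

test_that("sliding accuracy is deterministic and affine/permutation invariant", {
  ep <- make_template_epochs(8, 77, noise = 3)
  cfg <- feature_window_config(length = 0.6)
  a1 <- sliding_accuracy(ep, cfg, folds = 4, repeats = 2, seed = 3,
                         times = c(0.9, 1.2))
  a2 <- sliding_accuracy(ep, cfg, folds = 4, repeats = 2, seed = 3,
                         times = c(0.9, 1.2))
  expect_identical(a1$accuracy, a2$accuracy)
  # microvolt rescaling by a positive constant
  eps <- ep; eps$data <- eps$data * 7.3
  a3 <- sliding_accuracy(eps, cfg, folds = 4, repeats = 2, seed = 3,
                         times = c(0.9, 1.2))
  expect_equal(a3$accuracy, a1$accuracy, tolerance = 1e-8)
  # channel reordering
  set.seed(1); perm <- sample(nrow(ep$channels))
  epp <- epoch_set(ep$data[, perm, , drop = FALSE], ep$t0_offset, ep$rate,
                   ep$channels[perm, ], ep$labels)
  a4 <- sliding_accuracy(epp, cfg, folds = 4, repeats = 2, seed = 3,
                         times = c(0.9, 1.2))
  expect_equal(a4$accuracy, a1$accuracy, tolerance = 1e-8)
  # too few trials per class for the fold count
  expect_error(sliding_accuracy(ep, cfg, folds = 20, repeats = 1,
                                times = 1), "folds")
})

test_that("confusion matrices are row-stochastic and mirror class similarity", {
  # perfectly separated toy classes -> 100% diagonal
  mont <- standard_montage("reduced")
  set.seed(20)
  n_s <- 64
  dat <- array(rnorm(40 * nrow(mont) * n_s, sd = 0.01),
               c(40, nrow(mont), n_s))
  dat[1:20, 5, ] <- dat[1:20, 5, ] + 10
  ep <- epoch_set(dat, 0, 64, mont, rep(c("a", "b"), each = 20))
  cm <- confusion_at(ep, 0.5, feature_window_config(length = 0),
                     folds = 4, repeats = 1, seed = 2)
  expect_equal(unname(diag(cm)), c(100, 100))
  expect_equal(unname(rowSums(cm)), c(100, 100))
  # overlapping grasp templates confuse each other more than pronation
  set.seed(21)
  tp <- flat_params()
  tp["palmar_grasp", c("pos_amp_mean", "neg_amp_mean")] <- c(6.6, -4.4)
  tp["lateral_grasp", c("pos_amp_mean", "neg_amp_mean")] <- c(6.7, -4.5)
  tp["lateral_grasp", c("pos_lat_mean", "neg_lat_mean")] <-
    tp["palmar_grasp", c("pos_lat_mean", "neg_lat_mean")] + 0.02
  gain <- mrcp_spatial_pattern(mont)
  classes <- rep(c("pronation", "palmar_grasp", "lateral_grasp"), each = 30)
  dat2 <- array(0, c(length(classes), nrow(mont), 224))
  for (i in seq_along(classes)) {
    wf <- make_mrcp_waveform(classes[i], tp, rate = 64, duration = 3.5)
    dat2[i, , ] <- outer(gain, wf$waveform) +
      matrix(rnorm(nrow(mont) * 224, sd = 2.5), nrow(mont))
  }
  ep2 <- epoch_set(dat2, 0, 64, mont, classes)
  cm2 <- confusion_at(ep2, 1.1, feature_window_config(length = 1),
                      folds = 5, repeats = 2, seed = 4)
  expect_gt(cm2["palmar_grasp", "lateral_grasp"],
            cm2["palmar_grasp", "pronation"])
  expect_gt(cm2["lateral_grasp", "palmar_grasp"],
            cm2["lateral_grasp", "pronation"])
})

test_that("longer feature windows saturate rather than degrade accuracy", {
  ep <- make_template_epochs(30, 12)
  lens <- seq(0, 1.4, by = 0.2)
  accs <- vapply(lens, function(L)
    mean(sliding_accuracy(ep, feature_window_config(length = L),
                          folds = 5, repeats = 1, seed = 3,
                          times = 1.1)$accuracy), 0)
  expect_gt(accs[length(accs)], accs[1] + 20)
  expect_gt(stats::cor(lens, accs, method = "spearman"), 0.5)
})

test_that("more training trials do not degrade accuracy (across seeds)", {
  gains <- vapply(1:10, function(s) {
    a1 <- mean(sliding_accuracy(make_template_epochs(8, 100 + s),
                                folds = 4, repeats = 1, seed = 1,
                                times = 1.1)$accuracy)
    a2 <- mean(sliding_accuracy(make_template_epochs(24, 100 + s),
                                folds = 4, repeats = 1, seed = 1,
                                times = 1.1)$accuracy)
    a2 - a1
  }, 0)
  expect_lt(stats::t.test(gains, alternative = "greater")$p.value, 0.05)
})
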