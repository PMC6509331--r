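sine_rec <- function(freqs, rate = 256, dur = 20, mont_rows = 4) {
  mont <- standard_montage("reduced")[c(8, 20:22), ][seq_len(mont_rows), ]
  tt <- (0:(dur * rate - 1)) / rate
  sig <- do.call(rbind, lapply(seq_len(mont_rows), function(i)
    if (i <= length(freqs)) sin(2 * pi * freqs[i] * tt) else 0 * tt))
  eeg_recording(sig, rate, mont)
}

# amplitude of a sinusoid at f Hz in x, by least squares on a steady segment
fit_gain <- function(x, f, rate) {
  idx <- (5 * rate):(15 * rate)
  tt <- (idx - 1) / rate
  co <- stats::coef(stats::lm(x[idx] ~ sin(2 * pi * f * tt) +
                                cos(2 * pi * f * tt) - 1))
  sqrt(sum(co^2))
}

test_that("band-pass magnitude response matches the analytic Butterworth oracle", {
  rate <- 256
  rec <- sine_rec(c(1, 10))
  out <- bandpass(rec, 0.3, 3)
  # analytic two-pass (squared) magnitude response
  b <- signal::butter(4, c(0.3, 3) / (rate / 2), "pass")
  h <- signal::freqz(b, n = 2^14, Fs = rate)
  g1_oracle <- abs(h$h[which.min(abs(h$f - 1))])^2
  g1 <- fit_gain(out$signals[1, ], 1, rate)
  expect_lt(abs(g1 - g1_oracle), 0.01)
  expect_gt(g1, 0.95); expect_lt(g1, 1.005)   # 1 Hz passes (design ripple)
  expect_lt(fit_gain(out$signals[2, ], 10, rate), 1e-3)  # 10 Hz blocked
  # a DC offset is in the deep stop band (measured away from the edge
  # transients of the 0.3 Hz high-pass, which decay over seconds)
  dc <- sine_rec(numeric(0), dur = 80, mont_rows = 1)
  dc$signals[1, ] <- 5
  mid <- (35 * rate):(45 * rate)
  expect_lt(max(abs(bandpass(dc, 0.3, 3)$signals[1, mid])), 5 * 1e-3)
  expect_error(bandpass(rec, 3, 0.3), "invalid band")
  expect_error(bandpass(rec, 0.3, 200), "invalid band")
})

test_that("zero-phase filtering introduces no group delay", {
  rate <- 256
  set.seed(6)
  mont <- standard_montage("reduced")[c(8, 20:22), ]
  x <- as.numeric(stats::filter(rnorm(rate * 20), rep(1, 4), sides = 1))
  x[is.na(x)] <- 0
  rec <- eeg_recording(rbind(x, x, x, x), rate, mont)
  y <- bandpass(rec, 0.3, 3)$signals[1, ]
  cc <- stats::ccf(y, x, lag.max = rate %/% 2, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("causal filtering is causal and starts from steady state", {
  rate <- 256
  rec <- sine_rec(1)
  out1 <- bandpass(rec, 0.3, 3, mode = "causal")
  # changing the future never changes the past
  rec2 <- rec
  cut <- 10 * rate
  rec2$signals[, (cut + 1):ncol(rec2$signals)] <- 0
  out2 <- bandpass(rec2, 0.3, 3, mode = "causal")
  expect_equal(out1$signals[, 1:cut], out2$signals[, 1:cut])
  # steady-state initialization: constant input produces no onset blow-up
  recc <- rec; recc$signals[1, ] <- 7
  yc <- bandpass(recc, 0.3, 3, mode = "causal")$signals[1, ]
  expect_lt(max(abs(yc[1:10])), 0.5)
})

test_that("the notch suppresses the line frequency and spares the passband", {
  rate <- 256
  rec <- sine_rec(c(50, 10))
  out <- notch(rec)
  idx <- (5 * rate):(15 * rate)
  expect_lt(stats::sd(out$signals[1, idx]) /
              stats::sd(rec$signals[1, idx]), 0.03)
  g10 <- fit_gain(out$signals[2, ], 10, rate)
  expect_gt(g10, 0.9); expect_lte(g10, 1.0 + 1e-6)
  # zero in, zero out
  expect_equal(max(abs(out$signals[3, ])), 0)
})

test_that("bad-channel detection flags AFz by default plus outlier channels", {
  set.seed(41)
  mont <- standard_montage("reduced")
  sig <- matrix(rnorm(nrow(mont) * 2000), nrow(mont))
  rec <- eeg_recording(sig, 256, mont)
  expect_identical(detect_bad_channels(rec), "AFz")
  # a 10x amplitude channel is caught
  i <- which(mont$name == "P3")
  rec$signals[i, ] <- rnorm(2000, sd = 10)
  expect_setequal(detect_bad_channels(rec), c("AFz", "P3"))
  # without AFz in the montage, only the variance policy applies
  sub <- mont$name != "AFz"
  rec2 <- eeg_recording(sig[sub, ], 256, mont[sub, ])
  expect_identical(detect_bad_channels(rec2), character(0))
})

test_that("the robust sample mask implements the k-MAD rule", {
  set.seed(12)
  x <- matrix(rnorm(2e5), 1)
  expect_gte(mean(robust_sample_mask(x)), 0.9999)  # 10.4 MAD ~ 7 sd
  y <- matrix(c(rnorm(500), 100), 1)
  m <- robust_sample_mask(y)
  expect_false(m[1, 501])
  expect_true(all(m[1, 1:500]))
  # constant channel: MAD = 0 keeps everything
  expect_true(all(robust_sample_mask(matrix(3, 1, 50))))
})

test_that("ICA recovers independent sources and respects rank and mask", {
  set.seed(2)
  n <- 8000; rate <- 256; tt <- (1:n) / rate
  S <- rbind(sin(2 * pi * 3 * tt), sign(sin(2 * pi * 0.73 * tt)),
             (tt * 5) %% 2 - 1)
  A <- matrix(rnorm(24), 8, 3)
  mont <- standard_montage("reduced")[2:9, ]
  rec <- eeg_recording(A %*% S + 0.02 * matrix(rnorm(8 * n), 8), rate, mont)
  m <- fit_ica(rec, variance_keep = 0.999)
  cc <- abs(stats::cor(t(ica_sources(m, rec)), t(S)))
  expect_true(all(apply(cc, 2, max) > 0.95))
  # exactly rank-2 data yields 2 components
  rec2 <- eeg_recording(A[, 1:2] %*% S[1:2, ], rate, mont)
  expect_equal(fit_ica(rec2)$n_comp, 2)
  # masked spikes do not disturb the unmixing
  rec3 <- rec
  spikes <- seq(100, n, by = 500)
  rec3$signals[3, spikes] <- 500
  m3 <- fit_ica(rec3, variance_keep = 0.999)
  cc3 <- abs(stats::cor(t(ica_sources(m3, rec)), t(S)))
  expect_true(all(apply(cc3, 2, max) > 0.95))
})

blink_rec <- function(seed = 7, n = 12000, rate = 256, n_src = 8) {
  set.seed(seed)
  mont <- standard_montage()
  gain <- mrcp_spatial_pattern(mont)
  # latent low-rank background (like real EEG), blink projecting to EOG
  # and frontal rows, and a Cz-centred MRCP train
  L <- t(sapply(seq_len(n_src), function(i) pink_noise(n, 3, rate)))
  A <- matrix(stats::rnorm(nrow(mont) * n_src), nrow(mont))
  A[mont$kind == "EOG", ] <- 0.5 * A[mont$kind == "EOG", ]
  sig <- A %*% L + matrix(stats::rnorm(nrow(mont) * n, sd = 0.3),
                          nrow(mont))
  blink <- numeric(n)
  shape <- sin(pi * seq(0, 1, length.out = round(0.4 * rate)))^2
  for (at in seq(400, n - 200, by = 500))
    blink[at + seq_along(shape) - 1] <- 60 * shape
  proj <- ifelse(mont$kind == "EOG", 1, pmax(0, mont$y - 0.2) * 0.8)
  sig <- sig + outer(proj, blink)
  mr <- numeric(n)
  wf <- make_mrcp_waveform("pronation", flat_params())
  for (at in seq(1000, n - 800, by = 1100))
    mr[at + seq_along(wf$waveform) - 1] <-
      mr[at + seq_along(wf$waveform) - 1] + wf$waveform
  sig <- sig + outer(gain, mr)
  list(rec = eeg_recording(sig, rate, mont), blink = blink, mrcp = mr,
       proj = proj)
}

# linear content of a template time course in one channel
beta_of <- function(x, template) unname(stats::coef(stats::lm(x ~ template))[2])

test_that("ocular and muscle components are identified and removable", {
  bx <- blink_rec()
  m <- fit_ica(bx$rec)
  ics <- identify_artifact_ics(m, bx$rec)
  expect_gte(length(ics), 1)
  # the flagged set contains the blink component (max EOG correlation)
  S <- ica_sources(m, bx$rec)
  r_blink <- apply(abs(stats::cor(t(S), bx$blink)), 1, max)
  expect_true(which.max(r_blink) %in% ics)
  expect_gt(max(r_blink), 0.95)
  clean <- remove_ics(bx$rec, m, ics)
  fp1 <- which(bx$rec$channels$name == "Fp1")
  cz <- which(bx$rec$channels$name == "Cz")
  # frontal blink amplitude (linear blink content) drops by > 90%
  expect_lt(abs(beta_of(clean$signals[fp1, ], bx$blink)),
            0.1 * abs(beta_of(bx$rec$signals[fp1, ], bx$blink)))
  # the Cz MRCP amplitude is preserved within 10%
  ratio <- beta_of(clean$signals[cz, ], bx$mrcp) /
    beta_of(bx$rec$signals[cz, ], bx$mrcp)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
  # no artifacts: empty set
  set.seed(30)
  mont <- standard_montage("reduced")
  quiet <- eeg_recording(matrix(rnorm(nrow(mont) * 8000), nrow(mont)),
                         256, mont)
  mq <- fit_ica(quiet, variance_keep = 0.99)
  expect_length(identify_artifact_ics(mq, quiet), 0)
  # a 40-70 Hz broadband source trips the spectral rule
  hz <- quiet
  tt <- (1:8000) / 256
  muscle <- rowSums(sapply(seq(42, 68, by = 2), function(f)
    sin(2 * pi * f * tt + stats::runif(1) * 2 * pi)))
  hz$signals[5, ] <- hz$signals[5, ] + 20 * muscle
  mh <- fit_ica(hz, variance_keep = 0.999)
  expect_gte(length(identify_artifact_ics(mh, hz)), 1)
})

test_that("removing no components is the identity; removing all leaves ~nothing", {
  bx <- blink_rec(9)
  m <- fit_ica(bx$rec, variance_keep = 0.999)
  expect_identical(remove_ics(bx$rec, m, integer(0))$signals,
                   bx$rec$signals)
  expect_error(remove_ics(bx$rec, m, 999), "out of range")
  gone <- remove_ics(bx$rec, m, seq_len(m$n_comp))
  eeg <- which(bx$rec$channels$kind == "EEG")
  v_before <- mean(apply(bx$rec$signals[eeg, ], 1, stats::var))
  v_after <- mean(apply(gone$signals[eeg, ], 1, stats::var))
  expect_lt(v_after, 0.02 * v_before)
})

test_that("trial rejection combines amplitude, joint-probability and kurtosis rules", {
  set.seed(33)
  mont <- standard_montage("reduced")
  n_tr <- 40; n_s <- 128
  dat <- array(rnorm(n_tr * nrow(mont) * n_s, sd = 5),
               c(n_tr, nrow(mont), n_s))
  ep <- epoch_set(dat, 0, 256, mont, rep("a", n_tr))
  rep0 <- mark_bad_trials(ep)
  # i.i.d. Gaussian trials: well under the 5% nominal worry level
  expect_lte(mean(rep0$rejected), 0.05)
  # a 150 uV spike trips the amplitude rule
  ep$data[7, 3, 10] <- 150
  rep1 <- mark_bad_trials(ep)
  expect_true(rep1$amplitude[7])
  expect_true(rep1$rejected[7])
  # identical trials are never flagged
  same <- epoch_set(array(rep(rnorm(nrow(mont) * n_s), each = 10),
                          c(10, nrow(mont), n_s)),
                    0, 256, mont, rep("a", 10))
  expect_false(any(mark_bad_trials(same)$rejected))
  # the mask propagates into the epoch set
  ep2 <- apply_rejection(ep, rep1)
  expect_true(ep2$rejected[7])
})

test_that("common average referencing is exact, EOG-sparing and idempotent", {
  set.seed(14)
  mont <- standard_montage("reduced")
  rec <- eeg_recording(matrix(rnorm(nrow(mont) * 500), nrow(mont)),
                       256, mont)
  out <- common_average_reference(rec)
  eeg <- which(mont$kind == "EEG")
  expect_lt(max(abs(colMeans(out$signals[eeg, ]))), 1e-12)
  expect_identical(out$signals[mont$kind == "EOG", ],
                   rec$signals[mont$kind == "EOG", ])
  # single-channel deflection keeps N * (M - 1) / M
  M <- length(eeg)
  rec2 <- rec; rec2$signals[] <- 0; rec2$signals[eeg[3], 100] <- 10
  out2 <- common_average_reference(rec2)
  expect_equal(unname(out2$signals[eeg[3], 100]), 10 * (M - 1) / M)
  # idempotence
  expect_equal(common_average_reference(out)$signals, out$signals)
  # epoch-set method agrees with the recording method
  ep <- epoch_set(array(rec$signals, c(1, nrow(mont), 500)), 0, 256, mont,
                  "a")
  expect_equal(common_average_reference(ep)$data[1, , ], out$signals,
               ignore_attr = TRUE)
})

test_that("the cleaning pipeline is near-transparent on artifact-free data", {
  pc <- paradigm_config("offline", runs = 1, trials_per_run = 10,
                        montage = "reduced", seed = 51)
  rec <- generate_offline_session(
    pc, ncfg = noise_config(pink_rms = 2, line_amp = 0, blink_rate = 0,
                            transient_rate = 0))
  full <- preprocess_recording(rec, use_ica = TRUE)
  plain <- bandpass(set_bad_channels(rec, "AFz"), 0.3, 3)
  cz <- which(rec$channels$name == "Cz")
  ep_full <- class_averages(epoch(full$rec, "class_cue", c(0, 3)))
  ep_plain <- class_averages(epoch(plain, "class_cue", c(0, 3)))
  for (cl in names(ep_full)) {
    delta <- ep_full[[cl]][cz, ] - ep_plain[[cl]][cz, ]
    expect_lt(sqrt(mean(delta^2)), 0.05 * sqrt(mean(ep_plain[[cl]][cz, ]^2)))
  }
})

test_that("cleaning blink-contaminated data improves decoding over seeds", {
  one <- function(seed) {
    pc <- paradigm_config("offline", runs = 2, trials_per_run = 15,
                          seed = seed, montage = "reduced")
    nc <- noise_config(pink_rms = 3, blink_rate = 25, blink_amp = 250,
                       transient_rate = 0, line_amp = 1)
    rec <- generate_offline_session(pc, ncfg = nc)
    acc_of <- function(clean) {
      pp <- preprocess_recording(rec, use_ica = clean)
      ep <- common_average_reference(epoch(pp$rec, "class_cue", c(-2, 3)))
      mean(sliding_accuracy(ep, folds = 3, repeats = 1, seed = 1,
                            times = c(1, 1.25))$accuracy)
    }
    acc_of(TRUE) - acc_of(FALSE)
  }
  gains <- vapply(1:10, one, 0)
  expect_lt(stats::wilcox.test(gains, alternative = "greater",
                               exact = FALSE)$p.value, 0.05)
})
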