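# Fixture builders shared across the suite. Everything is generated in
# code; rates below 256 Hz keep the stochastic tests fast while exercising
# the same code paths.

# template table with all spread parameters collapsed to zero
flat_params <- function() {
  p <- mrcp_template_params()
  p[, grep("_sd$", names(p))] <- 0
  p
}

# epochs built directly from MRCP templates + white noise on the reduced
# montage (cue-locked, t = 0 at the class cue)
make_template_epochs <- function(n_per_class, seed,
                                 classes = rownames(mrcp_template_params()),
                                 noise = 3, amp = 1, rate = 64,
                                 duration = 3.5) {
  set.seed(seed)
  mont <- standard_montage("reduced")
  gain <- mrcp_spatial_pattern(mont)
  tp <- draw_session_templates()
  n_s <- round(duration * rate)
  labs <- rep(classes, each = n_per_class)
  dat <- array(0, c(length(labs), nrow(mont), n_s))
  for (i in seq_along(labs)) {
    wf <- make_mrcp_waveform(labs[i], tp, rate = rate,
                             duration = duration, amp_scale = amp)
    dat[i, , ] <- outer(gain, wf$waveform) +
      matrix(stats::rnorm(nrow(mont) * n_s, 0, noise), nrow(mont))
  }
  epoch_set(dat, 0, rate, mont, labs)
}

# go-locked 3-class epochs (hand_open / palmar_grasp / rest) for the
# online training path, t = 0 at the go cue, epoch span -2..3 s
make_go_epochs <- function(seed, n_move = 20, n_rest = 40, rate = 64,
                           noise = 3, amp = 1) {
  set.seed(seed)
  mont <- standard_montage("reduced")
  gain <- mrcp_spatial_pattern(mont)
  tp <- draw_session_templates()
  classes <- c(rep("hand_open", n_move), rep("palmar_grasp", n_move),
               rep("rest", n_rest))
  n_s <- round(5 * rate)
  dat <- array(0, c(length(classes), nrow(mont), n_s))
  for (i in seq_along(classes)) {
    dat[i, , ] <- matrix(stats::rnorm(nrow(mont) * n_s, 0, noise),
                         nrow(mont))
    if (classes[i] != "rest") {
      wf <- make_mrcp_waveform(classes[i], tp, rate = rate, duration = 3,
                               pos_scale = 0.3, amp_scale = amp)
      idx <- round(2 * rate) + seq_along(wf$waveform)
      dat[i, , idx] <- dat[i, , idx] + outer(gain, wf$waveform)
    }
  }
  epoch_set(dat, -2, rate, mont, classes)
}

# small random recording for round-trip / epoching property tests
make_random_recording <- function(seed, n_s = 600, rate = 128) {
  set.seed(seed)
  mont <- standard_montage("reduced")
  keep <- sort(sample(nrow(mont), sample(6:12, 1)))
  mont <- mont[keep, ]
  sig <- matrix(stats::rnorm(nrow(mont) * n_s), nrow(mont))
  n_ev <- sample(0:6, 1)
  ev <- if (n_ev) {
    data.frame(onset = sort(sample(0:(n_s - 1), n_ev)),
               label = sample(c("trial_start", "class_cue:pronation",
                                "go_cue", "custom_marker"), n_ev,
                              replace = TRUE))
  } else empty_events()
  eeg_recording(sig, rate, mont, ev)
}

# pure-noise epoch sets for permutation-test calibration
make_null_epoch_sets <- function(seed, n_participants = 3, n_trials = 24,
                                 n_channels = 6, n_s = 64, rate = 64,
                                 classes = c("a", "b", "c")) {
  set.seed(seed)
  mont <- standard_montage("reduced")[seq(2, 1 + n_channels), ]
  lapply(seq_len(n_participants), function(i) {
    dat <- array(stats::rnorm(n_trials * n_channels * n_s),
                 c(n_trials, n_channels, n_s))
    epoch_set(dat, 0, rate, mont,
              rep_len(classes, n_trials))
  })
}

# minimal plain-EDF writer (16-bit), used to exercise the optional reader
write_minimal_edf <- function(path, signals, rate, labels,
                              phys_range = c(-200, 200)) {
  ns <- nrow(signals)
  n_per_rec <- rate           # 1-s records
  n_rec <- floor(ncol(signals) / n_per_rec)
  pad <- function(x, w) formatC(as.character(x), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  put("0", 8); put("synthetic", 80); put("synthetic", 80)
  put("01.01.20", 8); put("00.00.00", 8)
  put(256 + 256 * ns, 8); put("", 44); put(n_rec, 8); put(1, 8)
  put(ns, 4)
  for (l in labels) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(phys_range[1], 8)
  for (i in seq_len(ns)) put(phys_range[2], 8)
  for (i in seq_len(ns)) put(-32768, 8)
  for (i in seq_len(ns)) put(32767, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(n_per_rec, 8)
  for (i in seq_len(ns)) put("", 32)
  gain <- (phys_range[2] - phys_range[1]) / (32767 - (-32768))
  dig <- round((signals - phys_range[1]) / gain) - 32768
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * n_per_rec + seq_len(n_per_rec)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}
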