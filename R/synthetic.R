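#' MRCP template parameters per movement class
#'
#' Generative per-trial distributions of the two Cz potential peaks for the
#' five movement classes: an early positive peak (cue processing) followed
#' by a negative peak (the movement-related cortical potential proper).
#' Defaults are the descriptive statistics measured on Cz in persons with
#' cervical SCI (mean and standard deviation of peak amplitude in uV and
#' latency in seconds, latency relative to the class cue).
#'
#' @return `data.frame` with one row per class (`pronation`, `supination`,
#'   `hand_open`, `palmar_grasp`, `lateral_grasp`) and columns
#'   `pos_amp_mean`, `pos_amp_sd`, `pos_lat_mean`, `pos_lat_sd`,
#'   `neg_amp_mean`, `neg_amp_sd`, `neg_lat_mean`, `neg_lat_sd`.
#' @export
mrcp_template_params <- function() {
  p <- data.frame(
    class = c("pronation", "supination", "hand_open", "palmar_grasp",
              "lateral_grasp"),
    pos_amp_mean = c(8.01, 8.44, 8.17, 6.56, 6.68),
    pos_amp_sd   = c(2.97, 3.79, 3.36, 3.34, 2.86),
    pos_lat_mean = c(0.44, 0.49, 0.51, 0.53, 0.56),
    pos_lat_sd   = c(0.14, 0.13, 0.11, 0.08, 0.08),
    neg_amp_mean = c(-5.48, -6.05, -5.33, -4.45, -3.68),
    neg_amp_sd   = c(2.38, 2.15, 2.41, 2.02, 2.19),
    neg_lat_mean = c(1.10, 1.05, 1.35, 1.41, 1.27),
    neg_lat_sd   = c(0.09, 0.11, 0.59, 0.41, 0.21),
    stringsAsFactors = FALSE)
  rownames(p) <- p$class
  p
}

#' Draw one MRCP waveform for a movement class
#'
#' The waveform is a smooth two-lobe shape: a positive Gaussian lobe
#' followed by a negative one. Peak amplitudes and latencies are drawn from
#' the class's normal distributions (a zero standard deviation collapses to
#' a point mass at the mean). The two lobe coefficients are solved from a
#' 2x2 linear system so the waveform passes exactly through the drawn
#' amplitudes at the drawn latencies despite lobe overlap; the residual
#' tail of the opposite lobe shifts the true extrema from the drawn values
#' by well under 1% in amplitude and a few milliseconds in latency.
#'
#' @param class class name, a row of `params`.
#' @param params template table, see [mrcp_template_params()].
#' @param rate sampling rate (Hz).
#' @param duration waveform support in seconds (from the cue).
#' @param pos_width,neg_width Gaussian lobe widths (s); defaults 0.2 / 0.3.
#' @param pos_scale multiplier on the positive (cue-related) peak; the
#'   online training paradigm uses a reduced value because its go cue
#'   elicits a weaker cue-processing potential.
#' @param second_negativity add a second, half-amplitude negative lobe
#'   0.6 s after the main one (morphology of short, non-sustained attempts).
#' @param amp_scale overall amplitude multiplier.
#' @return list with `t` (seconds), `waveform` (uV), and `truth` (the drawn
#'   peak amplitudes/latencies).
#' @export
make_mrcp_waveform <- function(class, params = mrcp_template_params(),
                               rate = 256, duration = 3,
                               pos_width = 0.2, neg_width = 0.3,
                               pos_scale = 1, second_negativity = FALSE,
                               amp_scale = 1) {
  if (!class %in% rownames(params))
    stop("unknown class '", class, "'")
  p <- params[class, ]
  draw <- function(m, s) if (s > 0) stats::rnorm(1, m, s) else m
  a_pos <- draw(p$pos_amp_mean, p$pos_amp_sd) * pos_scale * amp_scale
  l_pos <- max(0.05, draw(p$pos_lat_mean, p$pos_lat_sd))
  a_neg <- draw(p$neg_amp_mean, p$neg_amp_sd) * amp_scale
  l_neg <- max(l_pos + 0.2, draw(p$neg_lat_mean, p$neg_lat_sd))
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  g1 <- exp(-(t - l_pos)^2 / (2 * pos_width^2))
  g2 <- exp(-(t - l_neg)^2 / (2 * neg_width^2))
  # coefficients so that w(l_pos) = a_pos and w(l_neg) = a_neg exactly
  c12 <- exp(-(l_neg - l_pos)^2 / (2 * neg_width^2))
  c21 <- exp(-(l_neg - l_pos)^2 / (2 * pos_width^2))
  ab <- solve(matrix(c(1, c21, c12, 1), 2), c(a_pos, a_neg))
  w <- ab[1] * g1 + ab[2] * g2
  if (second_negativity) {
    l3 <- l_neg + 0.6
    w <- w + 0.5 * a_neg * exp(-(t - l3)^2 / (2 * neg_width^2))
  }
  list(t = t, waveform = w,
       truth = list(pos_amp = a_pos, pos_lat = l_pos,
                    neg_amp = a_neg, neg_lat = l_neg))
}

#' Spatial projection pattern of the simulated MRCP
#'
#' Radially decaying gain centred on Cz (gain 1 there), reaching
#' approximately zero at temporal sites, so that simulated class
#' differences arise over the central motor cortex. EOG channels get zero
#' gain.
#'
#' @param channels channel table.
#' @param sigma spatial decay constant in head-coordinate units.
#' @return Numeric gain per channel.
#' @export
mrcp_spatial_pattern <- function(channels, sigma = 0.35) {
  cz <- channels[channels$name == "Cz", ]
  if (!nrow(cz)) stop("montage must contain Cz")
  d2 <- (channels$x - cz$x)^2 + (channels$y - cz$y)^2
  g <- exp(-d2 / (2 * sigma^2))
  g[channels$kind != "EEG"] <- 0
  g
}

#' Noise and artifact configuration for the synthetic generator
#'
#' @param pink_rms RMS amplitude (uV) of the 1/f background noise.
#' @param line_amp,line_freq amplitude (uV) and frequency (Hz) of the
#'   power-line interference.
#' @param blink_rate,blink_amp ocular blink rate (events/min) and peak
#'   amplitude (uV, at the EOG channels).
#' @param transient_rate,transient_amp transient artifact rate (events/min)
#'   and amplitude (uV).
#' @param n_bad_channels number of channels rendered unusable by strong
#'   wide-band noise.
#' @export
noise_config <- function(pink_rms = 4, line_amp = 2, line_freq = 50,
                         blink_rate = 4, blink_amp = 80,
                         transient_rate = 1, transient_amp = 150,
                         n_bad_channels = 0) {
  vals <- c(pink_rms, line_amp, line_freq, blink_rate, blink_amp,
            transient_rate, transient_amp, n_bad_channels)
  if (any(vals < 0)) stop("all rates and amplitudes must be >= 0")
  structure(list(pink_rms = pink_rms, line_amp = line_amp,
                 line_freq = line_freq, blink_rate = blink_rate,
                 blink_amp = blink_amp, transient_rate = transient_rate,
                 transient_amp = transient_amp,
                 n_bad_channels = n_bad_channels),
            class = "noise_config")
}

#' Paradigm configuration for the synthetic generator
#'
#' Defaults reproduce the study schedules: the offline paradigm records 9
#' runs of 40 trials (5-s trials, class cue 2 s after trial start, breaks
#' uniform in 1-3 s, 72 trials per class); the online training paradigm 5
#' movement runs of 30 trials (class cue at trial start, ready cue at 2 s,
#' go cue after a 0.5-1 s hold plus a 2-4 s shrink) plus 4 rest runs of
#' 70 s; the online test paradigm runs of 4 movement + 1 rest trial, each a
#' 5 s cue followed by a 60 s self-paced period, attempts reported about
#' 2 s later.
#'
#' @param paradigm `"offline"`, `"online_training"` or `"online_test"`.
#' @param runs,trials_per_run schedule size (movement runs for the online
#'   paradigms).
#' @param classes movement classes used.
#' @param seed integer seed; every generated session is reproducible from
#'   the configuration and this seed alone.
#' @param montage `"full"` (61+3 channels) or `"reduced"` (19+3).
#' @param break_range inter-trial break (s), drawn uniformly.
#' @param hold_range,shrink_range online-training delays between ready and
#'   go cue (s).
#' @param rest_runs,rest_trial_s rest runs and their length (s).
#' @param attempt_gap_range gap between self-paced attempts (s); the
#'   paradigm asks for at least 3 s between reports.
#' @param report_delay,report_jitter delay from attempt to the reported
#'   movement marker and its uniform jitter half-width (s).
#' @param pos_scale positive-peak multiplier (see [make_mrcp_waveform()]).
#' @param second_negativity morphology toggle for short attempts.
#' @param amp_scale overall MRCP amplitude multiplier (0 gives null data).
#' @param amp_jitter_cv,lat_jitter_sd trial-to-trial variability of the
#'   peaks around the session-level template: amplitude coefficient of
#'   variation and latency standard deviation (s). The template table's
#'   own standard deviations describe variability *across participants*
#'   (each simulated session draws its class templates once from those
#'   distributions); the within-session jitter is deliberately smaller so
#'   a session's class average converges to its template as 1/sqrt(n).
#' @export
paradigm_config <- function(paradigm = c("offline", "online_training",
                                         "online_test"),
                            runs = NULL, trials_per_run = NULL,
                            classes = NULL, seed = 1,
                            montage = c("full", "reduced"),
                            break_range = c(1, 3),
                            hold_range = c(0.5, 1),
                            shrink_range = c(2, 4),
                            rest_runs = 4, rest_trial_s = 70,
                            attempt_gap_range = c(4, 8),
                            report_delay = 2, report_jitter = 0.3,
                            pos_scale = NULL, second_negativity = FALSE,
                            amp_scale = 1,
                            amp_jitter_cv = 0.15, lat_jitter_sd = 0.03) {
  paradigm <- match.arg(paradigm)
  montage <- match.arg(montage)
  if (is.null(classes))
    classes <- switch(paradigm,
      offline = c("pronation", "supination", "hand_open", "palmar_grasp",
                  "lateral_grasp"),
      c("hand_open", "palmar_grasp"))
  if (is.null(runs))
    runs <- switch(paradigm, offline = 9, online_training = 5,
                   online_test = 6)
  if (is.null(trials_per_run))
    trials_per_run <- switch(paradigm, offline = 40, online_training = 30,
                             online_test = 5)
  if (is.null(pos_scale))
    pos_scale <- if (paradigm == "offline") 1 else 0.3
  stopifnot(length(classes) >= 1, runs >= 1, trials_per_run >= 1,
            all(break_range >= 0), all(hold_range >= 0),
            all(shrink_range >= 0), all(attempt_gap_range >= 0),
            report_delay >= 0, report_jitter >= 0, amp_scale >= 0)
  structure(list(paradigm = paradigm, runs = runs,
                 trials_per_run = trials_per_run, classes = classes,
                 seed = seed, montage = montage,
                 break_range = break_range, hold_range = hold_range,
                 shrink_range = shrink_range, rest_runs = rest_runs,
                 rest_trial_s = rest_trial_s,
                 attempt_gap_range = attempt_gap_range,
                 report_delay = report_delay,
                 report_jitter = report_jitter,
                 pos_scale = pos_scale,
                 second_negativity = second_negativity,
                 amp_scale = amp_scale,
                 amp_jitter_cv = amp_jitter_cv,
                 lat_jitter_sd = lat_jitter_sd),
            class = "paradigm_config")
}

#' 1/f (pink) background noise
#'
#' Spectrally shaped Gaussian noise with amplitude spectrum proportional to
#' 1/sqrt(f), scaled to a target RMS.
#'
#' @param n samples.
#' @param rms target RMS (uV).
#' @param rate sampling rate (Hz); the shaping is flat below 0.1 Hz so the
#'   variance stays finite.
#' @export
pink_noise <- function(n, rms, rate = 256) {
  if (rms == 0 || n == 0) return(numeric(n))
  # pad to a 2-3-5-smooth length so the FFT stays O(n log n)
  m <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(m)
  f <- seq(0, rate / 2, length.out = floor(m / 2) + 1)
  shape <- 1 / sqrt(pmax(f, 0.1))
  full <- c(shape, rev(shape[2:(ceiling(m / 2))]))
  x <- Re(stats::fft(stats::fft(white) * full, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x * rms / stats::sd(x)
}

# biphasic ~0.4 s blink shape, peak 1
.blink_shape <- function(rate) {
  t <- seq(0, 0.4, by = 1 / rate)
  s <- sin(pi * t / 0.4)^2 * (1 - 0.4 * sin(2 * pi * t / 0.4))
  s / max(s)
}

#' Draw session-level MRCP templates
#'
#' Draws one set of per-class peak parameters from the across-participant
#' distributions of `params` (this is what a simulated participant
#' "brings" to a session) and returns a template table whose means are the
#' drawn values and whose standard deviations encode the smaller
#' trial-to-trial jitter (`amp_jitter_cv` of the drawn amplitude;
#' `lat_jitter_sd` seconds). Latency order is enforced
#' (negative at least 0.25 s after positive) and amplitudes keep their
#' sign.
#'
#' @param params across-participant table ([mrcp_template_params()]).
#' @param amp_jitter_cv,lat_jitter_sd trial-level jitter, see
#'   [paradigm_config()].
#' @return A template table of the same shape as `params`, usable by
#'   [make_mrcp_waveform()].
#' @export
draw_session_templates <- function(params = mrcp_template_params(),
                                   amp_jitter_cv = 0.15,
                                   lat_jitter_sd = 0.03) {
  out <- params
  for (cl in rownames(params)) {
    p <- params[cl, ]
    dr <- function(m, s) if (s > 0) stats::rnorm(1, m, s) else m
    pos_amp <- max(0.5, dr(p$pos_amp_mean, p$pos_amp_sd))
    neg_amp <- min(-0.5, dr(p$neg_amp_mean, p$neg_amp_sd))
    pos_lat <- max(0.1, dr(p$pos_lat_mean, p$pos_lat_sd))
    neg_lat <- max(pos_lat + 0.25, dr(p$neg_lat_mean, p$neg_lat_sd))
    out[cl, ] <- data.frame(class = cl,
                            pos_amp_mean = pos_amp,
                            pos_amp_sd = amp_jitter_cv * abs(pos_amp),
                            pos_lat_mean = pos_lat,
                            pos_lat_sd = lat_jitter_sd,
                            neg_amp_mean = neg_amp,
                            neg_amp_sd = amp_jitter_cv * abs(neg_amp),
                            neg_lat_mean = neg_lat,
                            neg_lat_sd = lat_jitter_sd)
  }
  out
}

# uniform draw helper honouring collapsed ranges
.runif_range <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

# Add noise, artifacts and bad channels to a signal matrix, in place.
.add_noise <- function(sig, rate, channels, ncfg) {
  n <- ncol(sig); nch <- nrow(sig)
  dur_min <- n / rate / 60
  if (ncfg$pink_rms > 0)
    for (i in seq_len(nch))
      sig[i, ] <- sig[i, ] + pink_noise(n, ncfg$pink_rms, rate)
  if (ncfg$line_amp > 0) {
    tt <- (seq_len(n) - 1) / rate
    for (i in seq_len(nch))
      sig[i, ] <- sig[i, ] + ncfg$line_amp *
        sin(2 * pi * ncfg$line_freq * tt + stats::runif(1, 0, 2 * pi))
  }
  if (ncfg$blink_rate > 0 && ncfg$blink_amp > 0) {
    n_blinks <- stats::rpois(1, ncfg$blink_rate * dur_min)
    shape <- .blink_shape(rate) * ncfg$blink_amp
    gain <- ifelse(channels$kind == "EOG", 1,
                   pmax(0, channels$y - 0.2) * 0.8)
    for (b in seq_len(n_blinks)) {
      at <- sample.int(n - length(shape), 1)
      amp <- stats::runif(1, 0.7, 1.3)
      idx <- at + seq_along(shape) - 1
      sig[, idx] <- sig[, idx] + outer(gain, shape * amp)
    }
  }
  if (ncfg$transient_rate > 0 && ncfg$transient_amp > 0) {
    n_tr <- stats::rpois(1, ncfg$transient_rate * dur_min)
    for (b in seq_len(n_tr)) {
      len <- sample(round(c(0.05, 0.2) * rate), 1)
      at <- sample.int(n - len, 1)
      ch <- sample.int(nch, 1)
      burst <- ncfg$transient_amp * stats::runif(1, 0.8, 1.2) *
        sin(pi * seq_len(len) / len)
      sig[ch, at + seq_len(len) - 1] <- sig[ch, at + seq_len(len) - 1] + burst
    }
  }
  if (ncfg$n_bad_channels > 0) {
    eeg_idx <- which(channels$kind == "EEG" &
                     !channels$name %in% c("Cz", "AFz"))
    bad <- sample(eeg_idx, min(ncfg$n_bad_channels, length(eeg_idx)))
    for (ch in bad)
      sig[ch, ] <- sig[ch, ] + stats::rnorm(n, 0, 10 * max(ncfg$pink_rms, 5))
    attr(sig, "true_bad") <- channels$name[bad]
  }
  sig
}

# balanced, shuffled class sequence for a session
.class_sequence <- function(classes, n_trials) {
  k <- length(classes)
  if (n_trials %% k != 0)
    stop("number of trials (", n_trials,
         ") must divide evenly across the ", k, " classes")
  sample(rep(classes, n_trials / k))
}

#' Generate a synthetic offline-paradigm session
#'
#' Emulates the cue-based 5-class offline recording: per trial a
#' `trial_start` marker, the `class_cue:<class>` 2 s later, a 5-s trial
#' period and a random 1-3 s break. The class-specific two-peak MRCP is
#' added at the cue through the Cz-centred spatial pattern, on top of 1/f
#' noise, line interference, blinks and transient artifacts.
#'
#' @param pcfg [paradigm_config()] with `paradigm = "offline"`.
#' @param tparams template table ([mrcp_template_params()]).
#' @param ncfg [noise_config()].
#' @param rate sampling rate (Hz).
#' @return An [eeg_recording()]; the per-trial drawn peak truth is attached
#'   as attribute `"ground_truth"` (a `data.frame`).
#' @export
generate_offline_session <- function(pcfg = paradigm_config("offline"),
                                     tparams = mrcp_template_params(),
                                     ncfg = noise_config(), rate = 256) {
  stopifnot(pcfg$paradigm == "offline")
  set.seed(pcfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  tparams <- draw_session_templates(tparams, pcfg$amp_jitter_cv,
                                    pcfg$lat_jitter_sd)
  channels <- standard_montage(pcfg$montage)
  n_trials <- pcfg$runs * pcfg$trials_per_run
  seq_classes <- .class_sequence(pcfg$classes, n_trials)
  gain <- mrcp_spatial_pattern(channels)

  trial_len <- 5
  events <- list(); truth <- list()
  cue_starts <- numeric(n_trials)
  t_cursor <- 1  # lead-in second
  for (i in seq_len(n_trials)) {
    t0 <- t_cursor
    cue <- t0 + 2
    events[[length(events) + 1]] <-
      data.frame(onset = round(t0 * rate),
                 label = "trial_start")
    events[[length(events) + 1]] <-
      data.frame(onset = round(cue * rate),
                 label = paste0("class_cue:", seq_classes[i]))
    cue_starts[i] <- cue
    t_cursor <- t0 + trial_len + .runif_range(pcfg$break_range)
  }
  total_s <- t_cursor + 1
  n <- round(total_s * rate)
  sig <- matrix(0, nrow(channels), n)
  for (i in seq_len(n_trials)) {
    wf <- make_mrcp_waveform(seq_classes[i], tparams, rate = rate,
                             duration = 3, pos_scale = pcfg$pos_scale,
                             second_negativity = pcfg$second_negativity,
                             amp_scale = pcfg$amp_scale)
    idx <- round(cue_starts[i] * rate) + seq_along(wf$waveform)
    sig[, idx] <- sig[, idx] + outer(gain, wf$waveform)
    truth[[i]] <- data.frame(trial = i, class = seq_classes[i],
                             cue_s = cue_starts[i],
                             pos_amp = wf$truth$pos_amp,
                             pos_lat = wf$truth$pos_lat,
                             neg_amp = wf$truth$neg_amp,
                             neg_lat = wf$truth$neg_lat)
  }
  sig <- .add_noise(sig, rate, channels, ncfg)
  true_bad <- attr(sig, "true_bad"); attr(sig, "true_bad") <- NULL
  rec <- eeg_recording(sig, rate, channels, do.call(rbind, events))
  attr(rec, "ground_truth") <- do.call(rbind, truth)
  attr(rec, "session_templates") <- tparams
  attr(rec, "true_bad_channels") <- true_bad
  rec
}

#' Generate a synthetic online-training-paradigm session
#'
#' Movement trials show the class cue at trial start, the ready cue 2 s
#' later, and the go cue after a uniform 0.5-1 s hold plus a 2-4 s shrink;
#' the MRCP (with a reduced cue-related positive peak) is time-locked to
#' the go cue. Rest runs of 70 s are appended with `rest_start` markers.
#'
#' @inheritParams generate_offline_session
#' @export
generate_online_training_session <- function(
    pcfg = paradigm_config("online_training"),
    tparams = mrcp_template_params(),
    ncfg = noise_config(), rate = 256) {
  stopifnot(pcfg$paradigm == "online_training")
  set.seed(pcfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  tparams <- draw_session_templates(tparams, pcfg$amp_jitter_cv,
                                    pcfg$lat_jitter_sd)
  channels <- standard_montage(pcfg$montage)
  n_trials <- pcfg$runs * pcfg$trials_per_run
  seq_classes <- .class_sequence(pcfg$classes, n_trials)
  gain <- mrcp_spatial_pattern(channels)

  events <- list(); truth <- list()
  t_cursor <- 1
  go_times <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    t0 <- t_cursor
    ready <- t0 + 2
    go <- ready + .runif_range(pcfg$hold_range) +
      .runif_range(pcfg$shrink_range)
    events[[length(events) + 1]] <- data.frame(
      onset = round(c(t0, t0, ready, go) * rate),
      label = c("trial_start", paste0("class_cue:", seq_classes[i]),
                "ready_cue", "go_cue"))
    go_times[i] <- go
    t_cursor <- go + 2 + .runif_range(c(2, 3))   # 2 s display + break
  }
  rest_starts <- numeric(pcfg$rest_runs)
  for (r in seq_len(pcfg$rest_runs)) {
    rest_starts[r] <- t_cursor
    events[[length(events) + 1]] <- data.frame(
      onset = round(t_cursor * rate), label = "rest_start")
    t_cursor <- t_cursor + pcfg$rest_trial_s + 2
  }
  total_s <- t_cursor + 1
  sig <- matrix(0, nrow(channels), round(total_s * rate))
  for (i in seq_len(n_trials)) {
    wf <- make_mrcp_waveform(seq_classes[i], tparams, rate = rate,
                             duration = 3, pos_scale = pcfg$pos_scale,
                             second_negativity = pcfg$second_negativity,
                             amp_scale = pcfg$amp_scale)
    idx <- round(go_times[i] * rate) + seq_along(wf$waveform)
    sig[, idx] <- sig[, idx] + outer(gain, wf$waveform)
    truth[[i]] <- data.frame(trial = i, class = seq_classes[i],
                             go_s = go_times[i],
                             pos_amp = wf$truth$pos_amp,
                             pos_lat = wf$truth$pos_lat,
                             neg_amp = wf$truth$neg_amp,
                             neg_lat = wf$truth$neg_lat)
  }
  sig <- .add_noise(sig, rate, channels, ncfg)
  true_bad <- attr(sig, "true_bad"); attr(sig, "true_bad") <- NULL
  rec <- eeg_recording(sig, rate, channels, do.call(rbind, events))
  attr(rec, "ground_truth") <- do.call(rbind, truth)
  attr(rec, "session_templates") <- tparams
  attr(rec, "rest_starts_s") <- rest_starts
  attr(rec, "true_bad_channels") <- true_bad
  rec
}

#' Generate a synthetic online-test-paradigm session
#'
#' Each run holds movement trials (two per movement class) and one rest
#' trial in shuffled order. A trial shows its class cue for 5 s, then a
#' 60 s self-paced period: movement trials contain attempts at randomized
#' times (gaps drawn from `attempt_gap_range`), each adding a go-locked
#' MRCP and a `reported_movement` marker `report_delay` (+/- jitter)
#' seconds later; rest trials contain no MRCPs.
#'
#' @inheritParams generate_offline_session
#' @return An [eeg_recording()] with attributes `"ground_truth"`
#'   (`data.frame` of true attempt onsets with trial and class) and
#'   `"rest_intervals"` (`data.frame` of the 60-s rest periods, seconds).
#' @export
generate_online_test_session <- function(
    pcfg = paradigm_config("online_test"),
    tparams = mrcp_template_params(),
    ncfg = noise_config(), rate = 256) {
  stopifnot(pcfg$paradigm == "online_test")
  set.seed(pcfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  tparams <- draw_session_templates(tparams, pcfg$amp_jitter_cv,
                                    pcfg$lat_jitter_sd)
  channels <- standard_montage(pcfg$montage)
  gain <- mrcp_spatial_pattern(channels)
  n_move_per_run <- pcfg$trials_per_run - 1

  events <- list(); attempts <- list(); rest_iv <- list()
  t_cursor <- 1
  cue_s <- 5; period_s <- 60
  for (r in seq_len(pcfg$runs)) {
    trial_classes <- sample(c(rep(pcfg$classes,
                                  n_move_per_run / length(pcfg$classes)),
                              "rest"))
    for (cl in trial_classes) {
      t0 <- t_cursor
      events[[length(events) + 1]] <- data.frame(
        onset = round(t0 * rate),
        label = c("trial_start", paste0("class_cue:", cl)))
      p_start <- t0 + cue_s
      p_end <- p_start + period_s
      if (cl == "rest") {
        events[[length(events) + 1]] <- data.frame(
          onset = round(p_start * rate), label = "rest_start")
        rest_iv[[length(rest_iv) + 1]] <-
          data.frame(start = p_start, end = p_end)
      } else {
        at <- p_start + .runif_range(c(1, 4))
        while (at < p_end - 3.5) {
          report <- at + pcfg$report_delay +
            .runif_range(c(-1, 1) * pcfg$report_jitter)
          events[[length(events) + 1]] <- data.frame(
            onset = round(report * rate), label = "reported_movement")
          attempts[[length(attempts) + 1]] <-
            data.frame(trial_start = t0, class = cl, onset_s = at,
                       reported_s = report)
          at <- at + .runif_range(pcfg$attempt_gap_range)
        }
      }
      t_cursor <- p_end + .runif_range(c(2, 3))
    }
  }
  total_s <- t_cursor + 1
  sig <- matrix(0, nrow(channels), round(total_s * rate))
  attempts <- if (length(attempts)) do.call(rbind, attempts) else
    data.frame(trial_start = numeric(0), class = character(0),
               onset_s = numeric(0), reported_s = numeric(0))
  for (i in seq_len(nrow(attempts))) {
    wf <- make_mrcp_waveform(attempts$class[i], tparams, rate = rate,
                             duration = 3, pos_scale = pcfg$pos_scale,
                             second_negativity = pcfg$second_negativity,
                             amp_scale = pcfg$amp_scale)
    idx <- round(attempts$onset_s[i] * rate) + seq_along(wf$waveform)
    sig[, idx] <- sig[, idx] + outer(gain, wf$waveform)
  }
  sig <- .add_noise(sig, rate, channels, ncfg)
  true_bad <- attr(sig, "true_bad"); attr(sig, "true_bad") <- NULL
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$onset), ]
  rec <- eeg_recording(sig, rate, channels, ev)
  attr(rec, "ground_truth") <- attempts
  attr(rec, "session_templates") <- tparams
  attr(rec, "rest_intervals") <- do.call(rbind, rest_iv)
  attr(rec, "true_bad_channels") <- true_bad
  rec
}
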