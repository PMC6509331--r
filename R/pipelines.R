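# End-to-end orchestration of the two experiments on synthetic sessions:
# the offline multiclass decoding study and the online self-paced
# detection proof-of-concept. Every report is reproducible from its
# configuration and seed alone.

#' Configuration for the offline analysis pipeline
#'
#' @param n_participants simulated participants.
#' @param classes movement classes (5-class full set by default; pass the
#'   grasp subset for the 3-class analysis - configuration, not code).
#' @param runs,trials_per_run session schedule per participant.
#' @param montage `"full"` or `"reduced"` (see [standard_montage()]).
#' @param noise a [noise_config()].
#' @param window a [feature_window_config()].
#' @param folds,repeats cross-validation setup.
#' @param times evaluation times (s, relative to the class cue; `NULL` =
#'   full sliding grid).
#' @param use_ica run the ICA artifact-removal steps (disable only for
#'   artifact-free simulations).
#' @param band narrow band for classification (Hz).
#' @param broadband ICA fitting band (Hz).
#' @param n_perm,alpha permutation-test setup.
#' @param amp_scale MRCP effect-size multiplier (0 = null data).
#' @param seed master seed; participant i is simulated with seed
#'   `seed + 101 * i`.
#' @export
offline_run_config <- function(n_participants = 10,
                               classes = c("pronation", "supination",
                                           "hand_open", "palmar_grasp",
                                           "lateral_grasp"),
                               runs = 9, trials_per_run = 40,
                               montage = "full",
                               noise = noise_config(),
                               window = feature_window_config(),
                               folds = 10, repeats = 10,
                               times = NULL,
                               use_ica = TRUE,
                               band = c(0.3, 3), broadband = c(0.3, 70),
                               n_perm = 1000, alpha = 0.05,
                               amp_scale = 1, seed = 1) {
  structure(as.list(environment()), class = "offline_run_config")
}

#' Preprocess one continuous recording (offline variant)
#'
#' The four-step cleaning pipeline: flag noisy channels (AFz by default),
#' fit ICA on the 0.3-70 Hz signal restricted to samples within 10.4 MADs,
#' identify ocular/muscle components, band-pass the original signal to
#' the narrow band and remove the cached components there.
#'
#' @param rec raw [eeg_recording()].
#' @param use_ica run the ICA steps.
#' @param band,broadband filter bands (Hz).
#' @param mode filter mode (`"zero_phase"` offline, `"causal"` online).
#' @return list with `rec` (cleaned narrow-band recording with bad
#'   channels flagged), `bad_channels`, `artifact_ics`, `ica`.
#' @export
preprocess_recording <- function(rec, use_ica = TRUE, band = c(0.3, 3),
                                 broadband = c(0.3, 70),
                                 mode = "zero_phase") {
  bad <- detect_bad_channels(rec)
  rec <- set_bad_channels(rec, bad)
  model <- NULL; ics <- integer(0)
  narrow <- bandpass(rec, band[1], band[2], mode = mode)
  if (use_ica) {
    wide <- bandpass(rec, broadband[1], min(broadband[2], rec$rate / 2 - 1),
                     mode = mode)
    model <- fit_ica(wide)
    ics <- identify_artifact_ics(model, wide)
    narrow <- remove_ics(narrow, model, ics)
  }
  list(rec = narrow, bad_channels = bad, artifact_ics = ics, ica = model)
}

#' Run the offline multiclass decoding analysis
#'
#' Simulates (or accepts) one session per participant, cleans it, epochs
#' around the class cue (-2 to 3 s), rejects artifact trials, re-references
#' to the common average, computes the sliding-window cross-validated
#' accuracy curve per participant, the grand average with its t-based
#' confidence interval and adjusted-Wald significance threshold, the
#' confusion matrix at the grand-average peak, difference topoplots with
#' the max-statistic permutation mask, and the Cz peak features with
#' Friedman tests across classes.
#'
#' @param cfg an [offline_run_config()].
#' @param sessions optional list of pre-generated recordings (one per
#'   participant); when `NULL` they are simulated from `cfg`.
#' @return A report list; see Details in the package vignette.
#' @export
run_offline_analysis <- function(cfg = offline_run_config(),
                                 sessions = NULL) {
  n_p <- if (is.null(sessions)) cfg$n_participants else length(sessions)
  participants <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    rec <- if (is.null(sessions)) {
      generate_offline_session(
        paradigm_config("offline", runs = cfg$runs,
                        trials_per_run = cfg$trials_per_run,
                        classes = cfg$classes, montage = cfg$montage,
                        amp_scale = cfg$amp_scale,
                        seed = cfg$seed + 101L * i),
        ncfg = cfg$noise)
    } else sessions[[i]]
    pp <- preprocess_recording(rec, use_ica = cfg$use_ica,
                               band = cfg$band, broadband = cfg$broadband)
    ep <- epoch(pp$rec, "class_cue", c(-2, 3))
    rej <- mark_bad_trials(ep)
    ep <- apply_rejection(ep, rej)
    ep_car <- common_average_reference(ep)
    curve <- sliding_accuracy(ep_car, cfg$window, folds = cfg$folds,
                              repeats = cfg$repeats,
                              seed = cfg$seed + 7L * i,
                              times = cfg$times)
    cz <- which(ep$channels$name == "Cz")
    cz_avg <- lapply(class_averages(ep), function(m) m[cz, ])
    participants[[i]] <- list(
      curve = curve, epochs = ep_car, epochs_monopolar = ep,
      bad_channels = pp$bad_channels, artifact_ics = pp$artifact_ics,
      n_rejected = sum(rej$rejected), n_trials = sum(!ep$rejected),
      cz_class_averages = cz_avg,
      times_axis = epoch_times(ep))
  }
  times <- participants[[1]]$curve$time
  acc_mat <- sapply(participants, function(p) p$curve$accuracy)
  acc_mat <- matrix(acc_mat, nrow = length(times))
  grand <- rowMeans(acc_mat)
  ci <- if (n_p >= 2) {
    cis <- apply(acc_mat, 1, t_ci, alpha = cfg$alpha)
    list(lo = vapply(cis, `[[`, 0, "lo"), hi = vapply(cis, `[[`, 0, "hi"))
  } else list(lo = grand, hi = grand)
  peak_i <- which.max(grand)
  n_trials_med <- stats::median(vapply(participants, `[[`, 0, "n_trials"))
  thresh <- significance_threshold(n_trials_med, length(cfg$classes),
                                   cfg$alpha, n_comparisons = length(times))
  confusion <- confusion_at(participants[[1]]$epochs, times[peak_i],
                            cfg$window, folds = cfg$folds,
                            repeats = min(cfg$repeats, 2),
                            seed = cfg$seed)
  # pooled confusion over participants
  for (i in seq_len(n_p)[-1])
    confusion <- confusion + confusion_at(participants[[i]]$epochs,
                                          times[peak_i], cfg$window,
                                          folds = cfg$folds,
                                          repeats = min(cfg$repeats, 2),
                                          seed = cfg$seed + 7L * i)
  confusion <- confusion / n_p

  topo <- permutation_max_stat(lapply(participants, `[[`,
                                      "epochs_monopolar"),
                               n_perm = cfg$n_perm, alpha = cfg$alpha,
                               seed = cfg$seed)
  tax <- participants[[1]]$times_axis
  pk <- do.call(rbind, lapply(seq_len(n_p), function(i) {
    cz <- participants[[i]]$cz_class_averages
    do.call(rbind, lapply(names(cz), function(cl) {
      cbind(participant = i, class = cl,
            peak_features(cz[[cl]], tax))
    }))
  }))
  fried <- lapply(c("pos_amp", "neg_amp", "pos_lat", "neg_lat"),
                  function(v) {
    m <- stats::reshape(pk[, c("participant", "class", v)],
                        idvar = "participant", timevar = "class",
                        direction = "wide")
    m <- as.matrix(m[, -1])
    if (n_p >= 2) friedman_by_class(m) else NULL
  })
  names(fried) <- c("pos_amp", "neg_amp", "pos_lat", "neg_lat")
  list(participants = lapply(participants, function(p)
         p[setdiff(names(p), c("epochs", "epochs_monopolar"))]),
       times = times,
       grand_accuracy = grand, ci_lo = ci$lo, ci_hi = ci$hi,
       peak_accuracy = grand[peak_i], peak_time = times[peak_i],
       significance_threshold = thresh,
       confusion = confusion,
       topoplots = topo,
       peak_features = pk,
       friedman = fried,
       config = cfg)
}

#' Configuration for the online proof-of-concept pipeline
#'
#' @param training,test [paradigm_config()]s for the two sessions.
#' @param noise a [noise_config()].
#' @param window causal [feature_window_config()].
#' @param detection a [detection_config()].
#' @param t_train_grid candidate times for [select_t_train()].
#' @param folds training cross-validation folds.
#' @param cadence classifier evaluation cadence in samples.
#' @param band classification band (Hz).
#' @param seed master seed.
#' @export
online_run_config <- function(training = paradigm_config("online_training"),
                              test = paradigm_config("online_test"),
                              noise = noise_config(),
                              window = feature_window_config(
                                alignment = "causal"),
                              detection = detection_config(),
                              t_train_grid = seq(1, 2, by = 1 / 16),
                              folds = 10, cadence = 1L,
                              band = c(0.3, 3), seed = 1) {
  structure(as.list(environment()), class = "online_run_config")
}

#' Run the online self-paced detection experiment
#'
#' Simulates a training session, selects t_train by cross-validation,
#' trains the 5-class classifier (movement classes, rest, pre, post),
#' simulates a test session, replays it causally through the detection
#' state machine, chooses the true-positive-window offset by the
#' detection-ratio search, and evaluates TPR, FP/min and accuracy.
#'
#' @param cfg an [online_run_config()].
#' @return Report list with `t_train`, `detection_delay`, `detections`,
#'   `offset_search`, `evaluation`, and the trained `model`.
#' @export
run_online_experiment <- function(cfg = online_run_config()) {
  cfg$training$seed <- cfg$seed
  cfg$test$seed <- cfg$seed + 1L
  train_rec <- generate_online_training_session(cfg$training,
                                                ncfg = cfg$noise)
  pp <- preprocess_recording(train_rec, use_ica = FALSE, band = cfg$band,
                             mode = "causal")
  rec <- common_average_reference(pp$rec)
  span <- cfg$window$span
  move_ep <- epoch(rec, "go_cue", c(-span - 0.6, 3))
  rest_len <- cfg$training$rest_trial_s
  rest_ep <- epoch(rec, "rest_start", c(0, rest_len))
  rest_ep$labels <- rep("rest", length(rest_ep$labels))

  # 3-class t_train grid search uses movement epochs plus matched rest
  # epochs cut from the long rest trials
  n_move <- sum(!move_ep$rejected)
  three_ep <- .merge_rest_epochs(move_ep, rest_ep, n_move, cfg$window)
  sel <- select_t_train(three_ep, cfg$window, grid = cfg$t_train_grid,
                        folds = cfg$folds, seed = cfg$seed)
  t_train <- sel$t_train

  train_set <- build_five_class_training(move_ep, rest_ep, t_train,
                                         cfg$window)
  model <- fit_slda(train_set$X, train_set$y)

  test_rec <- generate_online_test_session(cfg$test, ncfg = cfg$noise)
  pp_t <- preprocess_recording(test_rec, use_ica = FALSE, band = cfg$band,
                               mode = "causal")
  pp_t$rec$channels$is_bad <- rec$channels$is_bad  # training channel policy
  rec_t <- common_average_reference(pp_t$rec)
  trace <- classifier_probability_trace(rec_t, model, cfg$window,
                                        cadence = cfg$cadence)
  detections <- run_detector(trace, cfg$detection,
                             classes = cfg$test$classes)
  reported <- rec_t$events$onset[rec_t$events$label ==
                                   "reported_movement"] / rec_t$rate
  truth <- attr(test_rec, "ground_truth")
  rest_iv <- attr(test_rec, "rest_intervals")
  offs <- select_tp_offset(detections$time, reported)
  ev <- evaluate_online(detections, reported, rest_iv, offs$offset,
                        truth$class)
  list(t_train = t_train, t_train_search = sel,
       detection_delay = detection_delay(t_train, cfg$detection),
       model = model, detections = detections,
       reported_times = reported, truth = truth,
       offset_search = offs, evaluation = ev, config = cfg)
}

# movement epochs + n rest feature epochs merged into one 3-class epoch
# set on the movement epochs' time axis
.merge_rest_epochs <- function(move_ep, rest_ep, n_rest, cfg) {
  move_ep <- drop_rejected(move_ep)
  n_samp <- dim(move_ep$data)[3]
  tax <- epoch_times(rest_ep)
  n_tr <- dim(rest_ep$data)[1]
  starts <- seq(1, length(tax) - n_samp, by = n_samp)
  picks <- expand.grid(trial = seq_len(n_tr), start = starts)
  picks <- picks[round(seq(1, nrow(picks),
                           length.out = min(n_rest, nrow(picks)))), ]
  cut <- array(0, c(nrow(picks), dim(rest_ep$data)[2], n_samp))
  for (i in seq_len(nrow(picks)))
    cut[i, , ] <- rest_ep$data[picks$trial[i], ,
                               picks$start[i] + seq_len(n_samp) - 1]
  epoch_set(abind_first(move_ep$data, cut), move_ep$t0_offset,
            move_ep$rate, move_ep$channels,
            c(move_ep$labels, rep("rest", nrow(picks))))
}

# bind two trials x channels x samples arrays along the first axis
abind_first <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
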