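# Self-paced movement detection: 5-class training-set construction around
# t_train, the causal detection state machine, delay accounting and
# TPR / FP-per-minute / accuracy evaluation.

#' Detection state-machine configuration
#'
#' Three time windows relative to a reference point t0 gate a detection:
#' the pre window (-650 to -350 ms) must hold the pre-class probability
#' above `pre_post_threshold` for at least `dwell_s` cumulatively, the
#' movement window (-50 to 50 ms) must contain a movement-class
#' probability above `movement_threshold`, and the post window (350 to
#' 650 ms) mirrors the pre window on the post class. After a detection a
#' refractory period suppresses further detections.
#'
#' @param pre_window,movement_window,post_window window edges relative to
#'   t0, in seconds.
#' @param pre_post_threshold probability threshold for pre/post (0.7).
#' @param movement_threshold probability threshold for movement (0.9).
#' @param dwell_s minimum cumulative supra-threshold time (0.15 s).
#' @param dwell_consecutive require the dwell to be consecutive rather
#'   than cumulative.
#' @param refractory_s refractory period after a detection (2 s).
#' @export
detection_config <- function(pre_window = c(-0.65, -0.35),
                             movement_window = c(-0.05, 0.05),
                             post_window = c(0.35, 0.65),
                             pre_post_threshold = 0.7,
                             movement_threshold = 0.9,
                             dwell_s = 0.15,
                             dwell_consecutive = FALSE,
                             refractory_s = 2) {
  stopifnot(pre_window[1] < pre_window[2],
            movement_window[1] < movement_window[2],
            post_window[1] < post_window[2],
            pre_window[2] <= movement_window[1],
            movement_window[2] <= post_window[1],
            pre_post_threshold > 0, pre_post_threshold < 1,
            movement_threshold > 0, movement_threshold < 1,
            dwell_s <= diff(pre_window), dwell_s <= diff(post_window),
            refractory_s >= 0)
  structure(list(pre_window = pre_window,
                 movement_window = movement_window,
                 post_window = post_window,
                 pre_post_threshold = pre_post_threshold,
                 movement_threshold = movement_threshold,
                 dwell_s = dwell_s,
                 dwell_consecutive = dwell_consecutive,
                 refractory_s = refractory_s),
            class = "detection_config")
}

#' Select the training time point t_train
#'
#' Runs a k-fold cross-validated 3-class (hand open, palmar grasp, rest)
#' classification on a grid of candidate times after the go cue (1-2 s in
#' 1/16-s steps) with a causal feature window, and returns the time with
#' the highest accuracy (earliest on ties).
#'
#' @param epochs an [epoch_set()] aligned to the go cue containing all
#'   three classes.
#' @param cfg causal [feature_window_config()] (1.4 s default).
#' @param grid candidate times (s after the go cue).
#' @param folds cross-validation folds (default 10; single repeat).
#' @param seed RNG seed for fold assignment.
#' @return list with `t_train`, `accuracy` (at `t_train`, %), `grid`,
#'   `accuracies` (per grid point, %).
#' @export
select_t_train <- function(epochs,
                           cfg = feature_window_config(alignment = "causal"),
                           grid = seq(1, 2, by = 1 / 16),
                           folds = 10, seed = 1) {
  stopifnot(cfg$alignment == "causal")
  curve <- sliding_accuracy(epochs, cfg, folds = folds, repeats = 1,
                            seed = seed, times = grid)
  best <- which.max(curve$accuracy)     # which.max takes the earliest tie
  list(t_train = curve$time[best], accuracy = curve$accuracy[best],
       grid = curve$time, accuracies = curve$accuracy)
}

#' Build the 5-class online training set
#'
#' Movement-class features are extracted at `t_train`; the auxiliary `pre`
#' and `post` classes take features from both movement classes (never
#' rest) at `t_train - 0.5` and `t_train + 0.5` s; rest features are cut
#' from the long rest trials so that the rest class matches the total
#' movement trial count.
#'
#' @param movement_epochs [epoch_set()] aligned to the go cue with labels
#'   in the two movement classes.
#' @param rest_epochs [epoch_set()] of long rest trials (e.g. 4 x 70 s).
#' @param t_train training time (s after go cue).
#' @param cfg causal [feature_window_config()].
#' @param class_shift pre/post feature-window shift (s, default 0.5).
#' @return list with `X` (features), `y` (factor with levels hand_open,
#'   palmar_grasp, rest, pre, post).
#' @export
build_five_class_training <- function(movement_epochs, rest_epochs,
                                      t_train,
                                      cfg = feature_window_config(
                                        alignment = "causal"),
                                      class_shift = 0.5) {
  movement_epochs <- drop_rejected(movement_epochs)
  n_move <- dim(movement_epochs$data)[1]
  X_move <- extract_features(movement_epochs, t_train, cfg)
  X_pre <- extract_features(movement_epochs, t_train - class_shift, cfg)
  X_post <- extract_features(movement_epochs, t_train + class_shift, cfg)

  # sub-epoch the rest trials: non-overlapping causal windows, evenly
  # thinned (or overlapped) to yield exactly n_move rest feature rows
  rest_epochs <- drop_rejected(rest_epochs)
  tax <- epoch_times(rest_epochs)
  n_rest_tr <- dim(rest_epochs$data)[1]
  span <- cfg$span
  refs <- seq(tax[1] + span, tax[length(tax)] - 1 / rest_epochs$rate,
              by = span)
  total <- length(refs) * n_rest_tr
  if (total < n_move) {
    refs <- seq(tax[1] + span, tax[length(tax)] - 1 / rest_epochs$rate,
                length.out = ceiling(n_move / n_rest_tr))
    total <- length(refs) * n_rest_tr
  }
  rest_rows <- vector("list", n_rest_tr)
  for (i in seq_len(n_rest_tr)) {
    one <- epoch_set(rest_epochs$data[i, , , drop = FALSE],
                     rest_epochs$t0_offset, rest_epochs$rate,
                     rest_epochs$channels, "rest")
    rest_rows[[i]] <- do.call(rbind, lapply(refs, function(tr)
      extract_features(one, tr, cfg)))
  }
  X_rest <- do.call(rbind, rest_rows)
  X_rest <- X_rest[round(seq(1, nrow(X_rest), length.out = n_move)), ,
                   drop = FALSE]

  X <- rbind(X_move, X_pre, X_post, X_rest)
  y <- factor(c(movement_epochs$labels,
                rep("pre", n_move), rep("post", n_move),
                rep("rest", n_move)),
              levels = c("hand_open", "palmar_grasp", "rest", "pre",
                         "post"))
  list(X = X, y = y)
}

#' Causal classifier probability trace over a recording
#'
#' Evaluates a 5-class sLDA model at every `cadence`-th sample of a
#' (causally filtered, re-referenced) recording with a causal feature
#' window, producing the probability time series the detector consumes.
#'
#' @param rec preprocessed [eeg_recording()].
#' @param model an `slda` model from [fit_slda()].
#' @param cfg causal [feature_window_config()].
#' @param cadence evaluate every `cadence`-th sample (default 1 = the
#'   full 256 Hz stream).
#' @return A `probability_trace`: matrix samples x classes with attributes
#'   `time` (s) and `rate` (the trace rate, Hz).
#' @export
classifier_probability_trace <- function(rec, model,
                                         cfg = feature_window_config(
                                           alignment = "causal"),
                                         cadence = 1L) {
  chans <- which(rec$channels$kind == "EEG" & !rec$channels$is_bad)
  lag_samp <- round((seq_len(cfg$n_lags) - 1) * cfg$spacing * rec$rate)
  span_samp <- max(lag_samp)
  n <- ncol(rec$signals)
  eval_at <- seq(span_samp + 1, n, by = cadence)
  X <- matrix(0, length(eval_at), length(chans) * cfg$n_lags)
  col <- 1
  for (ci in chans) {
    for (li in seq_along(lag_samp)) {
      # lag grid ends at the evaluation sample (causal)
      X[, col] <- rec$signals[ci, eval_at - span_samp + lag_samp[li]]
      col <- col + 1
    }
  }
  p <- predict(model, X, type = "prob")
  attr(p, "time") <- (eval_at - 1) / rec$rate
  attr(p, "rate") <- rec$rate / cadence
  class(p) <- c("probability_trace", class(p))
  p
}

#' Run the movement detection state machine over a probability trace
#'
#' At each sample `t` the reference point is `t0 = t - 650 ms`, so the
#' decision uses only probabilities up to `t` (causal). A movement is
#' detected when (1) the pre-class probability exceeds its threshold for
#' the dwell time within the pre window, (2) a movement-class probability
#' exceeds its threshold within the movement window, and (3) the
#' post-class probability exceeds its threshold for the dwell time within
#' the post window. The detected class is the movement class with the
#' higher maximum probability inside the movement window; a refractory
#' period then suppresses further detections. Dwell time is counted in
#' whole samples (`ceiling(dwell_s * rate)`).
#'
#' @param probs samples x classes probability matrix with columns
#'   including `pre`, `post` and the movement classes; a
#'   `probability_trace` carries its own time axis, otherwise `rate` (and
#'   optionally `t_start`) must be given.
#' @param cfg a [detection_config()].
#' @param rate trace sampling rate (Hz), if `probs` has no `rate`
#'   attribute.
#' @param classes the two movement class names.
#' @param t_start time of the first trace sample (s).
#' @return `data.frame` of detection events: `time` (decision time, s),
#'   `t0` (reference point, s), `class`, and the movement-window maximum
#'   probability per movement class.
#' @export
run_detector <- function(probs, cfg = detection_config(), rate = NULL,
                         classes = c("hand_open", "palmar_grasp"),
                         t_start = NULL) {
  if (is.null(rate)) rate <- attr(probs, "rate")
  if (is.null(rate)) stop("trace rate unknown; pass `rate`")
  tm <- attr(probs, "time")
  if (is.null(tm)) {
    if (is.null(t_start)) t_start <- 0
    tm <- t_start + (seq_len(nrow(probs)) - 1) / rate
  }
  stopifnot(all(c("pre", "post", classes) %in% colnames(probs)))
  n <- nrow(probs)
  s <- function(sec) round(sec * rate)
  # sample offsets of the window edges relative to the decision sample i,
  # where t0 = t(i) - 650 ms and windows are inclusive of both edges
  off_t0 <- s(-cfg$pre_window[1])               # 650 ms
  pre_lo <- -off_t0 + s(cfg$pre_window[1]); pre_hi <- -off_t0 + s(cfg$pre_window[2])
  mov_lo <- -off_t0 + s(cfg$movement_window[1]); mov_hi <- -off_t0 + s(cfg$movement_window[2])
  post_lo <- -off_t0 + s(cfg$post_window[1]); post_hi <- -off_t0 + s(cfg$post_window[2])
  need <- ceiling(cfg$dwell_s * rate)
  span <- -pre_lo + 1
  if (n < span) return(data.frame(time = numeric(0), t0 = numeric(0),
                                  class = character(0)))

  pre_above <- probs[, "pre"] > cfg$pre_post_threshold
  post_above <- probs[, "post"] > cfg$pre_post_threshold
  mov_p <- pmax(probs[, classes[1]], probs[, classes[2]])

  count_in <- function(above, lo, hi) {
    cs0 <- c(0, cumsum(above))      # cs0[k + 1] = count of the first k
    i <- seq_len(n)
    a <- i + lo; b <- i + hi
    ok <- a >= 1 & b <= n
    out <- rep(NA_integer_, n)
    out[ok] <- cs0[b[ok] + 1] - cs0[a[ok]]
    out
  }
  run_in <- function(above, lo, hi) {
    # longest consecutive run within the window, per decision sample
    w <- hi - lo + 1
    out <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      a <- i + lo; b <- i + hi
      if (a < 1 || b > n) next
      r <- rle(above[a:b])
      out[i] <- max(c(0, r$lengths[r$values]))
    }
    out
  }
  dwell_fn <- if (cfg$dwell_consecutive) run_in else count_in
  pre_ok <- dwell_fn(pre_above, pre_lo, pre_hi) >= need
  post_ok <- dwell_fn(post_above, post_lo, post_hi) >= need
  mov_ok <- count_in(mov_p > cfg$movement_threshold, mov_lo, mov_hi) >= 1
  cand <- which(pre_ok & post_ok & mov_ok)

  out <- list()
  last <- -Inf
  for (i in cand) {
    if (tm[i] - last < cfg$refractory_s) next
    widx <- (i + mov_lo):(i + mov_hi)
    p1 <- max(probs[widx, classes[1]])
    p2 <- max(probs[widx, classes[2]])
    cls <- if (p1 >= p2) classes[1] else classes[2]
    out[[length(out) + 1]] <- data.frame(
      time = tm[i], t0 = tm[i + mov_lo + (mov_hi - mov_lo) %/% 2],
      class = cls, p1 = p1, p2 = p2)
    last <- tm[i]
  }
  if (!length(out)) {
    det <- data.frame(time = numeric(0), t0 = numeric(0),
                      class = character(0), p1 = numeric(0),
                      p2 = numeric(0))
  } else det <- do.call(rbind, out)
  names(det)[4:5] <- paste0("p_", classes)
  det
}

#' Average maximum detection delay
#'
#' The conservative estimate of the delay between the movement attempt and
#' its detection: `t_train` (distance from the attempt to the most
#' discriminative feature window) plus the distance from `t_train` to the
#' post-window center (500 ms) plus half the dwell time (75 ms).
#'
#' @param t_train training time (s).
#' @param cfg a [detection_config()].
#' @return Delay in seconds.
#' @export
detection_delay <- function(t_train, cfg = detection_config()) {
  stopifnot(t_train >= 0)
  post_center <- mean(cfg$post_window)
  t_train + post_center + cfg$dwell_s / 2
}

#' Choose the true-positive-window offset
#'
#' The 2-s true-positive window is centred `offset` seconds after each
#' reported movement attempt. The offset is iterated over a grid (0-5 s,
#' 0.1-s steps); for each value, detections inside any window count as
#' true positives and all others as false positives, and the offset
#' maximizing the TP/FP detection ratio is returned. A zero-FP offset
#' dominates any finite ratio (ranked by TP count among themselves).
#' Exact detection-ratio ties (plateaus are common, since shifting the
#' window by less than the detection jitter changes nothing) are resolved
#' by the offset that best centres the matched detections in their
#' windows, then by the smallest offset.
#'
#' @param detection_times detection decision times (s).
#' @param reported_times reported-movement marker times (s).
#' @param window_len true-positive window length (s, default 2).
#' @param offsets candidate offsets (s).
#' @return list with `offset`, `tp`, `fp`, `ratio`, and the full `table`.
#' @export
select_tp_offset <- function(detection_times, reported_times,
                             window_len = 2,
                             offsets = seq(0, 5, by = 0.1)) {
  if (!length(reported_times)) stop("need at least one reported event")
  half <- window_len / 2
  tab <- data.frame(offset = offsets, tp = 0L, fp = 0L, ratio = 0,
                    miscenter = Inf)
  for (k in seq_along(offsets)) {
    centers <- reported_times + offsets[k]
    dist <- vapply(detection_times, function(d) min(abs(d - centers)),
                   numeric(1))
    inside <- dist <= half
    tp <- sum(inside); fp <- sum(!inside)
    tab$tp[k] <- tp; tab$fp[k] <- fp
    tab$ratio[k] <- if (fp == 0) (if (tp > 0) Inf else 0) else tp / fp
    tab$miscenter[k] <- if (tp > 0) mean(dist[inside]) else Inf
  }
  # lexicographic: ratio (Inf = zero-FP dominates), then TP, then window
  # centering, then the smallest offset
  best <- order(-tab$ratio, -tab$tp, tab$miscenter, tab$offset)[1]
  list(offset = tab$offset[best], tp = tab$tp[best], fp = tab$fp[best],
       ratio = tab$ratio[best], table = tab,
       no_detections = length(detection_times) == 0)
}

#' Evaluate online detection and classification performance
#'
#' True positives are detections falling inside a true-positive window
#' (`offset` seconds after a reported attempt, `window_len` long,
#' class-agnostic; at most one detection per window counts). TPR =
#' TP / P * 100 with P the number of reported attempts. The hand-open vs
#' palmar-grasp accuracy uses true positives only. FP/min counts
#' detections inside rest trials, normalized by the total rest minutes;
#' detections in movement trials outside the windows are ignored here
#' (they only enter the offset search).
#'
#' @param detections `data.frame` from [run_detector()].
#' @param reported_times reported-movement marker times (s).
#' @param rest_intervals `data.frame` with `start`, `end` (s) of the rest
#'   periods.
#' @param offset chosen true-positive-window offset (s).
#' @param truth_classes cued class per reported attempt.
#' @param window_len true-positive window length (s).
#' @return list with `P`, `tp`, `tpr`, `fp_per_min`, `accuracy`,
#'   `offset`, `n_rest_min`.
#' @export
evaluate_online <- function(detections, reported_times, rest_intervals,
                            offset, truth_classes, window_len = 2) {
  stopifnot(length(truth_classes) == length(reported_times))
  half <- window_len / 2
  P <- length(reported_times)
  centers <- reported_times + offset
  matched <- rep(FALSE, P)
  correct <- 0L; tp <- 0L
  for (d in seq_len(nrow(detections))) {
    dt <- detections$time[d]
    hit <- which(abs(dt - centers) <= half & !matched)
    if (length(hit)) {
      j <- hit[which.min(abs(dt - centers[hit]))]
      matched[j] <- TRUE
      tp <- tp + 1L
      if (detections$class[d] == truth_classes[j]) correct <- correct + 1L
    }
  }
  rest_min <- sum(rest_intervals$end - rest_intervals$start) / 60
  fp_rest <- 0L
  if (nrow(detections) && nrow(rest_intervals)) {
    for (d in detections$time)
      if (any(d >= rest_intervals$start & d <= rest_intervals$end))
        fp_rest <- fp_rest + 1L
  }
  list(P = P, tp = tp, tpr = if (P > 0) 100 * tp / P else NA_real_,
       fp_per_min = if (rest_min > 0) fp_rest / rest_min else NA_real_,
       accuracy = if (tp > 0) 100 * correct / tp else NA_real_,
       offset = offset, n_rest_min = rest_min)
}
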