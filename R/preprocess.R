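# Filtering, artifact handling and referencing.
#
# The offline cleaning pipeline follows four steps: (1) remove noisy
# channels (AFz by default), (2) remove stationary artifacts with ICA
# fitted on 0.3-70 Hz data restricted to samples within 10.4 MADs,
# (3) mark trials with transient artifacts (amplitude, joint probability,
# kurtosis), (4) apply the cached ICA weights to the narrow-band
# (0.3-3 Hz) signal, remove the artifactual components, and back-project.

# apply a filter function to every channel of a recording
.map_channels <- function(rec, fn) {
  out <- rec
  out$signals <- t(apply(rec$signals, 1, fn))
  rownames(out$signals) <- rec$channels$name
  out
}

#' Butterworth band-pass filter
#'
#' Band-pass of design order `order` (the argument of the classic
#' `butter(order, band)` design, giving `2 * order` poles for a
#' band-pass). `mode = "zero_phase"` applies the filter forward and backward
#' (`signal::filtfilt`): zero phase shift and a squared magnitude
#' response. `mode = "causal"` applies a single forward pass with
#' steady-state initial conditions (the filter state is initialized to the
#' steady-state response to the first sample value, suppressing the onset
#' transient); this is the variant used on the online path.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz band edges (Hz); `0 < low < high < rate/2`.
#' @param order filter design order (default 4).
#' @param mode `"zero_phase"` or `"causal"`.
#' @return Filtered recording.
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 4,
                     mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$rate / 2))
    stop("invalid band: need 0 < low < high < rate/2")
  filt <- signal::butter(order, c(low_hz, high_hz) / (rec$rate / 2),
                         type = "pass")
  .map_channels(rec, function(x) .apply_filter(filt, x, mode, rec$rate))
}

#' Notch filter for power-line interference
#'
#' A 4th-order Butterworth band-stop around `freq`, attenuating the line
#' frequency by more than 30 dB while leaving frequencies 5 Hz away within
#' 1 dB.
#'
#' @param rec an [eeg_recording()].
#' @param freq line frequency (Hz, default 50).
#' @param width half-width of the stop band (Hz).
#' @param mode `"zero_phase"` or `"causal"` (see [bandpass()]).
#' @export
notch <- function(rec, freq = 50, width = 2,
                  mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "eeg_recording"))
  if (freq + width >= rec$rate / 2) stop("notch frequency above Nyquist")
  filt <- signal::butter(2, c(freq - width, freq + width) / (rec$rate / 2),
                         type = "stop")
  .map_channels(rec, function(x) .apply_filter(filt, x, mode, rec$rate))
}

# single- or two-pass application; causal mode pads with the first sample
# for 6 s so the filter reaches its steady state w.r.t. the initial value
# (the 0.3 Hz high-pass settles over several seconds)
.apply_filter <- function(filt, x, mode, rate) {
  if (mode == "zero_phase") {
    as.numeric(signal::filtfilt(filt, x))
  } else {
    pad <- round(6 * rate)
    y <- signal::filter(filt, c(rep(x[1], pad), x))
    as.numeric(y)[-seq_len(pad)]
  }
}

#' Flag noisy channels
#'
#' AFz is always flagged when present (it is sensitive to eye blinks and
#' eye movements). In addition, channels whose robust amplitude (the MAD
#' of the signal) deviates from the channel population on a log scale by
#' more than `z_thresh` robust z-units are flagged - an automated stand-in
#' for visual inspection.
#'
#' @param rec an [eeg_recording()].
#' @param z_thresh robust z threshold on log-MAD (default 4).
#' @return Character vector of flagged channel names.
#' @export
detect_bad_channels <- function(rec, z_thresh = 4) {
  eeg <- rec$channels$kind == "EEG"
  if (sum(eeg) < 2) stop("need at least 2 EEG channels")
  m <- apply(rec$signals[eeg, , drop = FALSE], 1, stats::mad)
  lm <- log(m + 1e-12)
  s <- stats::mad(lm)
  z <- if (s > 0) (lm - stats::median(lm)) / s else rep(0, length(lm))
  flagged <- rec$channels$name[eeg][abs(z) > z_thresh]
  if ("AFz" %in% rec$channels$name) flagged <- union("AFz", flagged)
  if (length(flagged) >= sum(eeg))
    stop("all EEG channels flagged as bad; recording unusable")
  flagged
}

#' Mark channels as bad on a recording or epoch set
#' @param x an `eeg_recording` or `epoch_set`.
#' @param names channel names to flag.
#' @export
set_bad_channels <- function(x, names) {
  x$channels$is_bad <- x$channels$is_bad | x$channels$name %in% names
  x
}

#' Robust per-sample outlier mask
#'
#' A sample is kept iff `|x - median| < k * MAD` of its channel, with the
#' MAD unnormalized (constant 1); `k = 10.4` corresponds to 7 standard
#' deviations for normally distributed data. A constant channel (MAD = 0)
#' keeps all its samples.
#'
#' @param signals channels x samples matrix.
#' @param k threshold multiplier (default 10.4).
#' @return Logical matrix of the same shape, `TRUE` = keep.
#' @export
robust_sample_mask <- function(signals, k = 10.4) {
  signals <- as.matrix(signals)
  keep <- matrix(TRUE, nrow(signals), ncol(signals))
  for (i in seq_len(nrow(signals))) {
    med <- stats::median(signals[i, ])
    m <- stats::mad(signals[i, ], constant = 1)
    if (m > 0) keep[i, ] <- abs(signals[i, ] - med) < k * m
  }
  keep
}

#' Fit an ICA decomposition for artifact removal
#'
#' Dimensionality is first reduced with PCA to the smallest number of
#' components explaining `variance_keep` of the variance; extended Infomax
#' ICA (`ica::icaimax`) is then run on the retained scores. The fit uses
#' only samples passing the robust mask (all channels simultaneously
#' within bounds), and should be given broadband (0.3-70 Hz) data to ease
#' artifact detection. The returned model caches the transforms so the
#' weights can later be applied to differently filtered data.
#'
#' @param rec broadband [eeg_recording()].
#' @param variance_keep PCA variance fraction to retain (default 0.99).
#' @param mask optional logical channels x samples matrix from
#'   [robust_sample_mask()] (computed internally when `NULL`).
#' @param exclude channel names to exclude (bad channels); EOG channels
#'   are always excluded from the decomposition.
#' @param maxit Infomax iteration cap.
#' @param max_samples cap on the number of (masked) samples used for the
#'   fit; longer recordings are thinned evenly. The estimate is already
#'   stable well below this cap for EEG-like data.
#' @return An `ica_model`: channel set, centering vector, PCA basis,
#'   unmixing/mixing matrices on the retained subspace, component count.
#' @export
fit_ica <- function(rec, variance_keep = 0.99, mask = NULL,
                    exclude = character(0), maxit = 200,
                    max_samples = 20000) {
  use <- rec$channels$kind == "EEG" & !rec$channels$is_bad &
    !rec$channels$name %in% exclude
  X <- rec$signals[use, , drop = FALSE]
  if (is.null(mask)) mask <- robust_sample_mask(X)
  keep_cols <- colSums(!mask) == 0
  if (sum(keep_cols) < 10 * nrow(X))
    warning("few masked samples relative to channel count; ",
            "ICA estimate may be unstable")
  Xm <- X[, keep_cols, drop = FALSE]
  if (ncol(Xm) > max_samples)
    Xm <- Xm[, round(seq(1, ncol(Xm), length.out = max_samples)),
             drop = FALSE]
  center <- rowMeans(Xm)
  Xc <- Xm - center
  sv <- svd(Xc %*% t(Xc) / ncol(Xc))
  var_frac <- cumsum(sv$d) / sum(sv$d)
  k <- which(var_frac >= variance_keep)[1]
  if (is.na(k) || k < 2)
    stop("input is rank-deficient below 2 components; cannot fit ICA")
  V <- sv$u[, seq_len(k), drop = FALSE]           # channels x k
  scores <- t(V) %*% Xc                           # k x samples
  fit <- ica::icaimax(t(scores), nc = k, center = TRUE, maxit = maxit,
                      fun = "ext")
  # derive the scores -> sources map from the fitted sources themselves
  # (robust to the library's W/M conventions): S = R %*% scores
  S_fit <- t(fit$S)                               # k x samples
  R <- t(solve(scores %*% t(scores), scores %*% fit$S))
  Minv <- solve(R)                                # sources -> scores
  structure(list(channel_names = rec$channels$name[use],
                 center = center, V = V, R = R, Minv = Minv,
                 n_comp = k, variance_keep = variance_keep,
                 mask_fraction = mean(keep_cols)),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat("<ica_model> ", x$n_comp, " components over ",
      length(x$channel_names), " channels (",
      round(100 * x$mask_fraction, 1), "% samples used)\n", sep = "")
  invisible(x)
}

#' Component time courses of an ICA model on a recording
#' @param model an `ica_model`.
#' @param rec recording providing the model's channels.
#' @return components x samples matrix.
#' @export
ica_sources <- function(model, rec) {
  X <- rec$signals[match(model$channel_names, rec$channels$name), ,
                   drop = FALSE]
  model$R %*% (t(model$V) %*% (X - model$center))
}

#' Identify artifact-carrying independent components
#'
#' Automated stand-in for manual component screening: a component is
#' flagged when its time course correlates with any EOG channel at
#' `|r| >= eog_corr` (ocular artifacts), or when its high-band spectral
#' power (40-70 Hz) exceeds `muscle_ratio` times its low-band power
#' (1-15 Hz) (muscle-like spectrum).
#'
#' @param model an `ica_model` from [fit_ica()].
#' @param rec the broadband recording the model was fitted on.
#' @param eog_corr EOG correlation threshold (default 0.7).
#' @param muscle_ratio high/low band-power ratio threshold (default 2).
#' @return Integer vector of component indices (possibly empty).
#' @export
identify_artifact_ics <- function(model, rec, eog_corr = 0.7,
                                  muscle_ratio = 2) {
  S <- ica_sources(model, rec)
  eog <- rec$signals[rec$channels$kind == "EOG", , drop = FALSE]
  flagged <- logical(model$n_comp)
  if (nrow(eog)) {
    r <- abs(stats::cor(t(S), t(eog)))
    flagged <- flagged | apply(r, 1, max) >= eog_corr
  }
  # band-power ratio on a power-of-two segment (cheap, smooth FFT length)
  n <- min(ncol(S), 2^17)
  n <- 2^floor(log2(n))
  f <- seq(0, rec$rate / 2, length.out = n / 2 + 1)
  hi <- f >= 40 & f <= min(70, rec$rate / 2 - 1)
  lo <- f >= 1 & f <= 15
  if (any(hi) && any(lo)) {
    for (i in seq_len(model$n_comp)) {
      pw <- Mod(stats::fft(S[i, seq_len(n)]))[seq_along(f)]^2
      if (mean(pw[hi]) > muscle_ratio * mean(pw[lo]))
        flagged[i] <- TRUE
    }
  }
  which(flagged)
}

#' Remove independent components from a recording
#'
#' Applies the cached ICA weights to the (possibly differently filtered)
#' recording, subtracts the back-projection of the selected components,
#' and leaves all other channels untouched. With an empty index set the
#' recording is returned unchanged.
#'
#' @param rec full-band or narrow-band [eeg_recording()].
#' @param model `ica_model` fitted on the same channel set.
#' @param indices component indices to remove.
#' @export
remove_ics <- function(rec, model, indices) {
  if (length(indices) == 0) return(rec)
  if (any(indices < 1 | indices > model$n_comp))
    stop("component index out of range (model has ", model$n_comp,
         " components)")
  rows <- match(model$channel_names, rec$channels$name)
  if (anyNA(rows)) stop("recording lacks channels the model was fitted on")
  X <- rec$signals[rows, , drop = FALSE]
  S <- model$R %*% (t(model$V) %*% (X - rowMeans(X)))
  back <- model$V %*% (model$Minv[, indices, drop = FALSE] %*%
                         S[indices, , drop = FALSE])
  rec$signals[rows, ] <- X - back
  rec
}

#' Mark trials contaminated by transient artifacts
#'
#' Three rejection rules, applied to the good EEG channels and combined by
#' union: (1) amplitude - any sample beyond +/- `amp_uv` microvolts;
#' (2) joint probability - the per-trial mean negative log-probability of
#' its samples under per-channel empirical densities pooled over trials
#' (fixed-width histogram, `bins` bins) exceeds the across-trial mean by
#' more than `sd_k` standard deviations; (3) kurtosis - the per-trial mean
#' channel kurtosis exceeds the across-trial mean by more than `sd_k`
#' standard deviations.
#'
#' @param epochs an [epoch_set()].
#' @param sd_k deviation multiplier for rules 2 and 3 (default 5).
#' @param amp_uv amplitude bound in microvolts (default 100).
#' @param bins histogram bin count for the empirical densities.
#' @return A `rejection_report`: `data.frame` with logical columns
#'   `amplitude`, `joint_probability`, `kurtosis` and `rejected` (their
#'   union), one row per trial.
#' @export
mark_bad_trials <- function(epochs, sd_k = 5, amp_uv = 100, bins = 100) {
  n_tr <- dim(epochs$data)[1]
  if (n_tr < 3) stop("need at least 3 trials")
  chans <- which(epochs$channels$kind == "EEG" & !epochs$channels$is_bad)
  dat <- epochs$data[, chans, , drop = FALSE]

  amp <- apply(dat, 1, function(tr) max(abs(tr)) > amp_uv)

  jp_stat <- rep(0, n_tr)
  for (ci in seq_along(chans)) {
    x <- dat[, ci, ]                          # trials x samples
    rng <- range(x)
    if (diff(rng) == 0) next
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE),
                    nbins = bins)
    p <- pmax(cnt / length(x), 1e-12)
    lp <- -log(p)[pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE),
                            1), bins)]
    jp_stat <- jp_stat + rowMeans(matrix(lp, nrow = n_tr))
  }
  jp_stat <- jp_stat / length(chans)
  jp <- .above_sd(jp_stat, sd_k)

  kurt_stat <- apply(dat, 1, function(tr) {
    mean(apply(tr, 1, .kurtosis))
  })
  ku <- .above_sd(kurt_stat, sd_k)

  rep_df <- data.frame(trial = seq_len(n_tr), amplitude = amp,
                       joint_probability = jp, kurtosis = ku,
                       rejected = amp | jp | ku)
  attr(rep_df, "statistics") <- data.frame(joint_probability = jp_stat,
                                           kurtosis = kurt_stat)
  class(rep_df) <- c("rejection_report", class(rep_df))
  rep_df
}

.above_sd <- function(stat, k) {
  s <- stats::sd(stat)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(stat)))
  stat > mean(stat) + k * s
}

.kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}

#' Apply a rejection report to an epoch set
#' @param epochs an [epoch_set()].
#' @param report a `rejection_report` from [mark_bad_trials()].
#' @export
apply_rejection <- function(epochs, report) {
  epochs$rejected <- epochs$rejected | report$rejected
  epochs
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over the good EEG channels from
#' each good EEG channel. EOG and bad channels are untouched. Idempotent.
#'
#' @param x an `eeg_recording` or `epoch_set`.
#' @export
common_average_reference <- function(x) {
  UseMethod("common_average_reference")
}

#' @export
common_average_reference.eeg_recording <- function(x) {
  idx <- which(x$channels$kind == "EEG" & !x$channels$is_bad)
  if (length(idx) < 2) stop("need at least 2 good EEG channels")
  x$signals[idx, ] <- sweep(x$signals[idx, , drop = FALSE], 2,
                            colMeans(x$signals[idx, , drop = FALSE]))
  x
}

#' @export
common_average_reference.epoch_set <- function(x) {
  idx <- which(x$channels$kind == "EEG" & !x$channels$is_bad)
  if (length(idx) < 2) stop("need at least 2 good EEG channels")
  for (i in seq_len(dim(x$data)[1])) {
    tr <- x$data[i, idx, , drop = TRUE]
    x$data[i, idx, ] <- sweep(tr, 2, colMeans(tr))
  }
  x
}
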