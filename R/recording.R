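#' Continuous multichannel EEG recording
#'
#' The central data container: a channels x samples signal matrix in
#' microvolts, its sampling rate, a channel table (see
#' [standard_montage()]) and an event stream. Sample indexing is 0-based
#' throughout: an event with `onset = 0` refers to the first sample.
#'
#' Recognised event labels are `trial_start`, `class_cue:<class>`,
#' `ready_cue`, `go_cue`, `reported_movement`, `detection:<class>` and
#' `rest_start`; unknown labels are preserved but ignored by the analysis
#' pipelines.
#'
#' @param signals numeric matrix, channels x samples, in uV.
#' @param rate sampling rate in Hz (nominally 256).
#' @param channels channel table as from [standard_montage()].
#' @param events `data.frame` with integer column `onset` (0-based sample
#'   index) and character column `label`, sorted by onset.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, rate, channels,
                          events = empty_events()) {
  signals <- as.matrix(signals)
  validate_channels(channels)
  if (nrow(signals) != nrow(channels))
    stop("signal row count (", nrow(signals),
         ") must equal channel count (", nrow(channels), ")")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a single positive number")
  if (!all(is.finite(signals)))
    stop("all signal values must be finite")
  events <- as.data.frame(events)
  if (nrow(events)) {
    stopifnot(all(c("onset", "label") %in% names(events)))
    events$onset <- as.integer(events$onset)
    events$label <- as.character(events$label)
    if (is.unsorted(events$onset))
      stop("event onsets must be non-decreasing")
    if (any(events$onset < 0) || any(events$onset >= ncol(signals)))
      stop("event onsets must lie within the recording")
  } else {
    events <- empty_events()
  }
  rownames(signals) <- channels$name
  structure(list(signals = signals, rate = rate,
                 channels = channels, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$signals), " channels x ",
      ncol(x$signals), " samples @ ", x$rate, " Hz (",
      round(ncol(x$signals) / x$rate, 1), " s), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' @rdname eeg_recording
#' @export
empty_events <- function() {
  data.frame(onset = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$signals) / rec$rate

#' Write a recording to the package's fixture container
#'
#' The fixture format is a single-file container holding the fields
#' `signals` (channels x samples, uV), `rate`, `channels` (the channel
#' table) and `events`, serialized with R's native serialization
#' (version 3). Round-trips through [read_recording()] are bit-faithful.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  payload <- list(format = "mrcpdecode-recording", version = 1L,
                  signals = rec$signals, rate = rec$rate,
                  channels = rec$channels, events = rec$events)
  ok <- tryCatch({ saveRDS(payload, path, version = 3); TRUE },
                 error = function(e) {
                   stop("cannot write recording to '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  invisible(path)
}

#' Read a recording from disk
#'
#' `format = "fixture"` reads the package's own container (see
#' [write_recording()]). `format = "edf"` is an optional reader for
#' European Data Format files as used by public biosignal archives; it
#' supports plain EDF (16-bit integer records) and assigns channel kinds
#' from names (labels containing "EOG" become EOG channels). EDF carries
#' no event stream, so `events` is empty unless a sidecar is supplied by
#' the caller.
#'
#' @param path file to read.
#' @param format `"fixture"` or `"edf"`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("fixture", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file does not exist: '", path, "'")
  if (format == "fixture") {
    payload <- tryCatch(readRDS(path), error = function(e)
      stop("cannot parse fixture container '", path, "': ",
           conditionMessage(e), call. = FALSE))
    if (!is.list(payload) ||
        !identical(payload$format, "mrcpdecode-recording"))
      stop("'", path, "' is not an mrcpdecode recording container")
    if (is.null(payload$rate))
      stop("fixture container missing sampling rate")
    eeg_recording(payload$signals, payload$rate, payload$channels,
                  payload$events)
  } else {
    read_edf(path)
  }
}

# Minimal plain-EDF reader: 256-byte fixed header, 256 bytes per signal
# header field block, data records of 2-byte little-endian integers scaled
# channel-wise from digital to physical range.
#' @keywords internal
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) {
    raw <- readBin(con, "raw", n)
    if (length(raw) < n) stop("truncated EDF header in '", path, "'")
    trimws(rawToChar(raw))
  }
  hdr(8)                       # version
  hdr(80); hdr(80)             # patient / recording id
  hdr(8); hdr(8)               # start date / time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                      # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) stop("EDF format error: bad signal count")
  if (is.na(record_dur) || record_dur <= 0)
    stop("EDF format error: record duration (sampling rate) missing")
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), "")
  labels <- field(16)
  field(80); field(8)                       # transducer, dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)                                 # prefiltering
  n_samp <- as.integer(field(8))
  field(32)                                 # reserved
  if (length(unique(n_samp)) != 1)
    stop("EDF reader supports a common sampling rate only")
  expect <- header_bytes - 256 - 256 * ns
  if (expect != 0) stop("EDF format error: inconsistent header size")
  rate <- n_samp[1] / record_dur
  total <- n_records * n_samp[1]
  sig <- matrix(0, ns, total)
  for (r in seq_len(n_records)) {
    block <- readBin(con, "integer", n = ns * n_samp[1], size = 2,
                     signed = TRUE, endian = "little")
    if (length(block) < ns * n_samp[1])
      stop("truncated EDF data record ", r, " in '", path, "'")
    idx <- (r - 1) * n_samp[1] + seq_len(n_samp[1])
    sig[, idx] <- matrix(block, nrow = ns, byrow = TRUE)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  off <- phys_min - gain * dig_min
  sig <- sig * gain + off
  montage <- standard_montage()
  pos <- montage[match(labels, montage$name), c("x", "y")]
  channels <- data.frame(
    name = make.unique(labels),
    kind = ifelse(grepl("EOG", labels, ignore.case = TRUE), "EOG", "EEG"),
    x = ifelse(is.na(pos$x), 0, pos$x),
    y = ifelse(is.na(pos$y), 0, pos$y),
    is_bad = FALSE, stringsAsFactors = FALSE)
  eeg_recording(sig, rate, channels)
}

#' Extract epochs aligned to an event label
#'
#' Cuts trials from a continuous recording around every event matching
#' `align_label`. The label `"class_cue"` matches any `class_cue:<class>`
#' marker. The epoch sample range is half-open: the first sample of a trial
#' is `round(onset + window[1] * rate)` and the trial holds
#' `round((window[2] - window[1]) * rate)` samples. Class labels are drawn
#' from the nearest `class_cue:<class>` marker at or before each alignment
#' event.
#'
#' @param rec an [eeg_recording()].
#' @param align_label event label to align on (e.g. `"class_cue"`,
#'   `"go_cue"`).
#' @param window numeric length-2, epoch start/end in seconds relative to
#'   the alignment event.
#' @param class_from labelling rule; only `"preceding_class_cue"` is
#'   defined.
#' @return An object of class `epoch_set`: list with `data`
#'   (trials x channels x samples array, uV), `t0_offset` (= `window[1]`),
#'   `rate`, `channels`, `labels` (character per trial), `rejected`
#'   (logical per trial), and `align_onsets` (0-based sample indices).
#' @export
epoch <- function(rec, align_label, window,
                  class_from = "preceding_class_cue") {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2,
            window[1] < window[2])
  ev <- rec$events
  if (align_label == "class_cue") {
    hit <- grepl("^class_cue(:|$)", ev$label)
  } else {
    hit <- ev$label == align_label
  }
  onsets <- ev$onset[hit]
  n_samp <- round((window[2] - window[1]) * rec$rate)
  starts <- round(onsets + window[1] * rec$rate)
  if (length(onsets)) {
    bad <- starts < 0 | (starts + n_samp) > ncol(rec$signals)
    if (any(bad))
      stop("epoch window exceeds recording bounds for events at samples: ",
           paste(onsets[bad], collapse = ", "))
  }
  n_tr <- length(onsets)
  dat <- array(0, dim = c(n_tr, nrow(rec$signals), n_samp))
  labels <- character(n_tr)
  cues <- ev[grepl("^class_cue:", ev$label), , drop = FALSE]
  for (i in seq_len(n_tr)) {
    dat[i, , ] <- rec$signals[, starts[i] + seq_len(n_samp), drop = FALSE]
    prev <- cues$onset <= onsets[i]
    labels[i] <- if (any(prev))
      sub("^class_cue:", "", cues$label[max(which(prev))]) else NA_character_
  }
  epoch_set(dat, window[1], rec$rate, rec$channels, labels,
            align_onsets = onsets)
}

#' Epoch container constructor
#'
#' @param data trials x channels x samples array (uV).
#' @param t0_offset time of the first sample relative to the alignment
#'   event, in seconds.
#' @param rate sampling rate (Hz).
#' @param channels channel table.
#' @param labels class label per trial.
#' @param rejected logical rejection mask per trial.
#' @param align_onsets optional 0-based onsets of the alignment events.
#' @export
epoch_set <- function(data, t0_offset, rate, channels, labels,
                      rejected = rep(FALSE, dim(data)[1]),
                      align_onsets = NULL) {
  stopifnot(length(dim(data)) == 3)
  validate_channels(channels)
  if (dim(data)[2] != nrow(channels))
    stop("channel axis must match channel table")
  if (length(labels) != dim(data)[1])
    stop("label count must equal trial count")
  if (length(rejected) != dim(data)[1])
    stop("rejection mask must have one entry per trial")
  structure(list(data = data, t0_offset = t0_offset, rate = rate,
                 channels = channels, labels = labels,
                 rejected = rejected, align_onsets = align_onsets),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$rate, " Hz, t0 ", x$t0_offset, " s, ",
      sum(x$rejected), " rejected\n", sep = "")
  invisible(x)
}

#' Time axis of an epoch set (seconds relative to the alignment event)
#' @param epochs an `epoch_set`.
#' @export
epoch_times <- function(epochs) {
  epochs$t0_offset + (seq_len(dim(epochs$data)[3]) - 1) / epochs$rate
}

#' Drop rejected trials from an epoch set
#' @param epochs an `epoch_set`.
#' @export
drop_rejected <- function(epochs) {
  keep <- !epochs$rejected
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$t0_offset,
            epochs$rate, epochs$channels, epochs$labels[keep],
            align_onsets = epochs$align_onsets[keep])
}

#' Per-class trial-average waveforms
#'
#' @param epochs an `epoch_set` (rejected trials are excluded).
#' @param classes classes to average; defaults to the sorted unique labels.
#' @return Named list of channels x samples matrices, one per class.
#' @export
class_averages <- function(epochs, classes = NULL) {
  keep <- !epochs$rejected
  if (is.null(classes)) classes <- sort(unique(epochs$labels[keep]))
  out <- lapply(classes, function(cl) {
    idx <- which(keep & epochs$labels == cl)
    if (!length(idx)) stop("no retained trials for class '", cl, "'")
    colMeans(epochs$data[idx, , , drop = FALSE], dims = 1)
  })
  names(out) <- classes
  out
}
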