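#' Standard EEG montage used throughout the package
#'
#' Builds the channel table for the recording montage: 61 EEG electrodes of
#' the 10-5 system covering frontal, central, parietal and temporal areas,
#' plus 3 EOG electrodes (one above the nasion, two below the outer canthi).
#' Positions are schematic 2-D head coordinates on the unit disc (x: left
#' negative/right positive; y: front positive/back negative) used for the
#' radial MRCP spatial pattern and for topographic interpolation; they are
#' not digitized electrode locations.
#'
#' @param subset `"full"` for the complete 61+3 montage, `"reduced"` for a
#'   19-channel 10-20-style subset (plus the 3 EOG channels) that keeps the
#'   central electrodes; useful for fast simulations.
#' @return A `data.frame` with columns `name`, `kind` (`"EEG"`/`"EOG"`),
#'   `x`, `y`, `is_bad`.
#' @export
#' @examples
#' m <- standard_montage()
#' nrow(m)                  # 64
#' sum(m$kind == "EEG")     # 61
standard_montage <- function(subset = c("full", "reduced")) {
  subset <- match.arg(subset)
  rows <- list(
    # row name prefix pairs: (y position, channel names left..right)
    list(y = 0.90, n = c("Fp1", "Fpz", "Fp2")),
    list(y = 0.72, n = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.50, n = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    list(y = 0.25, n = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                         "FC6", "FT8")),
    list(y = 0.00, n = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                         "T8")),
    list(y = -0.25, n = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                          "CP6", "TP8")),
    list(y = -0.50, n = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
                          "P8")),
    list(y = -0.72, n = c("PO7", "PO3", "POz", "PO4", "PO8")),
    list(y = -0.90, n = c("O1", "Oz", "O2"))
  )
  tabs <- lapply(rows, function(r) {
    k <- length(r$n)
    # lateral spread shrinks towards the front/back of the head
    half <- sqrt(max(0, 1 - r$y^2))
    x <- if (k == 1) 0 else seq(-half, half, length.out = k)
    data.frame(name = r$n, kind = "EEG", x = x, y = r$y,
               stringsAsFactors = FALSE)
  })
  eeg <- do.call(rbind, tabs)
  eog <- data.frame(
    name = c("EOGnasion", "EOGleft", "EOGright"),
    kind = "EOG",
    x = c(0, -0.4, 0.4), y = c(1.05, 1.0, 1.0),
    stringsAsFactors = FALSE)
  mt <- rbind(eeg, eog)
  if (subset == "reduced") {
    keep <- c("AFz", "Fz", "F3", "F4", "FCz", "FC3", "FC4",
              "Cz", "C1", "C2", "C3", "C4",
              "CPz", "CP3", "CP4", "Pz", "P3", "P4", "Oz",
              "EOGnasion", "EOGleft", "EOGright")
    mt <- mt[match(keep, mt$name), ]
  }
  mt$is_bad <- FALSE
  rownames(mt) <- NULL
  mt
}

#' @keywords internal
validate_channels <- function(channels) {
  stopifnot(is.data.frame(channels),
            all(c("name", "kind", "x", "y", "is_bad") %in% names(channels)))
  if (anyDuplicated(channels$name))
    stop("channel names must be unique")
  if (!all(channels$kind %in% c("EEG", "EOG")))
    stop("channel kind must be 'EEG' or 'EOG'")
  eeg <- channels$kind == "EEG"
  if (any(!is.finite(channels$x[eeg])) || any(!is.finite(channels$y[eeg])))
    stop("every EEG channel needs a finite 2-D position")
  invisible(channels)
}

#' Names of the good EEG channels of a recording or channel table
#'
#' @param x an `eeg_recording`, `epoch_set`, or channel `data.frame`.
#' @return Character vector of EEG channel names not flagged bad.
#' @export
good_eeg_channels <- function(x) {
  ch <- if (is.data.frame(x)) x else x$channels
  ch$name[ch$kind == "EEG" & !ch$is_bad]
}
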