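#' Class labels used throughout the package
#' @export
intention_classes <- c("sit_to_stand", "stand_to_sit", "rest")

#' Labeled trial epochs
#'
#' Container for aligned trial windows: a trials x channels x time array,
#' per-trial class labels, the window in seconds relative to movement onset
#' (half-open `[start, end)`), the sampling rate and channel metadata.
#'
#' @param data numeric array, trials x channels x time.
#' @param labels per-trial labels, coerced to a factor over
#'   [intention_classes] (extra levels are an error).
#' @param window numeric length-2 `(start_s, end_s)` relative to onset.
#' @param rate sampling rate in Hz.
#' @param channel_labels,modality channel metadata as in [recording()].
#' @return An object of class `"epoch_set"`.
#' @export
epoch_set <- function(data, labels, window, rate,
                      channel_labels = NULL, modality = "EEG") {
  if (length(dim(data)) != 3L)
    stop("`data` must be a trials x channels x time array")
  n_trial <- dim(data)[1]; n_ch <- dim(data)[2]; n_t <- dim(data)[3]
  if (length(labels) != n_trial)
    stop("need one label per trial")
  if (!all(as.character(labels) %in% intention_classes))
    stop("labels must be drawn from: ",
         paste(intention_classes, collapse = ", "))
  labels <- factor(as.character(labels), levels = intention_classes)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n_ch))
  if (length(channel_labels) != n_ch)
    stop("label count does not equal channel count")
  if (length(modality) == 1L) modality <- rep(modality, n_ch)
  expected <- round((window[2] - window[1]) * rate)
  if (expected != n_t)
    stop("window length x rate (", expected,
         ") does not equal the time dimension (", n_t, ")")
  structure(
    list(data = data, labels = labels, window = as.numeric(window),
         rate = rate, channel_labels = as.character(channel_labels),
         modality = toupper(modality)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " trial(s) x ", dim(x$data)[2],
      " channel(s) x ", dim(x$data)[3], " samples @ ", x$rate, " Hz, window [",
      x$window[1], ", ", x$window[2], ") s\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Extract labeled epochs around movement onsets
#'
#' Cuts one window per onset from a continuous recording. Windows are
#' half-open in samples: `[onset + round(start_s*rate), onset + round(end_s*rate))`,
#' which prevents double-counting at shared boundaries. Onsets whose window
#' falls outside the recording are rejected per trial (with a message naming
#' the trial), not a global failure.
#'
#' @param rec a [recording()].
#' @param onsets integer onset samples, or a list of `"onset_event"` objects.
#' @param window numeric `(start_s, end_s)` relative to each onset,
#'   default `c(-1.5, 0)` (the pre-movement intention window).
#' @param labels one class label per onset (see [intention_classes]).
#' @return An [epoch_set()] of the retained trials; the integer indices of
#'   rejected onsets are attached as attribute `"rejected"`.
#' @export
segment_trials <- function(rec, onsets, window = c(-1.5, 0), labels) {
  stopifnot(inherits(rec, "recording"))
  if (is.list(onsets))
    onsets <- vapply(onsets, function(o) o$onset_sample, integer(1))
  onsets <- as.integer(onsets)
  if (length(labels) != length(onsets))
    stop("need one label per onset")
  if (window[1] >= window[2]) stop("window start must precede window end")
  off0 <- as.integer(round(window[1] * rec$rate))
  off1 <- as.integer(round(window[2] * rec$rate))
  len <- off1 - off0
  n_total <- ncol(rec$samples)

  keep <- logical(length(onsets))
  for (k in seq_along(onsets)) {
    lo <- onsets[k] + off0
    hi <- onsets[k] + off1 - 1L
    if (is.na(onsets[k]) || lo < 1L || hi > n_total) {
      message("segment_trials: rejecting trial ", k,
              " (window [", lo, ", ", hi, "] outside recording)")
    } else keep[k] <- TRUE
  }
  kept <- which(keep)
  if (!length(kept)) stop("no trial window fits inside the recording")
  data <- array(0, c(length(kept), nrow(rec$samples), len))
  for (j in seq_along(kept)) {
    lo <- onsets[kept[j]] + off0
    data[j, , ] <- rec$samples[, lo:(lo + len - 1L), drop = FALSE]
  }
  es <- epoch_set(data, labels[kept], window = window, rate = rec$rate,
                  channel_labels = rec$channel_labels,
                  modality = rec$modality)
  attr(es, "rejected") <- which(!keep)
  es
}

#' Subset an epoch set by modality
#'
#' @param epochs an [epoch_set()].
#' @param modality `"eeg"`, `"emg"` or `"fusion"` (all channels).
#' @return An [epoch_set()] restricted to the selected channels.
#' @export
select_modality <- function(epochs, modality = c("fusion", "eeg", "emg")) {
  modality <- match.arg(tolower(modality), c("fusion", "eeg", "emg"))
  if (modality == "fusion") return(epochs)
  idx <- which(epochs$modality == toupper(modality))
  if (!length(idx)) stop("no ", toupper(modality), " channels in epoch set")
  epoch_set(epochs$data[, idx, , drop = FALSE], epochs$labels,
            window = epochs$window, rate = epochs$rate,
            channel_labels = epochs$channel_labels[idx],
            modality = epochs$modality[idx])
}
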