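#' Multichannel biosignal recording
#'
#' Container for a continuous multichannel recording: a channels-by-time
#' numeric matrix (microvolts), its sampling rate, ordered channel labels,
#' a per-channel modality tag (`"EEG"` or `"EMG"`), and the sample indices
#' of visual "move" cues.
#'
#' @param samples numeric matrix, channels x time.
#' @param rate sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one label per channel. Defaults to
#'   `ch1, ch2, ...`.
#' @param modality character vector of `"EEG"`/`"EMG"` tags, one per channel,
#'   or a single tag recycled to all channels.
#' @param cue_times integer sample indices (1-based) of visual cues; must be
#'   strictly increasing and within the recording.
#'
#' @return An object of class `"recording"`.
#' @export
recording <- function(samples, rate, channel_labels = NULL,
                      modality = "EEG", cue_times = integer(0)) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric channels x time matrix")
  n_ch <- nrow(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a positive scalar (Hz)")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(n_ch))
  if (length(channel_labels) != n_ch)
    stop("label count (", length(channel_labels),
         ") does not equal channel count (", n_ch, ")")
  if (length(modality) == 1L) modality <- rep(modality, n_ch)
  if (length(modality) != n_ch)
    stop("`modality` must have one tag per channel")
  modality <- toupper(modality)
  if (!all(modality %in% c("EEG", "EMG")))
    stop("modality tags must be \"EEG\" or \"EMG\"")
  cue_times <- as.integer(cue_times)
  if (length(cue_times)) {
    if (any(diff(cue_times) <= 0))
      stop("cue indices must be strictly increasing")
    if (min(cue_times) < 1L || max(cue_times) > ncol(samples))
      stop("cue indices must lie within the signal length")
  }
  structure(
    list(samples = samples, rate = rate,
         channel_labels = as.character(channel_labels),
         modality = modality, cue_times = cue_times),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", nrow(x$samples), " channel(s) x ", ncol(x$samples),
      " samples @ ", x$rate, " Hz (",
      sprintf("%.2f", ncol(x$samples) / x$rate), " s)\n", sep = "")
  cat("  EEG: ", sum(x$modality == "EEG"),
      "  EMG: ", sum(x$modality == "EMG"),
      "  cues: ", length(x$cue_times), "\n", sep = "")
  invisible(x)
}

#' Read a recording from delimited text
#'
#' Expects one column per channel with a header row of channel labels; rows
#' are samples. Cue times and modality tags are supplied by the caller since
#' delimited text carries no event track.
#'
#' @param path file path.
#' @param rate sampling rate in Hz.
#' @param modality per-channel modality tags (or a single recycled tag).
#' @param cue_times cue sample indices.
#' @param sep field separator (default tab).
#' @return A [recording()].
#' @export
read_recording_tsv <- function(path, rate, modality = "EEG",
                               cue_times = integer(0), sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  m <- t(as.matrix(df))
  dimnames(m) <- NULL
  recording(m, rate = rate, channel_labels = colnames(df),
            modality = modality, cue_times = cue_times)
}

#' Write a recording to delimited text
#'
#' @param rec a [recording()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path, sep = "\t") {
  stopifnot(inherits(rec, "recording"))
  m <- t(rec$samples)
  colnames(m) <- rec$channel_labels
  utils::write.table(m, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load package objects as a single-file container
#'
#' Serializes recordings, epoch sets, connectivity matrices, filter banks and
#' fitted ensembles with all metadata (rate, labels, modality, events, seed)
#' so they round-trip exactly.
#'
#' @param x object to save.
#' @param path file path.
#' @return `save_container()` returns `path` invisibly; `load_container()`
#'   returns the stored object.
#' @export
save_container <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) readRDS(path)
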