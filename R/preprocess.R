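## Zero-phase IIR filtering with odd-reflection padding, run as a cascade of
## second-order sections: high-order Butterworth designs with band edges far
## below Nyquist have poles so close to the unit circle that the expanded
## transfer function loses precision; biquads do not.
## Pad length follows 3 * order * (rate / f_char), capped at n - 1, where
## f_char is the low cutoff (band-pass) or the stop-band width (notch) -
## long enough for the slowest transient to settle.

.zero_phase <- function(b, a, x, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  pre  <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(pre, x, post)
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

.poly_from_roots <- function(r) {
  p <- 1
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

## group roots into conjugate (or real) pairs
.root_pairs <- function(v, tol = 1e-8) {
  out <- list(); used <- rep(FALSE, length(v))
  for (i in seq_along(v)) if (!used[i] && abs(Im(v[i])) > tol) {
    j <- which(!used & seq_along(v) != i & abs(v - Conj(v[i])) < 1e-6)[1]
    if (!is.na(j)) { used[c(i, j)] <- TRUE; out[[length(out) + 1]] <- c(v[i], v[j]) }
  }
  re <- which(!used)
  re <- re[order(Re(v[re]))]
  while (length(re) >= 2) { out[[length(out) + 1]] <- v[re[1:2]]; re <- re[-(1:2)] }
  if (length(re)) out[[length(out) + 1]] <- v[re]
  out
}

## second-order sections from a butter() design: pole pairs ordered nearest
## the unit circle first, each matched with its nearest zero pair
.butter_sos <- function(bf) {
  z <- signal::as.Zpg(bf)
  pp <- .root_pairs(z$pole)
  zz <- .root_pairs(z$zero)
  pp <- pp[order(-vapply(pp, function(p) max(Mod(p)), numeric(1)))]
  sos <- list()
  for (p in pp) {
    if (length(zz)) {
      d <- vapply(zz, function(q) min(Mod(q[1] - p[1]), Mod(q[1] - p[length(p)])),
                  numeric(1))
      j <- which.min(d); zpair <- zz[[j]]; zz <- zz[-j]
    } else zpair <- numeric(0)
    sos[[length(sos) + 1]] <- list(b = Re(.poly_from_roots(zpair)),
                                   a = Re(.poly_from_roots(p)))
  }
  for (q in zz) sos[[length(sos) + 1]] <- list(b = Re(.poly_from_roots(q)), a = 1)
  sos[[1]]$b <- sos[[1]]$b * Re(z$gain)
  sos
}

.zero_phase_sos <- function(sos, x, pad) {
  for (s in sos) x <- .zero_phase(s$b, s$a, x, pad)
  x
}

.filter_channels <- function(rec, sos, pad, channels = seq_len(nrow(rec$samples))) {
  out <- rec$samples
  for (i in channels) out[i, ] <- .zero_phase_sos(sos, out[i, ], pad)
  rec$samples <- out
  rec
}

.check_filter_length <- function(n, order) {
  if (n <= 3L * (order + 1L))
    stop("signal too short to filter: ", n, " samples")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass filter forward and backward (zero phase)
#' to every channel, with odd-reflection padding of
#' `3 * order * rate / low` samples (capped at the signal length minus one)
#' to suppress edge transients. The default 0.5-45 Hz band is the standard
#' EEG broadband; EMG is typically filtered 15-300 Hz.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz; `0 <= low < high < rate/2`.
#' @param order Butterworth design order (default 4).
#' @return The filtered [recording()].
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45, order = 4L) {
  stopifnot(inherits(rec, "recording"))
  if (!(low >= 0 && low < high && high < rec$rate / 2))
    stop("invalid band edges: need 0 <= low < high < rate/2 (low=", low,
         ", high=", high, ", rate=", rec$rate, ")")
  .check_filter_length(ncol(rec$samples), order)
  sos <- .butter_sos(signal::butter(order, c(low, high) / (rec$rate / 2),
                                    type = "pass"))
  pad <- round(3 * order * rec$rate / max(low, 1e-3))
  .filter_channels(rec, sos, pad)
}

#' Zero-phase Butterworth band-stop (notch) filter
#'
#' Used to remove power-line interference (48-52 Hz for a 50 Hz mains).
#'
#' @param rec a [recording()].
#' @param stop_low,stop_high stop-band edges in Hz; `0 < stop_low < stop_high < rate/2`.
#' @param order Butterworth design order (default 4).
#' @return The filtered [recording()].
#' @export
notch_filter <- function(rec, stop_low = 48, stop_high = 52, order = 4L) {
  stopifnot(inherits(rec, "recording"))
  if (!(stop_low > 0 && stop_low < stop_high && stop_high < rec$rate / 2))
    stop("invalid stop band: need 0 < stop_low < stop_high < rate/2 (",
         stop_low, ", ", stop_high, ", rate=", rec$rate, ")")
  .check_filter_length(ncol(rec$samples), order)
  sos <- .butter_sos(signal::butter(order, c(stop_low, stop_high) / (rec$rate / 2),
                                    type = "stop"))
  pad <- round(3 * order * rec$rate / (stop_high - stop_low))
  .filter_channels(rec, sos, pad)
}

#' Common average reference
#'
#' Re-references the EEG channels by subtracting, at every sample, the mean
#' across all EEG channels. EMG channels are left untouched. Requires at
#' least two EEG channels.
#'
#' @param rec a [recording()].
#' @return The re-referenced [recording()].
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  eeg <- which(rec$modality == "EEG")
  if (length(eeg) < 2L)
    stop("common average reference needs >= 2 EEG channels, found ",
         length(eeg))
  avg <- colMeans(rec$samples[eeg, , drop = FALSE])
  rec$samples[eeg, ] <- sweep(rec$samples[eeg, , drop = FALSE], 2L, avg)
  rec
}

#' Resample a recording to a new rate
#'
#' Rational-factor polyphase resampling with built-in anti-alias filtering
#' (via [signal::resample()]). Used to bring 1.5 kHz EMG onto the 1 kHz EEG
#' clock before cross-modal connectivity; downsampling the higher-rate signal
#' avoids interpolating EEG. Cue times are rescaled to the new rate.
#' Upsampling beyond the original rate triggers a warning (no information is
#' added above the original Nyquist frequency).
#'
#' @param rec a [recording()].
#' @param target_rate new sampling rate in Hz.
#' @return The resampled [recording()].
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("`target_rate` must be a positive scalar")
  if (target_rate == rec$rate) return(rec)
  if (target_rate > rec$rate)
    warning("upsampling above the original rate cannot reconstruct content ",
            "beyond the original Nyquist frequency")
  pq <- .rational(target_rate / rec$rate)
  n_out <- round(ncol(rec$samples) * target_rate / rec$rate)
  out <- matrix(0, nrow(rec$samples), n_out)
  for (i in seq_len(nrow(rec$samples))) {
    y <- signal::resample(rec$samples[i, ], pq[1], pq[2])
    if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
    out[i, ] <- y[seq_len(n_out)]
  }
  recording(out, rate = target_rate, channel_labels = rec$channel_labels,
            modality = rec$modality,
            cue_times = pmax(1L, pmin(n_out,
              as.integer(round(rec$cue_times * target_rate / rec$rate)))))
}

## continued-fraction rational approximation p/q of r, denominator <= 1000
.rational <- function(r, max_den = 1000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; x <- r
  repeat {
    a <- floor(x)
    p2 <- as.integer(a * p1 + p0); q2 <- as.integer(a * q1 + q0)
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    x <- 1 / (x - a)
  }
  c(p1, q1)
}
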