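## Welch spectral machinery shared by the coherence estimator and the
## fatigue indices: Hann-windowed, mean-detrended, overlapping segments.

.welch_starts <- function(n, L, overlap_frac) {
  if (n < L)
    stop("signal (", n, " samples) shorter than one Welch segment (", L, ")")
  step <- L - floor(L * overlap_frac)
  if (step < 1L) stop("overlap fraction must be < 1")
  starts <- seq(1L, n - L + 1L, by = step)
  if (!length(starts)) stop("signal shorter than one Welch segment")
  starts
}

## windowed segment FFTs for one channel: (L x K) complex matrix
.welch_fft <- function(x, L, starts, win) {
  K <- length(starts)
  segs <- matrix(0, L, K)
  for (k in seq_len(K)) {
    s <- x[starts[k]:(starts[k] + L - 1L)]
    segs[, k] <- (s - mean(s)) * win
  }
  stats::mvfft(segs)
}

## one-sided averaged cross-spectral density from two FFT matrices
.welch_csd <- function(X, Y, rate, win) {
  L <- nrow(X)
  nb <- L %/% 2L + 1L
  cs <- rowMeans(X[seq_len(nb), , drop = FALSE] *
                 Conj(Y[seq_len(nb), , drop = FALSE]))
  scale <- 1 / (rate * sum(win^2))
  cs <- cs * scale
  # one-sided doubling, excluding DC and (for even L) Nyquist
  dbl <- rep(2, nb); dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[nb] <- 1
  cs * dbl
}

.welch_freqs <- function(L, rate) (0:(L %/% 2L)) * rate / L

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlapping (by default), mean-detrended Welch estimate
#' of the one-sided power spectral density.
#'
#' @param x numeric series.
#' @param rate sampling rate in Hz.
#' @param segment_s segment length in seconds (default 1).
#' @param overlap_frac fractional overlap between segments in `[0, 1)`.
#' @return An object of class `"spectrum_estimate"`: list with `freqs` (Hz),
#'   `power` (density, power per Hz) and `resolution` (Hz between bins).
#' @export
power_spectrum <- function(x, rate, segment_s = 1, overlap_frac = 0.5) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  L <- as.integer(round(segment_s * rate))
  if (L < 2L) stop("segment too short")
  if (length(x) < L)
    stop("signal (", length(x), " samples) shorter than one segment (", L, ")")
  starts <- .welch_starts(length(x), L, overlap_frac)
  win <- .hann(L)
  X <- .welch_fft(x, L, starts, win)
  p <- Re(.welch_csd(X, X, rate, win))
  p[p < 0] <- 0
  structure(list(freqs = .welch_freqs(L, rate), power = p,
                 resolution = rate / L),
            class = "spectrum_estimate")
}

.hann <- function(L) 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat("<spectrum_estimate> ", length(x$freqs), " bins, ",
      x$freqs[1], "-", x$freqs[length(x$freqs)], " Hz @ ",
      signif(x$resolution, 4), " Hz resolution\n", sep = "")
  invisible(x)
}
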