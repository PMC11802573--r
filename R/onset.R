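#' Teager-Kaiser energy operator
#'
#' Instantaneous-energy proxy `psi[n] = x[n]^2 - x[n-1] * x[n+1]`, defined for
#' interior samples only, so the output is two samples shorter than the input.
#' For a sinusoid `A*sin(w*n)` the operator returns the constant
#' `A^2 * sin(w)^2`, i.e. it tracks amplitude-and-frequency energy, which makes
#' it a sensitive detector of EMG burst onsets.
#'
#' @param x numeric vector, length >= 3.
#' @return Numeric vector of length `length(x) - 2`; element `k` corresponds
#'   to input sample `k + 1`.
#' @export
tkeo <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  n <- length(x)
  if (n < 3L) stop("tkeo needs at least 3 samples, got ", n)
  x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]
}

#' Detect movement onset from an energy series
#'
#' Thresholds a (typically Teager-Kaiser) energy series at `T = mu + h*sigma`,
#' where `mu` and `sigma` are the mean and standard deviation of a baseline
#' window positioned relative to the visual cue (default 3 to 2 s before the
#' cue). The onset is the first sample of the first run of strictly more than
#' `run_len` consecutive supra-threshold samples (i.e. the run must contain at
#' least `run_len + 1` samples), searching forward from the cue. A short
#' centered moving average (default 10 ms) is applied before thresholding;
#' raw sample-wise energy of a stochastic burst is heavy-tailed and rarely
#' sustains long uninterrupted threshold crossings.
#'
#' @param energy numeric energy series (e.g. output of [tkeo()]).
#' @param rate sampling rate of `energy` in Hz.
#' @param cue_sample 1-based index of the visual cue within `energy`.
#' @param baseline numeric length-2, baseline window in seconds relative to
#'   the cue (default `c(-3, -2)`).
#' @param h threshold multiplier (default 5).
#' @param run_len run-length parameter (default 20; strict "more than").
#' @param smooth_s moving-average length in seconds (0 disables smoothing).
#' @return An object of class `"onset_event"`: list with `onset_sample`
#'   (`NA_integer_` when no qualifying run exists), `threshold`,
#'   `baseline_mean`, `baseline_sd`, `h`.
#' @export
detect_onset <- function(energy, rate, cue_sample, baseline = c(-3, -2),
                         h = 5, run_len = 20L, smooth_s = 0.01) {
  if (!is.numeric(energy)) stop("`energy` must be numeric")
  if (h <= 0) stop("`h` must be positive")
  run_len <- as.integer(run_len)
  if (run_len < 1L) stop("`run_len` must be >= 1")
  n <- length(energy)
  if (cue_sample < 1L || cue_sample > n)
    stop("`cue_sample` outside the energy series")
  if (smooth_s > 0) {
    k <- max(1L, as.integer(round(smooth_s * rate)))
    if (k > 1L) {
      energy <- stats::filter(energy, rep(1 / k, k), sides = 2)
      energy <- as.numeric(energy)
      # edges: shrink to available samples
      half <- k %/% 2L
      for (i in which(is.na(energy))) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        energy[i] <- mean(energy[lo:hi], na.rm = TRUE)
      }
    }
  }
  b0 <- cue_sample + as.integer(round(baseline[1] * rate))
  b1 <- cue_sample + as.integer(round(baseline[2] * rate))
  if (b0 < 1L || b1 > n || b0 >= b1)
    stop("baseline window [", b0, ", ", b1, ") outside the energy series")
  base <- energy[b0:(b1 - 1L)]
  mu <- mean(base); sigma <- stats::sd(base)
  thr <- mu + h * sigma

  above <- energy[cue_sample:n] > thr
  onset <- NA_integer_
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths > run_len)
  if (length(ok))
    onset <- cue_sample + starts[ok[1L]] - 1L

  structure(list(onset_sample = onset, threshold = thr,
                 baseline_mean = mu, baseline_sd = sigma, h = h),
            class = "onset_event")
}

#' @export
print.onset_event <- function(x, ...) {
  if (is.na(x$onset_sample)) {
    cat("<onset_event> no onset detected (T =", signif(x$threshold, 4), ")\n")
  } else {
    cat("<onset_event> onset at sample", x$onset_sample,
        " (T =", signif(x$threshold, 4), ", h =", x$h, ")\n")
  }
  invisible(x)
}
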