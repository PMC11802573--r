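#' Mean frequency of a power spectrum
#'
#' The power-weighted mean of the bin frequencies,
#' `MNF = sum(f_i * P_i) / sum(P_i)`. MNF shifts downward as a muscle
#' fatigues, because fatigued motor units fire with slower conduction
#' velocities that compress the EMG spectrum toward low frequencies.
#'
#' @param s a `"spectrum_estimate"` from [power_spectrum()].
#' @return Mean frequency in Hz.
#' @export
mean_frequency <- function(s) {
  stopifnot(inherits(s, "spectrum_estimate"))
  tot <- sum(s$power)
  if (tot <= 0) stop("zero total power: mean frequency undefined")
  sum(s$freqs * s$power) / tot
}

#' Median frequency of a power spectrum
#'
#' The frequency splitting spectral power into equal halves. On a discrete
#' grid the exact two-sided equality is generally unattainable; the package
#' returns the frequency of the first bin where the cumulative power reaches
#' at least half of the total.
#'
#' @param s a `"spectrum_estimate"` from [power_spectrum()].
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(s) {
  stopifnot(inherits(s, "spectrum_estimate"))
  tot <- sum(s$power)
  if (tot <= 0) stop("zero total power: median frequency undefined")
  s$freqs[which(cumsum(s$power) >= tot / 2)[1L]]
}

#' Sliding-window fatigue trend
#'
#' Computes MNF and MDF in sliding windows along a long EMG series and fits
#' an ordinary least-squares line of each index against window midpoint time.
#' Progressively negative slopes are the standard spectral signature of
#' muscle fatigue.
#'
#' @param x numeric EMG series.
#' @param rate sampling rate in Hz.
#' @param window_s sliding-window length in seconds (default 5).
#' @param step_s step between windows in seconds (default half the window).
#' @param segment_s Welch segment length inside each window (default 1 s).
#' @return An object of class `"fatigue_trend"`: list with `table`
#'   (data.frame: `time_s`, `mnf_hz`, `mdf_hz`), `mnf_slope`, `mdf_slope`
#'   (Hz per second) and their standard errors `mnf_slope_se`, `mdf_slope_se`.
#' @export
fatigue_trend <- function(x, rate, window_s = 5, step_s = window_s / 2,
                          segment_s = 1) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  L <- as.integer(round(window_s * rate))
  step <- as.integer(round(step_s * rate))
  if (step < 1L) stop("`step_s` too small")
  starts <- seq(1L, length(x) - L + 1L, by = step)
  if (length(starts) < 2L)
    stop("need at least 2 windows (signal ", length(x) / rate,
         " s, window ", window_s, " s, step ", step_s, " s)")
  mnf <- mdf <- mid <- numeric(length(starts))
  for (k in seq_along(starts)) {
    s <- power_spectrum(x[starts[k]:(starts[k] + L - 1L)], rate,
                        segment_s = segment_s)
    mnf[k] <- mean_frequency(s)
    mdf[k] <- median_frequency(s)
    mid[k] <- (starts[k] - 1L + L / 2) / rate
  }
  fit1 <- stats::lm(mnf ~ mid)
  fit2 <- stats::lm(mdf ~ mid)
  structure(list(
    table = data.frame(time_s = mid, mnf_hz = mnf, mdf_hz = mdf),
    mnf_slope = unname(stats::coef(fit1)[2]),
    mdf_slope = unname(stats::coef(fit2)[2]),
    mnf_slope_se = summary(fit1)$coefficients[2, 2],
    mdf_slope_se = summary(fit2)$coefficients[2, 2]),
    class = "fatigue_trend")
}

#' @export
print.fatigue_trend <- function(x, ...) {
  cat("<fatigue_trend> ", nrow(x$table), " windows\n",
      "  MNF slope: ", signif(x$mnf_slope, 4), " Hz/s (se ",
      signif(x$mnf_slope_se, 3), ")\n",
      "  MDF slope: ", signif(x$mdf_slope, 4), " Hz/s (se ",
      signif(x$mdf_slope_se, 3), ")\n", sep = "")
  invisible(x)
}
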