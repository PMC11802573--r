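#' Default EEG montage and thigh-EMG channel labels
#'
#' 22 scalp channels over the sensorimotor midline (10-20 system) and 6
#' bilateral thigh-muscle channels (rectus femoris, vastus lateralis
#' obliquus, vastus medialis obliquus).
#' @export
eeg_channel_labels <- c("FZ", "F1", "F2", "F3", "F4",
                        "FCZ", "FC1", "FC2", "FC3", "FC4",
                        "CZ", "C1", "C2", "C3", "C4",
                        "CP1", "CP2", "CP3", "CP4",
                        "PZ", "P3", "P4")

#' @rdname eeg_channel_labels
#' @export
emg_channel_labels <- c("RF_L", "RF_R", "VLO_L", "VLO_R", "VMO_L", "VMO_R")

.default_coupled_edges <- function() {
  list(
    sit_to_stand = list(
      c("CZ", "C1"), c("C2", "C3"), c("CP1", "CP2"),
      c("CZ", "RF_R"), c("C1", "VLO_R"),
      c("RF_R", "VLO_R"), c("RF_L", "VMO_L")),
    stand_to_sit = list(
      c("FCZ", "FC1"), c("FC2", "FC3"), c("CP3", "CP4"),
      c("FCZ", "RF_L"), c("FC1", "VLO_L"),
      c("RF_L", "VLO_L"), c("RF_R", "VMO_R")),
    rest = list())
}

#' Fusion-favorable coupled-edge topology
#'
#' An edge layout in which each single modality carries only partial class
#' information: the two movement classes share the same EEG-EEG coupled
#' edges (so EEG alone separates movement from rest but not sit-to-stand
#' from stand-to-sit), while only sit-to-stand carries EMG-EMG coupled
#' edges (so EMG alone cannot separate stand-to-sit from rest). Only the
#' fused EEG-EMG network can separate all three classes, making this the
#' canonical configuration for demonstrating the value of multimodal
#' fusion.
#'
#' @return A named list of per-class channel-pair lists, suitable for the
#'   `coupled_edges` argument of [synth_config()].
#' @export
fusion_favorable_edges <- function() {
  eeg_shared <- list(c("CZ", "C1"), c("C2", "C3"), c("CP1", "CP2"),
                     c("FCZ", "FC1"))
  list(
    sit_to_stand = c(eeg_shared,
                     list(c("RF_R", "VLO_R"), c("RF_L", "VMO_L"),
                          c("VLO_L", "VMO_R"))),
    stand_to_sit = eeg_shared,
    rest = list())
}

#' Synthetic-data generator configuration
#'
#' Defines the simulated study conditions: 22 EEG channels at 1000 Hz, 6 EMG
#' channels at 1500 Hz, 1.5-s pre-movement windows, 40 trials per class, and
#' class-dependent coupling planted on a per-class list of channel pairs.
#' The class signal lives purely in the network topology (which edges are
#' coupled), not in amplitude, matching the premise that spatial network
#' patterns discriminate the intentions; the `"rest"` class has no planted
#' coupling.
#'
#' @param n_eeg,n_emg channel counts (defaults 22 and 6).
#' @param eeg_rate,emg_rate native sampling rates in Hz (1000 and 1500).
#' @param n_trials trials per class (default 40).
#' @param window_s epoch length in seconds (default 1.5).
#' @param coupling_strength mixing coefficient in `[0, 1]` of the shared
#'   latent source added to each coupled channel pair (default 0.8).
#' @param coupled_edges named list (`sit_to_stand`, `stand_to_sit`, `rest`)
#'   of channel-label pairs carrying that class's coupling.
#' @param noise_sd background-noise standard deviation (microvolts).
#' @param burst_amp_ratio EMG burst amplitude as a multiple of the baseline
#'   standard deviation (default 10).
#' @param seed integer seed recorded in every generated artifact.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_eeg = 22L, n_emg = 6L,
                         eeg_rate = 1000, emg_rate = 1500,
                         n_trials = 40L, window_s = 1.5,
                         coupling_strength = 0.8,
                         coupled_edges = .default_coupled_edges(),
                         noise_sd = 1, burst_amp_ratio = 10,
                         seed = 7L) {
  if (n_eeg < 1L || n_emg < 1L || n_trials < 1L)
    stop("channel and trial counts must be >= 1")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("`coupling_strength` must be in [0, 1]")
  labels <- c(eeg_channel_labels[seq_len(min(n_eeg, 22L))],
              if (n_eeg > 22L) paste0("EEG", 23:n_eeg),
              emg_channel_labels[seq_len(min(n_emg, 6L))],
              if (n_emg > 6L) paste0("EMG", 7:n_emg))
  for (cls in names(coupled_edges)) {
    for (e in coupled_edges[[cls]]) {
      if (length(e) != 2L || !all(e %in% labels))
        stop("coupled edge references unknown channel: ",
             paste(e, collapse = "-"), " (class ", cls, ")")
    }
  }
  structure(list(n_eeg = as.integer(n_eeg), n_emg = as.integer(n_emg),
                 eeg_rate = eeg_rate, emg_rate = emg_rate,
                 n_trials = as.integer(n_trials), window_s = window_s,
                 coupling_strength = coupling_strength,
                 coupled_edges = coupled_edges,
                 noise_sd = noise_sd, burst_amp_ratio = burst_amp_ratio,
                 seed = as.integer(seed), channel_labels = labels),
            class = "synth_config")
}

## Band-limited noise of length n via FFT shaping: unit-variance Gaussian
## noise whose spectrum is masked to [band[1], band[2]] Hz, with 1/sqrt(f)
## (pink) weighting when pink = TRUE.
.band_noise <- function(n, rate, band, pink = FALSE) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)  # two-sided frequency axis
  mask <- as.numeric(f >= band[1] & f <= band[2])
  if (pink) mask <- mask / sqrt(pmax(f, band[1]))
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

#' Generate a labeled synthetic epoch set with planted coupling
#'
#' Each channel is band-limited background noise (EEG: pink 0.5-45 Hz at
#' 1000 Hz; EMG: flat 15-300 Hz at 1500 Hz). For every coupled edge of a
#' trial's class, one shared latent beta-band (13-30 Hz) source is drawn on
#' a common 3 kHz grid and added - subsampled to each endpoint's native
#' rate - to both endpoint channels with weight
#' `coupling_strength * noise_sd`. The beta-band latent elevates coherence,
#' correlation and mutual information on the planted edges simultaneously.
#' EMG channels are then resampled to the EEG rate and the two modality
#' blocks fused into one epoch set. Fully reproducible from `cfg$seed`
#' (the caller's RNG state is untouched); the configuration is embedded as
#' attribute `"synth_config"`.
#'
#' @param cfg a [synth_config()].
#' @return An [epoch_set()] with `3 * cfg$n_trials` balanced trials at the
#'   EEG rate.
#' @export
generate_epochs <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  rng <- .seeded_rng(cfg$seed)
  .with_rng(rng, .generate_epochs_impl(cfg))
}

.generate_epochs_impl <- function(cfg) {
  n_hi <- as.integer(round(cfg$window_s * 3000))
  n_eeg_t <- as.integer(round(cfg$window_s * cfg$eeg_rate))
  n_emg_t <- as.integer(round(cfg$window_s * cfg$emg_rate))
  eeg_stride <- as.integer(round(3000 / cfg$eeg_rate))
  emg_stride <- as.integer(round(3000 / cfg$emg_rate))
  labels_all <- cfg$channel_labels
  eeg_idx <- seq_len(cfg$n_eeg)
  emg_idx <- cfg$n_eeg + seq_len(cfg$n_emg)
  classes <- intention_classes
  n_total <- length(classes) * cfg$n_trials
  data <- array(0, c(n_total, cfg$n_eeg + cfg$n_emg, n_eeg_t))
  labels <- character(n_total)

  t_i <- 0L
  for (cls in classes) {
    edges <- cfg$coupled_edges[[cls]]
    if (is.null(edges)) edges <- list()
    for (k in seq_len(cfg$n_trials)) {
      t_i <- t_i + 1L
      labels[t_i] <- cls
      eeg <- matrix(0, cfg$n_eeg, n_eeg_t)
      for (i in seq_len(cfg$n_eeg))
        eeg[i, ] <- cfg$noise_sd *
          .band_noise(n_eeg_t, cfg$eeg_rate, c(0.5, 45), pink = TRUE)
      emg <- matrix(0, cfg$n_emg, n_emg_t)
      for (i in seq_len(cfg$n_emg))
        emg[i, ] <- cfg$noise_sd *
          .band_noise(n_emg_t, cfg$emg_rate, c(15, 300))
      for (e in edges) {
        lat <- .band_noise(n_hi, 3000, c(13, 30))
        amp <- cfg$coupling_strength * cfg$noise_sd
        for (lab in e) {
          ch <- match(lab, labels_all)
          if (ch <= cfg$n_eeg) {
            eeg[ch, ] <- eeg[ch, ] +
              amp * lat[seq(1L, by = eeg_stride, length.out = n_eeg_t)]
          } else {
            emg[ch - cfg$n_eeg, ] <- emg[ch - cfg$n_eeg, ] +
              amp * lat[seq(1L, by = emg_stride, length.out = n_emg_t)]
          }
        }
      }
      emg_rec <- recording(emg, cfg$emg_rate,
                           channel_labels = labels_all[emg_idx],
                           modality = "EMG")
      emg_rs <- resample_recording(emg_rec, cfg$eeg_rate)
      data[t_i, eeg_idx, ] <- eeg
      data[t_i, emg_idx, ] <- emg_rs$samples
    }
  }
  es <- epoch_set(data, labels, window = c(-cfg$window_s, 0),
                  rate = cfg$eeg_rate, channel_labels = labels_all,
                  modality = c(rep("EEG", cfg$n_eeg), rep("EMG", cfg$n_emg)))
  attr(es, "synth_config") <- cfg
  es
}

#' Generate a single-channel synthetic EMG trial with a known onset
#'
#' Produces an 8-s, 1500 Hz EMG channel: band-limited (15-300 Hz) baseline
#' noise, a visual cue at 4 s, and - after a uniform 0.2-0.5 s reaction
#' delay - a 1-s burst of amplitude `burst_amp_ratio * noise_sd` with a 5-ms
#' raised-cosine rise, added from the true onset onward. The cue marker
#' always precedes the onset.
#'
#' @param cfg a [synth_config()] (`emg_rate`, `noise_sd`, `burst_amp_ratio`,
#'   `seed` are used).
#' @param duration_s total length in seconds (default 8).
#' @param cue_s cue time in seconds (default 4).
#' @param burst_s burst duration in seconds (default 1).
#' @return List with `rec` (a one-channel [recording()] with the cue marker)
#'   and `true_onset` (sample index of the burst start).
#' @export
generate_emg_trial <- function(cfg = synth_config(), duration_s = 8,
                               cue_s = 4, burst_s = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$burst_amp_ratio <= 0) stop("`burst_amp_ratio` must be positive")
  rng <- .seeded_rng(cfg$seed)
  .with_rng(rng, {
    rate <- cfg$emg_rate
    n <- as.integer(round(duration_s * rate))
    cue <- as.integer(round(cue_s * rate))
    x <- cfg$noise_sd * .band_noise(n, rate, c(15, 300))
    delay <- stats::runif(1, 0.2, 0.5)
    onset <- cue + as.integer(round(delay * rate))
    nb <- as.integer(round(burst_s * rate))
    nb <- min(nb, n - onset + 1L)
    burst <- cfg$burst_amp_ratio * cfg$noise_sd *
      .band_noise(nb, rate, c(15, 300))
    rise <- as.integer(round(0.005 * rate))
    env <- rep(1, nb)
    env[seq_len(rise)] <- 0.5 - 0.5 * cos(pi * seq_len(rise) / rise)
    x[onset:(onset + nb - 1L)] <- x[onset:(onset + nb - 1L)] + burst * env
    rec <- recording(matrix(x, 1L), rate, channel_labels = "EMG1",
                     modality = "EMG", cue_times = cue)
    list(rec = rec, true_onset = onset)
  })
}

#' Noise series with linearly drifting spectral center
#'
#' Narrowband noise whose center frequency drifts linearly from `f_start`
#' down to `f_end` over the series, emulating the spectral compression of a
#' fatiguing muscle: complex Gaussian baseband noise (low-pass `bw/2`) is
#' modulated onto the instantaneous-frequency track. With
#' `f_start == f_end` the series is stationary.
#'
#' @param f_start,f_end center frequencies in Hz, `f_start >= f_end > 0`.
#' @param duration_s series length in seconds.
#' @param rate sampling rate in Hz (default 1500).
#' @param bw bandwidth around the drifting center in Hz (default 20).
#' @param seed optional integer seed; when `NULL` the caller's RNG is used.
#' @return Numeric series of length `duration_s * rate`, unit variance.
#' @export
spectral_compression_series <- function(f_start, f_end, duration_s,
                                        rate = 1500, bw = 20, seed = NULL) {
  if (f_end <= 0 || f_start <= 0) stop("frequencies must be positive")
  if (f_end > f_start) stop("`f_end` must not exceed `f_start`")
  gen <- function() {
    n <- as.integer(round(duration_s * rate))
    # complex baseband noise, low-pass bw/2
    zre <- .band_noise(n, rate, c(0, bw / 2))
    zim <- .band_noise(n, rate, c(0, bw / 2))
    fc <- seq(f_start, f_end, length.out = n)
    phase <- 2 * pi * cumsum(fc) / rate
    x <- zre * cos(phase) - zim * sin(phase)
    x / stats::sd(x)
  }
  if (is.null(seed)) gen() else .with_rng(.seeded_rng(seed), gen())
}
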