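# Shared fixtures: all synthetic, generated in code.

# Small montage for fast property tests: 8 EEG + 4 EMG channels.
small_synth_config <- function(n_trials = 8L, coupling_strength = 0.8,
                               seed = 7L, ...) {
  synth_config(
    n_eeg = 8L, n_emg = 4L, n_trials = n_trials,
    coupling_strength = coupling_strength,
    coupled_edges = list(
      sit_to_stand = list(c("FZ", "F1"), c("F2", "F3"), c("FC1", "RF_L"),
                          c("RF_L", "VLO_L")),
      stand_to_sit = list(c("FCZ", "FC1"), c("F1", "F4"), c("FC2", "RF_R"),
                          c("RF_R", "VLO_R")),
      rest = list()),
    seed = seed, ...)
}

# random symmetric positive-definite matrix
random_spd <- function(n, jitter = 0.1) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + jitter * diag(n)
}

# recording with deterministic content for indexing tests
ramp_recording <- function(n_ch = 3, n_t = 5000, rate = 1000,
                           modality = "EEG") {
  recording(outer(seq_len(n_ch), seq_len(n_t), function(i, t) i * 1000 + t),
            rate = rate, modality = modality)
}

# brute-force plug-in MI oracle: explicit double loop over the joint table
mi_bruteforce <- function(x, y, bins) {
  bin1 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    i <- floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L
    pmin(i, bins)
  }
  ix <- bin1(x); iy <- bin1(y); n <- length(x)
  mi <- 0
  for (a in 1:bins) for (b in 1:bins) {
    pab <- sum(ix == a & iy == b) / n
    if (pab > 0) {
      pa <- sum(ix == a) / n; pb <- sum(iy == b) / n
      mi <- mi + pab * log2(pab / (pa * pb))
    }
  }
  mi
}

# exhaustive binomial-CDF chance-level oracle
chance_bruteforce <- function(alpha, n, c) {
  cdf <- cumsum(dbinom(0:n, n, 1 / c))
  m <- which(cdf >= 1 - alpha)[1] - 1L
  100 * m / n
}

# dense unit-sphere grid maximization of the Rayleigh ratio (3-D)
rayleigh_grid_max <- function(A, B, step_deg = 1) {
  th <- seq(0, 180, by = step_deg) * pi / 180
  ph <- seq(0, 359, by = step_deg) * pi / 180
  g <- expand.grid(th = th, ph = ph)
  D <- rbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  num <- colSums(D * (A %*% D))
  den <- colSums(D * (B %*% D))
  max(num / den)
}
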