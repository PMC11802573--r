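#' Connectivity estimator configuration
#'
#' @param method `"coh"` (band-averaged magnitude-squared coherence),
#'   `"cc"` (Pearson correlation) or `"mi"` (histogram plug-in mutual
#'   information).
#' @param coh_band frequency band in Hz over which coherence is averaged
#'   (inclusive of both edges); default `c(13, 30)`, the beta band where
#'   corticomuscular coupling concentrates.
#' @param welch_segment_s Welch segment length in seconds (default 1).
#' @param welch_overlap_frac fractional segment overlap in `[0, 1)`.
#' @param mi_bins equal-width histogram bins per series for MI (default 16).
#' @return An object of class `"connectivity_config"`.
#' @export
connectivity_config <- function(method = c("mi", "cc", "coh"),
                                coh_band = c(13, 30),
                                welch_segment_s = 1,
                                welch_overlap_frac = 0.5,
                                mi_bins = 16L) {
  method <- match.arg(tolower(method), c("mi", "cc", "coh"))
  if (length(coh_band) != 2L || coh_band[1] <= 0 || coh_band[1] >= coh_band[2])
    stop("`coh_band` must be (low, high) with 0 < low < high")
  if (welch_overlap_frac < 0 || welch_overlap_frac >= 1)
    stop("`welch_overlap_frac` must be in [0, 1)")
  mi_bins <- as.integer(mi_bins)
  if (mi_bins < 2L) stop("`mi_bins` must be >= 2")
  structure(list(method = method, coh_band = as.numeric(coh_band),
                 welch_segment_s = welch_segment_s,
                 welch_overlap_frac = welch_overlap_frac,
                 mi_bins = mi_bins),
            class = "connectivity_config")
}

#' Band-averaged magnitude-squared coherence edge weight
#'
#' Welch cross- and auto-spectra (Hann window) give the magnitude-squared
#' coherence `C_xy(f) = |P_xy|^2 / (P_xx * P_yy)` per frequency bin; the edge
#' weight is its mean over the bins inside `cfg$coh_band` (band edges
#' inclusive).
#'
#' @param x,y numeric series of equal length at a shared rate.
#' @param rate sampling rate in Hz.
#' @param cfg a [connectivity_config()].
#' @return Scalar weight in `[0, 1]`.
#' @export
coherence_edge <- function(x, y, rate, cfg = connectivity_config("coh")) {
  if (length(x) != length(y)) stop("series lengths differ")
  L <- as.integer(round(cfg$welch_segment_s * rate))
  starts <- .welch_starts(length(x), L, cfg$welch_overlap_frac)
  if (length(starts) < 2L)
    stop("coherence needs >= 2 Welch segments (signal ", length(x),
         " samples, segment ", L, ")")
  win <- .hann(L)
  X <- .welch_fft(x, L, starts, win)
  Y <- .welch_fft(y, L, starts, win)
  .coh_from_fft(X, Y, rate, win, cfg$coh_band)
}

.coh_from_fft <- function(X, Y, rate, win, band) {
  pxy <- .welch_csd(X, Y, rate, win)
  pxx <- Re(.welch_csd(X, X, rate, win))
  pyy <- Re(.welch_csd(Y, Y, rate, win))
  freqs <- .welch_freqs(nrow(X), rate)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(sel)) stop("coherence band empty after discretization")
  coh <- Mod(pxy[sel])^2 / (pxx[sel] * pyy[sel])
  mean(pmin(coh, 1))
}

#' Pearson correlation edge weight
#'
#' Sample Pearson correlation over the full broadband window. The signed
#' value is kept; min-max standardization of the assembled adjacency matrix
#' later maps the signed range into `[0, 1]`.
#'
#' @param x,y numeric series of equal length (>= 2), both non-constant.
#' @return Scalar weight in `[-1, 1]`.
#' @export
pearson_edge <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant series")
  stats::cor(x, y)
}

## equal-width bin assignment over the series' own [min, max];
## a constant series maps to a single occupied bin
.bin_indices <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  ix <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  ix[ix > bins] <- bins
  as.integer(ix)
}

.mi_from_bins <- function(ix, iy, bins) {
  n <- length(ix)
  joint <- tabulate(ix + bins * (iy - 1L), nbins = bins * bins)
  nz <- joint > 0L
  pxy <- joint[nz] / n
  px <- tabulate(ix, nbins = bins) / n
  py <- tabulate(iy, nbins = bins) / n
  idx <- which(nz) - 1L
  pa <- px[idx %% bins + 1L]
  pb <- py[idx %/% bins + 1L]
  sum(pxy * log2(pxy / (pa * pb)))
}

#' Mutual-information edge weight
#'
#' Plug-in Shannon mutual information (bits) from a two-dimensional
#' equal-width histogram: each series is binned over its own `[min, max]`
#' range into `cfg$mi_bins` bins and
#' `MI = sum p(a,b) * log2( p(a,b) / (p(a) p(b)) )` over occupied cells.
#' MI captures nonlinear as well as linear dependence, which is why it is
#' the strongest connectivity weighting for corticomuscular networks.
#' A constant series yields MI = 0 (single occupied bin), with a warning.
#'
#' @param x,y numeric series of equal length.
#' @param cfg a [connectivity_config()] (only `mi_bins` is used).
#' @return Scalar weight >= 0, in bits.
#' @export
mutual_info_edge <- function(x, y, cfg = connectivity_config("mi")) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant series: mutual information defined as 0")
    return(0)
  }
  bins <- cfg$mi_bins
  .mi_from_bins(.bin_indices(x, bins), .bin_indices(y, bins), bins)
}

#' Connectivity adjacency matrix
#'
#' @param weights n x n symmetric numeric matrix, zero diagonal.
#' @param channel_labels channel names.
#' @param method estimator tag.
#' @param standardized whether min-max standardization has been applied.
#' @return An object of class `"connectivity_matrix"`.
#' @export
connectivity_matrix <- function(weights, channel_labels, method,
                                standardized = FALSE) {
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-9)))
    stop("adjacency matrix must be symmetric")
  if (any(abs(diag(weights)) > 1e-12))
    stop("adjacency diagonal must be zero")
  dimnames(weights) <- list(channel_labels, channel_labels)
  structure(list(weights = weights,
                 channel_labels = as.character(channel_labels),
                 method = method, standardized = standardized),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$weights), " x ", ncol(x$weights),
      " (", x$method, if (x$standardized) ", standardized", ")\n", sep = "")
  invisible(x)
}

#' Build a connectivity adjacency matrix from one epoch
#'
#' Computes the configured edge estimator on every unordered channel pair and
#' mirrors it into a symmetric matrix with a zero diagonal (self-connectivity
#' is constant and carries no class information). The result is raw
#' (unstandardized); apply [minmax_standardize()] before filter learning.
#'
#' @param epoch numeric channels x time matrix (one trial window).
#' @param rate sampling rate in Hz.
#' @param cfg a [connectivity_config()].
#' @param channel_labels channel names (defaults to `ch1, ...`).
#' @param subset optional character vector of labels to restrict to.
#' @return A [connectivity_matrix()].
#' @export
build_adjacency <- function(epoch, rate, cfg = connectivity_config("mi"),
                            channel_labels = NULL, subset = NULL) {
  if (!is.matrix(epoch)) stop("`epoch` must be a channels x time matrix")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(epoch)))
  if (!is.null(subset)) {
    missing <- setdiff(subset, channel_labels)
    if (length(missing))
      stop("unknown channels in subset: ", paste(missing, collapse = ", "))
    epoch <- epoch[match(subset, channel_labels), , drop = FALSE]
    channel_labels <- subset
  }
  n <- nrow(epoch)
  w <- matrix(0, n, n)

  if (cfg$method == "cc") {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      w[i, j] <- w[j, i] <- tryCatch(
        pearson_edge(epoch[i, ], epoch[j, ]),
        error = function(e) stop("edge (", channel_labels[i], ", ",
                                 channel_labels[j], "): ",
                                 conditionMessage(e)))
    }
  } else if (cfg$method == "mi") {
    bins <- cfg$mi_bins
    bin_idx <- lapply(seq_len(n), function(i) .bin_indices(epoch[i, ], bins))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      w[i, j] <- w[j, i] <- .mi_from_bins(bin_idx[[i]], bin_idx[[j]], bins)
    }
  } else {
    L <- as.integer(round(cfg$welch_segment_s * rate))
    starts <- .welch_starts(ncol(epoch), L, cfg$welch_overlap_frac)
    if (length(starts) < 2L)
      stop("coherence needs >= 2 Welch segments per epoch")
    win <- .hann(L)
    ffts <- lapply(seq_len(n),
                   function(i) .welch_fft(epoch[i, ], L, starts, win))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      w[i, j] <- w[j, i] <- .coh_from_fft(ffts[[i]], ffts[[j]], rate, win,
                                          cfg$coh_band)
    }
  }
  connectivity_matrix(w, channel_labels, cfg$method, standardized = FALSE)
}

#' Min-max standardize an adjacency matrix
#'
#' Maps the off-diagonal entries of a single matrix affinely onto `[0, 1]`
#' via `(v - min) / (max - min)` computed over that matrix's off-diagonal
#' set. The diagonal stays 0. Standardization is per matrix (per trial
#' window), not per dataset. Idempotent.
#'
#' @param m a [connectivity_matrix()].
#' @return The standardized [connectivity_matrix()].
#' @export
minmax_standardize <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  w <- m$weights
  off <- w[row(w) != col(w)]
  lo <- min(off); hi <- max(off)
  if (hi == lo)
    stop("degenerate adjacency: all off-diagonal weights equal (",
         signif(lo, 6), "); window is uninformative")
  w <- (w - lo) / (hi - lo)
  diag(w) <- 0
  connectivity_matrix(w, m$channel_labels, m$method, standardized = TRUE)
}

#' Per-trial standardized connectivity matrices from an epoch set
#'
#' Convenience wrapper running [build_adjacency()] + [minmax_standardize()]
#' on every trial of an epoch set, optionally restricted to one modality.
#'
#' @param epochs an [epoch_set()].
#' @param cfg a [connectivity_config()].
#' @param modality `"fusion"` (all channels), `"eeg"` or `"emg"`.
#' @return List with `matrices` (list of standardized
#'   [connectivity_matrix()]) and `labels` (per-trial factor).
#' @export
connectivity_matrices <- function(epochs, cfg = connectivity_config("mi"),
                                  modality = "fusion") {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs <- select_modality(epochs, modality)
  n <- dim(epochs$data)[1]
  mats <- vector("list", n)
  for (t in seq_len(n)) {
    mats[[t]] <- minmax_standardize(build_adjacency(
      epochs$data[t, , ], epochs$rate, cfg,
      channel_labels = epochs$channel_labels))
  }
  list(matrices = mats, labels = epochs$labels)
}

#' Write / read a connectivity matrix as delimited text
#'
#' Square matrix with a label header row and label row names.
#'
#' @param m a [connectivity_matrix()].
#' @param path file path.
#' @param method,standardized metadata to attach on read.
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   a [connectivity_matrix()].
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  utils::write.table(m$weights, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, method = "mi", standardized = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  connectivity_matrix(as.matrix(df), colnames(df), method, standardized)
}
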