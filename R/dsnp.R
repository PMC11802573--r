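#' Class scatter matrix of connectivity networks
#'
#' For a class with trials `M_1 ... M_N` (standardized adjacency matrices),
#' the scatter is `C = (1/N) * sum_k M_k %*% t(M_k)`. Since each `M_k` is
#' symmetric this equals the mean of `M_k^2`. No trace normalization is
#' applied (unlike classical CSP on covariance matrices).
#'
#' @param matrices list of [connectivity_matrix()] (or plain symmetric
#'   matrices), all of the same dimension.
#' @param label optional class label to attach.
#' @return An object of class `"class_scatter"`: list with `C`, `n_trials`,
#'   `label`.
#' @export
class_scatter <- function(matrices, label = NULL) {
  if (!length(matrices)) stop("need at least one matrix")
  ms <- lapply(matrices, function(m)
    if (inherits(m, "connectivity_matrix")) m$weights else m)
  d <- dim(ms[[1]])
  if (!all(vapply(ms, function(m) identical(dim(m), d), logical(1))))
    stop("matrices differ in dimension")
  C <- matrix(0, d[1], d[2])
  for (m in ms) C <- C + m %*% t(m)
  C <- C / length(ms)
  C <- (C + t(C)) / 2  # exact symmetry against rounding
  structure(list(C = C, n_trials = length(ms), label = label),
            class = "class_scatter")
}

#' Learn discriminative spatial network filters for a class pair
#'
#' Solves the generalized eigenproblem `C_i w = lambda C_j w` for the two
#' class scatter matrices. A filter `w` maximizes (or, at the other end,
#' minimizes) the Rayleigh ratio `(w' C_i w) / (w' C_j w)`, i.e. it projects
#' the networks onto the direction along which the two classes' scatter
#' differs most. The `n_keep_each_side` eigenvectors of the largest and of
#' the smallest eigenvalues are kept (default 2 + 2), each rescaled so that
#' `w' C_j w = 1`, with the largest-magnitude entry made positive.
#'
#' The problem is solved in whitened coordinates: with
#' `C_j = V D V'`, set `P = V D^{-1/2} V'` and eigendecompose the symmetric
#' `P C_i P`; back-transformed eigenvectors satisfy the generalized equation
#' and the equivalent non-symmetric form `solve(C_j) %*% C_i`. `C_j` is
#' ridge-regularized by `gamma * tr(C_j)/n * I` before whitening, since a
#' scatter from few trials can be rank-deficient.
#'
#' @param Ci,Cj `"class_scatter"` objects (or plain symmetric matrices) for
#'   the two classes.
#' @param n_keep_each_side filters kept per extreme (default 2).
#' @param gamma relative ridge regularization of `C_j`, applied only when
#'   `C_j` is numerically rank-deficient (default 1e-6).
#' @return An object of class `"spatial_filter_bank"`: list with `filters`
#'   (n x k, columns ordered largest eigenvalues first, then smallest),
#'   `eigenvalues` (length k, same order), `all_eigenvalues`, `class_pair`.
#' @export
learn_pair_filters <- function(Ci, Cj, n_keep_each_side = 2L, gamma = 1e-6) {
  lab_i <- if (inherits(Ci, "class_scatter")) Ci$label else NULL
  lab_j <- if (inherits(Cj, "class_scatter")) Cj$label else NULL
  A <- if (inherits(Ci, "class_scatter")) Ci$C else Ci
  B <- if (inherits(Cj, "class_scatter")) Cj$C else Cj
  if (!identical(dim(A), dim(B))) stop("scatter matrices differ in dimension")
  n <- nrow(A)
  k <- as.integer(n_keep_each_side)
  if (2L * k > n)
    stop("cannot keep 2*", k, " filters from ", n, "-dimensional scatter")

  eb <- eigen(B, symmetric = TRUE)
  if (min(eb$values) <= 1e-10 * max(abs(eb$values))) {
    # rank-deficient scatter (few trials): ridge before whitening
    Breg <- B + gamma * sum(diag(B)) / n * diag(n)
    eb <- eigen(Breg, symmetric = TRUE)
  }
  if (min(eb$values) <= 0) {
    stop("class-j scatter is singular even after regularization ",
         "(condition number ", format(max(eb$values) / max(min(eb$values), .Machine$double.xmin),
                                      digits = 3), ")")
  }
  P <- eb$vectors %*% (t(eb$vectors) / sqrt(eb$values))
  S <- P %*% A %*% P
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)      # eigenvalues descending
  W <- P %*% es$vectors                 # generalized eigenvectors

  sel <- c(seq_len(k), (n - k + 1L):n)  # 2 largest first, then 2 smallest
  W <- W[, sel, drop = FALSE]
  lam <- es$values[sel]

  # rescale so w' C_j w = 1 (against the unregularized B), fix sign
  for (c_ in seq_len(ncol(W))) {
    q <- drop(crossprod(W[, c_], B %*% W[, c_]))
    if (q > 0) W[, c_] <- W[, c_] / sqrt(q)
    imax <- which.max(abs(W[, c_]))
    if (W[imax, c_] < 0) W[, c_] <- -W[, c_]
  }

  structure(list(filters = W, eigenvalues = lam,
                 all_eigenvalues = es$values,
                 class_pair = c(lab_i, lab_j)),
            class = "spatial_filter_bank")
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat("<spatial_filter_bank> ", nrow(x$filters), "-channel, ",
      ncol(x$filters), " filters", sep = "")
  if (length(x$class_pair) == 2L)
    cat(" (", x$class_pair[1], " vs ", x$class_pair[2], ")", sep = "")
  cat("\n  generalized eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project a network through a filter bank into features
#'
#' For each retained filter `w_k` the feature is the log of the projected
#' network energy, `f_k = log( w_k' M M' w_k + eps )` with `eps = 1e-12`,
#' mirroring the log-variance feature convention of spatial-pattern methods.
#'
#' @param M a standardized [connectivity_matrix()] (or plain symmetric
#'   matrix).
#' @param bank a `"spatial_filter_bank"`.
#' @param eps numerical floor inside the log.
#' @return Numeric feature vector, one value per filter.
#' @export
extract_features <- function(M, bank, eps = 1e-12) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  m <- if (inherits(M, "connectivity_matrix")) M$weights else M
  if (nrow(m) != nrow(bank$filters))
    stop("matrix dimension (", nrow(m), ") does not match filters (",
         nrow(bank$filters), ")")
  proj <- crossprod(bank$filters, m)       # k x n, rows w_k' M
  log(rowSums(proj^2) + eps)               # w' M M' w = ||w' M||^2
}
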