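#' Fit the pairwise spatial-network-pattern decoder
#'
#' The multiclass decoder is a one-vs-one ensemble: for each unordered class
#' pair it (1) computes the two class scatter matrices from the training
#' trials' standardized adjacency matrices, (2) learns a
#' [spatial filter bank][learn_pair_filters()] by generalized
#' eigendecomposition, (3) projects each training trial to log-energy
#' [features][extract_features()], (4) z-normalizes each feature with
#' training statistics and (5) fits a linear support-vector machine
#' (cost = 1). With `c` classes the ensemble holds `c*(c-1)/2` units
#' (3 units for the 3 intention classes).
#'
#' @param matrices list of standardized [connectivity_matrix()], one per
#'   labeled trial.
#' @param labels per-trial class labels (factor or character).
#' @param n_keep_each_side filters kept per eigenvalue extreme (default 2,
#'   i.e. 4 features per pair unit).
#' @param cost linear-SVM regularization parameter (default 1).
#' @return An object of class `"dsnp_decoder"`.
#' @export
dsnp_decoder <- function(matrices, labels, n_keep_each_side = 2L, cost = 1) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  classes <- levels(labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (length(matrices) != length(labels))
    stop("need one matrix per label")
  counts <- table(labels)
  low <- names(counts)[counts < 2L]
  if (length(low))
    stop("class with fewer than 2 training trials: ",
         paste(low, collapse = ", "))

  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  units <- lapply(pairs, function(pr) {
    ia <- which(labels == pr[1]); ib <- which(labels == pr[2])
    Ca <- class_scatter(matrices[ia], label = pr[1])
    Cb <- class_scatter(matrices[ib], label = pr[2])
    bank <- learn_pair_filters(Ca, Cb, n_keep_each_side)
    idx <- c(ia, ib)
    feats <- t(vapply(matrices[idx], extract_features, bank = bank,
                      FUN.VALUE = numeric(ncol(bank$filters))))
    mu <- colMeans(feats)
    sdv <- apply(feats, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    z <- sweep(sweep(feats, 2L, mu), 2L, sdv, "/")
    y <- factor(as.character(labels[idx]), levels = pr)
    fit <- e1071::svm(x = z, y = y, kernel = "linear", cost = cost,
                      scale = FALSE)
    # calibrate decision-value sign: positive must favor the first class
    dv <- attr(stats::predict(fit, z, decision.values = TRUE),
               "decision.values")[, 1L]
    flip <- mean(dv[y == pr[1]]) < mean(dv[y == pr[2]])
    list(classes = pr, bank = bank, mu = mu, sd = sdv, svm = fit,
         flip = flip)
  })
  structure(list(classes = classes, units = units,
                 n_keep_each_side = as.integer(n_keep_each_side),
                 cost = cost),
            class = "dsnp_decoder")
}

#' @export
print.dsnp_decoder <- function(x, ...) {
  cat("<dsnp_decoder> ", length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), "), ",
      length(x$units), " pairwise unit(s), ",
      2L * x$n_keep_each_side, " features/unit\n", sep = "")
  invisible(x)
}

#' @export
summary.dsnp_decoder <- function(object, ...) {
  print(object)
  for (u in object$units)
    cat("  ", u$classes[1], " vs ", u$classes[2],
        ": eigenvalues ", paste(signif(u$bank$eigenvalues, 4),
                                collapse = ", "), "\n", sep = "")
  invisible(object)
}

.unit_vote <- function(unit, M) {
  f <- extract_features(M, unit$bank)
  z <- (f - unit$mu) / unit$sd
  dv <- attr(stats::predict(unit$svm, matrix(z, nrow = 1L),
                            decision.values = TRUE),
             "decision.values")[1L, 1L]
  if (unit$flip) dv <- -dv
  list(vote = if (dv >= 0) unit$classes[1] else unit$classes[2],
       margin = abs(dv))
}

#' Predict the intention class of a network
#'
#' Each pairwise unit votes for one of its two classes; the class with the
#' most votes wins. A three-way (cyclic) tie is broken by the largest summed
#' absolute SVM decision margin over the votes each class received, and any
#' residual tie deterministically by class order.
#'
#' @param object a fitted [dsnp_decoder()].
#' @param newdata a standardized [connectivity_matrix()] (or plain symmetric
#'   matrix), or a list of them.
#' @param ... unused.
#' @return For a single matrix, a character label with attribute `"votes"`
#'   (data.frame of per-unit votes and margins); for a list, a character
#'   vector of labels.
#' @export
predict.dsnp_decoder <- function(object, newdata, ...) {
  if (is.list(newdata) && !inherits(newdata, "connectivity_matrix")) {
    return(vapply(newdata, function(m) predict(object, m), character(1)))
  }
  votes <- lapply(object$units, .unit_vote, M = newdata)
  vt <- data.frame(
    pair = vapply(object$units, function(u) paste(u$classes, collapse = "/"),
                  character(1)),
    vote = vapply(votes, `[[`, character(1), "vote"),
    margin = vapply(votes, `[[`, numeric(1), "margin"))
  out <- .majority_vote(vt$vote, vt$margin, object$classes)
  attr(out, "votes") <- vt
  out
}

## majority vote with margin tie-break, then class order
.majority_vote <- function(vote, margin, classes) {
  tallies <- vapply(classes, function(cl) sum(vote == cl), numeric(1))
  top <- which(tallies == max(tallies))
  if (length(top) > 1L) {
    margins <- vapply(classes[top], function(cl)
      sum(margin[vote == cl]), numeric(1))
    top <- top[which.max(margins)]  # which.max takes the first on exact ties
  }
  classes[top[1L]]
}

#' Binomial chance level for classification accuracy
#'
#' The smallest integer `m` with binomial CDF `F(m; n, 1/c) >= 1 - alpha`,
#' returned as a percentage `100 * m / n`. An observed accuracy above this
#' threshold is better than guessing at significance `alpha`. For
#' `alpha = 0.05`, `n = 160` trials and `c = 3` classes the threshold is
#' 39.375%.
#'
#' @param alpha significance level in (0, 1).
#' @param n number of classified samples.
#' @param c number of classes.
#' @return Chance-level accuracy in percent.
#' @export
chance_level <- function(alpha = 0.05, n, c = 3L) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (n < 1L) stop("`n` must be >= 1")
  if (c < 2L) stop("`c` must be >= 2")
  m <- stats::qbinom(1 - alpha, size = n, prob = 1 / c)
  100 * m / n
}

#' Confusion matrix and per-class accuracy
#'
#' @param true,predicted equal-length label vectors.
#' @param classes class set (defaults to the union of observed labels);
#'   labels outside it are an error.
#' @return List with `counts` (true rows x predicted columns) and
#'   `per_class_accuracy` (percent, diagonal / row sum).
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("`true` and `predicted` lengths differ")
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad))
    stop("label outside the class set: ", paste(bad, collapse = ", "))
  counts <- table(factor(true, levels = classes),
                  factor(predicted, levels = classes))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("true", "predicted")
  acc <- 100 * diag(counts) / pmax(rowSums(counts), 1L)
  list(counts = counts, per_class_accuracy = acc)
}

#' Stratified k-fold cross-validation of the decoder
#'
#' Assigns trials of each class to folds by a seeded shuffle (so per-fold
#' class proportions stay within one trial of the global proportions), then,
#' for each fold, refits the entire pipeline from the class scatter and
#' spatial filters onward on the training folds only - no statistic of a
#' test trial ever enters training. Reports per-fold accuracy, the pooled
#' confusion matrix, per-class accuracy and the binomial
#' [chance_level()].
#'
#' @param matrices list of standardized [connectivity_matrix()] per trial.
#' @param labels per-trial class labels.
#' @param k number of folds (default 10); every class must have at least
#'   `k` trials.
#' @param seed integer seed controlling the fold assignment.
#' @param alpha significance level for the chance threshold.
#' @param n_keep_each_side,cost passed to [dsnp_decoder()].
#' @return An object of class `"cv_result"`: list with `fold_accuracy`
#'   (percent per fold), `mean_accuracy`, `sd_accuracy`, `confusion`,
#'   `per_class_accuracy`, `chance_level`, `folds` (per-trial fold id),
#'   `seed`, `k`.
#' @export
cross_validate <- function(matrices, labels, k = 10L, seed = 1L,
                           alpha = 0.05, n_keep_each_side = 2L, cost = 1) {
  labels <- droplevels(factor(labels))
  k <- as.integer(k)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs >= k trials (k = ", k, "; smallest class has ",
         min(counts), ")")
  n <- length(labels)

  folds <- integer(n)
  rng <- .seeded_rng(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[.rng_permutation(rng, length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }

  pred <- character(n)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    fit <- dsnp_decoder(matrices[tr], labels[tr],
                        n_keep_each_side = n_keep_each_side, cost = cost)
    pred[te] <- predict(fit, matrices[te])
    fold_acc[f] <- 100 * mean(pred[te] == as.character(labels[te]))
  }
  conf <- confusion_matrix(as.character(labels), pred,
                           classes = levels(labels))
  structure(list(
    fold_accuracy = fold_acc,
    mean_accuracy = 100 * mean(pred == as.character(labels)),
    sd_accuracy = stats::sd(fold_acc),
    confusion = conf$counts,
    per_class_accuracy = conf$per_class_accuracy,
    chance_level = chance_level(alpha, n, length(levels(labels))),
    folds = folds, seed = seed, k = k),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$k, "-fold stratified CV (seed ", x$seed, ")\n",
      "  mean accuracy: ", sprintf("%.2f", x$mean_accuracy), "% (sd ",
      sprintf("%.2f", x$sd_accuracy), ")  chance level: ",
      sprintf("%.3f", x$chance_level), "%\n", sep = "")
  cat("  per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 2))
  cat("  confusion (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

## Isolated RNG: a private stream seeded from `seed`, leaving the caller's
## .Random.seed untouched so a single pipeline seed governs all stochastic
## choices without side effects.
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    get(".Random.seed", globalenv())
  })
  env
}

.with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

.rng_permutation <- function(rng, n) .with_rng(rng, sample.int(n))
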