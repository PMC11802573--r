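test_that("class scatter matches hand-multiplied cases", {
  M <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(class_scatter(list(M))$C, diag(2))  # M %*% t(M) = I

  # averaging N identical matrices equals the N = 1 case
  one <- class_scatter(list(M))
  five <- class_scatter(rep(list(M), 5))
  expect_equal(five$C, one$C)
  expect_equal(five$n_trials, 5)

  expect_error(class_scatter(list(M, diag(3))), "dimension")
  expect_error(class_scatter(list()), "at least one")
})

test_that("generalized eigenproblem solves the diagonal and degenerate cases", {
  # C_i = diag(3,1), C_j = I: eigenvalues {3, 1}, top filter on first axis
  bank <- learn_pair_filters(diag(c(3, 1)), diag(2), n_keep_each_side = 1L)
  expect_equal(bank$all_eigenvalues, c(3, 1), tolerance = 1e-9)
  w1 <- bank$filters[, 1]
  expect_equal(abs(w1) / sqrt(sum(w1^2)), c(1, 0), tolerance = 1e-9)

  # C_i = C_j: the Rayleigh ratio is identically 1
  set.seed(31)
  C <- random_spd(4)
  bank2 <- learn_pair_filters(C, C)
  expect_equal(bank2$all_eigenvalues, rep(1, 4), tolerance = 1e-6)
})

test_that("largest generalized eigenvalue matches a brute-force Rayleigh grid search", {
  set.seed(99)
  for (s in 1:12) {
    A <- random_spd(3); B <- random_spd(3)
    bank <- learn_pair_filters(A, B, n_keep_each_side = 1L)
    grid_max <- rayleigh_grid_max(A, B, step_deg = 1)
    expect_equal(bank$eigenvalues[1], grid_max, tolerance = 0.005)
  }
})

test_that("returned filters satisfy the eigen-equation and the C_j normalization", {
  set.seed(7)
  A <- random_spd(6); B <- random_spd(6)
  bank <- learn_pair_filters(A, B)
  expect_equal(ncol(bank$filters), 4)
  # eigenvalues ordered: 2 largest (descending) then 2 smallest
  expect_equal(bank$eigenvalues,
               sort(bank$all_eigenvalues, decreasing = TRUE)[c(1, 2, 5, 6)])
  for (k in 1:4) {
    w <- bank$filters[, k]; lam <- bank$eigenvalues[k]
    resid <- A %*% w - lam * (B %*% w)
    expect_lte(sqrt(sum(resid^2)), 1e-6 * sqrt(sum((A %*% w)^2)))
    expect_equal(drop(crossprod(w, B %*% w)), 1, tolerance = 1e-6)
    expect_gt(w[which.max(abs(w))], 0)  # sign convention
  }
})

test_that("swapping the class pair inverts eigenvalues and keeps directions", {
  set.seed(12)
  for (s in 1:5) {
    A <- random_spd(5); B <- random_spd(5)
    fwd <- learn_pair_filters(A, B)
    bwd <- learn_pair_filters(B, A)
    expect_equal(sort(bwd$all_eigenvalues),
                 sort(1 / fwd$all_eigenvalues), tolerance = 1e-6)
    # each forward filter direction appears among the backward filters
    for (k in 1:4) {
      w <- fwd$filters[, k] / sqrt(sum(fwd$filters[, k]^2))
      cors <- abs(crossprod(
        w, apply(bwd$filters, 2, function(v) v / sqrt(sum(v^2)))))
      expect_gt(max(cors), 1 - 1e-6)
    }
  }
})

test_that("filters are equivariant under simultaneous orthogonal rotation", {
  set.seed(23)
  A <- random_spd(4); B <- random_spd(4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  fwd <- learn_pair_filters(A, B)
  rot <- learn_pair_filters(Q %*% A %*% t(Q), Q %*% B %*% t(Q))
  expect_equal(rot$eigenvalues, fwd$eigenvalues, tolerance = 1e-8)
  for (k in 1:4) {
    a <- Q %*% fwd$filters[, k]
    b <- rot$filters[, k]
    expect_equal(abs(drop(crossprod(a, b))) / sqrt(sum(a^2) * sum(b^2)), 1,
                 tolerance = 1e-6)
  }
})

test_that("feature extraction is the log quadratic form with its scaling law", {
  # w = e1, M = [[0,1],[1,0]]: w' M M' w = 1, feature log(1 + eps) ~ 0
  M <- matrix(c(0, 1, 1, 0), 2, 2)
  bank <- learn_pair_filters(diag(c(3, 1)), diag(2), n_keep_each_side = 1L)
  bank$filters <- matrix(c(1, 0), 2, 1)
  f <- extract_features(M, bank)
  expect_equal(f, log(1 + 1e-12), tolerance = 1e-12)

  # scaling M by c adds 2*log(c) to every feature
  set.seed(3)
  A <- random_spd(5); B <- random_spd(5)
  bank5 <- learn_pair_filters(A, B)
  W <- matrix(0, 5, 5); W[lower.tri(W)] <- runif(10); W <- W + t(W)
  expect_equal(extract_features(3 * W, bank5),
               extract_features(W, bank5) + 2 * log(3), tolerance = 1e-9)
  expect_equal(length(extract_features(W, bank5)), 4)

  expect_error(extract_features(diag(3), bank5), "does not match")
})

test_that("the top filter loads on the planted channels of a two-class ensemble", {
  # two classes differing in one planted edge block: the largest-eigenvalue
  # filter should concentrate its largest loadings on the planted channels
  n_ch <- 8
  hit <- 0L
  for (s in 1:10) {
    set.seed(s)
    mk <- function(planted) {
      w <- matrix(0, n_ch, n_ch)
      w[lower.tri(w)] <- runif(choose(n_ch, 2), 0, 0.3)
      w <- w + t(w)
      if (planted) {
        w[1, 2] <- w[2, 1] <- w[1, 2] + 1
        w[2, 3] <- w[3, 2] <- w[2, 3] + 1
      }
      minmax_standardize(connectivity_matrix(w, paste0("c", 1:n_ch), "mi"))
    }
    Ca <- class_scatter(lapply(1:20, function(i) mk(TRUE)))
    Cb <- class_scatter(lapply(1:20, function(i) mk(FALSE)))
    bank <- learn_pair_filters(Ca, Cb)
    top2 <- order(abs(bank$filters[, 1]), decreasing = TRUE)[1:2]
    if (all(top2 %in% 1:3)) hit <- hit + 1L
  }
  expect_gte(hit, 9L)
})
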