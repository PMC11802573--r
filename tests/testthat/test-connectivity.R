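test_that("coherence closed forms: self-coherence 1, delay-invariance, independence null", {
  set.seed(3)
  x <- rnorm(30000)
  expect_equal(coherence_edge(x, x, 1000), 1, tolerance = 1e-9)

  # pure delay leaves magnitude-squared coherence at ~1
  y <- c(rep(0, 10), x[1:(length(x) - 10)])
  expect_gte(coherence_edge(x, y, 1000), 0.99)

  # independent white noise, 30 s, 1 s segments, 50% overlap: near the 1/K bias
  z <- rnorm(30000)
  expect_lt(coherence_edge(x, z, 1000), 0.15)

  expect_error(coherence_edge(x[1:100], z[1:100], 1000), "Welch segment")
  expect_error(coherence_edge(x, z, 1000,
                              connectivity_config("coh", coh_band = c(0.01, 0.02))),
               "band empty")
})

test_that("pearson edge reproduces exact linear relations and rejects constants", {
  expect_equal(pearson_edge(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)
  x <- c(0.3, 1.9, -2, 4.4, 0)
  expect_equal(pearson_edge(x, -x + 7), -1)
  expect_error(pearson_edge(rep(1, 5), rnorm(5)), "constant")
})

test_that("mutual information matches hand-computable tables and identities", {
  # perfectly co-binned 2x2 table [[5,0],[0,5]] -> 1 bit
  x <- c(rep(0, 5), rep(1, 5))
  expect_equal(mutual_info_edge(x, x, connectivity_config("mi", mi_bins = 2)),
               1, tolerance = 1e-12)

  # MI(x, x) equals the marginal entropy of binned x
  set.seed(8)
  x <- rnorm(500)
  cfg <- connectivity_config("mi", mi_bins = 16)
  counts <- tabulate(pmin(floor((x - min(x)) / diff(range(x)) * 16) + 1, 16), 16)
  p <- counts[counts > 0] / 500
  expect_equal(mutual_info_edge(x, x, cfg), -sum(p * log2(p)),
               tolerance = 1e-9)

  expect_warning(mi0 <- mutual_info_edge(rep(1, 10), rnorm(10)), "constant")
  expect_equal(mi0, 0)
})

test_that("MI agrees with a brute-force joint-histogram oracle", {
  cfg <- connectivity_config("mi", mi_bins = 4)
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(8:64, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    expect_equal(mutual_info_edge(x, y, cfg), mi_bruteforce(x, y, 4),
                 tolerance = 1e-12)
  }
})

test_that("MI estimator properties: symmetry, affine invariance, plug-in bias bound", {
  cfg <- connectivity_config("mi")
  set.seed(13)
  x <- rnorm(800); y <- rnorm(800) + 0.3 * x
  expect_equal(mutual_info_edge(x, y, cfg), mutual_info_edge(y, x, cfg),
               tolerance = 1e-12)
  # affine rescale of one series preserves bin assignment hence MI exactly
  expect_identical(mutual_info_edge(x, y, cfg),
                   mutual_info_edge(x, 3.7 * y - 11, cfg))

  # independent uniforms: plug-in MI below 3x the (B-1)^2/(2 n ln2) bias
  n <- 100000
  bound <- 3 * (15 * 15) / (2 * n * log(2))
  for (s in 1:50) {
    set.seed(s)
    expect_lte(mutual_info_edge(runif(n), runif(n), cfg), bound)
  }
})

test_that("adjacency assembly: dimensions, symmetry, zero diagonal", {
  ep <- generate_epochs(synth_config(n_trials = 1L, seed = 3L))
  cfg <- connectivity_config("mi")
  m <- build_adjacency(ep$data[1, , ], ep$rate, cfg,
                       channel_labels = ep$channel_labels)
  expect_equal(dim(m$weights), c(28, 28))  # 22 EEG + 6 EMG fused
  expect_equal(m$weights, t(m$weights), tolerance = 1e-9)
  expect_equal(diag(m$weights), setNames(rep(0, 28), ep$channel_labels))

  # EMG-only subset: 6 x 6 with n(n-1)/2 = 15 unique off-diagonal values
  emg <- build_adjacency(ep$data[1, , ], ep$rate, cfg,
                         channel_labels = ep$channel_labels,
                         subset = emg_channel_labels)
  expect_equal(dim(emg$weights), c(6, 6))
  off <- emg$weights[upper.tri(emg$weights)]
  expect_equal(length(off), 15)
  expect_equal(length(unique(off)), 15)

  expect_error(build_adjacency(ep$data[1, , ], ep$rate, cfg,
                               channel_labels = ep$channel_labels,
                               subset = c("FZ", "NOPE")), "unknown channels")
})

test_that("min-max standardization maps off-diagonals onto [0,1] and is idempotent", {
  w <- matrix(0, 3, 3)
  w[lower.tri(w)] <- c(0.2, 0.5, 0.8)
  w <- w + t(w)
  m <- connectivity_matrix(w, paste0("ch", 1:3), "cc")
  s <- minmax_standardize(m)
  expect_equal(sort(s$weights[lower.tri(s$weights)]), c(0, 0.5, 1))
  expect_true(s$standardized)
  # idempotent
  s2 <- minmax_standardize(s)
  expect_equal(s2$weights, s$weights, tolerance = 1e-12)
  # rank order preserved for random input
  set.seed(4)
  w2 <- matrix(0, 5, 5); w2[lower.tri(w2)] <- rnorm(10); w2 <- w2 + t(w2)
  m2 <- minmax_standardize(connectivity_matrix(w2, paste0("c", 1:5), "cc"))
  expect_identical(order(w2[lower.tri(w2)]),
                   order(m2$weights[lower.tri(m2$weights)]))

  flat <- connectivity_matrix(matrix(0.4, 2, 2) - 0.4 * diag(2),
                              c("a", "b"), "mi")
  expect_error(minmax_standardize(flat), "degenerate")
})

test_that("all three edge estimators are symmetric in their arguments", {
  set.seed(17)
  x <- rnorm(3000); y <- 0.4 * x + rnorm(3000)
  expect_equal(coherence_edge(x, y, 1000), coherence_edge(y, x, 1000),
               tolerance = 1e-9)
  expect_equal(pearson_edge(x, y), pearson_edge(y, x), tolerance = 1e-12)
  cfg <- connectivity_config("mi")
  expect_equal(mutual_info_edge(x, y, cfg), mutual_info_edge(y, x, cfg),
               tolerance = 1e-12)
})

test_that("matrix text serialization round-trips values and labels", {
  set.seed(6)
  w <- matrix(0, 4, 4); w[lower.tri(w)] <- runif(6); w <- w + t(w)
  m <- connectivity_matrix(w, c("FZ", "CZ", "RF_L", "RF_R"), "mi")
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  m2 <- read_matrix_tsv(path, method = "mi", standardized = FALSE)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(m2$channel_labels, m$channel_labels)
})
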