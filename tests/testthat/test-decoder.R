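# shared small decoding problem
conn_small <- local({
  ep <- generate_epochs(small_synth_config(n_trials = 6L))
  connectivity_matrices(ep, connectivity_config("mi"), "fusion")
})

test_that("the ensemble holds one unit per unordered class pair", {
  fit <- dsnp_decoder(conn_small$matrices, conn_small$labels)
  expect_s3_class(fit, "dsnp_decoder")
  expect_length(fit$units, 3)  # 3*(3-1)/2
  pairs <- sort(vapply(fit$units, function(u)
    paste(sort(u$classes), collapse = "/"), character(1)))
  expect_identical(pairs, c("rest/sit_to_stand", "rest/stand_to_sit",
                            "sit_to_stand/stand_to_sit"))

  # 2 classes -> 1 unit
  keep <- conn_small$labels != "rest"
  fit2 <- dsnp_decoder(conn_small$matrices[keep],
                       droplevels(conn_small$labels[keep]))
  expect_length(fit2$units, 1)

  # a class with < 2 trials is a training error naming the class
  idx <- c(which(conn_small$labels == "rest")[1],
           which(conn_small$labels != "rest"))
  expect_error(dsnp_decoder(conn_small$matrices[idx],
                            conn_small$labels[idx]), "rest")
})

test_that("separable planted-topology trials are classified perfectly in-sample", {
  fit <- dsnp_decoder(conn_small$matrices, conn_small$labels)
  pred <- predict(fit, conn_small$matrices)
  expect_equal(mean(pred == as.character(conn_small$labels)), 1)
  # vote record exposed for a single prediction
  p1 <- predict(fit, conn_small$matrices[[1]])
  expect_s3_class(attr(p1, "votes"), "data.frame")
  expect_equal(nrow(attr(p1, "votes")), 3)
})

test_that("majority voting and margin tie-breaking follow the stated rules", {
  mv <- neurofuse:::.majority_vote
  classes <- c("A", "B", "C")
  # {A beats B, A beats C, B beats C} -> A with 2 votes
  expect_equal(mv(c("A", "A", "B"), c(1, 1, 1), classes), "A")
  # cyclic tie: winner is the largest summed margin
  expect_equal(mv(c("A", "B", "C"), c(0.9, 0.1, 0.1), classes), "A")
  expect_equal(mv(c("A", "B", "C"), c(0.1, 0.8, 0.1), classes), "B")
  # exact margin tie falls back to class order
  expect_equal(mv(c("A", "B", "C"), c(0.5, 0.5, 0.5), classes), "A")
  # {B, B, anything} -> B
  expect_equal(mv(c("B", "B", "A"), c(0.1, 0.1, 5), classes), "B")
})

test_that("chance level reproduces the inverse-binomial formula exactly", {
  expect_identical(chance_level(0.05, 160, 3), 39.375)
  # alpha -> 1 limit: quantile at 0
  expect_identical(chance_level(0.9999, 10, 2), 0)
  expect_error(chance_level(0, 10, 2), "alpha")
  expect_error(chance_level(0.05, 10, 1), "c")

  # exhaustive CDF-summation oracle over the full stated range
  for (c_ in c(2, 3, 4)) for (a in c(0.05, 0.01)) {
    n <- 1:500
    got <- vapply(n, function(nn) chance_level(a, nn, c_), numeric(1))
    want <- vapply(n, function(nn) chance_bruteforce(a, nn, c_), numeric(1))
    expect_identical(got, want)
  }
})

test_that("confusion matrix counts and per-class accuracy match hand counts", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(unname(cm$counts), rbind(c(1, 1), c(0, 1)))
  expect_equal(unname(cm$per_class_accuracy), c(50, 100))

  perfect <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(diag(perfect$counts)), rep(1, 3))
  expect_equal(unname(perfect$per_class_accuracy), rep(100, 3))

  onecol <- confusion_matrix(c("A", "B", "C"), rep("B", 3),
                             classes = c("A", "B", "C"))
  expect_equal(unname(colSums(onecol$counts)), c(0, 3, 0))

  expect_error(confusion_matrix("A", "D", classes = c("A", "B")),
               "outside the class set")
})

test_that("cross-validation partitions, stratifies and is deterministic", {
  cv <- cross_validate(conn_small$matrices, conn_small$labels, k = 3, seed = 5)
  # every sample in exactly one test fold
  expect_length(cv$folds, length(conn_small$labels))
  expect_true(all(cv$folds %in% 1:3))
  # stratification: per-fold class counts within 1 of n/k
  for (f in 1:3) {
    tab <- table(conn_small$labels[cv$folds == f])
    expect_true(all(abs(tab - 2) <= 1))
  }
  # confusion row sums equal per-class test counts
  expect_equal(unname(rowSums(cv$confusion)),
               unname(as.integer(table(conn_small$labels))))
  # mean accuracy = total correct / total tested
  expect_equal(cv$mean_accuracy,
               100 * sum(diag(cv$confusion)) / sum(cv$confusion))

  cv2 <- cross_validate(conn_small$matrices, conn_small$labels, k = 3, seed = 5)
  expect_identical(cv, cv2)
  cv3 <- cross_validate(conn_small$matrices, conn_small$labels, k = 3, seed = 6)
  expect_false(identical(cv$folds, cv3$folds))

  expect_error(cross_validate(conn_small$matrices, conn_small$labels,
                              k = 10, seed = 1), ">= k trials")
})
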