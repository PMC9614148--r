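test_that("confusion matrix tallies pairs over the fixed label universe", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(unclass(cm)[, ], matrix(c(1, 0, 1, 1), 2, 2,
    dimnames = list(truth = c("a", "b"), estimate = c("a", "b"))))
  # hand-listed 6 pairs
  cm6 <- confusion(c(1, 1, 1, 2, 2, 2), c(1, 2, 1, 2, 2, 1), levels = c("1", "2"))
  expect_equal(as.vector(unclass(cm6)), c(2, 1, 1, 2))
  # identical vectors give a diagonal matrix; disjoint give zero diagonal
  cmd <- confusion(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sum(unclass(cmd)) , sum(diag(cmd)))
  cmz <- confusion(c(1, 1), c(2, 2), levels = c("1", "2"))
  expect_equal(diag(cmz), c("1" = 0, "2" = 0))
  # absent classes keep zero rows
  cma <- confusion(factor("a", levels = letters[1:3]),
                   factor("a", levels = letters[1:3]))
  expect_equal(dim(cma), c(3, 3))
})

test_that("accuracy is trace over total, in percent", {
  cm <- confusion(rep(1:2, c(50, 50)),
                  rep(c(1, 2, 2, 1), c(40, 10, 45, 5)), levels = c("1", "2"))
  expect_equal(unclass(cm)[, ], matrix(c(40, 5, 10, 45), 2, 2,
    dimnames = list(truth = c("1", "2"), estimate = c("1", "2"))))
  expect_equal(accuracy(cm), 85)
  expect_equal(accuracy(confusion(1:3, 1:3)), 100)
  off <- confusion(c(1, 2), c(2, 1), levels = c("1", "2"))
  expect_equal(accuracy(off), 0)
})

test_that("Cohen's kappa matches the textbook oracle and the known cases", {
  expect_equal(cohen_kappa(confusion(1:5, 1:5)), 1)
  # constant prediction on balanced 5-class truth: p1 = p2 = 0.2, kappa 0
  cm0 <- confusion(rep(1:5, each = 20), rep(1, 100), levels = as.character(1:5))
  expect_equal(cohen_kappa(cm0), 0)
  set.seed(15)
  for (i in 1:50) {
    y <- sample(1:4, 200, replace = TRUE)
    p <- ifelse(runif(200) < 0.6, y, sample(1:4, 200, replace = TRUE))
    cm <- confusion(y, p, levels = as.character(1:4))
    expect_equal(cohen_kappa(cm), oracle_kappa(cm), tolerance = 1e-12)
    if (requireNamespace("e1071", quietly = TRUE)) {
      expect_equal(cohen_kappa(cm),
                   e1071::classAgreement(unclass(cm))$kappa, tolerance = 1e-12)
    }
  }
  # degenerate: single class truth and prediction -> p2 = 1 sentinel
  expect_true(is.na(cohen_kappa(confusion(rep(1, 5), rep(1, 5)))))
})

test_that("kappa is 1 exactly when the matrix is diagonal with positive trace", {
  set.seed(16)
  for (i in 1:20) {
    y <- sample(1:3, 60, replace = TRUE)
    p <- sample(1:3, 60, replace = TRUE)
    cm <- confusion(y, p, levels = as.character(1:3))
    k <- cohen_kappa(cm)
    is_diag <- sum(diag(cm)) == sum(cm)
    if (!is.na(k)) expect_lte(k, 1)
    if (is_diag && !is.na(k)) expect_equal(k, 1)
    # p1 reconstructs accuracy algebraically
    p2 <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    if (!is.na(k)) {
      expect_equal(k * (1 - p2) + p2, accuracy(cm) / 100, tolerance = 1e-12)
    }
  }
})

test_that("per-class kappa follows the printed asymmetric form", {
  # perfect diagonal: kappa(i) = 1 for every class present
  cmd <- confusion(rep(1:3, 10), rep(1:3, 10), levels = as.character(1:3))
  expect_equal(unname(per_class_kappa(cmd)), rep(1, 3))
  # hand 3-class matrix
  Q <- matrix(c(20, 3, 1,
                2, 15, 2,
                0, 1, 6), 3, 3, byrow = TRUE,
              dimnames = list(truth = 1:3, estimate = 1:3))
  class(Q) <- c("confusion_matrix", class(Q))
  M <- sum(Q)
  for (t in 1:3) {
    ptt <- Q[t, t] / M
    ptr <- sum(Q[t, ]) / M
    ptc <- sum(Q[, t]) / M
    expect_equal(unname(per_class_kappa(Q, t)),
                 (ptt - ptr * ptc) / (ptc - ptr * ptc), tolerance = 1e-12)
  }
  # class never true and never predicted: 0/0 sentinel
  cms <- confusion(factor(rep("a", 4), levels = c("a", "b")),
                   factor(rep("a", 4), levels = c("a", "b")))
  expect_true(is.na(per_class_kappa(cms, "b")))
})

test_that("repeated holdout: perfect and chance classifiers behave as expected", {
  d <- make_blobs(n_per = 60, k = 3, sep = 8, seed = 17)
  rep1 <- repeated_holdout(d, trainer = train_dt, n_rep = 5, seed = 1)
  s <- rep1$summary
  expect_equal(s$mean[s$metric == "accuracy"], 100)
  expect_equal(s$sd[s$metric == "accuracy"], 0)
  expect_equal(s$mean[s$metric == "kappa"], 1)
  # identical seeds give identical reports
  rep2 <- repeated_holdout(d, trainer = train_dt, n_rep = 2, seed = 9)
  rep3 <- repeated_holdout(d, trainer = train_dt, n_rep = 2, seed = 9)
  expect_equal(rep2$metrics, rep3$metrics)
  # chance-level classifier on balanced labels: kappa near 0
  chance_trainer <- function(data, label_col = "label", seed = NULL) {
    m <- train_dt(data[c("f1", label_col)], label_col = label_col)
    m$fit <- NULL
    class(m) <- c("chance_model", "prv_model")
    m
  }
  assign("predict.chance_model",
         function(object, newdata, ...) {
           factor(sample(object$levels, nrow(newdata), replace = TRUE),
                  levels = object$levels)
         }, envir = globalenv())
  on.exit(rm("predict.chance_model", envir = globalenv()), add = TRUE)
  set.seed(2)
  balanced <- tibble::tibble(f1 = rnorm(500),
                             label = factor(rep(1:5, 100)))
  repc <- repeated_holdout(balanced, trainer = chance_trainer,
                           n_rep = 50, seed = 3)
  expect_lt(abs(repc$summary$mean[repc$summary$metric == "kappa"]), 0.05)
})

test_that("report tidiers expose summary rows and headline numbers", {
  d <- make_blobs(n_per = 30, k = 2, sep = 8, seed = 18)
  rep1 <- repeated_holdout(d, trainer = train_dt, n_rep = 3, seed = 4)
  td <- tidy(rep1)
  expect_true(all(c("metric", "mean", "sd") %in% names(td)))
  gl <- glance(rep1)
  expect_equal(gl$n_rep, 3)
  expect_true(gl$accuracy_mean >= 0 && gl$accuracy_mean <= 100)
  path <- tempfile(fileext = ".json")
  write_eval_report(rep1, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
  unlink(path)
})
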