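# standardisation, L2 logistic readout, prediction, error rate

toy_separable <- function(n = 10, gap = 1, sd = 0.1, seed = 12) {
  holocyto:::with_seed(seed, {
    x <- rbind(cbind(rnorm(n, -gap, sd), rnorm(n, 0, sd)),
               cbind(rnorm(n, +gap, sd), rnorm(n, 0, sd)))
    list(x = x, labels = rep(c("A", "B"), each = n))
  })
}

test_that("standardiser fits on training data only, with zero-variance guard", {
  x <- matrix(c(1, 1, 1, 2, 4, 6), 3)
  std <- fit_standardizer(x)
  expect_equal(std$means, c(1, 4))
  expect_equal(std$scales[1], 1)  # zero-variance column
  xs <- holocyto:::standardize(x, std)
  expect_equal(colMeans(xs), c(0, 0), tolerance = 1e-9)
  expect_equal(sqrt(mean(xs[, 2]^2)), 1, tolerance = 1e-9)
  expect_error(fit_standardizer(x[1, , drop = FALSE]), ">= 2")

  # leakage contract: test samples are standardised with training statistics
  train <- matrix(rnorm(20, mean = 5), 10)
  test <- matrix(rnorm(20, mean = -5), 10)
  std <- fit_standardizer(train)
  xt <- holocyto:::standardize(test, std)
  expect_lt(mean(xt), -1)  # would be ~0 had the test set been self-standardised
})

test_that("training solves the separable toy and respects regularisation", {
  toy <- toy_separable()
  fit <- train_readout(toy$x, toy$labels, C = 10)
  pred <- predict(fit, toy$x)
  expect_equal(error_rate(pred, toy$labels), 0)
  # stronger regularisation shrinks the weights
  weak <- train_readout(toy$x, toy$labels, C = 1e-5)
  expect_lt(sqrt(sum(weak$weights^2)), sqrt(sum(fit$weights^2)))
  expect_error(train_readout(toy$x, rep("A", nrow(toy$x)), C = 1),
               "two classes")
  expect_error(train_readout(toy$x, toy$labels, C = 0), "positive")
})

test_that("balanced class weights keep the minority class above chance", {
  holocyto:::with_seed(3, {
    x <- rbind(cbind(rnorm(90, -1, 0.3), rnorm(90)),
               cbind(rnorm(10, +1, 0.3), rnorm(10)))
    labels <- c(rep("A", 90), rep("B", 10))
    fit <- train_readout(x, labels, C = 1)
    pred <- predict(fit, x)
    minority_recall <- mean(pred$class[labels == "B"] == "B")
    expect_gt(minority_recall, 0.5)
  })
})

test_that("prediction is the single weighted sum, class A iff margin > 0", {
  toy <- toy_separable()
  fit <- train_readout(toy$x, toy$labels, C = 1)
  # degenerate readout: zero weights, intercept 1 -> everything is class A
  z <- fit
  z$weights <- rep(0, 2); z$intercept <- 1
  pz <- predict(z, toy$x)
  expect_true(all(pz$class == "A"))
  expect_true(all(pz$margin == 1))
  # negating weights and intercept flips every margin sign
  neg <- fit
  neg$weights <- -fit$weights; neg$intercept <- -fit$intercept
  expect_equal(predict(neg, toy$x)$margin, -predict(fit, toy$x)$margin)
  # brute-force dot-product oracle
  holocyto:::with_seed(9, {
    xs <- matrix(rnorm(20), 10, 2)
    p <- predict(fit, xs)
    for (i in 1:10) {
      zstd <- (xs[i, ] - fit$feature_means) / fit$feature_scales
      m <- sum(zstd * fit$weights) + fit$intercept
      expect_equal(p$margin[i], m, tolerance = 1e-12)
    }
  })
  expect_error(predict(fit, matrix(0, 2, 5)), "features")
})

test_that("error rate counts misclassified fractions", {
  expect_equal(error_rate(c("A", "B"), c("A", "B")), 0)
  expect_equal(error_rate(c("B", "A"), c("A", "B")), 1)
  expect_equal(error_rate(rep(c("A", "B"), 6), c(rep("A", 9), rep("B", 3))),
               5 / 12)
  expect_equal(error_rate(c(rep("A", 9), rep("B", 3)),
                          c(rep("A", 12))), 0.25)
  expect_error(error_rate(character(0), character(0)), "empty")
  expect_error(error_rate("A", c("A", "B")), "mismatch")
})

test_that("training is deterministic and lands at a convex minimum", {
  toy <- toy_separable(n = 15, gap = 0.6, sd = 0.4)
  f1 <- train_readout(toy$x, toy$labels, C = 0.5)
  f2 <- train_readout(toy$x, toy$labels, C = 0.5)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$intercept, f2$intercept)
  # objective of the returned readout beats 100 random perturbations
  std <- list(means = f1$feature_means, scales = f1$feature_scales)
  xs <- holocyto:::standardize(toy$x, std)
  y01 <- as.integer(toy$labels == "A")
  base <- holocyto:::logistic_objective(f1$weights, f1$intercept, xs, y01, 0.5)
  holocyto:::with_seed(33, {
    for (r in 1:100) {
      w <- f1$weights + rnorm(2, sd = 0.05)
      b <- f1$intercept + rnorm(1, sd = 0.05)
      expect_gte(holocyto:::logistic_objective(w, b, xs, y01, 0.5),
                 base - 1e-6)
    }
  })
})

test_that("readouts round-trip through JSON with identical predictions", {
  toy <- toy_separable()
  m <- structure(list(values = matrix(runif(2), 1, 2), n_A = 5, n_B = 5),
                 class = "separation_map")
  mask <- select_features(m, 1)
  fit <- train_readout(toy$x, toy$labels, C = 2, feature_mask = mask)
  path <- tempfile(fileext = ".json")
  save_readout(fit, path)
  back <- load_readout(path)
  expect_equal(predict(back, toy$x), predict(fit, toy$x), tolerance = 1e-12)
  unlink(path)
})
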