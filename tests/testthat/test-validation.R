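# nested session-wise validation, UM test, bias audit

test_that("fold membership at N_s = 3 matches the hand enumeration", {
  ds <- null_session_dataset(N_s = 3, n_per_session = 8)
  rep <- nested_session_cv(ds, hyper_grid = 0.1)
  expect_equal(nrow(rep$folds), 3)
  expect_equal(rep$p_final, mean(rep$folds$error))
  # hand enumeration: outer i, inner j != i, train = the remaining pair
  want <- list(
    `1` = list(c(2, 3), list(list(validate = 2, train = 3),
                             list(validate = 3, train = 2))),
    `2` = list(c(1, 3), list(list(validate = 1, train = 3),
                             list(validate = 3, train = 1))),
    `3` = list(c(1, 2), list(list(validate = 1, train = 2),
                             list(validate = 2, train = 1))))
  for (i in 1:3) {
    mem <- rep$membership[[i]]
    expect_equal(mem$test, i)
    expect_length(mem$inner, 2)
    for (inn in mem$inner) {
      expect_equal(inn, list(validate = inn$validate,
                             train = setdiff(1:3, c(i, inn$validate))),
                   ignore_attr = TRUE)
    }
  }
  expect_error(nested_session_cv(null_session_dataset(N_s = 2)), "N_s >= 3")
})

test_that("train, validation and test sessions are always disjoint", {
  ds <- null_session_dataset(N_s = 5, n_per_session = 6)
  rep <- nested_session_cv(ds, hyper_grid = c(0.01, 1))
  for (i in seq_along(rep$membership)) {
    mem <- rep$membership[[i]]
    for (inn in mem$inner) {
      expect_length(intersect(inn$train, c(mem$test, inn$validate)), 0)
      expect_false(mem$test %in% inn$train)
      expect_false(mem$test == inn$validate)
    }
  }
})

test_that("identical class distributions give chance-level p_final", {
  ds <- null_session_dataset(N_s = 4, n_per_session = 30, seed = 5)
  rep <- nested_session_cv(ds, hyper_grid = c(0.001, 0.1, 10))
  se <- sqrt(0.25 / sum(rep$folds$n_test))
  expect_lt(abs(rep$p_final - 0.5), 3 * se + 0.05)
})

test_that("hyperparameter ties break toward the smallest C", {
  ds <- null_session_dataset(N_s = 3, n_per_session = 4, seed = 8)
  rep <- suppressWarnings(nested_session_cv(ds, hyper_grid = c(1e-5, 1e-4)))
  # with 4 noise samples per session the tiny-C fits are equivalent: the
  # chosen C must then be the smallest grid value
  for (i in 1:3) {
    inner_mean <- apply(rep$inner_errors[i, , , drop = FALSE], 3, mean,
                        na.rm = TRUE)
    if (abs(diff(inner_mean)) < 1e-12) expect_equal(rep$folds$C[i], 1e-5)
  }
})

test_that("uniform mislabelling swaps even pairs and is an involution", {
  ds <- null_session_dataset(N_s = 4, n_per_session = 5)
  # tag ground truth to follow the swap
  for (n in 1:4) {
    ds$pairs[[n]]$A$meta$true_label <- "A"
    ds$pairs[[n]]$B$meta$true_label <- "B"
  }
  um <- uniform_mislabel(ds)
  for (n in 1:4) {
    if (n %% 2 == 0) {
      # nominal A slot now holds true-B samples
      expect_equal(unique(um$pairs[[n]]$A$meta$true_label), "B")
      expect_equal(unique(um$pairs[[n]]$A$meta$label), "A")
    } else {
      expect_equal(unique(um$pairs[[n]]$A$meta$true_label), "A")
    }
  }
  twice <- uniform_mislabel(um)
  for (n in 1:4) {
    expect_equal(twice$pairs[[n]]$A$meta$true_label,
                 ds$pairs[[n]]$A$meta$true_label)
    expect_equal(twice$pairs[[n]]$A$images, ds$pairs[[n]]$A$images)
  }
})

test_that("cross-session testing refuses leaking session sets", {
  ds <- null_session_dataset(N_s = 4, n_per_session = 10)
  expect_error(cross_session_test(ds, 1:3, 3:4, 0.1), "overlap")
  out <- cross_session_test(ds, 1:2, 3:4, c(0.01, 1))
  expect_true(out$error >= 0 && out$error <= 1)
  expect_equal(out$n_test, 40)
})

test_that("same-session CV validates its fold count", {
  a <- noise_samples(10, sid = "a"); b <- noise_samples(10, sid = "b")
  expect_error(same_session_cv(a, b, 0.1, k_folds = 2), ">= 3")
  expect_error(same_session_cv(a, b, 0.1, k_folds = 11), "exceeds")
  rep <- suppressWarnings(same_session_cv(a, b, c(0.01, 1), k_folds = 3,
                                          seed = 2))
  expect_equal(nrow(rep$folds), 3)
})

test_that("the audit reports 'no signal' on contrastless, drift-free data", {
  ds <- null_session_dataset(N_s = 4, n_per_session = 24, seed = 14)
  aud <- suppressWarnings(bias_audit(ds, hyper_grid = c(0.01, 1), k_folds = 3))
  expect_equal(aud$verdict, "no signal")
  expect_gte(aud$cross_session_error, 0.45)
  expect_gte(aud$same_session_error, 0.45)
})

test_that("an empty session is reported by name", {
  pairs <- list(list(A = noise_samples(3, sid = "a1"),
                     B = noise_samples(0, sid = "b1")))
  expect_error(session_dataset(pairs), "pair 1 class B")
})
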