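#' @title Session-intertwined nested validation and bias diagnostics
#'
#' @description Training, validation and test sets are not only disjoint but
#' come from chronologically separate measurement sessions, so slow drift of
#' the acquisition conditions cannot leak class information. For each outer
#' session pair i the hyperparameter is selected by an inner loop over the
#' remaining pairs j (train on everything except i and j, validate on j),
#' the model is retrained on everything except i, and tested on i; the final
#' estimate is the mean of the per-fold test errors. The uniform-mislabelling
#' (UM) test reruns the whole procedure with the labels of every
#' even-indexed session pair swapped: if the learner exploits only
#' particle-related features the resulting error is chance (~50%); a
#' departure flags measurement bias.
#'
#' @name session_validation
#' @keywords internal
NULL

#' Assemble accepted per-session samples into a validation dataset
#'
#' @param pairs list over session pairs; each element is a list with
#'   \code{A} and \code{B}, the accepted \code{difference_samples} of that
#'   pair's class-A and class-B sessions (nominal labels are taken from the
#'   list slot and written into the sample metadata; ground truth is kept in
#'   \code{true_label}).
#' @param theta acceptance threshold used to build the samples (recorded).
#' @return a \code{session_dataset}.
#' @export
session_dataset <- function(pairs, theta = NA_real_) {
  stopifnot(length(pairs) >= 1)
  for (n in seq_along(pairs)) {
    for (cls in c("A", "B")) {
      s <- pairs[[n]][[cls]]
      if (is.null(s) || nrow(s$images) == 0) {
        stop(sprintf("session pair %d class %s is empty after acceptance", n, cls))
      }
      if (is.null(s$meta$true_label) || all(is.na(s$meta$true_label))) {
        pairs[[n]][[cls]]$meta$true_label <- s$meta$label
      }
      pairs[[n]][[cls]]$meta$label <- cls
      pairs[[n]][[cls]]$meta$pair <- n
    }
  }
  structure(list(pairs = pairs, N_s = length(pairs), theta = theta),
            class = "session_dataset")
}

#' @export
print.session_dataset <- function(x, ...) {
  na <- sum(vapply(x$pairs, function(p) nrow(p$A$images), 0L))
  nb <- sum(vapply(x$pairs, function(p) nrow(p$B$images), 0L))
  cat(sprintf("<session_dataset> %d session pairs, %d A + %d B accepted samples\n",
              x$N_s, na, nb))
  invisible(x)
}

# pooled (images, labels) over a set of pair indices
pool_pairs <- function(dataset, idx) {
  xs <- list(); labs <- character(0)
  for (n in idx) {
    for (cls in c("A", "B")) {
      s <- dataset$pairs[[n]][[cls]]
      xs[[length(xs) + 1]] <- s$images
      labs <- c(labs, s$meta$label)
    }
  }
  list(x = do.call(rbind, xs), labels = labs)
}

# mask + standardizer + glmnet path fitted on training data only;
# returns closure-free list usable for prediction at each C
fit_fold <- function(train, C_grid, keep_fraction) {
  keep <- NULL
  x <- train$x
  if (keep_fraction < 1) {
    sep <- separation_map(x, train$labels)
    keep <- as.logical(select_features(sep, keep_fraction)$mask)
    x <- x[, keep, drop = FALSE]
  }
  std <- fit_standardizer(x)
  xs <- standardize(x, std)
  y01 <- as.integer(train$labels == "A")
  path <- fit_logistic_path(xs, y01, C_grid)
  list(keep = keep, std = std, path = path)
}

fold_errors <- function(fit, test_x, test_labels, C_grid) {
  x <- if (!is.null(fit$keep)) test_x[, fit$keep, drop = FALSE] else test_x
  xs <- standardize(x, fit$std)
  vapply(seq_along(C_grid), function(k) {
    margin <- as.numeric(xs %*% fit$path[[k]]$weights) + fit$path[[k]]$intercept
    mean(ifelse(margin > 0, "A", "B") != test_labels)
  }, 0)
}

#' Nested session-wise cross-validation
#'
#' @param dataset a \code{session_dataset} with \code{N_s >= 3} pairs.
#' @param hyper_grid increasing vector of C values (inverse L2 strength);
#'   default 13 values log-spaced from 1e-5 to 10.
#' @param keep_fraction feature-selection fraction, refit inside every
#'   training set (1 = no selection).
#' @return a \code{cv_report}: per-outer-fold chosen C and test error,
#'   \code{p_final} (their mean), the full inner validation-error array and
#'   the fold membership (for structural leakage checks).
#' @export
nested_session_cv <- function(dataset, hyper_grid = default_C_grid(),
                              keep_fraction = 1) {
  N_s <- dataset$N_s
  if (N_s < 3) stop("nested session CV needs N_s >= 3")
  if (length(hyper_grid) == 0) stop("empty hyperparameter grid")
  K <- length(hyper_grid)
  inner <- array(NA_real_, dim = c(N_s, N_s, K))
  membership <- vector("list", N_s)
  folds <- data.frame(pair = seq_len(N_s), C = NA_real_, error = NA_real_,
                      n_test = NA_integer_)
  for (i in seq_len(N_s)) {
    js <- setdiff(seq_len(N_s), i)
    membership[[i]] <- list(test = i, inner = lapply(js, function(j) {
      list(validate = j, train = setdiff(seq_len(N_s), c(i, j)))
    }))
    for (j in js) {
      train <- pool_pairs(dataset, setdiff(seq_len(N_s), c(i, j)))
      fit <- fit_fold(train, hyper_grid, keep_fraction)
      val <- pool_pairs(dataset, j)
      inner[i, j, ] <- fold_errors(fit, val$x, val$labels, hyper_grid)
    }
    mean_val <- apply(inner[i, js, , drop = FALSE], 3, mean)
    k_best <- which(mean_val <= min(mean_val) + 1e-12)[1]  # tie: smallest C
    train <- pool_pairs(dataset, js)
    fit <- fit_fold(train, hyper_grid[k_best], keep_fraction)
    test <- pool_pairs(dataset, i)
    folds$C[i] <- hyper_grid[k_best]
    folds$error[i] <- fold_errors(fit, test$x, test$labels, hyper_grid[k_best])
    folds$n_test[i] <- nrow(test$x)
  }
  structure(list(folds = folds, p_final = mean(folds$error),
                 inner_errors = inner, hyper_grid = hyper_grid,
                 membership = membership, keep_fraction = keep_fraction),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d outer folds, p_final = %.3f (per-fold %s)\n",
              nrow(x$folds), x$p_final,
              paste(sprintf("%.2f", x$folds$error), collapse = " ")))
  invisible(x)
}

#' Conventional k-fold CV within single sessions (biased baseline)
#'
#' Partitions each class's single measurement session into \code{k_folds}
#' random pseudo-sessions and runs the same nested machinery, i.e. standard
#' k-fold cross-validation that ignores chronology. On drifting data this is
#' the misleading protocol: it reports low errors even when the class signal
#' is pure measurement bias.
#'
#' @param samples_a,samples_b accepted \code{difference_samples} of the one
#'   class-A and one class-B session.
#' @param hyper_grid C grid.
#' @param k_folds number of folds (>= 3, <= samples per class).
#' @param seed fold-assignment seed.
#' @param keep_fraction feature-selection fraction.
#' @return a \code{cv_report}.
#' @export
same_session_cv <- function(samples_a, samples_b,
                            hyper_grid = default_C_grid(), k_folds = 5,
                            seed = 1, keep_fraction = 1) {
  na <- nrow(samples_a$images); nb <- nrow(samples_b$images)
  if (k_folds < 3) stop("k_folds must be >= 3")
  if (k_folds > min(na, nb)) stop("k_folds exceeds samples per class")
  with_seed(seed, {
    fa <- sample(rep_len(seq_len(k_folds), na))
    fb <- sample(rep_len(seq_len(k_folds), nb))
    pairs <- lapply(seq_len(k_folds), function(n) {
      list(A = subset_samples(samples_a, fa == n),
           B = subset_samples(samples_b, fb == n))
    })
    nested_session_cv(session_dataset(pairs), hyper_grid, keep_fraction)
  })
}

#' Error on chronologically held-out sessions
#'
#' Selects C by leave-one-pair-out validation within the training sessions,
#' retrains on all training sessions, and reports the error on the disjoint
#' test sessions.
#'
#' @param dataset a \code{session_dataset}.
#' @param train_pairs,test_pairs disjoint pair-index vectors.
#' @param hyper_grid C grid.
#' @param keep_fraction feature-selection fraction.
#' @return list with \code{error}, chosen \code{C} and \code{n_test}.
#' @export
cross_session_test <- function(dataset, train_pairs, test_pairs,
                               hyper_grid = default_C_grid(),
                               keep_fraction = 1) {
  if (length(intersect(train_pairs, test_pairs)) > 0) {
    stop("train and test sessions overlap")
  }
  if (length(train_pairs) < 2) stop("need >= 2 training session pairs")
  K <- length(hyper_grid)
  val_err <- matrix(NA_real_, length(train_pairs), K)
  for (m in seq_along(train_pairs)) {
    j <- train_pairs[m]
    train <- pool_pairs(dataset, setdiff(train_pairs, j))
    fit <- fit_fold(train, hyper_grid, keep_fraction)
    val <- pool_pairs(dataset, j)
    val_err[m, ] <- fold_errors(fit, val$x, val$labels, hyper_grid)
  }
  mean_val <- colMeans(val_err)
  k_best <- which(mean_val <= min(mean_val) + 1e-12)[1]
  fit <- fit_fold(pool_pairs(dataset, train_pairs), hyper_grid[k_best],
                  keep_fraction)
  test <- pool_pairs(dataset, test_pairs)
  err <- fold_errors(fit, test$x, test$labels, hyper_grid[k_best])
  list(error = err, C = hyper_grid[k_best], n_test = nrow(test$x))
}

#' Uniform mislabelling (UM) of a session dataset
#'
#' Swaps the nominal class labels of every even-indexed session pair
#' (A2<->B2, A4<->B4, ...), so each nominal class contains both true bead
#' classes in equal measure; ground-truth annotations are untouched.
#' Applying it twice restores the original labels. A classifier that learns
#' only particle features then scores ~50%; a bias-exploiting one may not.
#'
#' @param dataset a \code{session_dataset}.
#' @return the mislabelled \code{session_dataset}.
#' @export
uniform_mislabel <- function(dataset) {
  for (n in seq_len(dataset$N_s)) {
    if (n %% 2 == 0) {
      a <- dataset$pairs[[n]]$A
      b <- dataset$pairs[[n]]$B
      a$meta$label <- "B"; b$meta$label <- "A"
      dataset$pairs[[n]]$A <- b
      dataset$pairs[[n]]$B <- a
    }
  }
  dataset
}

#' One-stop measurement-bias audit
#'
#' Runs the three diagnostics on an intertwined dataset: the biased
#' same-session baseline (within the first session pair), the
#' chronologically held-out cross-session error (first half pairs train,
#' second half test), and the UM test under the full nested validation.
#' Bias is flagged when the UM error departs from 0.5 by more than 3
#' binomial standard errors, or when the same-session error undercuts the
#' cross-session error by more than \code{margin}.
#'
#' @param dataset a \code{session_dataset} (>= 4 pairs recommended).
#' @param hyper_grid C grid (a reduced grid keeps the audit fast).
#' @param margin same-vs-cross gap that triggers the bias flag.
#' @param k_folds folds of the same-session arm.
#' @param keep_fraction feature-selection fraction.
#' @param seed fold-assignment seed for the same-session arm.
#' @return list with the three errors, the per-criterion flags and a
#'   \code{verdict}: "bias detected", "no bias detected" or "no signal".
#' @export
bias_audit <- function(dataset, hyper_grid = 10^seq(-4, 1, length.out = 4),
                       margin = 0.15, k_folds = 4, keep_fraction = 1,
                       seed = 1) {
  half <- floor(dataset$N_s / 2)
  same <- same_session_cv(dataset$pairs[[1]]$A, dataset$pairs[[1]]$B,
                          hyper_grid, k_folds = k_folds,
                          keep_fraction = keep_fraction, seed = seed)
  cross <- cross_session_test(dataset, seq_len(half),
                              seq(half + 1, dataset$N_s), hyper_grid,
                              keep_fraction)
  um <- nested_session_cv(uniform_mislabel(dataset), hyper_grid, keep_fraction)
  n_um <- sum(um$folds$n_test)
  um_se <- sqrt(0.25 / n_um)
  um_flag <- abs(um$p_final - 0.5) > 3 * um_se
  gap_flag <- (cross$error - same$p_final) > margin
  verdict <- if (um_flag || gap_flag) {
    "bias detected"
  } else if (cross$error >= 0.45 && same$p_final >= 0.45) {
    "no signal"
  } else {
    "no bias detected"
  }
  list(same_session_error = same$p_final, cross_session_error = cross$error,
       um_error = um$p_final, um_se = um_se, um_flag = um_flag,
       gap_flag = gap_flag, verdict = verdict)
}
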