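#' @title Trainable linear readout
#'
#' @description The classifier is a single weighted sum over (masked,
#' standardised) difference-image pixels: an L2-regularised logistic
#' regression with class weights inversely proportional to class frequency
#' ("balanced"). A positive margin maps to class A, negative to class B.
#' \code{C} is the inverse regularisation strength; the convex problem is
#' solved by glmnet with \code{lambda = 1/(C * n)} and weights summing to
#' \code{n}, which reproduces the usual \code{0.5 * ||w||^2 + C * sum(loss)}
#' parameterisation.
#'
#' @name linear_readout
#' @keywords internal
NULL

#' Default hyperparameter grid for C
#'
#' 13 values equidistant in log scale from 1e-5 to 10.
#' @return numeric vector of length 13, increasing.
#' @export
default_C_grid <- function() 10^seq(-5, 1, length.out = 13)

#' Fit per-feature standardisation parameters
#'
#' Means and (population) standard deviations over the training samples
#' only; zero-variance features get scale 1 so they standardise to a
#' constant 0 and receive no weight.
#'
#' @param x numeric matrix, samples x features (>= 2 rows).
#' @return list with \code{means} and \code{scales} vectors.
#' @export
fit_standardizer <- function(x) {
  if (nrow(x) < 2) stop("need >= 2 training samples")
  means <- colMeans(x)
  scales <- sqrt(colMeans(sweep(x, 2, means)^2))
  scales[scales == 0 | !is.finite(scales)] <- 1
  list(means = means, scales = scales)
}

standardize <- function(x, std) {
  sweep(sweep(x, 2, std$means), 2, std$scales, "/")
}

balanced_weights <- function(y01) {
  n <- length(y01)
  w <- numeric(n)
  w[y01 == 1] <- n / (2 * sum(y01 == 1))
  w[y01 == 0] <- n / (2 * sum(y01 == 0))
  w
}

# Fit the L2 logistic path for all C values in one glmnet call.
# x is already masked + standardised; returns list of (weights, intercept).
fit_logistic_path <- function(x, y01, C_grid) {
  n <- nrow(x)
  lambdas <- 1 / (C_grid * n)
  ord <- order(lambdas, decreasing = TRUE)  # glmnet wants decreasing lambda
  fit <- glmnet::glmnet(
    x, y01, family = "binomial", alpha = 0, lambda = lambdas[ord],
    weights = balanced_weights(y01), standardize = FALSE, intercept = TRUE,
    thresh = 1e-8, maxit = 1e5
  )
  coefs <- as.matrix(stats::coef(fit))
  out <- vector("list", length(C_grid))
  for (m in seq_along(ord)) {
    k <- ord[m]
    out[[k]] <- list(weights = coefs[-1, m], intercept = coefs[1, m])
  }
  out
}

#' Train the linear readout
#'
#' @param samples a \code{difference_samples} object with labels, or a
#'   numeric matrix (samples x pixels) plus \code{labels}.
#' @param labels class labels (two classes); the alphabetically first level
#'   is class A (positive margin).
#' @param C inverse L2 regularisation strength (> 0).
#' @param feature_mask optional \code{feature_mask} fitted on training data.
#' @return object of class \code{linear_readout} holding weights, intercept,
#'   standardisation parameters, the mask and \code{C}.
#' @export
train_readout <- function(samples, labels = NULL, C = 1, feature_mask = NULL) {
  if (C <= 0) stop("C must be positive")
  if (inherits(samples, "difference_samples")) {
    labels <- samples$meta$label
    x <- if (!is.null(feature_mask)) apply_mask(samples, feature_mask)
         else samples$images
    shape <- samples$shape
  } else {
    x <- samples
    if (!is.null(feature_mask)) x <- x[, as.logical(feature_mask$mask), drop = FALSE]
    shape <- NULL
  }
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("training data must contain exactly two classes")
  y01 <- as.integer(labels == lev[1])  # class A -> 1 -> positive margin
  std <- fit_standardizer(x)
  xs <- standardize(x, std)
  par <- fit_logistic_path(xs, y01, C)[[1]]
  structure(list(weights = par$weights, intercept = par$intercept,
                 feature_means = std$means, feature_scales = std$scales,
                 feature_mask = feature_mask, classes = lev, C = C,
                 input_shape = shape),
            class = "linear_readout")
}

#' @export
print.linear_readout <- function(x, ...) {
  cat(sprintf("<linear_readout> %d features, C=%g, classes %s(+)/%s(-)\n",
              length(x$weights), x$C, x$classes[1], x$classes[2]))
  invisible(x)
}

#' Classify samples with a trained readout
#'
#' The margin is the weighted sum of the standardised masked pixels plus the
#' intercept; a positive margin is class A, otherwise class B.
#'
#' @param object a \code{linear_readout}.
#' @param samples a \code{difference_samples} object or numeric matrix.
#' @param ... unused.
#' @return data frame with \code{margin} and \code{class}.
#' @export
predict.linear_readout <- function(object, samples, ...) {
  if (inherits(samples, "difference_samples")) {
    x <- if (!is.null(object$feature_mask))
      apply_mask(samples, object$feature_mask) else samples$images
  } else {
    x <- samples
    if (!is.null(object$feature_mask)) {
      x <- x[, as.logical(object$feature_mask$mask), drop = FALSE]
    }
  }
  if (ncol(x) != length(object$weights)) {
    stop(sprintf("sample has %d features, readout expects %d", ncol(x),
                 length(object$weights)))
  }
  xs <- standardize(x, list(means = object$feature_means,
                            scales = object$feature_scales))
  margin <- as.numeric(xs %*% object$weights) + object$intercept
  data.frame(margin = margin,
             class = ifelse(margin > 0, object$classes[1], object$classes[2]),
             stringsAsFactors = FALSE)
}

#' Classification error rate
#'
#' Fraction of misclassified samples (the complement of accuracy).
#'
#' @param predictions predicted class labels (or a \code{predict} result).
#' @param labels true class labels, same length.
#' @return error fraction in [0, 1].
#' @export
error_rate <- function(predictions, labels) {
  if (is.data.frame(predictions)) predictions <- predictions$class
  if (length(predictions) == 0) stop("empty predictions")
  if (length(predictions) != length(labels)) stop("length mismatch")
  mean(predictions != labels)
}

# penalised training objective; used by the convexity property test
logistic_objective <- function(weights, intercept, x, y01, C) {
  eta <- as.numeric(x %*% weights) + intercept
  w <- balanced_weights(y01)
  # -log p(y) = log(1 + exp(-s * eta)), s = +1 for y=1, -1 for y=0 (stable form)
  s <- ifelse(y01 == 1, 1, -1)
  loss <- sum(w * (log1p(exp(-abs(s * eta))) + pmax(-s * eta, 0)))
  loss + sum(weights^2) / (2 * C)
}

#' Serialize a readout to JSON
#' @param readout a \code{linear_readout}.
#' @param path output file path.
#' @export
save_readout <- function(readout, path) {
  obj <- readout
  obj$feature_mask <- if (!is.null(readout$feature_mask)) {
    list(mask = as.logical(readout$feature_mask$mask),
         dim = dim(readout$feature_mask$mask),
         kept_fraction = readout$feature_mask$kept_fraction)
  }
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a readout from JSON
#' @param path file written by \code{\link{save_readout}}.
#' @return a \code{linear_readout}.
#' @export
load_readout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$feature_mask)) {
    obj$feature_mask <- structure(
      list(mask = matrix(obj$feature_mask$mask, obj$feature_mask$dim[1],
                         obj$feature_mask$dim[2]),
           kept_fraction = obj$feature_mask$kept_fraction),
      class = "feature_mask")
  }
  structure(obj[c("weights", "intercept", "feature_means", "feature_scales",
                  "feature_mask", "classes", "C", "input_shape")],
            class = "linear_readout")
}
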