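#' @title Per-pixel Mann-Whitney class separation
#'
#' @description For every pixel the separation statistic measures how
#' stochastically larger or smaller its values are in one class versus the
#' other, via the normalised Mann-Whitney expression
#' \deqn{|U - (n_A n_B + 1)/2| / ((n_A n_B + 1)/2)}
#' with \code{U} the two-sided (symmetrised, midrank-tied) Mann-Whitney
#' statistic \code{max(U_A, U_B)}. Values lie in \code{[0, 1)} with maximum
#' \code{(n_A n_B - 1)/(n_A n_B + 1)} at complete separation, and are
#' invariant under swapping the class roles. Pixels with low separation are
#' noise and can be discarded before training.
#'
#' @name class_separation
#' @keywords internal
NULL

# midrank U statistic of class A (wins of A, ties half credit)
u_stat_a <- function(values_a, values_b) {
  n_a <- length(values_a)
  r <- rank(c(values_a, values_b))  # midranks for ties
  sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
}

#' Normalised Mann-Whitney separation of two samples
#'
#' @param values_a,values_b numeric vectors of per-class pixel values, each
#'   with at least one finite observation.
#' @return separation in \code{[0, (n_A n_B - 1)/(n_A n_B + 1)]}.
#' @examples
#' mann_whitney_separation(c(1, 2), c(3, 4)) # complete separation: 0.6
#' mann_whitney_separation(c(5, 5), c(5, 5)) # all tied: 0.2
#' @export
mann_whitney_separation <- function(values_a, values_b) {
  if (length(values_a) < 1 || length(values_b) < 1) stop("empty class sample")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b))) {
    stop("non-finite values")
  }
  nm <- length(values_a) * length(values_b)
  u_a <- u_stat_a(values_a, values_b)
  u <- max(u_a, nm - u_a)
  center <- (nm + 1) / 2
  abs(u - center) / center
}

#' Per-pixel separation map of a labelled sample set
#'
#' @param samples a \code{difference_samples} object whose metadata carries a
#'   class label (exactly two classes) for every sample, or a numeric matrix
#'   (samples x pixels) together with \code{labels}.
#' @param labels optional label vector when \code{samples} is a plain matrix.
#' @return object of class \code{separation_map}: list with \code{values}
#'   (matrix of separations, image-shaped when the shape is known),
#'   \code{n_A}, \code{n_B}.
#' @export
separation_map <- function(samples, labels = NULL) {
  if (inherits(samples, "difference_samples")) {
    labels <- samples$meta$label
    x <- samples$images
    shape <- samples$shape
  } else {
    x <- samples
    shape <- NULL
  }
  if (is.null(labels) || anyNA(labels)) stop("every sample needs a class label")
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("exactly two classes required, got: ",
                             paste(lev, collapse = ", "))
  ia <- labels == lev[1]
  n_a <- sum(ia); n_b <- sum(!ia)
  if (n_a < 2 || n_b < 2) stop("need >= 2 samples per class")
  nm <- n_a * n_b
  center <- (nm + 1) / 2
  # column-wise midrank U via one rank() per pixel
  vals <- apply(x, 2, function(col) {
    u_a <- sum(rank(col)[ia]) - n_a * (n_a + 1) / 2
    abs(max(u_a, nm - u_a) - center) / center
  })
  values <- if (!is.null(shape)) matrix(vals, shape[1], shape[2]) else
    matrix(vals, nrow = 1)
  structure(list(values = values, n_A = n_a, n_B = n_b),
            class = "separation_map")
}

#' @export
print.separation_map <- function(x, ...) {
  cat(sprintf("<separation_map> %dx%d px, n_A=%d n_B=%d, max=%.3f\n",
              nrow(x$values), ncol(x$values), x$n_A, x$n_B, max(x$values)))
  invisible(x)
}

#' Select the most class-separating pixels
#'
#' Keeps the \code{ceiling(keep_fraction * n_pixels)} pixels with the highest
#' separation (deterministic tie-break: row, then column, lexicographic).
#' Alternatively a hard separation threshold can be given.
#'
#' @param map a \code{separation_map}.
#' @param keep_fraction fraction of pixels to keep, in (0, 1].
#' @param threshold optional: keep pixels with separation >= threshold
#'   instead of a fixed fraction (overrides \code{keep_fraction}).
#' @return object of class \code{feature_mask}: list with logical matrix
#'   \code{mask} and \code{kept_fraction}.
#' @export
select_features <- function(map, keep_fraction = 1, threshold = NULL) {
  v <- map$values
  mask <- matrix(FALSE, nrow(v), ncol(v))
  if (!is.null(threshold)) {
    mask[v >= threshold] <- TRUE
  } else {
    if (keep_fraction <= 0 || keep_fraction > 1) {
      stop("keep_fraction must lie in (0, 1]")
    }
    n <- length(v)
    k <- ceiling(keep_fraction * n)
    rows <- row(v); cols <- col(v)
    ord <- order(-as.numeric(v), as.numeric(rows), as.numeric(cols))
    mask[ord[seq_len(k)]] <- TRUE
  }
  structure(list(mask = mask, kept_fraction = sum(mask) / length(mask)),
            class = "feature_mask")
}

#' Apply a feature mask to a sample set
#'
#' @param samples a \code{difference_samples} object.
#' @param feature_mask a \code{feature_mask} whose mask matches the sample
#'   shape.
#' @return numeric matrix (samples x kept features).
#' @export
apply_mask <- function(samples, feature_mask) {
  m <- feature_mask$mask
  if (!identical(dim(m), as.integer(samples$shape))) {
    stop("mask shape does not match sample shape")
  }
  samples$images[, as.logical(m), drop = FALSE]
}
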