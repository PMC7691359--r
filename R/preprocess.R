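#' @title Frame-stream preprocessing
#'
#' @description Raw free-run camera frames are turned into classification
#' samples in three steps: consecutive-frame background subtraction, the
#' overall perturbation statistic \code{P} (sum of squared pixel values of
#' the difference image), and an acceptance rule that keeps a frame when its
#' \code{P} exceeds the acceptance threshold \code{theta_P} while discarding
#' any frame that directly follows an accepted one (its difference image
#' would contain the previous particle's pattern with flipped sign).
#' Acceptance is evaluated at full camera resolution; downsampling is applied
#' afterwards, to accepted samples only.
#'
#' @name framestream_preprocess
#' @keywords internal
NULL

new_difference_samples <- function(images, shape, meta) {
  stopifnot(is.matrix(images), nrow(images) == nrow(meta),
            ncol(images) == prod(shape))
  structure(list(images = images, shape = as.integer(shape), meta = meta),
            class = "difference_samples")
}

#' @export
print.difference_samples <- function(x, ...) {
  cat(sprintf("<difference_samples> %d samples of %dx%d px", nrow(x$images),
              x$shape[1], x$shape[2]))
  if (!all(is.na(x$meta$label))) {
    cat(" |", paste(sprintf("%s:%d", names(table(x$meta$label)),
                            as.integer(table(x$meta$label))), collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' Subset difference samples by row index
#' @param samples a \code{difference_samples} object.
#' @param idx integer or logical index over samples.
#' @return a \code{difference_samples} object.
#' @export
subset_samples <- function(samples, idx) {
  new_difference_samples(samples$images[idx, , drop = FALSE], samples$shape,
                         samples$meta[idx, , drop = FALSE])
}

#' Concatenate difference-sample sets
#' @param ... \code{difference_samples} objects of identical shape.
#' @return a single \code{difference_samples} object.
#' @export
bind_samples <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) &&
      !inherits(xs[[1]], "difference_samples")) xs <- xs[[1]]
  shapes <- vapply(xs, function(x) paste(x$shape, collapse = "x"), "")
  if (length(unique(shapes)) != 1) stop("sample shapes differ: ",
                                        paste(unique(shapes), collapse = ", "))
  new_difference_samples(do.call(rbind, lapply(xs, `[[`, "images")),
                         xs[[1]]$shape,
                         do.call(rbind, lapply(xs, `[[`, "meta")))
}

#' Overall perturbation P of a difference image
#'
#' \code{P} is the sum of all squared pixel values of a background-subtracted
#' image; it measures how strongly a particle perturbs the illumination.
#'
#' @param image numeric matrix (or vector) of pixel differences.
#' @return non-negative scalar; zero iff the image is all-zero.
#' @examples
#' overall_perturbation(matrix(c(1, -2, 0, 3), 2)) # 14
#' @export
overall_perturbation <- function(image) {
  if (!all(is.finite(image))) stop("image contains non-finite entries")
  sum(as.numeric(image)^2)
}

#' Background subtraction by consecutive frame differencing
#'
#' Each frame has the previously acquired frame subtracted from it, after
#' promotion to double precision (8-bit integer input never wraps around).
#' The first frame of a stream has no predecessor and yields no sample.
#'
#' @param stream a \code{frame_stream}, or a plain list of numeric matrices.
#' @return a \code{difference_samples} object with one sample per frame
#'   \code{t >= 2}, carrying \code{frame_index}, \code{P}, \code{session_id}
#'   and (when the stream is labelled) the class label.
#' @export
background_subtract <- function(stream) {
  frames <- if (inherits(stream, "frame_stream")) stream$frames else stream
  if (length(frames) < 2) stop("need at least 2 frames to background-subtract")
  shp <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), shp)) stop("frame shape changes within the stream")
  }
  n <- length(frames) - 1L
  images <- matrix(0, nrow = n, ncol = prod(shp))
  prev <- as.numeric(frames[[1]])
  for (t in seq_len(n)) {
    cur <- as.numeric(frames[[t + 1L]])
    images[t, ] <- cur - prev
    prev <- cur
  }
  meta <- data.frame(
    frame_index = seq_len(n) + 1L,
    P = rowSums(images^2),
    session_id = if (inherits(stream, "frame_stream")) stream$session_id else NA_character_,
    label = if (inherits(stream, "frame_stream") && !is.null(stream$label))
      stream$label else NA_character_,
    stringsAsFactors = FALSE
  )
  new_difference_samples(images, shp, meta)
}

#' Acceptance decisions for an ordered P sequence
#'
#' Core rule on the perturbation sequence alone: sample \code{t} is accepted
#' iff \code{P_t > theta_P} (strictly) and sample \code{t - 1} was not
#' accepted. Used by both \code{\link{accept_frames}} and the calibration
#' curve builder.
#'
#' @param P numeric vector of perturbation values in acquisition order.
#' @param theta_P acceptance threshold (>= 0).
#' @return logical vector of acceptance flags.
#' @export
acceptance_flags <- function(P, theta_P) {
  stopifnot(theta_P >= 0)
  above <- P > theta_P
  acc <- logical(length(P))
  prev <- FALSE
  for (t in seq_along(P)) {
    acc[t] <- above[t] && !prev
    prev <- acc[t]
  }
  acc
}

#' Apply the acceptance threshold to difference samples
#'
#' @param samples a \code{difference_samples} object in acquisition order.
#' @param theta_P acceptance threshold on \code{P}.
#' @return list with \code{accepted} (a \code{difference_samples} subset, in
#'   order) and \code{decisions}, a data frame with one row per input sample
#'   (\code{frame_index}, \code{P}, \code{accepted}, \code{reason}); the
#'   reason is one of \code{above_threshold}, \code{below_threshold},
#'   \code{follows_accepted}.
#' @export
accept_frames <- function(samples, theta_P) {
  fi <- samples$meta$frame_index
  if (is.unsorted(fi, strictly = TRUE)) stop("samples are not in acquisition order")
  P <- samples$meta$P
  acc <- acceptance_flags(P, theta_P)
  above <- P > theta_P
  reason <- ifelse(acc, "above_threshold",
                   ifelse(above, "follows_accepted", "below_threshold"))
  decisions <- data.frame(frame_index = fi, P = P, accepted = acc,
                          reason = reason, stringsAsFactors = FALSE)
  list(accepted = subset_samples(samples, acc), decisions = decisions)
}

#' Block-mean downsampling
#'
#' Partitions the image into \code{factor x factor} blocks (zero-padding the
#' bottom/right edges up to a multiple of \code{factor}) and reduces each
#' block to its mean. A 508x632 frame at the standard factors 2, 5, 10, 20,
#' 40, 100, 400 yields 254x316, 102x127, 51x64, 26x32, 13x16, 6x7, 2x2
#' (rows x cols).
#'
#' @param image numeric matrix.
#' @param factor integer >= 1.
#' @return downsampled matrix of shape \code{ceiling(dim(image) / factor)}.
#' @export
downsample <- function(image, factor) {
  if (length(factor) != 1 || factor < 1 || factor != floor(factor)) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  nr <- nrow(image); nc <- ncol(image)
  nr_out <- ceiling(nr / factor); nc_out <- ceiling(nc / factor)
  padded <- matrix(0, nr_out * factor, nc_out * factor)
  padded[seq_len(nr), seq_len(nc)] <- image
  # sum over row blocks, then column blocks, then divide by block area
  rgrp <- rep(seq_len(nr_out), each = factor)
  cgrp <- rep(seq_len(nc_out), each = factor)
  rsum <- rowsum(padded, rgrp)
  csum <- t(rowsum(t(rsum), cgrp))
  dimnames(csum) <- NULL
  csum / factor^2
}

#' Downsample every image in a sample set
#'
#' \code{P} and acceptance are full-resolution quantities; the metadata
#' (including the recorded \code{P}) is carried over unchanged.
#'
#' @param samples a \code{difference_samples} object.
#' @param factor integer block size.
#' @return a \code{difference_samples} object at the reduced resolution.
#' @export
downsample_samples <- function(samples, factor) {
  if (factor == 1) return(samples)
  shp <- samples$shape
  out_shape <- c(ceiling(shp[1] / factor), ceiling(shp[2] / factor))
  images <- t(apply(samples$images, 1, function(v) {
    as.numeric(downsample(matrix(v, shp[1], shp[2]), factor))
  }))
  if (nrow(samples$images) == 1) images <- matrix(images, nrow = 1)
  new_difference_samples(images, out_shape, samples$meta)
}
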