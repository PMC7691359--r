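#' @title Acceptance-threshold calibration
#'
#' @description The particle ratio \code{R} is the fraction of acquired
#' frames accepted by the threshold rule. The calibration curve maps a grid
#' of thresholds \code{theta_P} to achieved ratios; picking the threshold
#' that realises a target \code{R} fixes the cytometer's field of view, and
#' doing so per configuration (e.g. with and without a diffraction grating)
#' makes classification performance comparable at equal sensitivity.
#'
#' @name acceptance_calibration
#' @keywords internal
NULL

# coerce input to a list of per-session P vectors (acquisition order)
as_P_sessions <- function(samples) {
  if (inherits(samples, "difference_samples")) {
    sid <- samples$meta$session_id
    if (all(is.na(sid))) return(list(samples$meta$P))
    return(split(samples$meta$P, factor(sid, levels = unique(sid))))
  }
  if (is.numeric(samples)) return(list(samples))
  samples  # already a list of P vectors
}

#' Default log-spaced threshold grid
#'
#' 200 log-spaced values between the 1st and 99.9th percentiles of the
#' observed perturbations.
#'
#' @param P numeric vector of observed perturbation values.
#' @param n grid size.
#' @return increasing numeric vector.
#' @export
default_threshold_grid <- function(P, n = 200) {
  q <- stats::quantile(P[P > 0], c(0.01, 0.999), names = FALSE)
  exp(seq(log(q[1]), log(q[2]), length.out = n))
}

#' Build the acceptance curve R(theta_P)
#'
#' Applies the full acceptance rule (strict threshold + discard of the
#' follower frame) at every grid value; sessions are processed separately so
#' the follower rule never crosses a session boundary.
#'
#' @param samples a \code{difference_samples} object, a numeric P vector, or
#'   a list of per-session P vectors.
#' @param threshold_grid increasing vector of theta_P values; defaults to
#'   \code{\link{default_threshold_grid}} of the pooled P.
#' @param tag configuration tag stored with the curve (e.g. "NDG"/"DG").
#' @return an \code{acceptance_curve}: data frame with \code{theta},
#'   \code{ratio}, \code{accepted}, \code{total} plus a \code{tag} attribute.
#' @export
build_curve <- function(samples, threshold_grid = NULL, tag = "NDG") {
  sessions <- as_P_sessions(samples)
  total <- sum(lengths(sessions))
  if (total == 0) stop("no samples to calibrate on")
  if (is.null(threshold_grid)) {
    threshold_grid <- default_threshold_grid(unlist(sessions))
  }
  if (length(threshold_grid) == 0) stop("empty threshold grid")
  if (is.unsorted(threshold_grid)) stop("threshold grid must be ascending")
  accepted <- vapply(threshold_grid, function(th) {
    sum(vapply(sessions, function(P) sum(acceptance_flags(P, th)), 0L))
  }, 0L)
  curve <- data.frame(theta = threshold_grid, ratio = accepted / total,
                      accepted = accepted, total = total)
  attr(curve, "tag") <- tag
  class(curve) <- c("acceptance_curve", "data.frame")
  curve
}

#' Threshold achieving a target particle ratio
#'
#' Among grid thresholds whose achieved ratio is \code{>= R_target}, returns
#' the one closest to the target; ties break toward the larger threshold
#' (fewer, cleaner samples). A single common threshold serves both classes.
#'
#' @param curve an \code{acceptance_curve}.
#' @param R_target target particle ratio in (0, max achieved ratio].
#' @return list with \code{theta} and \code{achieved_R}.
#' @export
threshold_for_ratio <- function(curve, R_target) {
  if (R_target <= 0) stop("R_target must be positive")
  ok <- which(curve$ratio >= R_target)
  if (length(ok) == 0) {
    stop(sprintf("R_target = %g unreachable; achievable range is [%g, %g]",
                 R_target, min(curve$ratio), max(curve$ratio)))
  }
  # ratio is non-increasing in theta: the largest qualifying theta is closest
  best <- ok[which.min(curve$ratio[ok] - R_target)]
  cand <- ok[curve$ratio[ok] == curve$ratio[best]]
  best <- cand[which.max(curve$theta[cand])]
  list(theta = curve$theta[best], achieved_R = curve$ratio[best])
}

#' Matched thresholds for two configurations at a common particle ratio
#'
#' With equal flow settings, a fixed particle ratio implies a fixed field of
#' view, so choosing per-configuration thresholds at the same \code{R} makes
#' e.g. the no-grating (NDG) and grating (DG) configurations comparable.
#'
#' @param curve_ndg,curve_dg \code{acceptance_curve}s of the two
#'   configurations.
#' @param R_target common target ratio.
#' @return list with per-configuration \code{theta} / \code{achieved_R}
#'   (named by curve tags).
#' @export
match_configurations <- function(curve_ndg, curve_dg, R_target) {
  res <- list(threshold_for_ratio(curve_ndg, R_target),
              threshold_for_ratio(curve_dg, R_target))
  names(res) <- c(attr(curve_ndg, "tag") %||% "NDG",
                  attr(curve_dg, "tag") %||% "DG")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an acceptance curve as CSV
#' @param curve an \code{acceptance_curve}.
#' @param path CSV path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  curve <- utils::read.csv(path)
  class(curve) <- c("acceptance_curve", "data.frame")
  curve
}
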