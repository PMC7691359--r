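#' Analytic Poisson sensitivity model
#'
#' The cytometer acquires frames in free-run mode, so a particle is imaged
#' only if it is at least partially inside the field of view (FoV) during an
#' exposure window. Treating particle passages as a Poisson process with rate
#' \code{R_f}, the number of particles captured by one exposure of duration
#' \code{tau} is Poisson with mean \code{R_f * (tau + FoV / v)}, where
#' \code{v} is the fluid velocity. These helpers implement that model, the
#' particle ratio \code{R = 1 - Pr(0)}, and its inversion to an implied FoV.
#'
#' @name sensitivity_model
#' @keywords internal
NULL

#' Particle flow rate from volumetric flux and concentration
#'
#' @param volumetric_flux_ml_min volumetric flux in ml/min (e.g. 0.2).
#' @param concentration_per_ml particle concentration in particles/ml.
#' @return expected particles per second passing the illuminated region.
#' @examples
#' particle_flow_rate(0.2, 1.6e4) # ~53.3 particles/s
#' @export
particle_flow_rate <- function(volumetric_flux_ml_min, concentration_per_ml) {
  stopifnot(is.numeric(volumetric_flux_ml_min), is.numeric(concentration_per_ml))
  if (volumetric_flux_ml_min < 0 || concentration_per_ml < 0) {
    stop("volumetric flux and concentration must be non-negative")
  }
  volumetric_flux_ml_min * concentration_per_ml / 60
}

#' Probability of capturing k particles in one exposure
#'
#' Poisson probability of \code{k} particle passages in the effective capture
#' window \code{tau + fov / v}.
#'
#' @param k non-negative integer particle count (vectorised).
#' @param tau exposure time in seconds.
#' @param fov field of view along the channel, metres.
#' @param v fluid velocity, m/s.
#' @param R_f particle flow rate, particles/s.
#' @return probability (same length as \code{k}).
#' @export
capture_probability <- function(k, tau, fov, v, R_f) {
  if (any(k < 0) || any(k != floor(k))) stop("k must be a non-negative integer")
  stopifnot(tau >= 0, fov >= 0, v >= 0, R_f >= 0)
  window <- tau + if (fov > 0) fov / v else 0
  stats::dpois(k, lambda = R_f * window)
}

#' Particle ratio implied by a field of view
#'
#' \code{R = 1 - Pr(0, tau + fov/v, R_f)}: the expected fraction of acquired
#' frames that contain at least one particle.
#'
#' @inheritParams capture_probability
#' @return ratio in [0, 1).
#' @export
ratio_from_fov <- function(fov, tau, v, R_f) {
  1 - capture_probability(0L, tau = tau, fov = fov, v = v, R_f = R_f)
}

#' Field of view implied by a particle ratio
#'
#' Inverts the zero-capture probability: \code{fov = -log(1 - R) * v / R_f -
#' tau * v}. The raw algebraic value can be negative when the exposure alone
#' already accounts for the requested ratio; the physical FoV is then clamped
#' to zero (with a warning) while the raw value is still returned.
#'
#' @param R target particle ratio in [0, 1).
#' @inheritParams capture_probability
#' @return list with elements \code{fov} (clamped, metres) and \code{fov_raw}.
#' @export
fov_from_ratio <- function(R, tau, v, R_f) {
  if (R < 0 || R >= 1) stop("R must lie in [0, 1)")
  if (R_f <= 0) stop("R_f must be positive to invert the ratio")
  raw <- -log(1 - R) * v / R_f - tau * v
  if (raw < 0) {
    warning("implied FoV is negative (exposure alone exceeds the capture window); clamping to 0")
  }
  list(fov = max(raw, 0), fov_raw = raw)
}

#' Fluid velocity from volumetric flux and channel cross-section
#'
#' Plug-flow approximation \code{v = Q / A}.
#'
#' @param volumetric_flux_ml_min flux in ml/min.
#' @param cross_section_m2 channel cross-sectional area in m^2
#'   (default 100 um x 100 um).
#' @return velocity in m/s.
#' @export
fluid_velocity <- function(volumetric_flux_ml_min, cross_section_m2 = 1e-8) {
  stopifnot(volumetric_flux_ml_min >= 0, cross_section_m2 > 0)
  (volumetric_flux_ml_min * 1e-6 / 60) / cross_section_m2
}
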