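#' @title Simulator configuration objects
#'
#' @description Plain validated S3 lists describing the synthetic lensless
#' holo-cytometer: optics and camera (\code{optical_config}), bead classes
#' (\code{bead_class}), flow (\code{flow_config}), acquisition timing
#' (\code{acquisition_config}) and the per-session drift model
#' (\code{session_drift_model}). All lengths are metres, times seconds.
#'
#' @name synthetic_holocytometer_config
#' @keywords internal
NULL

#' Optical and camera configuration
#'
#' @param wavelength laser wavelength (default HeNe, 632.8 nm).
#' @param pinhole_diameter pinhole diameter (default 25 um).
#' @param source_to_channel_distance pinhole-to-channel distance; sets the
#'   divergent-beam (Airy) envelope scale at the channel plane.
#' @param channel_to_sensor_distance propagation distance from the channel
#'   to the sensor.
#' @param sensor_shape integer (rows, cols) of the camera (default 508x632).
#' @param pixel_pitch camera pixel pitch (default 4.8 um).
#' @param simulation_grid_oversampling integer >= 1; the optical field is
#'   simulated on a grid this many times finer than the pixel pitch, then
#'   block-binned to camera pixels.
#' @param refractive_index_bead,refractive_index_medium bead (PMMA, 1.49)
#'   and medium (water, 1.33) refractive indices.
#' @param grating_enabled interpose the double-axis diffraction grating.
#' @param grating_period grating line period (default 1.88 um).
#' @param grating_amplitude amplitude transmission factor of the grating
#'   (< 1: the grating attenuates the beam).
#' @param grating_phase_depth phase modulation depth of the sinusoidal
#'   grating profile, radians.
#' @param propagation \code{"angular_spectrum"} (exact scalar free-space
#'   propagation) or \code{"parametric"} (fast analytic ring template, for
#'   quick tests; satisfies the same monotone-attenuation contract).
#' @param propagation_pad zero-padding factor of the angular-spectrum
#'   transform; larger pads admit longer propagation distances on a given
#'   grid.
#' @param photon_budget expected photon count at unit relative intensity;
#'   controls Poisson shot noise.
#' @param read_noise_sd additive Gaussian read noise, in 8-bit counts.
#' @param saturation relative intensity mapped to full scale (255); > 1
#'   leaves headroom above the unperturbed beam peak.
#' @return an \code{optical_config} object.
#' @export
optical_config <- function(wavelength = 632.8e-9,
                           pinhole_diameter = 25e-6,
                           source_to_channel_distance = 50e-3,
                           channel_to_sensor_distance = 2e-3,
                           sensor_shape = c(508L, 632L),
                           pixel_pitch = 4.8e-6,
                           simulation_grid_oversampling = 1L,
                           refractive_index_bead = 1.49,
                           refractive_index_medium = 1.33,
                           grating_enabled = FALSE,
                           grating_period = 1.88e-6,
                           grating_amplitude = 0.7,
                           grating_phase_depth = pi / 2,
                           propagation = c("angular_spectrum", "parametric"),
                           propagation_pad = 2L,
                           photon_budget = 20000,
                           read_noise_sd = 0.5,
                           saturation = 1.2) {
  propagation <- match.arg(propagation)
  lengths <- c(wavelength, pinhole_diameter, source_to_channel_distance,
               channel_to_sensor_distance, pixel_pitch, grating_period)
  if (any(lengths <= 0)) stop("all lengths must be positive")
  if (simulation_grid_oversampling < 1 ||
      simulation_grid_oversampling != floor(simulation_grid_oversampling)) {
    stop("simulation_grid_oversampling must be an integer >= 1")
  }
  if (length(sensor_shape) != 2 || any(sensor_shape < 2)) {
    stop("sensor_shape must be (rows, cols), each >= 2")
  }
  structure(list(
    wavelength = wavelength, pinhole_diameter = pinhole_diameter,
    source_to_channel_distance = source_to_channel_distance,
    channel_to_sensor_distance = channel_to_sensor_distance,
    sensor_shape = as.integer(sensor_shape), pixel_pitch = pixel_pitch,
    simulation_grid_oversampling = as.integer(simulation_grid_oversampling),
    refractive_index_bead = refractive_index_bead,
    refractive_index_medium = refractive_index_medium,
    grating_enabled = isTRUE(grating_enabled),
    grating_period = grating_period, grating_amplitude = grating_amplitude,
    grating_phase_depth = grating_phase_depth, propagation = propagation,
    propagation_pad = max(1L, as.integer(propagation_pad)),
    photon_budget = photon_budget, read_noise_sd = read_noise_sd,
    saturation = saturation
  ), class = "optical_config")
}

#' Desk-scale optical preset
#'
#' A reduced 52x64-pixel sensor with a 5 mm source distance (so the Airy
#' envelope's first zero, ~154 um, matches the half-width of the 307 um
#' sensor window) and a 1.5 mm channel-to-sensor distance that respects the
#' angular-spectrum sampling criterion on the oversampled grid. Used by the
#' test-suite and acceptance experiments so full sessions stay cheap; all
#' parameters remain overridable.
#'
#' @param ... overrides passed to \code{\link{optical_config}}.
#' @export
desk_optical_config <- function(...) {
  defaults <- list(sensor_shape = c(52L, 64L),
                   source_to_channel_distance = 5e-3,
                   channel_to_sensor_distance = 1.5e-3,
                   simulation_grid_oversampling = 2L)
  args <- utils::modifyList(defaults, list(...))
  do.call(optical_config, args)
}

#' Bead class description
#'
#' @param label class id, "A" or "B".
#' @param mean_diameter mean bead diameter (m).
#' @param diameter_sd nominal standard deviation of the diameter (m).
#' @param concentration_per_ml particle concentration, particles/ml.
#' @return a \code{bead_class} object.
#' @export
bead_class <- function(label, mean_diameter, diameter_sd,
                       concentration_per_ml) {
  stopifnot(mean_diameter > 0, diameter_sd >= 0, concentration_per_ml >= 0)
  structure(list(label = as.character(label), mean_diameter = mean_diameter,
                 diameter_sd = diameter_sd,
                 concentration_per_ml = concentration_per_ml),
            class = "bead_class")
}

#' @rdname bead_class
#' @param ... field overrides.
#' @export
bead_class_A <- function(...) {
  do.call(bead_class, utils::modifyList(
    list(label = "A", mean_diameter = 15.2e-6, diameter_sd = 0.5e-6,
         concentration_per_ml = 1.6e4), list(...)))
}

#' @rdname bead_class
#' @export
bead_class_B <- function(...) {
  do.call(bead_class, utils::modifyList(
    list(label = "B", mean_diameter = 18.6e-6, diameter_sd = 0.6e-6,
         concentration_per_ml = 0.91e4), list(...)))
}

#' Flow configuration
#'
#' @param volumetric_flux_ml_min pump rate in ml/min (default 0.2).
#' @param channel_side_m microfluidic channel side length; the channel cross
#'   section is square (default 100 um x 100 um).
#' @return a \code{flow_config} with derived plug-flow velocity \code{v}.
#' @export
flow_config <- function(volumetric_flux_ml_min = 0.2, channel_side_m = 100e-6) {
  stopifnot(volumetric_flux_ml_min > 0, channel_side_m > 0)
  area <- channel_side_m^2
  structure(list(volumetric_flux_ml_min = volumetric_flux_ml_min,
                 channel_side_m = channel_side_m,
                 cross_section_m2 = area,
                 v = fluid_velocity(volumetric_flux_ml_min, area)),
            class = "flow_config")
}

#' Acquisition configuration
#'
#' @param frame_rate frames per second (default 138, free-run).
#' @param exposure_time exposure per frame, seconds (default 29 us); must be
#'   shorter than the frame period.
#' @param session_duration length of one measurement session, seconds.
#' @return an \code{acquisition_config}.
#' @export
acquisition_config <- function(frame_rate = 138, exposure_time = 29e-6,
                               session_duration = 120) {
  stopifnot(frame_rate > 0, session_duration > 0)
  if (exposure_time >= 1 / frame_rate) {
    stop("exposure_time must be shorter than the frame period")
  }
  structure(list(frame_rate = frame_rate, exposure_time = exposure_time,
                 session_duration = session_duration,
                 n_frames = as.integer(round(frame_rate * session_duration))),
            class = "acquisition_config")
}

#' Per-session drift model
#'
#' Between measurement sessions the illumination drifts: the beam centre
#' moves by a random pixel offset and the overall intensity is rescaled;
#' within a session the intensity creeps slowly. When
#' \code{drift_class_correlation > 0} the per-session drift additionally
#' receives a displacement in a class-dependent direction, injecting
#' measurement bias (at 1, the displacement has the full stated magnitude;
#' the label-independent random component is always present).
#'
#' @param beam_center_sd_px per-axis SD of the per-session beam-centre
#'   offset, camera pixels.
#' @param beam_velocity_sd_px per-axis SD of the slow within-session beam
#'   drift velocity, camera pixels per frame. The moving background leaves a
#'   gradient-shaped residual in every difference image - the session
#'   fingerprint that survives background subtraction and biases
#'   conventional cross-validation.
#' @param intensity_log_sd SD of the per-session log intensity scale.
#' @param within_session_drift_rate fractional intensity change per frame.
#' @param drift_class_correlation in [0, 1]; 0 = drift independent of class.
#' @param bias_offset_px magnitude of the class-dependent beam displacement
#'   along the channel at correlation 1 (class A +, class B -).
#' @param bias_log_intensity class-dependent log-intensity displacement at
#'   correlation 1.
#' @return a \code{session_drift_model}.
#' @export
session_drift_model <- function(beam_center_sd_px = 1.5,
                                beam_velocity_sd_px = 5e-4,
                                intensity_log_sd = 0.05,
                                within_session_drift_rate = 2e-5,
                                drift_class_correlation = 0,
                                bias_offset_px = 8,
                                bias_log_intensity = 0.25) {
  if (drift_class_correlation < 0 || drift_class_correlation > 1) {
    stop("drift_class_correlation must lie in [0, 1]")
  }
  stopifnot(beam_center_sd_px >= 0, beam_velocity_sd_px >= 0,
            intensity_log_sd >= 0)
  structure(list(beam_center_sd_px = beam_center_sd_px,
                 beam_velocity_sd_px = beam_velocity_sd_px,
                 intensity_log_sd = intensity_log_sd,
                 within_session_drift_rate = within_session_drift_rate,
                 drift_class_correlation = drift_class_correlation,
                 bias_offset_px = bias_offset_px,
                 bias_log_intensity = bias_log_intensity),
            class = "session_drift_model")
}

#' Draw one session's drift state
#'
#' The label-independent random drift is always present. The class-dependent
#' bias displacement acts along a drift direction that is itself a slow
#' random property of the acquisition epoch (one draw per session pair in
#' the intertwined protocol): within an epoch the two classes are displaced
#' in opposite directions (scaled by \code{drift_class_correlation}), which
#' makes the bias fully learnable from samples measured in that epoch but
#' useless across epochs - exactly the structure that fools conventional
#' cross-validation while session-held-out testing stays at chance.
#'
#' @param model a \code{session_drift_model}.
#' @param class_sign +1 for class A, -1 for class B (sign of the
#'   class-dependent bias displacement).
#' @param bias_direction optional epoch drift direction from
#'   \code{\link{draw_bias_direction}}; drawn fresh when NULL.
#' @return a \code{drift_state}: beam centre offset (pixels, 2-vector),
#'   intensity scale (> 0), within-session drift rate.
#' @export
draw_drift_state <- function(model, class_sign = 0, bias_direction = NULL) {
  corr <- model$drift_class_correlation
  if (is.null(bias_direction)) bias_direction <- draw_bias_direction()
  offset <- stats::rnorm(2, sd = model$beam_center_sd_px) +
    corr * class_sign * model$bias_offset_px * bias_direction$offset
  velocity <- stats::rnorm(2, sd = model$beam_velocity_sd_px)
  scale <- exp(stats::rnorm(1, sd = model$intensity_log_sd) +
                 corr * class_sign * model$bias_log_intensity *
                   bias_direction$intensity)
  structure(list(beam_center_offset = offset, beam_velocity = velocity,
                 intensity_scale = scale,
                 within_session_drift_rate = model$within_session_drift_rate),
            class = "drift_state")
}

#' Draw an epoch drift direction for the bias displacement
#'
#' @return list with a unit 2-vector \code{offset} and an intensity sign.
#' @export
draw_bias_direction <- function() {
  u <- stats::rnorm(2)
  list(offset = u / sqrt(sum(u^2)), intensity = sample(c(-1, 1), 1))
}

#' A neutral (no-drift) state
#' @export
neutral_drift_state <- function() {
  structure(list(beam_center_offset = c(0, 0), beam_velocity = c(0, 0),
                 intensity_scale = 1,
                 within_session_drift_rate = 0), class = "drift_state")
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# counter-based child seed: adding sessions never reshuffles earlier ones
child_seed <- function(seed, index) {
  (as.double(seed %% 100000L) * 16561 + 97 * index) %% 2147483647
}
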