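#' @title Synthetic holo-cytometer frame streams
#'
#' @description Emulates free-run acquisition on the lensless cytometer:
#' most frames contain only the (slowly drifting) background illumination;
#' particle passages are a Poisson process with rate \code{R_f = flux x
#' concentration}, and a particle is captured when it is inside the sensor
#' window during the exposure. Captured beads appear at the position implied
#' by their arrival time, so positions are uniform over the illuminated span
#' and the interference signal weakens as the bead moves away from the beam
#' centre.
#'
#' @name synthetic_holocytometer
#' @keywords internal
NULL

# relative pre-noise sensor intensity for a set of particles
# particles: data.frame(x_m, diameter_m); empty for background.
# blur_length_m > 0 averages the intensity over the within-exposure particle
# travel (motion blur), in n_blur sub-steps.
sensor_intensity <- function(optical, drift_state, particles = NULL,
                             background_field = NULL, blur_length_m = 0,
                             n_blur = 3L) {
  if (!is.null(particles) && nrow(particles) > 0 && blur_length_m > 0) {
    offs <- seq(-blur_length_m / 2, blur_length_m / 2, length.out = n_blur)
    acc <- NULL
    for (o in offs) {
      p <- particles
      p$x_m <- p$x_m + o
      cur <- sensor_intensity(optical, drift_state, p, background_field,
                              blur_length_m = 0)
      acc <- if (is.null(acc)) cur else acc + cur
    }
    return(acc / n_blur)
  }
  if (optical$propagation == "parametric") {
    return(parametric_intensity(optical, drift_state, particles))
  }
  grid <- simulation_grid(optical)
  center_m <- drift_state$beam_center_offset * optical$pixel_pitch
  field <- if (is.null(background_field)) {
    illumination_field(optical, grid, center_m)
  } else {
    background_field
  }
  if (!is.null(particles) && nrow(particles) > 0) {
    for (q in seq_len(nrow(particles))) {
      field <- field * bead_phase_mask(optical, grid, particles$x_m[q],
                                       particles$diameter_m[q])
    }
  }
  if (optical$grating_enabled) field <- field * grating_transmission(optical, grid)
  u <- angular_spectrum_propagate(field, grid$dx,
                                  optical$channel_to_sensor_distance,
                                  optical$wavelength,
                                  pad = optical$propagation_pad %||% 2L)
  bin_to_pixels(Mod(u)^2, optical) * drift_state$intensity_scale
}

# fast analytic stand-in: Airy background envelope plus a chirped ring
# template whose amplitude scales with bead volume and with the local
# illumination intensity (same monotone-attenuation contract as the wave
# model)
parametric_intensity <- function(optical, drift_state, particles = NULL) {
  shp <- optical$sensor_shape
  pitch <- optical$pixel_pitch
  lam <- optical$wavelength
  zs <- optical$source_to_channel_distance + optical$channel_to_sensor_distance
  center_m <- drift_state$beam_center_offset * pitch
  x0 <- (seq_len(shp[2]) - (shp[2] + 1) / 2) * pitch  # sensor coords
  y0 <- (seq_len(shp[1]) - (shp[1] + 1) / 2) * pitch
  r <- sqrt(outer((y0 - center_m[2])^2, (x0 - center_m[1])^2, "+"))
  env <- airy_amplitude(pi * optical$pinhole_diameter * r / (lam * zs))^2
  att <- if (optical$grating_enabled) optical$grating_amplitude^2 else 1
  intensity <- env * att
  if (!is.null(particles) && nrow(particles) > 0) {
    z2 <- optical$channel_to_sensor_distance
    for (q in seq_len(nrow(particles))) {
      d <- particles$diameter_m[q]
      if (d <= 0) next
      rp <- sqrt(outer(y0^2, (x0 - particles$x_m[q])^2, "+"))
      envp <- airy_amplitude(pi * optical$pinhole_diameter *
                               abs(particles$x_m[q] - center_m[1]) / (lam * zs))^2
      amp <- 0.35 * (d / 15.2e-6)^3 * envp * att
      ring <- exp(-(rp / (4 * d))^2) * cos(pi * rp^2 / (lam * z2))
      intensity <- intensity + amp * ring
    }
    intensity <- pmax(intensity, 0)
  }
  intensity * drift_state$intensity_scale
}

# per-frame multiplicative intensity drift within a session
frame_drift_scale <- function(drift_state, frame_index) {
  1 + drift_state$within_session_drift_rate * frame_index
}

#' Simulate one background-only frame
#'
#' @param optical an \code{optical_config}.
#' @param drift_state a \code{drift_state} (see
#'   \code{\link{draw_drift_state}}).
#' @param seed optional integer; fixes the shot/read noise draw.
#' @param frame_index frame number within the session (drives the slow
#'   within-session intensity drift).
#' @return integer matrix of 8-bit camera counts, \code{sensor_shape}.
#' @export
simulate_background <- function(optical, drift_state = neutral_drift_state(),
                                seed = NULL, frame_index = 0) {
  st <- drift_state
  st$beam_center_offset <- st$beam_center_offset +
    (st$beam_velocity %||% c(0, 0)) * frame_index
  intensity <- sensor_intensity(optical, st) *
    frame_drift_scale(drift_state, frame_index)
  with_seed(seed, camera_sample(intensity, optical))
}

#' Simulate one frame containing a bead
#'
#' The bead is a thin phase object at axial position \code{x_m} along the
#' channel (0 = sensor centre), multiplied into the illumination at the
#' channel plane and propagated to the sensor. Signal strength decays with
#' the bead's distance from the beam centre through the illumination
#' envelope.
#'
#' @param optical an \code{optical_config}.
#' @param x_m axial bead position along the channel, metres; must lie within
#'   the illuminated sensor window.
#' @param diameter_m bead diameter draw (0 gives a background frame).
#' @param drift_state a \code{drift_state}.
#' @param seed optional noise seed.
#' @param frame_index frame number within the session.
#' @param channel_depth_m microfluidic channel depth; beads larger than the
#'   channel are rejected.
#' @param blur_length_m within-exposure travel of the bead (motion blur;
#'   \code{v * tau} when simulating a flowing session).
#' @return integer matrix of 8-bit camera counts.
#' @export
simulate_particle_frame <- function(optical, x_m, diameter_m,
                                    drift_state = neutral_drift_state(),
                                    seed = NULL, frame_index = 0,
                                    channel_depth_m = 100e-6,
                                    blur_length_m = 0) {
  if (diameter_m < 0) stop("diameter must be non-negative")
  if (diameter_m > channel_depth_m) {
    stop("bead diameter exceeds the channel depth")
  }
  half_window <- optical$sensor_shape[2] * optical$pixel_pitch / 2
  if (abs(x_m) > half_window + diameter_m / 2) {
    stop("bead position lies outside the illuminated sensor window")
  }
  particles <- data.frame(x_m = x_m, diameter_m = diameter_m)
  intensity <- sensor_intensity(optical, drift_state, particles,
                                blur_length_m = blur_length_m) *
    frame_drift_scale(drift_state, frame_index)
  with_seed(seed, camera_sample(intensity, optical))
}

#' Simulate a full free-run measurement session
#'
#' Particle arrivals are a Poisson process with rate \code{R_f}; a particle
#' is present in a frame when its transit interval overlaps the exposure
#' window, reproducing the analytic capture model
#' \code{Pr(k, tau + W/v, R_f)} for the sensor window span \code{W}.
#'
#' @param bead a \code{bead_class}.
#' @param optical an \code{optical_config}.
#' @param flow a \code{flow_config}.
#' @param acquisition an \code{acquisition_config}.
#' @param drift a \code{drift_state}, or a \code{session_drift_model} from
#'   which one state is drawn.
#' @param seed integer session seed (drives drift draw, arrivals, diameters
#'   and noise).
#' @param session_id character id stored with the stream.
#' @return a \code{frame_stream}: list with \code{frames} (list of integer
#'   matrices), \code{annotations} (ground truth per captured particle:
#'   frame, arrival time, position, diameter), the drift state, label and
#'   configs.
#' @export
simulate_session <- function(bead, optical, flow, acquisition,
                             drift = neutral_drift_state(), seed = NULL,
                             session_id = paste0("S_", bead$label)) {
  with_seed(seed, {
    class_sign <- if (identical(bead$label, "A")) 1 else -1
    state <- if (inherits(drift, "session_drift_model")) {
      draw_drift_state(drift, class_sign)
    } else drift
    n_frames <- acquisition$n_frames
    tau <- acquisition$exposure_time
    period <- 1 / acquisition$frame_rate
    W <- optical$sensor_shape[2] * optical$pixel_pitch
    v <- flow$v
    R_f <- particle_flow_rate(flow$volumetric_flux_ml_min,
                              bead$concentration_per_ml)
    t_total <- n_frames * period
    # arrivals (time the particle enters the window) on [-W/v, t_total]
    span <- t_total + W / v
    n_arr <- stats::rpois(1, R_f * span)
    t_in <- sort(stats::runif(n_arr, min = -W / v, max = t_total))
    d_arr <- pmax(stats::rnorm(n_arr, bead$mean_diameter, bead$diameter_sd),
                  optical$pixel_pitch)
    # frame capture: t_in in (t_start - W/v, t_start + tau]
    t_start <- (seq_len(n_frames) - 1) * period
    ann <- NULL
    if (n_arr > 0) {
      hits <- lapply(seq_len(n_frames), function(s) {
        which(t_in > t_start[s] - W / v & t_in <= t_start[s] + tau)
      })
      rows <- which(lengths(hits) > 0)
      if (length(rows) > 0) {
        ann <- do.call(rbind, lapply(rows, function(s) {
          idx <- hits[[s]]
          t_mid <- t_start[s] + tau / 2
          x <- -W / 2 + v * (t_mid - t_in[idx])
          data.frame(frame = s, t_in = t_in[idx],
                     x_m = pmin(pmax(x, -W / 2), W / 2),
                     diameter_m = d_arr[idx])
        }))
      }
    }
    if (is.null(ann)) {
      ann <- data.frame(frame = integer(), t_in = numeric(),
                        x_m = numeric(), diameter_m = numeric())
    }
    # the unperturbed beam translates rigidly under beam drift: compute the
    # background intensity once (pre-binning) and shift it per frame
    wave <- optical$propagation == "angular_spectrum"
    os <- if (wave) optical$simulation_grid_oversampling else 1L
    bg0 <- if (wave) {
      grid <- simulation_grid(optical)
      u <- angular_spectrum_propagate(
        illumination_field(optical, grid,
                           state$beam_center_offset * optical$pixel_pitch),
        grid$dx, optical$channel_to_sensor_distance, optical$wavelength,
        pad = optical$propagation_pad %||% 2L)
      Mod(u)^2
    } else {
      parametric_intensity(optical, state) / state$intensity_scale
    }
    vel <- state$beam_velocity %||% c(0, 0)
    blur <- v * tau  # within-exposure particle travel (motion blur)
    frames <- vector("list", n_frames)
    for (s in seq_len(n_frames)) {
      shifted <- shift_image(bg0, vel[2] * s * os, vel[1] * s * os)
      base <- if (wave) {
        bin_to_pixels(shifted, optical) * state$intensity_scale
      } else {
        shifted * state$intensity_scale
      }
      part <- ann[ann$frame == s, , drop = FALSE]
      if (nrow(part) > 0) {
        # particle perturbation computed exactly at the drifted beam centre;
        # added onto the same translated background used for empty frames so
        # consecutive-frame differences carry only physical drift residuals
        state_t <- state
        state_t$beam_center_offset <- state$beam_center_offset + vel * s
        pert <- sensor_intensity(optical, state_t, part,
                                 blur_length_m = blur) -
          sensor_intensity(optical, state_t)
        base <- pmax(base + pert, 0)
      }
      frames[[s]] <- camera_sample(base * frame_drift_scale(state, s), optical)
    }
    structure(list(frames = frames, session_id = session_id,
                   label = bead$label, drift_state = state, seed = seed,
                   annotations = ann, optical = optical, flow = flow,
                   acquisition = acquisition, n_frames = n_frames),
              class = "frame_stream")
  })
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %s: %d frames %dx%d, class %s, %d particle captures\n",
              x$session_id, x$n_frames, x$optical$sensor_shape[1],
              x$optical$sensor_shape[2], x$label, nrow(x$annotations)))
  invisible(x)
}

#' Plan an intertwined two-class measurement campaign
#'
#' Sessions alternate strictly A1, B1, A2, B2, ..., each with an
#' independently drawn drift state, so slow drift decorrelates from the
#' class labels. With \code{drift_class_correlation > 0} the drift states
#' additionally receive a class-dependent displacement (measurement-bias
#' injection). The plan is lightweight; frames are materialised per session
#' with \code{\link{materialize_session}} so a full campaign never has to be
#' held in memory.
#'
#' @param N_s sessions per class (>= 2; nested validation needs >= 3).
#' @param bead_a,bead_b the two \code{bead_class} objects.
#' @param optical,flow,acquisition shared configuration objects.
#' @param drift_model a \code{session_drift_model}.
#' @param seed master seed; per-session seeds are derived by a counter
#'   scheme so adding sessions never reshuffles earlier ones.
#' @return a \code{session_plan}: list of session entries (index, pair,
#'   label, seed, drift_state) plus the shared configs.
#' @export
make_intertwined_dataset <- function(N_s, bead_a = bead_class_A(),
                                     bead_b = bead_class_B(),
                                     optical = desk_optical_config(),
                                     flow = flow_config(),
                                     acquisition = acquisition_config(),
                                     drift_model = session_drift_model(),
                                     seed = 1) {
  if (N_s < 2) stop("N_s must be >= 2 (nested validation undefined below that)")
  entries <- vector("list", 2L * N_s)
  with_seed(seed, {
    for (n in seq_len(N_s)) {
      dir_n <- draw_bias_direction()  # epoch drift direction, one per pair
      for (cls in c("A", "B")) {
        idx <- 2L * (n - 1L) + if (cls == "A") 1L else 2L
        sign <- if (cls == "A") 1 else -1
        entries[[idx]] <- list(
          index = idx, pair = n, label = cls,
          bead = if (cls == "A") bead_a else bead_b,
          seed = child_seed(seed, idx),
          drift_state = draw_drift_state(drift_model, sign, dir_n),
          session_id = sprintf("session_%02d_%s", idx, cls))
      }
    }
  })
  structure(list(entries = entries, N_s = as.integer(N_s), optical = optical,
                 flow = flow, acquisition = acquisition,
                 drift_model = drift_model, seed = seed),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %d sessions (%d per class), %d frames each\n",
              length(x$entries), x$N_s, x$acquisition$n_frames))
  invisible(x)
}

#' Materialise the frames of one planned session
#'
#' @param plan a \code{session_plan}.
#' @param index session index in chronological order (1..2*N_s).
#' @return a \code{frame_stream}.
#' @export
materialize_session <- function(plan, index) {
  e <- plan$entries[[index]]
  simulate_session(e$bead, plan$optical, plan$flow, plan$acquisition,
                   drift = e$drift_state, seed = e$seed,
                   session_id = e$session_id)
}
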