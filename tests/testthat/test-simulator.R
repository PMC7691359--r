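# synthetic holo-cytometer: propagation, frames, sessions, campaigns

test_that("configuration objects validate their invariants", {
  expect_error(optical_config(wavelength = -1), "positive")
  expect_error(optical_config(simulation_grid_oversampling = 0.5), "integer")
  expect_error(bead_class("A", -1e-6, 0, 1), "mean_diameter")
  expect_error(acquisition_config(frame_rate = 138, exposure_time = 0.01),
               "frame period")
  expect_error(session_drift_model(drift_class_correlation = 2), "0, 1")
  acq <- acquisition_config(session_duration = 2)
  expect_equal(acq$n_frames, 276L)
  fl <- flow_config()
  expect_equal(fl$v, 0.2e-6 / 60 / 1e-8)  # plug flow: Q / A
})

test_that("angular spectrum propagation conserves energy (Parseval)", {
  # smooth band-limited field on a small unpadded grid: conservation is
  # limited only by round-off
  g <- expand.grid(y = seq(-15.5, 15.5), x = seq(-15.5, 15.5))
  dx <- 2e-6
  field <- matrix(exp(-((g$x^2 + g$y^2) * dx^2) / (2 * (8e-6)^2)), 32, 32)
  for (dz in c(10e-6, 50e-6)) {
    out <- angular_spectrum_propagate(field, dx, dz, 632.8e-9, pad = 1)
    expect_equal(sum(Mod(out)^2), sum(Mod(field)^2), tolerance = 1e-6)
  }
  # identity at dz = 0
  expect_identical(angular_spectrum_propagate(field, dx, 0, 632.8e-9), field)
  # the sampling criterion rejects distances the grid cannot represent
  expect_error(angular_spectrum_propagate(field, dx, 1, 632.8e-9),
               "sampling criterion")
})

test_that("background frames are deterministic and scale with intensity", {
  opt <- tiny_optical()
  st <- neutral_drift_state()
  f1 <- simulate_background(opt, st, seed = 42)
  f2 <- simulate_background(opt, st, seed = 42)
  expect_identical(f1, f2)
  expect_identical(dim(f1), as.integer(opt$sensor_shape))
  expect_true(all(f1 >= 0 & f1 <= 255))
  # doubling the drift intensity doubles the pre-quantisation intensity
  st2 <- st; st2$intensity_scale <- 2
  i1 <- holocyto:::sensor_intensity(opt, st)
  i2 <- holocyto:::sensor_intensity(opt, st2)
  expect_equal(i2, 2 * i1, tolerance = 1e-12)
})

test_that("particle frames attenuate away from the beam and respect guards", {
  opt <- tiny_optical()
  st <- neutral_drift_state()
  # diameter 0 reduces to the background frame (same noise seed)
  expect_identical(simulate_particle_frame(opt, 0, 0, st, seed = 7),
                   simulate_background(opt, st, seed = 7))
  expect_error(simulate_particle_frame(opt, 0, 200e-6, st), "channel depth")
  expect_error(simulate_particle_frame(opt, 1, 10e-6, st), "outside")
  # noiseless expected P is non-increasing over 20 positions, averaged over
  # 50 draws of diameter and sub-pixel placement (monotone attenuation
  # through the beam envelope; the jitter integrates out pixel-sampling
  # ripple, which is not part of the expectation over arrivals)
  optd <- desk_optical_config()
  bgd <- holocyto:::sensor_intensity(optd, st)
  half <- optd$sensor_shape[2] * optd$pixel_pitch / 2
  xs <- seq(0, 0.9 * half, length.out = 20)
  holocyto:::with_seed(13, {
    draws <- data.frame(d = rnorm(50, 15.2e-6, 0.5e-6),
                        dx = runif(50, -optd$pixel_pitch / 2, optd$pixel_pitch / 2))
    meanP <- vapply(xs, function(x) {
      mean(vapply(seq_len(nrow(draws)), function(i) {
        I <- holocyto:::sensor_intensity(
          optd, st, data.frame(x_m = x + draws$dx[i], diameter_m = draws$d[i]))
        overall_perturbation(I - bgd)
      }, 0))
    }, 0)
  })
  expect_true(all(diff(meanP) < 1e-8 * meanP[1]))
  # the parametric fast mode obeys the same contract
  optp <- parametric_optical(sensor_shape = c(24L, 32L))
  bgp <- holocyto:::sensor_intensity(optp, st)
  meanPp <- vapply(xs, function(x) {
    I <- holocyto:::sensor_intensity(optp, st, data.frame(x_m = x, diameter_m = 15.2e-6))
    overall_perturbation(I - bgp)
  }, 0)
  expect_true(all(diff(meanPp) < 1e-8 * meanPp[1]))
})

test_that("larger beads perturb the illumination more, on average", {
  opt <- desk_optical_config()
  st <- neutral_drift_state()
  holocyto:::with_seed(42, {
    mc <- function(dmean, dsd, n = 30) {
      vapply(seq_len(n), function(i) {
        d <- max(rnorm(1, dmean, dsd), 5e-6)
        f <- simulate_particle_frame(opt, 0, d, st)
        b <- simulate_background(opt, st)
        overall_perturbation(matrix(as.numeric(f) - as.numeric(b), nrow(f)))
      }, 0)
    }
    pa <- mc(15.2e-6, 0.5e-6)
    pb <- mc(18.6e-6, 0.6e-6)
  })
  expect_gt(mean(pb), mean(pa))
})

test_that("sessions reproduce the Poisson capture statistics", {
  opt <- parametric_optical()
  fl <- flow_config()
  acq <- acquisition_config(session_duration = 1500 / 138)
  bead <- bead_class_A(concentration_per_ml = 4e4)
  s <- simulate_session(bead, opt, fl, acq, seed = 19)
  s2 <- simulate_session(bead, opt, fl, acq, seed = 19)
  expect_identical(s$annotations, s2$annotations)
  expect_identical(s$frames[[5]], s2$frames[[5]])
  # empirical particle-frame fraction vs the analytic model, 3 binomial SE
  W <- opt$sensor_shape[2] * opt$pixel_pitch
  R_f <- particle_flow_rate(fl$volumetric_flux_ml_min, bead$concentration_per_ml)
  p_pred <- ratio_from_fov(W, acq$exposure_time, fl$v, R_f)
  frac <- length(unique(s$annotations$frame)) / acq$n_frames
  se <- sqrt(p_pred * (1 - p_pred) / acq$n_frames)
  expect_lt(abs(frac - p_pred), 3 * se)
  # zero concentration: no annotations
  empty <- simulate_session(bead_class_A(concentration_per_ml = 0), opt, fl,
                            acquisition_config(session_duration = 0.5),
                            seed = 3)
  expect_equal(nrow(empty$annotations), 0)
})

test_that("intertwined campaigns alternate classes with per-pair drift", {
  plan <- make_intertwined_dataset(11, seed = 5)
  expect_length(plan$entries, 22)
  expect_equal(vapply(plan$entries, `[[`, "", "label"),
               rep(c("A", "B"), 11))
  expect_error(make_intertwined_dataset(1), "N_s")
  # determinism of the plan
  plan2 <- make_intertwined_dataset(11, seed = 5)
  expect_identical(lapply(plan$entries, `[[`, "drift_state"),
                   lapply(plan2$entries, `[[`, "drift_state"))
  # adding sessions never reshuffles earlier ones (counter-based seeds)
  plan3 <- make_intertwined_dataset(12, seed = 5)
  expect_identical(plan$entries[[1]]$seed, plan3$entries[[1]]$seed)
  expect_identical(plan$entries[[22]]$seed, plan3$entries[[22]]$seed)
  # with zero correlation the drift draw ignores the class sign entirely
  model <- session_drift_model(drift_class_correlation = 0)
  d1 <- holocyto:::with_seed(7, draw_drift_state(model, +1))
  d2 <- holocyto:::with_seed(7, draw_drift_state(model, -1))
  expect_identical(d1, d2)
  # at correlation 1 the same RNG state yields class-displaced states
  model1 <- session_drift_model(drift_class_correlation = 1)
  b1 <- holocyto:::with_seed(7, draw_drift_state(model1, +1))
  b2 <- holocyto:::with_seed(7, draw_drift_state(model1, -1))
  expect_false(identical(b1$beam_center_offset, b2$beam_center_offset))
})

test_that("the grating is rejected on grids that cannot resolve it", {
  opt <- tiny_optical(grating_enabled = TRUE)  # dx = 2.4 um > period / 2
  expect_error(
    holocyto:::sensor_intensity(opt, neutral_drift_state(),
                                data.frame(x_m = 0, diameter_m = 15e-6)),
    "grating period")
  # resolved at high oversampling on a small grid and short throw
  opt2 <- optical_config(sensor_shape = c(12L, 12L), pixel_pitch = 4.8e-6,
                         simulation_grid_oversampling = 6L,
                         source_to_channel_distance = 5e-3,
                         channel_to_sensor_distance = 0.1e-3,
                         grating_enabled = TRUE, grating_amplitude = 0.5)
  i_dg <- holocyto:::sensor_intensity(opt2, neutral_drift_state())
  opt3 <- opt2; opt3$grating_enabled <- FALSE
  i_ndg <- holocyto:::sensor_intensity(opt3, neutral_drift_state())
  # the grating attenuates the transmitted energy
  expect_lt(sum(i_dg), sum(i_ndg))
})
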