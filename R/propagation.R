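#' @title Scalar optical field model
#'
#' @description The illumination is the divergent beam from a circular
#' pinhole: an Airy amplitude envelope with spherical phase curvature at the
#' channel plane. Beads are thin phase objects multiplied into that field;
#' the perturbed field is propagated to the sensor with the angular-spectrum
#' transform (exact scalar free-space propagation), band-limited at the
#' evanescent cutoff and zero-padded 2x to suppress wrap-around. The sensor
#' samples the intensity, bins the oversampled grid to camera pixels, adds
#' Poisson shot noise and Gaussian read noise, and quantises to 8 bits.
#'
#' @name propagation
#' @keywords internal
NULL

# simulation grid: coordinates (m) of the oversampled field samples,
# centred on the sensor; x runs along the channel (columns), y across (rows)
simulation_grid <- function(optical) {
  os <- optical$simulation_grid_oversampling
  dx <- optical$pixel_pitch / os
  nr <- optical$sensor_shape[1] * os
  nc <- optical$sensor_shape[2] * os
  list(dx = dx, nr = nr, nc = nc,
       x = (seq_len(nc) - (nc + 1) / 2) * dx,
       y = (seq_len(nr) - (nr + 1) / 2) * dx)
}

# Airy amplitude 2 J1(rho)/rho of a circular aperture, 1 at rho = 0
airy_amplitude <- function(rho) {
  out <- rep(1, length(rho))
  nz <- rho != 0
  out[nz] <- 2 * besselJ(rho[nz], 1) / rho[nz]
  dim(out) <- dim(rho)
  out
}

# illumination field at the channel plane, beam centre offset in metres
illumination_field <- function(optical, grid, center_m = c(0, 0)) {
  z1 <- optical$source_to_channel_distance
  lam <- optical$wavelength
  xs <- grid$x - center_m[1]
  ys <- grid$y - center_m[2]
  r2 <- outer(ys^2, xs^2, "+")
  r <- sqrt(r2)
  amp <- airy_amplitude(pi * optical$pinhole_diameter * r / (lam * z1))
  amp * exp(1i * pi * r2 / (lam * z1))
}

#' Angular-spectrum free-space propagation
#'
#' Propagates a sampled complex field by distance \code{dz}. The transfer
#' function phase must be adequately sampled; grids violating
#' \code{dz <= N_pad * dx^2 / lambda} are rejected as a configuration error
#' (aliasing). Evanescent components decay exponentially.
#'
#' @param field complex matrix (field samples).
#' @param dx sample spacing (m).
#' @param dz propagation distance (m, >= 0).
#' @param wavelength wavelength (m).
#' @param pad integer zero-padding factor per dimension (1 = none;
#'   2 recommended; larger factors admit longer propagation distances).
#' @return complex matrix of the propagated field, same size as input.
#' @export
angular_spectrum_propagate <- function(field, dx, dz, wavelength, pad = 2L) {
  if (dz < 0) stop("dz must be non-negative")
  if (dz == 0) return(field)
  pad <- max(1L, as.integer(pad))
  nr <- nrow(field); nc <- ncol(field)
  nrp <- pad * nr
  ncp <- pad * nc
  zmax <- min(nrp, ncp) * dx^2 / wavelength
  if (dz > zmax) {
    stop(sprintf(paste0("propagation sampling criterion violated: dz = %.3g m",
                        " exceeds N*dx^2/lambda = %.3g m; use a finer grid,",
                        " more padding or a shorter distance"), dz, zmax))
  }
  fp <- matrix(0 + 0i, nrp, ncp)
  fp[seq_len(nr), seq_len(nc)] <- field
  fr <- c(seq(0, floor(nrp / 2)), seq(-ceiling(nrp / 2) + 1, -1)) / (nrp * dx)
  fc <- c(seq(0, floor(ncp / 2)), seq(-ceiling(ncp / 2) + 1, -1)) / (ncp * dx)
  f2 <- outer(fr^2, fc^2, "+")
  k2 <- 1 / wavelength^2
  kz <- sqrt(abs(k2 - f2))
  H <- ifelse(f2 <= k2,
              exp(2i * pi * dz * kz),
              exp(-2 * pi * dz * kz))
  out <- stats::fft(stats::fft(fp) * H, inverse = TRUE) / (nrp * ncp)
  out[seq_len(nr), seq_len(nc)]
}

# thin phase-object transmission of one bead at (x_m, y_m); phase profile
# phi(r) = (2 pi / lambda) (n_bead - n_medium) 2 sqrt((d/2)^2 - r^2)
bead_phase_mask <- function(optical, grid, x_m, diameter_m, y_m = 0) {
  if (diameter_m < 0) stop("diameter must be non-negative")
  mask <- matrix(1 + 0i, grid$nr, grid$nc)
  if (diameter_m == 0) return(mask)
  rad <- diameter_m / 2
  xi <- which(abs(grid$x - x_m) <= rad)
  yi <- which(abs(grid$y - y_m) <= rad)
  if (length(xi) == 0 || length(yi) == 0) return(mask)
  r2 <- outer((grid$y[yi] - y_m)^2, (grid$x[xi] - x_m)^2, "+")
  thick <- 2 * sqrt(pmax(rad^2 - r2, 0))
  dn <- optical$refractive_index_bead - optical$refractive_index_medium
  mask[yi, xi] <- exp(1i * 2 * pi / optical$wavelength * dn * thick)
  mask
}

# separable double-axis sinusoidal phase grating with amplitude attenuation
grating_transmission <- function(optical, grid) {
  if (2 * grid$dx > optical$grating_period) {
    stop(sprintf(paste0("grating period %.3g m is not resolved by the grid",
                        " (dx = %.3g m); increase simulation_grid_oversampling"),
                 optical$grating_period, grid$dx))
  }
  m <- optical$grating_phase_depth
  gx <- cos(2 * pi * grid$x / optical$grating_period)
  gy <- cos(2 * pi * grid$y / optical$grating_period)
  phase <- outer(gy, gx, "+") * m
  optical$grating_amplitude * exp(1i * phase)
}

# bin the oversampled intensity to camera pixels (block mean)
bin_to_pixels <- function(intensity, optical) {
  os <- optical$simulation_grid_oversampling
  if (os == 1L) return(intensity)
  downsample(intensity, os)
}

# translate an image by (dy, dx) pixels (bilinear, edge-clamped); used for
# the rigid background translation under slow beam drift
shift_image <- function(img, dy, dx) {
  if (dy == 0 && dx == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  r <- seq_len(nr) - dy
  c <- seq_len(nc) - dx
  r0 <- pmin(pmax(floor(r), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(c), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- pmin(pmax(r - r0, 0), 1)
  fc <- pmin(pmax(c - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE]; b <- img[r0, c1, drop = FALSE]
  d <- img[r1, c0, drop = FALSE]; e <- img[r1, c1, drop = FALSE]
  wr <- matrix(fr, nr, nc); wc <- matrix(fc, nr, nc, byrow = TRUE)
  (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * d + wc * e)
}

# camera measurement: shot noise, read noise, 8-bit quantisation.
# intensity is relative (unperturbed beam peak ~ 1).
camera_sample <- function(intensity, optical) {
  nph <- optical$photon_budget
  electrons <- matrix(
    stats::rpois(length(intensity), lambda = pmax(intensity, 0) * nph),
    nrow(intensity), ncol(intensity))
  counts <- electrons * (255 / (nph * optical$saturation)) +
    stats::rnorm(length(intensity), sd = optical$read_noise_sd)
  matrix(as.integer(pmin(pmax(round(counts), 0), 255)),
         nrow(intensity), ncol(intensity))
}
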