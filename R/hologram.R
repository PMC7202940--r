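#' Raised-cosine coherence envelope
#'
#' `f_gamma(r) = (cos(pi r / gamma) + 1) / 2` for `r < gamma`, 0 beyond:
#' the finite spatial coherence of the LED truncates the ring pattern at a
#' radius `gamma` (pixels) from the pattern center.
#'
#' @param r_px Radii in pixels (any numeric array).
#' @param gamma_px Envelope width in pixels.
#' @return Array of envelope values in `[0, 1]`, same shape as `r_px`.
#' @export
coherence_envelope <- function(r_px, gamma_px) {
  if (gamma_px <= 0) stop("'gamma_px' must be positive")
  ifelse(r_px < gamma_px, (cos(pi * r_px / gamma_px) + 1) / 2, 0)
}

# validated axial range of the scalar far-field simulator (nm above focus)
.z_valid <- c(2000, 20000)

#' Render a Lorenz-Mie hologram of a single bead
#'
#' Evaluates the in-line hologram intensity
#' `I = beta * (1 + f_gamma(r) * (2 alpha Re(f_s exp(-i k z)) + alpha^2 |f_s|^2))`
#' per pixel, where `f_s` is the scalar Lorenz-Mie scattered field
#' ([scattering_amplitude()]) evaluated at the pixel's 3D displacement from
#' the bead, and `f_gamma` the coherence envelope centred on the bead. The
#' scattered field is computed on a 1D radial grid (0.25 pixel spacing) and
#' cubically interpolated to the pixel raster; the pattern is circularly
#' symmetric by construction, so the interpolation error is far below one
#' grayscale unit.
#'
#' @param model An [optical_model()].
#' @param pose Numeric length-3 `c(x, y, z)` in nm: lateral offsets from the
#'   ROI center (x right, y down) and height above the focal plane.
#' @param roi ROI side length in pixels (even, >= 32).
#' @param quantize Round (half away from zero) and clip to 0-255, emulating
#'   an 8-bit camera. Set `FALSE` for the float image used in fitting.
#' @param envelope `"scatter"` applies the coherence envelope to the
#'   scattering terms only (background stays at `beta` across the ROI, as in
#'   experimental images); `"literal"` multiplies the whole bracket,
#'   including the background.
#' @param dr_px Radial grid spacing in pixels for the 1D field evaluation.
#' @return Numeric `roi x roi` matrix (rows = y, columns = x) with
#'   attributes `pose` and `pixel_nm`. Pixel centers sit at integer
#'   coordinates `0 ... roi-1`; the ROI center is at `roi/2`.
#' @examples
#' img <- render_hologram(optical_model(), c(0, 0, 12000), roi = 64)
#' range(img)
#' @export
render_hologram <- function(model, pose, roi = 150L, quantize = TRUE,
                            envelope = c("scatter", "literal"),
                            dr_px = 0.25) {
  stopifnot(inherits(model, "optical_model"), length(pose) == 3)
  envelope <- match.arg(envelope)
  s <- as.integer(roi)
  if (s < 32L || s %% 2L != 0L) stop("'roi' must be even and >= 32")
  z <- pose[3]
  if (z < .z_valid[1] || z > .z_valid[2]) {
    warning(sprintf(
      "pose z = %.0f nm is outside the validated range [%d, %d] nm; rendering anyway",
      z, .z_valid[1], .z_valid[2]))
  }
  px <- model$pixel_nm
  c0 <- s / 2
  xs <- (0:(s - 1)) - (c0 + pose[1] / px)
  ys <- (0:(s - 1)) - (c0 + pose[2] / px)
  r_px <- sqrt(outer(ys^2, xs^2, "+"))
  rho <- r_px * px
  k <- 2 * pi * model$n_m / model$lambda_nm
  grid <- seq(0, max(rho) + px, by = dr_px * px)
  Rg <- sqrt(grid^2 + z^2)
  cf <- mie_coefficients(size_parameter(model), model$n_p / model$n_m)
  S <- mie_s_amplitudes(cf, z / Rg)
  fs <- 0.5 * (S$S1 + S$S2) * exp(1i * k * Rg) / (-1i * k * Rg)
  interf <- 2 * Re(fs * exp(-1i * k * z))
  mod2 <- Re(fs * Conj(fs))
  scat_prof <- model$alpha * interf + model$alpha^2 * mod2
  f_scat <- stats::splinefun(grid, scat_prof, method = "fmm")
  scat <- f_scat(rho)
  env <- coherence_envelope(r_px, model$gamma_px)
  img <- if (envelope == "scatter") {
    model$beta * (1 + env * scat)
  } else {
    model$beta * (1 + scat) * env
  }
  if (quantize) img <- quantize_image(img)
  attr(img, "pose") <- pose
  attr(img, "pixel_nm") <- px
  img
}

#' Quantize a float image to 8-bit grayscale
#'
#' Rounds half away from zero and clips to `[0, 255]`.
#'
#' @param img Numeric matrix.
#' @return Matrix of integers (stored as doubles) in 0-255.
#' @export
quantize_image <- function(img) {
  q <- floor(abs(img) + 0.5) * sign(img)
  pmin(pmax(q, 0), 255)
}

#' Bead trajectories
#'
#' `trajectory_random()` draws i.i.d. normal per-frame poses (the standard
#' robustness-simulation protocol uses `mean = c(0, 0, 12000)` nm and
#' `sd = c(5, 5, 5)` nm at 30 Hz); `trajectory_ramp()` produces a linear
#' focus ramp in z at fixed xy, as used for phase calibration.
#'
#' @param n_frames Number of frames.
#' @param f_s Sampling rate (Hz).
#' @param mean,sd Length-3 per-axis mean and SD (nm) of the random poses.
#' @param seed Optional integer seed (`NULL` leaves the RNG state alone).
#' @return Data frame of class `bead_trajectory` with columns
#'   `frame`, `t_s`, `x_nm`, `y_nm`, `z_nm` and attribute `f_s`.
#' @export
trajectory_random <- function(n_frames = 3600, f_s = 30,
                              mean = c(0, 0, 12000), sd = c(5, 5, 5),
                              seed = NULL) {
  stopifnot(n_frames >= 1, f_s > 0, length(mean) == 3, length(sd) == 3)
  if (!is.null(seed)) set.seed(seed)
  tr <- data.frame(
    frame = seq_len(n_frames),
    t_s = (seq_len(n_frames) - 1) / f_s,
    x_nm = stats::rnorm(n_frames, mean[1], sd[1]),
    y_nm = stats::rnorm(n_frames, mean[2], sd[2]),
    z_nm = stats::rnorm(n_frames, mean[3], sd[3]))
  structure(tr, f_s = f_s, class = c("bead_trajectory", "data.frame"))
}

#' @rdname trajectory_random
#' @param z_from,z_to Ramp endpoints (nm above focus).
#' @param x_nm,y_nm Fixed lateral position (nm).
#' @export
trajectory_ramp <- function(z_from = 5000, z_to = 15000, n_frames = 201,
                            f_s = 30, x_nm = 0, y_nm = 0) {
  stopifnot(n_frames >= 2)
  tr <- data.frame(
    frame = seq_len(n_frames),
    t_s = (seq_len(n_frames) - 1) / f_s,
    x_nm = rep(x_nm, n_frames),
    y_nm = rep(y_nm, n_frames),
    z_nm = seq(z_from, z_to, length.out = n_frames))
  structure(tr, f_s = f_s, class = c("bead_trajectory", "data.frame"))
}

#' Render a hologram video along a trajectory
#'
#' One frame per trajectory row, ground truth attached. With
#' `as_function = TRUE` a closure `function(i)` is returned instead of a
#' list, so long videos can be tracked frame by frame without holding the
#' full stack in memory.
#'
#' @param model An [optical_model()].
#' @param traj A `bead_trajectory` (or data frame with `x_nm`, `y_nm`,
#'   `z_nm`).
#' @param roi ROI side length (pixels).
#' @param quantize Quantize each frame to 8-bit.
#' @param as_function Return a frame generator closure instead of a list.
#' @param seed Optional integer seed recorded in the output metadata (the
#'   noiseless renderer itself is deterministic).
#' @return List of frames (class `holo_video`, attributes `trajectory`,
#'   `f_s`, `seed`) or a generator closure with attribute `n_frames`.
#' @export
render_video <- function(model, traj, roi = 150L, quantize = TRUE,
                         as_function = FALSE, seed = NULL) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 1)
  poses <- as.matrix(traj[, c("x_nm", "y_nm", "z_nm")])
  gen <- function(i) {
    render_hologram(model, poses[i, ], roi = roi, quantize = quantize)
  }
  if (as_function) {
    attr(gen, "n_frames") <- nrow(poses)
    return(gen)
  }
  frames <- lapply(seq_len(nrow(poses)), gen)
  structure(frames, trajectory = traj, f_s = attr(traj, "f_s"),
            seed = seed, class = "holo_video")
}

#' Radius of the first intensity minimum of a hologram
#'
#' Diagnostic used to verify ring expansion with height: returns the radius
#' (pixels) of the first local minimum of the radial intensity profile about
#' the bead center.
#'
#' @param img Hologram matrix (bead at the ROI center).
#' @return Radius in pixels (NA if no interior minimum).
#' @export
first_minimum_radius <- function(img) {
  prof <- radial_profile(img)
  n <- length(prof)
  for (j in 2:(n - 1)) {
    if (prof[j] < prof[j - 1] && prof[j] <= prof[j + 1]) return(j - 1)
  }
  NA_real_
}
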