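#' Superimpose a typical imaging artifact on a hologram
#'
#' Implements the five artifact classes used by the robustness benchmark.
#' Severities are percentages except for Poisson noise, whose severity is
#' in grayscale units.
#'
#' * `poisson_noise` — adds zero-mean noise with intensity-scaled variance.
#'   Under the default `noise_model = "mean_sd"` the per-pixel SD is
#'   `severity * sqrt(I / mean(I))`, so the image-mean SD equals the
#'   stated grayscale amplitude; `"full_scale"` uses per-pixel variance
#'   `severity * I / 255` (photon noise whose variance reaches the stated
#'   amplitude at full grayscale); `"gaussian"` is flat SD = severity.
#'   Result is re-quantized to 8 bits.
#' * `interlacing` — every other row multiplied by a gain of
#'   `1 + severity/100` (100% = gain 2), clipped.
#' * `light_gradient` — linear intensity ramp along y, scaled so that 100%
#'   lifts the background to 255 at the far edge, clipped.
#' * `astigmatism` — columns resampled in y onto fewer rows so the pattern
#'   aspect ratio becomes `1 + severity/100` (100% = 2), padded back to
#'   size with edge values.
#' * `roi_shift` — not an image operation: the mean bead x position is
#'   offset by `severity/100` of the ROI at the trajectory level (handled
#'   by [run_benchmark()]); calling `apply_aberration` with it is an error.
#'
#' @param image Numeric hologram matrix in the 8-bit range.
#' @param kind One of `"poisson_noise"`, `"interlacing"`,
#'   `"light_gradient"`, `"astigmatism"`.
#' @param severity Grayscale units (noise) or percent (others, 0-100).
#' @param noise_model Noise variant for `poisson_noise` (see above).
#' @return Aberrated image matrix in `[0, 255]`.
#' @examples
#' img <- matrix(100, 64, 64)
#' rng <- apply_aberration(img, "interlacing", 100)
#' unique(as.numeric(rng))
#' @export
apply_aberration <- function(image, kind, severity,
                             noise_model = c("mean_sd", "full_scale",
                                             "gaussian")) {
  stopifnot(is.matrix(image), severity >= 0)
  kind <- match.arg(kind, c("poisson_noise", "interlacing",
                            "light_gradient", "astigmatism", "roi_shift"))
  if (kind == "roi_shift") {
    stop("'roi_shift' acts on the trajectory, not the image; ",
         "use run_benchmark()")
  }
  if (kind != "poisson_noise" && severity > 100) {
    stop("percent severities must be <= 100")
  }
  s <- nrow(image)
  out <- switch(kind,
    poisson_noise = {
      if (severity == 0) {
        image
      } else {
        noise_model <- match.arg(noise_model)
        sdev <- switch(noise_model,
          mean_sd = severity * sqrt(pmax(image, 0) / mean(image)),
          full_scale = sqrt(severity * pmax(image, 0) / 255),
          gaussian = matrix(severity, nrow(image), ncol(image)))
        quantize_image(image + stats::rnorm(length(image)) * sdev)
      }
    },
    interlacing = {
      g <- 1 + severity / 100
      image[seq(2, s, by = 2), ] <- image[seq(2, s, by = 2), ] * g
      quantize_image(image)
    },
    light_gradient = {
      bg <- stats::median(image)
      ramp <- (severity / 100) * (255 - bg) * (0:(s - 1)) / (s - 1)
      quantize_image(image + matrix(ramp, s, ncol(image)))
    },
    astigmatism = {
      g <- 1 + severity / 100
      c0 <- s / 2
      src <- c0 + ((0:(s - 1)) - c0) * g     # compress y by sampling wider
      out <- apply(image, 2, function(col) {
        stats::approx(0:(s - 1), col, xout = src, rule = 2)$y
      })
      quantize_image(out)
    })
  out
}

# the aberration grid of the robustness figure: severities per artifact
fig5_grid <- function() {
  rbind(
    data.frame(kind = "none", severity = 0),
    data.frame(kind = "poisson_noise", severity = c(3, 10, 20)),
    data.frame(kind = "interlacing", severity = c(25, 50, 100)),
    data.frame(kind = "light_gradient", severity = c(10, 20, 50)),
    data.frame(kind = "astigmatism", severity = c(5, 15, 30)),
    data.frame(kind = "roi_shift", severity = c(10, 30, 45)))
}

#' Aberration grids for the robustness benchmark
#'
#' `"fig5"` covers all five artifact classes at three severities each plus
#' the unaberrated baseline; `"none"` is the baseline only.
#'
#' @param name Grid name.
#' @return Data frame with columns `kind` and `severity`.
#' @export
benchmark_grid <- function(name = c("fig5", "none")) {
  name <- match.arg(name)
  if (name == "none") return(data.frame(kind = "none", severity = 0))
  fig5_grid()
}

#' Robustness benchmark: track simulated videos under image artifacts
#'
#' For each aberration cell, simulates the standard random-motion protocol
#' (bead at `traj_mean` with per-axis SD `traj_sd`, one hologram per
#' frame, 8-bit), applies the artifact, tracks with 3DPT (or the LUT
#' baseline), and quantifies the per-axis tracking-error PSD plateau
#' (`sigma^2/f_s`), bias, and median +/- IQR. A cell in which more than
#' half the frames cannot be tracked is marked lost.
#'
#' @param model An [optical_model()].
#' @param refs A [reference_set()].
#' @param cal A [calibrate_phase()] result (3DPT) — also used to seed the
#'   LUT tracker's z search.
#' @param grid Data frame of cells (`kind`, `severity`), e.g.
#'   [benchmark_grid()].
#' @param n_frames Frames per cell (3600 reproduces the full protocol; 600
#'   is a faster variant with wider estimator spread).
#' @param seed Integer seed; every cell derives its own stream from it.
#' @param tracker `"3DPT"` or `"LUT"`.
#' @param lut A [build_lut()] result (required for `tracker = "LUT"`).
#' @param f_s Frame rate (Hz).
#' @param f_min Plateau fit lower frequency (Hz).
#' @param roi ROI side (pixels).
#' @param traj_mean,traj_sd Trajectory mean and SD per axis (nm).
#' @param noise_model Passed to [apply_aberration()].
#' @return Data frame of class `aberration_benchmark`: one row per cell
#'   with plateaus (nm^2/Hz), biases (nm), IQRs (nm), the fraction of
#'   flagged frames and the `lost` marker.
#' @export
run_benchmark <- function(model, refs, cal, grid = benchmark_grid("fig5"),
                          n_frames = 600, seed = 1, tracker = c("3DPT", "LUT"),
                          lut = NULL, f_s = 30, f_min = 5, roi = 150L,
                          traj_mean = c(0, 0, 12000), traj_sd = c(5, 5, 5),
                          noise_model = "mean_sd") {
  tracker <- match.arg(tracker)
  if (tracker == "LUT" && is.null(lut)) stop("tracker 'LUT' needs a lut")
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    kind <- as.character(grid$kind[g])
    sev <- grid$severity[g]
    set.seed((seed %% 100000L) * 19997L + g)
    mean_g <- traj_mean
    if (kind == "roi_shift") {
      mean_g[1] <- mean_g[1] + (sev / 100) * roi * model$pixel_nm
    }
    traj <- trajectory_random(n_frames, f_s, mean = mean_g, sd = traj_sd)
    noise_seeds <- sample.int(.Machine$integer.max, n_frames)
    gen <- function(i) {
      img <- render_hologram(model, as.numeric(traj[i, c("x_nm", "y_nm",
                                                         "z_nm")]),
                             roi = roi, quantize = FALSE)
      if (kind %in% c("interlacing", "light_gradient", "astigmatism") ||
          (kind == "poisson_noise" && sev > 0)) {
        # camera artifacts act on the analog image: apply them to the
        # float frame and digitize once (applying a gain to an already
        # quantized frame would spuriously amplify quantization noise)
        if (kind == "poisson_noise") set.seed(noise_seeds[i])
        img <- apply_aberration(img, kind, sev, noise_model = noise_model)
      } else {
        img <- quantize_image(img)
      }
      img
    }
    attr(gen, "n_frames") <- n_frames
    if (tracker == "3DPT") {
      trk <- track_video(gen, refs, cal, f_s = f_s,
                         pixel_nm = model$pixel_nm,
                         z_window = c(traj_mean[3] - 2000,
                                      traj_mean[3] + 2000))
      ok <- trk$flag %in% c("ok", "low_confidence")
    } else {
      trk <- lut_track_video(gen, lut, f_s = f_s,
                             pixel_nm = model$pixel_nm)
      ok <- trk$flag == "ok"
    }
    fail_frac <- 1 - mean(ok)
    lost <- fail_frac > 0.5
    res <- list(kind = kind, severity = sev, lost = lost,
                fail_frac = fail_frac)
    for (ax in c("x", "y", "z")) {
      e <- trk[[paste0(ax, "_nm")]][ok] - traj[[paste0(ax, "_nm")]][ok]
      if (lost || length(e) < 256) {
        res[[paste0("plateau_", ax)]] <- NA_real_
        res[[paste0("bias_", ax)]] <- NA_real_
        res[[paste0("iqr_", ax)]] <- NA_real_
      } else {
        p <- psd_estimate(e, f_s)
        res[[paste0("plateau_", ax)]] <- psd_plateau(p, f_min = f_min)
        res[[paste0("bias_", ax)]] <- mean(e)
        res[[paste0("iqr_", ax)]] <- stats::IQR(e)
      }
    }
    rows[[g]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, seed = seed, n_frames = n_frames, tracker = tracker,
            class = c("aberration_benchmark", "data.frame"))
}

#' @export
print.aberration_benchmark <- function(x, ...) {
  cat(sprintf("Aberration robustness benchmark (%s, %d frames/cell, seed %d)\n",
              attr(x, "tracker"), attr(x, "n_frames"), attr(x, "seed")))
  df <- data.frame(kind = x$kind, severity = x$severity,
                   plateau_z = signif(x$plateau_z, 3),
                   plateau_x = signif(x$plateau_x, 3),
                   bias_z = signif(x$bias_z, 3),
                   lost = x$lost)
  print(df, row.names = FALSE)
  invisible(x)
}
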