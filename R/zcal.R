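#' Unwrap a wrapped phase sequence
#'
#' Adds integer multiples of 2*pi so that successive differences lie in
#' `(-pi, pi]`; the first element is unchanged. On a calibration ramp the
#' bead height increases monotonically, so unwrapping is unambiguous as
#' long as the true per-step phase increment stays below pi.
#'
#' @param phi Numeric vector of phases (radians).
#' @return Unwrapped phases (radians).
#' @examples
#' unwrap_phase(c(3.0, -3.1))
#' @export
unwrap_phase <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  jumps <- round(d / (2 * pi))
  if (any(abs(d - 2 * pi * jumps) > 0.9 * pi)) {
    message("unwrap_phase: large phase gaps (close to pi) encountered; ",
            "unwrapping may be unreliable")
  }
  phi + c(0, cumsum(-2 * pi * jumps))
}

#' Reference periods matched to the pattern's frequency support
#'
#' The local ring frequency of a hologram at radius `rho` is
#' `q(rho) = k rho / (2 pi R)` with `R = sqrt(rho^2 + z^2)`; the coherence
#' envelope truncates the pattern at `rho = gamma`, so frequencies above
#' `q_edge = q(gamma)` are absent. Periods shorter than `1 / q_edge` pixels
#' carry no signal at height `z`. This helper returns `n` log-spaced periods
#' from `1.15 / q_edge` to `2.3 * (1.15 / q_edge)` pixels (the same relative
#' span as the empirical 7 to 16 px range), capped below `roi / 2`.
#'
#' @param model An [optical_model()].
#' @param z_nm Working height above focus (nm).
#' @param n Number of periods.
#' @param roi ROI side (pixels), used only for the upper cap.
#' @return Numeric vector of periods (pixels).
#' @export
periods_for_height <- function(model, z_nm, n = 15L, roi = 150L) {
  stopifnot(inherits(model, "optical_model"), z_nm > 0)
  k <- 2 * pi * model$n_m / model$lambda_nm
  rho <- model$gamma_px * model$pixel_nm
  q_edge <- k * rho / (2 * pi * sqrt(rho^2 + z_nm^2)) * model$pixel_nm
  p_lo <- 1.15 / q_edge
  p_hi <- min(2.3 * p_lo, roi / 2 - 1)
  log_periods(n, p_lo, p_hi)
}

#' Phase-to-height calibration
#'
#' Unwraps each period's phase ramp, fits a polynomial of order `order` to
#' the unwrapped phase as a function of the true height over `fit_range`,
#' checks strict monotonicity, and builds the monotone inverse interpolant
#' `z(phi)` used for tracking. The per-period residual SD is expressed in
#' nm through the local slope `dphi/dz`. As diagnostics, a straight line is
#' fitted to the upper part of each curve and the slopes are regressed
#' against the period, giving the empirical exponent of the linear
#' phase-height law (close to -2: the phase grows as `c z / k_n^2`) and the
#' calibration factor `c`.
#'
#' @param z_nm True heights (nm), monotonically increasing.
#' @param phases Numeric matrix, `length(z_nm)` rows by one column per
#'   period; wrapped or already-unwrapped phases (radians).
#' @param periods Reference periods (pixels) the columns belong to.
#' @param order Polynomial order (5 is the standard calibration choice;
#'   up to ~15 is useful, beyond ~10 the tracking accuracy no longer
#'   improves).
#' @param fit_range Length-2 height range (nm) to fit over; default the
#'   full ramp.
#' @param amplitudes Optional matrix of per-frame, per-period correlation
#'   amplitudes; medians are stored and used by [track_video()] to flag
#'   frames without a usable correlation peak.
#' @param dense_nm Grid spacing (nm) of the stored forward/inverse tables.
#' @return Object of class `phase_calibration`.
#' @export
calibrate_phase <- function(z_nm, phases, periods, order = 5,
                            fit_range = range(z_nm), amplitudes = NULL,
                            dense_nm = 10) {
  phases <- as.matrix(phases)
  stopifnot(length(z_nm) == nrow(phases), length(periods) == ncol(phases),
            order >= 1, diff(fit_range) > 0)
  if (is.unsorted(z_nm, strictly = TRUE)) {
    stop("'z_nm' must be strictly increasing")
  }
  if (sum(z_nm >= fit_range[1] & z_nm <= fit_range[2]) < 10 * (order + 1)) {
    stop("need at least 10 * (order + 1) samples inside 'fit_range'")
  }
  sel <- z_nm >= fit_range[1] & z_nm <= fit_range[2]
  zmid <- mean(fit_range)
  zhalf <- diff(fit_range) / 2
  grid <- seq(fit_range[1], fit_range[2], by = dense_nm)
  gsc <- (grid - zmid) / zhalf
  per_period <- vector("list", ncol(phases))
  for (j in seq_along(periods)) {
    # a period that has lost its signal yields noisy phases and a large-gap
    # unwrap message; the monotonicity check below is the authoritative gate
    pu <- suppressMessages(unwrap_phase(phases[, j]))
    df <- data.frame(zc = (z_nm[sel] - zmid) / zhalf, phi = pu[sel])
    # orthogonal polynomial basis: raw powers are ill-conditioned at the
    # orders (up to ~15) used for calibration
    fit <- stats::lm(phi ~ stats::poly(zc, order), data = df)
    cf <- stats::coef(fit)
    fwd <- unname(stats::predict(fit, newdata = data.frame(zc = gsc)))
    dgn <- diff(fwd)
    ok <- all(dgn > 0) || all(dgn < 0)
    slope_grid <- c(dgn[1], dgn) / dense_nm
    res_rad <- stats::residuals(fit)
    slope_at <- stats::approx(grid, abs(slope_grid), xout = z_nm[sel],
                              rule = 2)$y
    sigma_res <- stats::sd(res_rad / slope_at)
    # linear asymptote (diagnostics only): fitted around the height where
    # the period's band amplitude peaks — there its stationary ring sits
    # mid-envelope and the linear phase-height law holds; without
    # amplitudes, the upper 30% of the range
    hi <- if (!is.null(amplitudes)) {
      a <- amplitudes[sel, j]
      zb <- z_nm[sel][which.max(a)]
      abs(z_nm[sel] - zb) <= 0.125 * diff(fit_range)
    } else {
      z_nm[sel] >= fit_range[2] - 0.3 * diff(fit_range)
    }
    if (sum(hi) < 5) hi <- rank(abs(z_nm[sel] - mean(fit_range))) <= 10
    zz <- z_nm[sel][hi]
    lfit <- stats::lm(pu[sel][hi] ~ zz)
    per_period[[j]] <- list(
      period = periods[j], coef = cf, ok = ok,
      grid_z = grid, grid_phi = fwd,
      sigma_res_nm = sigma_res,
      asym_slope = unname(stats::coef(lfit)[2]),
      asym_intercept = unname(stats::coef(lfit)[1]),
      amp_median = if (!is.null(amplitudes)) stats::median(amplitudes[, j])
                   else NA_real_,
      # median-smoothed correlation amplitude vs height: used at track time
      # to pick the periods (and xy maps) that carry signal at the current
      # height, deterministically
      grid_amp = if (!is.null(amplitudes)) {
        a <- amplitudes[, j][sel]
        ka <- min(9L, length(a) - (1 - length(a) %% 2))
        if (ka >= 3) a <- stats::runmed(a, ka)
        stats::approx(z_nm[sel], a, xout = grid, rule = 2)$y
      } else NULL)
  }
  usable <- vapply(per_period, `[[`, logical(1), "ok")
  if (sum(usable) < 2 && length(periods) >= 2) {
    stop("fewer than two periods produced a monotonic phase-height curve; ",
         "calibration failed")
  }
  if (any(!usable)) {
    warning("calibration failed (non-monotonic phase) for period(s): ",
            paste(signif(periods[!usable], 4), collapse = ", "))
  }
  slopes <- vapply(per_period, `[[`, numeric(1), "asym_slope")
  exponent <- c_factor <- NA_real_
  if (sum(usable) >= 2) {
    efit <- stats::lm(log(abs(slopes[usable])) ~ log(periods[usable]))
    exponent <- unname(stats::coef(efit)[2])
    c_factor <- exp(unname(stats::coef(efit)[1]))
  }
  # focus estimate: z-intercept of each asymptote after reducing the
  # intercept modulo 2*pi (phase offsets after unwrapping are arbitrary
  # multiples of 2*pi); reported for diagnostics only
  ic <- vapply(per_period, `[[`, numeric(1), "asym_intercept")
  icm <- ((ic + pi) %% (2 * pi)) - pi
  z0 <- mean(-icm[usable] / slopes[usable])
  structure(
    list(periods = periods, order = order, range = fit_range,
         per_period = per_period, usable = usable,
         sigma_res_nm = vapply(per_period, `[[`, numeric(1), "sigma_res_nm"),
         slope_exponent = exponent, c_factor = c_factor, z0_nm = z0,
         amp_median = vapply(per_period, `[[`, numeric(1), "amp_median")),
    class = "phase_calibration")
}

#' @export
print.phase_calibration <- function(x, ...) {
  cat(sprintf(
    "Phase-height calibration: %d period(s), polynomial order %d, range %.1f-%.1f um\n",
    length(x$periods), x$order, x$range[1] / 1000, x$range[2] / 1000))
  tab <- data.frame(period_px = signif(x$periods, 4),
                    monotonic = x$usable,
                    sigma_res_nm = signif(x$sigma_res_nm, 3))
  print(tab, row.names = FALSE)
  if (is.finite(x$slope_exponent)) {
    cat(sprintf("  linear-law slope ~ period^%.2f (focus estimate %.0f nm)\n",
                x$slope_exponent, x$z0_nm))
  }
  invisible(x)
}

#' Predict calibrated phases at given heights
#'
#' @param object A `phase_calibration`.
#' @param z_nm Heights (nm) inside the calibrated range.
#' @param wrapped Wrap the result to `(-pi, pi]`.
#' @param ... Unused.
#' @return Matrix of phases, one column per period.
#' @export
predict.phase_calibration <- function(object, z_nm, wrapped = FALSE, ...) {
  out <- vapply(object$per_period, function(pp) {
    stats::approx(pp$grid_z, pp$grid_phi, xout = z_nm, rule = 2)$y
  }, numeric(length(z_nm)))
  out <- matrix(out, nrow = length(z_nm))
  if (wrapped) out <- (out + pi) %% (2 * pi) - pi
  colnames(out) <- signif(object$periods, 4)
  out
}

#' Run the phasor pipeline on a calibration video
#'
#' Convenience wrapper: measures per-frame phases and amplitudes with
#' [phasor_fix()] and calls [calibrate_phase()]. The xy peak uses the
#' product over all amplitude maps: along a focus ramp different periods
#' lose their signal at different heights, and the full product keeps the
#' peak well defined throughout.
#'
#' @param frames List of hologram matrices or a frame-generator closure
#'   (see [render_video()]).
#' @param z_nm True heights (nm), one per frame.
#' @param refs A [reference_set()].
#' @param n_xy Amplitude maps multiplied for the xy peak (default: all).
#' @param ... Passed to [calibrate_phase()].
#' @return A `phase_calibration`.
#' @export
calibrate_from_video <- function(frames, z_nm, refs,
                                 n_xy = length(refs$periods), ...) {
  n <- if (is.function(frames)) attr(frames, "n_frames") else length(frames)
  stopifnot(n == length(z_nm))
  get_frame <- if (is.function(frames)) frames else function(i) frames[[i]]
  np <- length(refs$periods)
  phases <- amps <- matrix(NA_real_, n, np)
  for (i in seq_len(n)) {
    fx <- phasor_fix(get_frame(i), refs, n_xy = n_xy)
    phases[i, ] <- fx$phases
    amps[i, ] <- fx$amplitudes
  }
  calibrate_phase(z_nm, phases, refs$periods, amplitudes = amps, ...)
}

#' Resolve the 2*pi height ambiguity from multiple periods
#'
#' Each period's wrapped phase maps to a comb of candidate heights spaced
#' by 2*pi in phase inside `z_window`. The combination taking one candidate
#' per period with the smallest sample variance is selected (anchor scan:
#' every candidate in turn anchors the closest candidate of each other
#' period) and its mean is returned; ties break toward the lowest mean.
#'
#' @param phases Wrapped phases (radians), one per calibrated period (NA
#'   entries are skipped).
#' @param cal A [calibrate_phase()] result.
#' @param z_window Length-2 height window (nm) to search; default the full
#'   calibrated range.
#' @param spread_max If the best combination's SD (nm) exceeds this, the
#'   fix is flagged low-confidence.
#' @param use Logical vector selecting which periods to use (default: all
#'   monotonically calibrated ones).
#' @return List with `z_nm`, `candidates` (the selected per-period heights),
#'   `spread_nm` and `flag` (`"ok"`, `"low_confidence"` or `"untrackable"`).
#' @export
resolve_z <- function(phases, cal, z_window = cal$range, spread_max = 250,
                      use = cal$usable) {
  stopifnot(inherits(cal, "phase_calibration"),
            length(phases) == length(cal$periods))
  z_window <- c(max(z_window[1], cal$range[1]),
                min(z_window[2], cal$range[2]))
  if (diff(z_window) <= 0) stop("'z_window' outside the calibrated range")
  keep <- which(use & !is.na(phases))
  if (length(keep) == 0) {
    return(list(z_nm = NA_real_, candidates = numeric(0),
                spread_nm = NA_real_, flag = "untrackable"))
  }
  cands <- vector("list", length(keep))
  for (jj in seq_along(keep)) {
    pp <- cal$per_period[[keep[jj]]]
    inw <- pp$grid_z >= z_window[1] & pp$grid_z <= z_window[2]
    gz <- pp$grid_z[inw]
    gp <- pp$grid_phi[inw]
    frange <- range(gp)
    mset <- seq.int(ceiling((frange[1] - phases[keep[jj]]) / (2 * pi)),
                    floor((frange[2] - phases[keep[jj]]) / (2 * pi)))
    if (length(mset) == 0) {
      return(list(z_nm = NA_real_, candidates = numeric(0),
                  spread_nm = NA_real_, flag = "untrackable"))
    }
    targets <- phases[keep[jj]] + 2 * pi * mset
    zc <- stats::approx(gp, gz, xout = targets)$y
    zc <- zc[!is.na(zc)]
    if (length(zc) == 0) {
      return(list(z_nm = NA_real_, candidates = numeric(0),
                  spread_nm = NA_real_, flag = "untrackable"))
    }
    cands[[jj]] <- zc
  }
  if (length(keep) == 1) {
    cc <- cands[[1]]
    if (length(cc) == 1) {
      return(list(z_nm = cc, candidates = cc, spread_nm = 0, flag = "ok"))
    }
    return(list(z_nm = NA_real_, candidates = cc, spread_nm = NA_real_,
                flag = "untrackable"))
  }
  anchors <- sort(unlist(cands))
  best_var <- Inf
  best_mean <- Inf
  best_sel <- NULL
  for (a in anchors) {
    sel <- vapply(cands, function(cc) cc[which.min(abs(cc - a))], numeric(1))
    v <- stats::var(sel)
    m <- mean(sel)
    if (v < best_var - 1e-9 ||
        (abs(v - best_var) <= 1e-9 && m < best_mean)) {
      best_var <- v
      best_mean <- m
      best_sel <- sel
    }
  }
  spread <- sqrt(best_var)
  list(z_nm = best_mean, candidates = best_sel, spread_nm = spread,
       flag = if (spread > spread_max) "low_confidence" else "ok")
}

#' Track a hologram video in three dimensions
#'
#' Runs the full per-frame 3DPT computation (band-passed cross correlation,
#' sub-pixel xy, amplitude-weighted phases, multi-frequency height
#' resolution). The height search window for frame `i` is centred on the
#' last resolved height (half-width `window_half`); the first frame (and
#' recovery after untrackable frames) uses `z_window`. Frames whose
#' correlation amplitude falls below `min_amp_frac` of the calibration
#' median are flagged `no_peak` and their coordinates set to missing;
#' tracking continues.
#'
#' @param frames List of hologram matrices or a frame-generator closure
#'   with attribute `n_frames`.
#' @param refs A [reference_set()].
#' @param cal A [calibrate_phase()] result for the same reference set.
#' @param f_s Sampling rate (Hz).
#' @param pixel_nm Pixel size (nm) used to convert xy to nm.
#' @param z_window Initial height window (nm); default the calibrated range.
#' @param window_half Half-width (nm) of the per-frame height window.
#' @param n_xy Amplitude maps multiplied for the xy peak. The default
#'   `"auto"` multiplies the two periods with the strongest calibrated
#'   amplitude at the current height; an integer reproduces the fixed
#'   first-`n` choice.
#' @param win Phase window (pixels).
#' @param min_amp_frac Per-frame xy peak amplitude threshold, as a fraction
#'   of the calibration median product amplitude (set 0 to disable).
#' @param period_amp_frac Per-period gate: periods whose calibrated
#'   correlation amplitude at the current height falls below this fraction
#'   of the strongest period's are left out of the height resolution (their
#'   band carries no signal there, so their phase is undefined). The gate
#'   uses the calibration's amplitude-height profile, so the selected set
#'   is a deterministic function of height and does not flicker with frame
#'   noise. Set 0 to disable.
#' @return A `bead_track` data frame: `frame`, `t_s`, `x_nm`, `y_nm`,
#'   `z_nm`, `amplitude`, `flag`, and one wrapped-phase column per period;
#'   attributes `f_s`, `periods`, `pixel_nm`.
#' @export
track_video <- function(frames, refs, cal, f_s = 30, pixel_nm = 112,
                        z_window = cal$range, window_half = 1500,
                        n_xy = "auto", win = 10L, min_amp_frac = 0.05,
                        period_amp_frac = 0.02) {
  n <- if (is.function(frames)) attr(frames, "n_frames") else length(frames)
  get_frame <- if (is.function(frames)) frames else function(i) frames[[i]]
  np <- length(refs$periods)
  # calibrated amplitude-height profiles (one column per period)
  amp_prof <- NULL
  if (!is.null(cal$per_period[[1]]$grid_amp)) {
    amp_prof <- vapply(cal$per_period, `[[`,
                       numeric(length(cal$per_period[[1]]$grid_z)),
                       "grid_amp")
    amp_grid_z <- cal$per_period[[1]]$grid_z
  }
  amp_at <- function(z) {
    i <- max(1L, min(nrow(amp_prof),
                     round(stats::approx(amp_grid_z, seq_along(amp_grid_z),
                                         xout = z, rule = 2)$y)))
    amp_prof[i, ]
  }
  out <- data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / f_s,
                    x_nm = NA_real_, y_nm = NA_real_, z_nm = NA_real_,
                    amplitude = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  phs <- matrix(NA_real_, n, np)
  last_z <- NA_real_
  for (i in seq_len(n)) {
    z_ref <- if (is.finite(last_z)) last_z else mean(z_window)
    use <- cal$usable
    xy_use <- NULL
    amp_ref <- NA_real_
    if (!is.null(amp_prof)) {
      ac <- amp_at(z_ref)
      if (period_amp_frac > 0) {
        use <- use & ac >= period_amp_frac * max(ac[cal$usable])
      }
      ord <- order(-ac * as.numeric(use))
      if (identical(n_xy, "auto")) {
        xy_use <- sort(ord[seq_len(min(2L, sum(use)))])
      }
      amp_ref <- mean(ac[if (is.null(xy_use)) ord[1:2] else xy_use])
    }
    if (is.null(xy_use) && identical(n_xy, "auto")) n_xy_i <- 2L
    else n_xy_i <- if (identical(n_xy, "auto")) 2L else n_xy
    fx <- phasor_fix(get_frame(i), refs, n_xy = n_xy_i, win = win,
                     xy_use = xy_use)
    out$amplitude[i] <- fx$amplitude
    phs[i, ] <- fx$phases
    if (fx$flag %in% c("no_bead", "edge")) {
      out$flag[i] <- fx$flag
      last_z <- NA_real_
      next
    }
    win_amp <- mean(fx$amplitudes[if (is.null(xy_use)) seq_len(n_xy_i)
                                  else xy_use])
    if (min_amp_frac > 0 && is.finite(amp_ref) &&
        win_amp < min_amp_frac * amp_ref) {
      out$flag[i] <- "no_peak"
      last_z <- NA_real_
      next
    }
    w <- if (is.finite(last_z)) {
      c(last_z - window_half, last_z + window_half)
    } else {
      z_window
    }
    rz <- resolve_z(fx$phases, cal, z_window = w, use = use)
    if (rz$flag == "untrackable") {
      out$flag[i] <- "untrackable"
      last_z <- NA_real_
      next
    }
    out$x_nm[i] <- fx$x * pixel_nm
    out$y_nm[i] <- fx$y * pixel_nm
    out$z_nm[i] <- rz$z_nm
    out$flag[i] <- if (rz$flag != "ok") rz$flag else "ok"
    last_z <- rz$z_nm
  }
  colnames(phs) <- sprintf("phi_k%s", signif(refs$periods, 4))
  out <- cbind(out, phs)
  structure(out, f_s = f_s, periods = refs$periods, pixel_nm = pixel_nm,
            class = c("bead_track", "data.frame"))
}

#' @export
print.bead_track <- function(x, ...) {
  ok <- x$flag == "ok" | x$flag == "low_confidence"
  cat(sprintf("3DPT bead track: %d frames at %.3g Hz (%d tracked, %d flagged)\n",
              nrow(x), attr(x, "f_s"), sum(ok), sum(!ok)))
  if (any(ok)) {
    cat(sprintf("  mean position: x %.1f nm, y %.1f nm, z %.0f nm\n",
                mean(x$x_nm[ok]), mean(x$y_nm[ok]), mean(x$z_nm[ok])))
    cat(sprintf("  SD:            x %.2f nm, y %.2f nm, z %.2f nm\n",
                stats::sd(x$x_nm[ok]), stats::sd(x$y_nm[ok]),
                stats::sd(x$z_nm[ok])))
  }
  invisible(x)
}

#' @export
plot.bead_track <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  for (axis in c("x_nm", "y_nm", "z_nm")) {
    graphics::plot(x$t_s, x[[axis]], type = "l", xlab = "t (s)",
                   ylab = axis, ...)
  }
  invisible(x)
}
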