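#' Mirror-correlation xy localization (LUT baseline)
#'
#' The classical camera-tracking center finder: the central five rows
#' (resp. columns) are summed into a 1D trace, cross-correlated with its
#' mirror image, and the bead center taken as half the lag of the
#' correlation maximum, refined by a 3-point quadratic fit.
#'
#' @param image Hologram matrix (`roi >= 16`).
#' @return List with `x`, `y` (pixels relative to the ROI center) and
#'   `flag` (`"ok"` or `"flat"`).
#' @export
lut_locate_xy <- function(image) {
  stopifnot(is.matrix(image), nrow(image) >= 16)
  s <- nrow(image)
  c0 <- s / 2
  ctr_rows <- (c0 - 1):(c0 + 3)              # central five lines (1-based)
  axis_center <- function(tr) {
    tr <- tr - mean(tr)
    if (all(abs(tr) < 1e-12)) return(NA_real_)
    m <- rev(tr)
    # zero-padded full cross correlation of the trace with its mirror
    nfft <- 2^ceiling(log2(2 * s))
    A <- stats::fft(c(tr, rep(0, nfft - s)))
    B <- stats::fft(c(m, rep(0, nfft - s)))
    cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / nfft
    lags <- c(0:(nfft / 2 - 1), -(nfft / 2):-1)
    keep <- which(abs(lags) <= s - 1)
    cc <- cc[keep]
    lags <- lags[keep]
    i <- which.max(cc)
    d <- 0
    ip <- which(lags == lags[i] + 1)
    im <- which(lags == lags[i] - 1)
    if (length(ip) == 1 && length(im) == 1) {
      den <- cc[im] - 2 * cc[i] + cc[ip]
      if (den < 0) d <- 0.5 * (cc[im] - cc[ip]) / den
    }
    lag <- lags[i] + d
    # trace symmetric about c: best mirror alignment at lag 2c - (s-1)
    (lag + s - 1) / 2
  }
  cx <- axis_center(colSums(image[ctr_rows, ]))
  cy <- axis_center(rowSums(image[, ctr_rows]))
  if (is.na(cx) || is.na(cy)) {
    return(list(x = 0, y = 0, flag = "flat"))
  }
  list(x = cx - c0, y = cy - c0, flag = "ok")
}

#' Radial intensity profile about a center
#'
#' Mean intensity in 1-pixel annuli (nearest-bin assignment of
#' pixel-center distances), radii `0 ... roi/2 - 1`; empty annuli are
#' linearly interpolated.
#'
#' @param image Hologram matrix.
#' @param center `c(x, y)` center in pixels relative to the ROI center
#'   (default the ROI center itself).
#' @return Numeric vector of length `roi/2`.
#' @export
radial_profile <- function(image, center = c(0, 0)) {
  stopifnot(is.matrix(image))
  s <- nrow(image)
  c0 <- s / 2
  xc <- c0 + center[1]
  yc <- c0 + center[2]
  if (xc < 0 || xc > s - 1 || yc < 0 || yc > s - 1) {
    stop("center lies outside the image")
  }
  r <- sqrt(outer(((0:(s - 1)) - yc)^2, ((0:(s - 1)) - xc)^2, "+"))
  bin <- floor(r + 0.5)
  nb <- s %/% 2
  prof <- rep(NA_real_, nb)
  sums <- tapply(as.numeric(image), factor(bin, levels = 0:(nb - 1)), mean)
  prof[seq_len(nb)] <- as.numeric(sums)
  if (anyNA(prof)) {
    ok <- which(!is.na(prof))
    prof <- stats::approx(ok - 1, prof[ok], xout = 0:(nb - 1), rule = 2)$y
  }
  prof
}

#' Build a radial-profile look-up table
#'
#' One radial profile per calibration frame, indexed by the known bead
#' heights. Profiles are computed about the mirror-correlation center of
#' each frame.
#'
#' @param frames List of hologram matrices (or generator closure) at known
#'   heights.
#' @param z_nm Heights (nm), strictly increasing, one per frame.
#' @return Object of class `radial_lut` with `z_nm` and `profiles` (one
#'   row per height).
#' @export
build_lut <- function(frames, z_nm) {
  n <- if (is.function(frames)) attr(frames, "n_frames") else length(frames)
  stopifnot(n == length(z_nm), n >= 3)
  if (is.unsorted(z_nm, strictly = TRUE)) {
    stop("'z_nm' must be strictly increasing")
  }
  get_frame <- if (is.function(frames)) frames else function(i) frames[[i]]
  profs <- NULL
  for (i in seq_len(n)) {
    img <- get_frame(i)
    ctr <- lut_locate_xy(img)
    p <- radial_profile(img, c(ctr$x, ctr$y))
    if (is.null(profs)) profs <- matrix(NA_real_, n, length(p))
    profs[i, ] <- p
  }
  structure(list(z_nm = z_nm, profiles = profs), class = "radial_lut")
}

#' @export
print.radial_lut <- function(x, ...) {
  cat(sprintf("Radial-profile LUT: %d profiles, z %.1f-%.1f um, %d radii\n",
              length(x$z_nm), min(x$z_nm) / 1000, max(x$z_nm) / 1000,
              ncol(x$profiles)))
  invisible(x)
}

#' Interpolate a height from a radial profile
#'
#' RMS difference against every LUT profile; the height is the
#' quadratically interpolated minimizer over the (uniform) height grid.
#'
#' @param profile Radial profile (same length as the LUT's).
#' @param lut A [build_lut()] result.
#' @return List with `z_nm` and `flag` (`"ok"` or `"edge"` when the
#'   minimum sits on the grid boundary, in which case the value is
#'   clamped).
#' @export
lut_z <- function(profile, lut) {
  stopifnot(inherits(lut, "radial_lut"),
            length(profile) == ncol(lut$profiles))
  rms <- sqrt(rowMeans(sweep(lut$profiles, 2, profile)^2))
  j <- which.min(rms)
  n <- length(rms)
  if (rms[j] == 0) {                     # exact node hit
    return(list(z_nm = lut$z_nm[j], flag = "ok"))
  }
  if (j == 1L || j == n) {
    return(list(z_nm = lut$z_nm[j], flag = "edge"))
  }
  den <- rms[j - 1] - 2 * rms[j] + rms[j + 1]
  d <- if (den > 0) 0.5 * (rms[j - 1] - rms[j + 1]) / den else 0
  dz <- if (d >= 0) lut$z_nm[j + 1] - lut$z_nm[j] else
                    lut$z_nm[j] - lut$z_nm[j - 1]
  list(z_nm = lut$z_nm[j] + d * dz, flag = "ok")
}

#' Track a video with the LUT baseline
#'
#' Per frame: mirror-correlation center, radial profile about it, height
#' from [lut_z()].
#'
#' @param frames List of hologram matrices or generator closure.
#' @param lut A [build_lut()] result.
#' @param f_s Sampling rate (Hz).
#' @param pixel_nm Pixel size (nm).
#' @return A `bead_track`-like data frame (`frame`, `t_s`, `x_nm`, `y_nm`,
#'   `z_nm`, `flag`).
#' @export
lut_track_video <- function(frames, lut, f_s = 30, pixel_nm = 112) {
  n <- if (is.function(frames)) attr(frames, "n_frames") else length(frames)
  get_frame <- if (is.function(frames)) frames else function(i) frames[[i]]
  out <- data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / f_s,
                    x_nm = NA_real_, y_nm = NA_real_, z_nm = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    img <- get_frame(i)
    ctr <- lut_locate_xy(img)
    zi <- lut_z(radial_profile(img, c(ctr$x, ctr$y)), lut)
    out$x_nm[i] <- ctr$x * pixel_nm
    out$y_nm[i] <- ctr$y * pixel_nm
    out$z_nm[i] <- zi$z_nm
    out$flag[i] <- if (ctr$flag != "ok") ctr$flag
                   else if (zi$flag != "ok") zi$flag else "ok"
  }
  structure(out, f_s = f_s, pixel_nm = pixel_nm,
            class = c("bead_track", "data.frame"))
}
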