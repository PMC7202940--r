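#' Log-spaced reference periods
#'
#' @param n Number of periods.
#' @param from,to Period range in pixels (the empirical useful range is
#'   7-16 px: below 7 px the correlation peak is no longer distinct).
#' @return Numeric vector of periods (pixels), strictly increasing.
#' @export
log_periods <- function(n, from = 7, to = 16) {
  stopifnot(n >= 1, from > 0, to > from || n == 1)
  if (n == 1) return(from)
  p <- exp(seq(log(from), log(to), length.out = n))
  p[1] <- from
  p[n] <- to
  p
}

# shift a 2D FFT output so that frequency/lag zero sits at index s/2 + 1
fftshift2 <- function(m) {
  s <- nrow(m)
  i <- c((s / 2 + 1):s, 1:(s / 2))
  m[i, i]
}

#' Build the 3DPT reference set
#'
#' For each period `k_n` constructs the complex single-frequency reference
#' image `I_n(r) = f_win(r) exp(i 2 pi r / k_n)` with `r` the distance from
#' the ROI center and `f_win(r) = (cos(2 pi r / s) + 1) / 2` for `r < s/2`
#' (0 beyond), and caches `conj(FFT(I_n)) * f_B(q)` where `f_B` is a
#' Gaussian annulus `exp(-(q - 1/k_n)^2 / (2 w^2))` on radial spatial
#' frequency `q` (cycles/pixel). Cross correlation of a hologram with these
#' cached kernels is then a single FFT plus one inverse FFT per period.
#'
#' @param roi ROI side length (pixels, even).
#' @param periods Reference periods in pixels (strictly increasing). Periods
#'   below 7 px trigger a warning (no distinct correlation peak there);
#'   periods must stay below `roi / 2`.
#' @param w_rel Relative bandpass width: `w = w_rel / k_n` cycles/pixel.
#' @return Object of class `reference_set`.
#' @examples
#' refs <- reference_set(64, c(7, 16))
#' @export
reference_set <- function(roi, periods = log_periods(2), w_rel = 0.2) {
  s <- as.integer(roi)
  stopifnot(s %% 2L == 0L, s >= 32L, length(periods) >= 1)
  periods <- as.numeric(periods)
  if (is.unsorted(periods, strictly = TRUE)) {
    stop("'periods' must be strictly increasing")
  }
  if (any(periods >= s / 2)) stop("periods must be below roi/2 pixels")
  if (any(periods < 7 - 1e-9)) {
    warning("periods below 7 pixels do not yield a distinct correlation peak")
  }
  c0 <- s / 2
  d <- (0:(s - 1)) - c0
  r <- sqrt(outer(d^2, d^2, "+"))
  fwin <- ifelse(r < s / 2, (cos(2 * pi * r / s) + 1) / 2, 0)
  fr <- c(0:(s / 2 - 1), -(s / 2):-1) / s       # cyclic frequency grid
  q <- sqrt(outer(fr^2, fr^2, "+"))
  kernels <- lapply(periods, function(kn) {
    ref <- fwin * exp(2i * pi * r / kn)
    fB <- exp(-(q - 1 / kn)^2 / (2 * (w_rel / kn)^2))
    Conj(stats::fft(ref)) * fB
  })
  structure(
    list(roi = s, periods = periods, w_rel = w_rel, kernels = kernels),
    class = "reference_set")
}

#' Reference image of one period (for inspection)
#'
#' @param refs A [reference_set()].
#' @param which Period index.
#' @return Complex `roi x roi` matrix `I_n`.
#' @export
reference_image <- function(refs, which = 1L) {
  stopifnot(inherits(refs, "reference_set"))
  s <- refs$roi
  c0 <- s / 2
  d <- (0:(s - 1)) - c0
  r <- sqrt(outer(d^2, d^2, "+"))
  fwin <- ifelse(r < s / 2, (cos(2 * pi * r / s) + 1) / 2, 0)
  fwin * exp(2i * pi * r / refs$periods[which])
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("3DPT reference set: ROI %d px, %d period(s)\n",
              x$roi, length(x$periods)))
  cat("  periods (px):", paste(signif(x$periods, 4), collapse = ", "), "\n")
  cat(sprintf("  bandpass width: %.0f%% of 1/k_n\n", 100 * x$w_rel))
  invisible(x)
}

#' Band-passed FFT cross correlation with the reference set
#'
#' `CC_n = IFFT(f_B(q) conj(FFT(I_n)) FFT(I_bead))` per period: a cyclic
#' (no zero-padding) cross correlation. The returned maps are fftshifted so
#' that lag zero sits at the center pixel `roi/2` (0-based); a bead offset
#' of `(dx, dy)` pixels moves the amplitude peak by exactly `(dx, dy)`.
#'
#' @param image Hologram matrix (`roi x roi`).
#' @param refs A [reference_set()] of matching ROI size.
#' @return Object of class `cc_maps`: list of complex matrices (one per
#'   period) plus `roi` and `periods`.
#' @export
cross_correlate <- function(image, refs) {
  stopifnot(inherits(refs, "reference_set"))
  if (!is.matrix(image) || nrow(image) != refs$roi || ncol(image) != refs$roi) {
    stop("image size does not match the reference set ROI (",
         refs$roi, " px)")
  }
  FI <- stats::fft(image)
  n2 <- as.numeric(refs$roi)^2
  maps <- lapply(refs$kernels, function(W) {
    fftshift2(stats::fft(W * FI, inverse = TRUE) / n2)
  })
  structure(list(maps = maps, roi = refs$roi, periods = refs$periods),
            class = "cc_maps")
}

#' Sub-pixel xy localization from the correlation amplitude maps
#'
#' Multiplies the amplitude maps of (by default the first two) periods
#' elementwise, takes the argmax, and refines it with a separable 2D
#' quadratic fit to the log-amplitude over the 3x3 neighborhood (a Gaussian
#' peak model: the multiplied correlation peak is sharp and near-Gaussian,
#' and fitting the log removes the pixel-locking bias a plain quadratic
#' shows on such peaks). Ties at the argmax break deterministically toward
#' the smallest column-major index.
#'
#' @param cc A `cc_maps` object from [cross_correlate()].
#' @param n_use How many amplitude maps to multiply (>= 2 recommended; use
#'   `length(cc$maps)` for the product over all periods).
#' @param use Optional integer indices of the maps to multiply, overriding
#'   `n_use` (e.g. the periods with the strongest calibrated amplitude at
#'   the current height).
#' @return List with `x`, `y` (pixels, sub-pixel, relative to the ROI
#'   center), `amplitude` (interpolated peak height of the product map) and
#'   `flag` (`"ok"`, `"edge"` or `"no_bead"`).
#' @export
locate_xy <- function(cc, n_use = 2L, use = NULL) {
  stopifnot(inherits(cc, "cc_maps"))
  if (is.null(use)) {
    n_use <- min(max(n_use, 1L), length(cc$maps))
    use <- seq_len(n_use)
  }
  A <- Mod(cc$maps[[use[1]]])
  for (j in use[-1]) A <- A * Mod(cc$maps[[j]])
  s <- cc$roi
  c0 <- s / 2
  if (all(A <= 0) || !any(is.finite(A))) {
    return(list(x = NA_real_, y = NA_real_, amplitude = 0, flag = "no_bead"))
  }
  idx <- arrayInd(which.max(A), dim(A))
  i <- idx[1]; j <- idx[2]
  if (i == 1L || i == s || j == 1L || j == s) {
    return(list(x = j - 1 - c0, y = i - 1 - c0,
                amplitude = A[i, j], flag = "edge"))
  }
  vertex <- function(am, a0, ap) {
    # quadratic vertex on log amplitudes (Gaussian peak model); the peak
    # height is returned on the original scale
    if (am <= 0 || ap <= 0) {        # fall back to plain quadratic
      den <- am - 2 * a0 + ap
      if (den == 0) return(c(0, a0))
      d <- 0.5 * (am - ap) / den
      return(c(d, a0 - (am - ap)^2 / (8 * den)))
    }
    lm_ <- log(am); l0 <- log(a0); lp <- log(ap)
    den <- lm_ - 2 * l0 + lp
    if (den == 0) return(c(0, a0))
    d <- 0.5 * (lm_ - lp) / den
    c(d, exp(l0 - (lm_ - lp)^2 / (8 * den)))
  }
  vy <- vertex(A[i - 1, j], A[i, j], A[i + 1, j])
  vx <- vertex(A[i, j - 1], A[i, j], A[i, j + 1])
  list(x = j - 1 - c0 + vx[1], y = i - 1 - c0 + vy[1],
       amplitude = (vx[2] + vy[2]) / 2, flag = "ok")
}

#' Amplitude-weighted phase at the correlation peak
#'
#' The height-encoding phase `phi_n` is the argument of the
#' amplitude-weighted complex sum of `CC_n` over a `win x win` pixel window
#' centred on the rounded peak (weights `|CC_n|`). Complex averaging makes
#' the estimate wrap-safe at +/- pi.
#'
#' @param cc_map Complex correlation map (fftshifted, as returned inside
#'   [cross_correlate()]).
#' @param peak Numeric `c(x, y)` peak position in pixels relative to the ROI
#'   center (from [locate_xy()]).
#' @param win Window side (pixels, default the 10-pixel ROI).
#' @return List with `phase` (radians in `(-pi, pi]`), `amplitude` (mean
#'   `|CC_n|` over the window) and `flag` (`"ok"` or `"shrunk"` when the
#'   window was clipped at the map border).
#' @export
extract_phase <- function(cc_map, peak, win = 10L) {
  stopifnot(is.matrix(cc_map), length(peak) >= 2)
  s <- nrow(cc_map)
  c0 <- s / 2
  pj <- round(peak[1]) + c0 + 1   # column (x)
  pi_ <- round(peak[2]) + c0 + 1  # row (y)
  off <- seq.int(-(win %/% 2), length.out = win)
  rows <- pi_ + off
  cols <- pj + off
  flag <- "ok"
  if (any(rows < 1) || any(rows > s) || any(cols < 1) || any(cols > s)) {
    rows <- rows[rows >= 1 & rows <= s]
    cols <- cols[cols >= 1 & cols <= s]
    flag <- "shrunk"
    if (length(rows) == 0 || length(cols) == 0) {
      return(list(phase = NA_real_, amplitude = 0, flag = "outside"))
    }
  }
  sub <- cc_map[rows, cols, drop = FALSE]
  w <- Mod(sub)
  z <- sum(w * sub)
  list(phase = Arg(z), amplitude = mean(w), flag = flag)
}

#' Full per-frame 3DPT measurement
#'
#' Convenience wrapper: cross correlation, xy localization, and phase
#' extraction for every reference period.
#'
#' @inheritParams cross_correlate
#' @param n_xy Number of amplitude maps multiplied for the xy peak.
#' @param win Phase window side (pixels).
#' @param xy_use Optional explicit map indices for the xy peak (overrides
#'   `n_xy`).
#' @return List with `x`, `y` (pixels relative to the ROI center),
#'   `amplitude`, `phases` (radians, one per period), `amplitudes` (mean
#'   window amplitude per period) and `flag`.
#' @export
phasor_fix <- function(image, refs, n_xy = 2L, win = 10L, xy_use = NULL) {
  cc <- cross_correlate(image, refs)
  loc <- locate_xy(cc, n_use = n_xy, use = xy_use)
  if (loc$flag == "no_bead") {
    np <- length(refs$periods)
    return(list(x = NA_real_, y = NA_real_, amplitude = 0,
                phases = rep(NA_real_, np), amplitudes = rep(0, np),
                flag = "no_bead"))
  }
  ph <- lapply(cc$maps, extract_phase, peak = c(loc$x, loc$y), win = win)
  list(x = loc$x, y = loc$y, amplitude = loc$amplitude,
       phases = vapply(ph, `[[`, numeric(1), "phase"),
       amplitudes = vapply(ph, `[[`, numeric(1), "amplitude"),
       flag = loc$flag)
}
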