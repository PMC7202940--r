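#' Power spectral density of a position trace
#'
#' Mean-removed periodogram of a uniformly sampled trace, reported as the
#' two-sided spectral density on the positive half-axis `(0, f_s/2]` in
#' nm^2/Hz. With this convention white noise of variance `s^2` has a flat
#' density `s^2 / f_s`, so the high-frequency plateau is the tracking
#' accuracy `sigma^2/f_s` and `sigma = sqrt(plateau * f_s)` (see
#' [plateau_to_sd()]). Summed over the full symmetric spectrum the density
#' integrates to the trace variance (Parseval); the reported half-axis
#' carries half of it.
#'
#' @param trace Numeric vector (nm), at least 256 samples, no missing
#'   values.
#' @param f_s Sampling rate (Hz).
#' @param welch Number of Welch segments (50% overlap, Hann window); the
#'   default 1 is the plain periodogram.
#' @return Object of class `bead_psd`: list with `freq` (Hz), `power`
#'   (nm^2/Hz), `f_s`, `n`.
#' @export
psd_estimate <- function(trace, f_s, welch = 1L) {
  stopifnot(is.numeric(trace), f_s > 0)
  if (length(trace) < 256) stop("need at least 256 samples")
  if (anyNA(trace)) stop("missing values must be excluded upstream")
  if (welch <= 1L) {
    n <- length(trace)
    x <- trace - mean(trace)
    p <- Mod(stats::fft(x))^2 / (n * f_s)
    idx <- 2:(n %/% 2 + 1)
    out <- list(freq = (idx - 1) * f_s / n, power = p[idx], f_s = f_s, n = n)
  } else {
    seg <- floor(length(trace) / ((welch + 1) / 2))
    seg <- seg - seg %% 2
    if (seg < 64) stop("too many Welch segments for this trace length")
    starts <- seq(1, length(trace) - seg + 1, by = seg / 2)
    w <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / (seg - 1)))
    u <- mean(w^2)
    idx <- 2:(seg %/% 2 + 1)
    acc <- numeric(length(idx))
    for (s0 in starts) {
      x <- trace[s0:(s0 + seg - 1)]
      x <- (x - mean(x)) * w
      acc <- acc + (Mod(stats::fft(x))^2 / (seg * f_s * u))[idx]
    }
    out <- list(freq = (idx - 1) * f_s / seg, power = acc / length(starts),
                f_s = f_s, n = length(trace))
  }
  class(out) <- "bead_psd"
  out
}

#' @export
print.bead_psd <- function(x, ...) {
  cat(sprintf("PSD: %d samples at %.3g Hz, %d frequency bins\n",
              x$n, x$f_s, length(x$freq)))
  cat(sprintf("  plateau (f > 5 Hz): %.4g nm^2/Hz\n",
              tryCatch(psd_plateau(x), error = function(e) NA)))
  invisible(x)
}

#' @export
plot.bead_psd <- function(x, ...) {
  graphics::plot(x$freq, x$power, log = "xy", type = "l",
                 xlab = "frequency (Hz)", ylab = "PSD (nm^2/Hz)", ...)
  invisible(x)
}

#' High-frequency plateau of a PSD
#'
#' Least-squares horizontal fit (i.e. the mean density) over frequencies
#' above `f_min`, excluding the 1/f region dominated by drift and
#' vibrations.
#'
#' @param psd A [psd_estimate()] result.
#' @param f_min Lower fit frequency (Hz); 5 Hz by default, 2 Hz is the
#'   common alternative for quieter instruments.
#' @return Plateau density (nm^2/Hz).
#' @export
psd_plateau <- function(psd, f_min = 5) {
  stopifnot(inherits(psd, "bead_psd"))
  if (f_min >= psd$f_s / 2) stop("'f_min' must be below the Nyquist frequency")
  mean(psd$power[psd$freq > f_min])
}

#' Convert a PSD plateau to a tracking SD
#'
#' `sigma = sqrt(plateau * f_s)`: the convention under which a plateau of
#' 0.2 nm^2/Hz at 30 Hz imaging corresponds to 2.4 nm, or 1.0 nm at 5 Hz.
#'
#' @param plateau Plateau density (nm^2/Hz), >= 0.
#' @param f_s Frame rate (Hz).
#' @return Tracking SD (nm).
#' @examples
#' plateau_to_sd(0.2, 30)
#' @export
plateau_to_sd <- function(plateau, f_s) {
  stopifnot(all(plateau >= 0), f_s > 0)
  sqrt(plateau * f_s)
}

#' Remove common-mode drift from simultaneous bead traces
#'
#' Mechanical drift and vibrations are shared between beads in the same
#' field of view: the across-bead mean trace is low-pass filtered
#' (zero-phase 4th-order Butterworth, forward-backward) and subtracted
#' from every trace.
#'
#' @param traces Numeric matrix, one column per bead (equal lengths,
#'   at least two beads).
#' @param f_s Sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz) applied to the common mode.
#' @return List with `corrected` (matrix like `traces`) and `common_mode`
#'   (the subtracted vector).
#' @export
remove_common_mode <- function(traces, f_s, cutoff = 1) {
  traces <- as.matrix(traces)
  if (ncol(traces) < 2) {
    stop("common-mode removal needs at least two simultaneous traces")
  }
  stopifnot(cutoff > 0, cutoff < f_s / 2)
  cm <- rowMeans(traces)
  bf <- signal::butter(4, cutoff / (f_s / 2), type = "low")
  cm_lp <- signal::filtfilt(bf, cm - mean(cm)) + mean(cm)
  list(corrected = traces - cm_lp, common_mode = cm_lp)
}
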