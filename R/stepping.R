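#' Worm-like-chain parameters
#'
#' Elasticity parameters for mapping force-extension data to released
#' contour length. Defaults are the standard double-stranded DNA values:
#' 50 nm persistence length, thermal energy 4.11 pN nm (room temperature),
#' 0.34 nm contour length per base pair.
#'
#' @param L_p_nm Persistence length (nm).
#' @param kBT_pNnm Thermal energy (pN nm).
#' @param nm_per_bp Contour length per base pair (nm/bp).
#' @param sigma_track_nm Tracking error (nm) added in quadrature to the
#'   thermal SD of each point.
#' @param K0_pN Enthalpic stretch modulus (pN); the default `Inf` is the
#'   inextensible chain. DNA above ~5 pN is often modelled with
#'   `K0_pN = 1000`: the extension gains a linear `F/K0` term.
#' @return Object of class `wlc_params`.
#' @export
wlc_params <- function(L_p_nm = 50, kBT_pNnm = 4.11, nm_per_bp = 0.34,
                       sigma_track_nm = 5, K0_pN = Inf) {
  stopifnot(L_p_nm > 0, kBT_pNnm > 0, nm_per_bp > 0, sigma_track_nm >= 0,
            K0_pN > 0)
  structure(list(L_p_nm = L_p_nm, kBT_pNnm = kBT_pNnm,
                 nm_per_bp = nm_per_bp, sigma_track_nm = sigma_track_nm,
                 K0_pN = K0_pN),
            class = "wlc_params")
}

# relative extension zeta = z/L solving the Marko-Siggia interpolation
# f_scaled = F * L_p / kBT = 1/4 (1 - zeta)^-2 - 1/4 + zeta
wlc_zeta <- function(f_scaled) {
  vapply(f_scaled, function(fs) {
    if (fs <= 0) return(0)
    stats::uniroot(function(z) 0.25 / (1 - z)^2 - 0.25 + z - fs,
                   lower = 0, upper = 1 - 1e-12, tol = 1e-14)$root
  }, numeric(1))
}

#' Worm-like-chain extension
#'
#' Extension of a WLC of contour length `L` at force `F`, solving the
#' Marko-Siggia interpolation formula
#' `F = (kBT / L_p) (1/4 (1 - z/L)^-2 - 1/4 + z/L)` numerically. Strictly
#' increasing in `F`, `z` in `(0, L)`.
#'
#' @param L_nm Contour length (nm), > 0 (vectorized).
#' @param F_pN Force (pN), > 0 (vectorized or scalar).
#' @param p A [wlc_params()].
#' @return Extension (nm).
#' @examples
#' wlc_extension(1000, 5)
#' @export
wlc_extension <- function(L_nm, F_pN, p = wlc_params()) {
  stopifnot(all(L_nm > 0), all(F_pN > 0))
  L_nm * (wlc_zeta(F_pN * p$L_p_nm / p$kBT_pNnm) + F_pN / p$K0_pN)
}

#' Theoretical SD of a force-extension point
#'
#' Equipartition: `sigma^2 = kBT (dz/dF) + sigma_track^2`, with `dz/dF`
#' the analytic derivative of the Marko-Siggia relation at the operating
#' point.
#'
#' @inheritParams wlc_extension
#' @return SD (nm), same length as the broadcast inputs.
#' @export
wlc_point_sd <- function(F_pN, L_nm, p = wlc_params()) {
  zeta <- wlc_zeta(F_pN * p$L_p_nm / p$kBT_pNnm)
  dFdz_wlc <- (p$kBT_pNnm / p$L_p_nm) * (0.5 / (1 - zeta)^3 + 1) / L_nm
  dzdF <- 1 / dFdz_wlc + L_nm / p$K0_pN
  sqrt(p$kBT_pNnm * dzdF + p$sigma_track_nm^2)
}

#' WLC probability landscape over contour length
#'
#' For every candidate contour length the z score of each force-extension
#' point against the theoretical WLC extension (with its equipartition SD)
#' is converted to a standard-normal density and summed over points.
#' Stable states appear as peaks of the summed probability; spacings
#' between neighboring peaks are single unwrapping steps.
#'
#' @param force_pN,ext_nm Paired force-extension samples.
#' @param grid_bp Contour-length grid (bp); default 1-bp steps from 1 to
#'   `substrate_bp`.
#' @param substrate_bp Substrate length (bp) bounding the default grid.
#' @param p A [wlc_params()].
#' @return Object of class `step_analysis` with `grid_bp` and
#'   `probability` filled in.
#' @export
state_probability <- function(force_pN, ext_nm, grid_bp = NULL,
                              substrate_bp = NULL, p = wlc_params()) {
  stopifnot(length(force_pN) == length(ext_nm), length(force_pN) > 0,
            all(force_pN > 0), all(is.finite(ext_nm)))
  if (is.null(grid_bp)) {
    if (is.null(substrate_bp)) stop("give 'grid_bp' or 'substrate_bp'")
    grid_bp <- seq(1, substrate_bp)
  }
  if (length(grid_bp) > 1 && max(diff(grid_bp)) > 1 + 1e-9) {
    warning("contour grid coarser than 1 bp; peak positions lose resolution")
  }
  zeta <- wlc_zeta(force_pN * p$L_p_nm / p$kBT_pNnm)   # one root per point
  zeta_ext <- zeta + force_pN / p$K0_pN
  dFdz_L <- (p$kBT_pNnm / p$L_p_nm) * (0.5 / (1 - zeta)^3 + 1)
  prob <- numeric(length(grid_bp))
  for (g in seq_along(grid_bp)) {
    L <- grid_bp[g] * p$nm_per_bp
    sdv <- sqrt(p$kBT_pNnm * (L / dFdz_L + L / p$K0_pN) +
                  p$sigma_track_nm^2)
    prob[g] <- sum(stats::dnorm((ext_nm - L * zeta_ext) / sdv))
  }
  structure(list(grid_bp = grid_bp, probability = prob, params = p,
                 peaks_bp = NULL, steps_bp = NULL, histogram = NULL,
                 mixture = NULL, fundamental_bp = NULL),
            class = "step_analysis")
}

#' Detect stable states and step sizes in a probability landscape
#'
#' Peaks are local maxima with topographic prominence of at least
#' `prominence` times the landscape maximum, separated by at least
#' `min_sep_bp`; steps are the spacings between neighboring peaks.
#'
#' @param sa A [state_probability()] result.
#' @param prominence Relative prominence threshold.
#' @param min_sep_bp Minimum peak separation (bp).
#' @return The `step_analysis` with `peaks_bp` and `steps_bp` filled in
#'   (empty step list, with a message, if fewer than two peaks).
#' @export
find_steps <- function(sa, prominence = 0.1, min_sep_bp = 20) {
  stopifnot(inherits(sa, "step_analysis"))
  y <- sa$probability
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  thr <- prominence * max(y)
  keep <- vapply(cand, function(i) {
    lo_l <- lo_r <- y[i]
    j <- i
    while (j > 1 && y[j] <= y[i]) { j <- j - 1; lo_l <- min(lo_l, y[j]) }
    if (j == 1 && y[1] <= y[i]) lo_l <- min(lo_l, y[1])
    j <- i
    while (j < n && y[j] <= y[i]) { j <- j + 1; lo_r <- min(lo_r, y[j]) }
    if (j == n && y[n] <= y[i]) lo_r <- min(lo_r, y[n])
    (y[i] - max(lo_l, lo_r)) >= thr
  }, logical(1))
  pk <- cand[keep]
  # enforce minimum separation, keeping the higher peak
  if (length(pk) > 1) {
    pk <- pk[order(-y[pk])]
    sel <- integer(0)
    for (i in pk) {
      if (!length(sel) ||
          all(abs(sa$grid_bp[i] - sa$grid_bp[sel]) >= min_sep_bp)) {
        sel <- c(sel, i)
      }
    }
    pk <- sort(sel)
  }
  sa$peaks_bp <- sa$grid_bp[pk]
  if (length(pk) < 2) {
    message("fewer than two states detected; no step sizes")
    sa$steps_bp <- numeric(0)
  } else {
    sa$steps_bp <- diff(sa$peaks_bp)
  }
  sa
}

#' Fit a Gaussian mixture to a step-size histogram
#'
#' Histogram of step sizes (default bin width 12 bp) fitted by least
#' squares with a `K`-component Gaussian sum; component `k` is interpreted
#' as `k` simultaneous steps, so the fundamental step is the count-weighted
#' mean of `mu_k / k`.
#'
#' @param steps_bp Step sizes (bp), at least 10.
#' @param bin_bp Histogram bin width (bp).
#' @param K Number of mixture components.
#' @return List with `histogram` (`mids`, `counts`), `mixture`
#'   (data frame `mean`, `sd`, `weight` per component, NA rows for
#'   components that could not be fitted) and `fundamental_bp`.
#' @export
fit_step_histogram <- function(steps_bp, bin_bp = 12, K = 3L) {
  stopifnot(bin_bp > 0)
  if (length(steps_bp) < 10) stop("need at least 10 steps for the histogram fit")
  breaks <- seq(0, max(steps_bp) + bin_bp, by = bin_bp)
  h <- graphics::hist(steps_bp, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  mu0 <- mids[which.max(counts)]
  st <- list(A = rep(max(counts), K) / (1:K)^2,
             mu = mu0 * (1:K),
             sg = rep(max(bin_bp / 2, stats::sd(steps_bp) / 4), K))
  mixfun <- function(par) {
    A <- par[1:K]; mu <- par[K + (1:K)]; sg <- abs(par[2 * K + (1:K)])
    pred <- rowSums(vapply(1:K, function(k) {
      A[k] * exp(-(mids - mu[k])^2 / (2 * sg[k]^2))
    }, numeric(length(mids))))
    counts - pred
  }
  # degenerate histograms (all mass in one bin) make the optimizer grumble
  # before the fallback below takes over
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = c(st$A, st$mu, st$sg), fn = mixfun,
                         control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) {
    mixture <- data.frame(mean = NA_real_, sd = NA_real_, weight = NA_real_)
    fundamental <- stats::median(steps_bp)
  } else {
    A <- pmax(fit$par[1:K], 0)
    mu <- fit$par[K + (1:K)]
    sg <- abs(fit$par[2 * K + (1:K)])
    w <- A * sg                       # component area ~ counts
    ok <- is.finite(w) & w > 1e-6 & mu > 0
    mixture <- data.frame(mean = mu, sd = sg, weight = w / sum(w[ok]))
    mixture[!ok, ] <- NA
    fundamental <- sum((mu[ok] / seq_len(K)[ok]) * w[ok]) / sum(w[ok])
  }
  list(histogram = list(mids = mids, counts = counts, bin_bp = bin_bp),
       mixture = mixture, fundamental_bp = fundamental)
}

#' @export
print.step_analysis <- function(x, ...) {
  cat(sprintf("WLC state-probability landscape: %d grid points (%.0f-%.0f bp)\n",
              length(x$grid_bp), min(x$grid_bp), max(x$grid_bp)))
  if (!is.null(x$peaks_bp)) {
    cat(sprintf("  %d states at: %s bp\n", length(x$peaks_bp),
                paste(round(x$peaks_bp), collapse = ", ")))
    if (length(x$steps_bp)) {
      cat(sprintf("  steps: %s bp\n",
                  paste(round(x$steps_bp, 1), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
plot.step_analysis <- function(x, ...) {
  graphics::plot(x$grid_bp, x$probability, type = "l",
                 xlab = "contour length (bp)",
                 ylab = "summed probability", ...)
  if (!is.null(x$peaks_bp)) {
    graphics::abline(v = x$peaks_bp, col = "red3", lty = 3)
  }
  invisible(x)
}

#' Synthesize a stepped force-extension curve
#'
#' Piecewise-WLC pulling curve of a tether whose free contour length grows
#' by `step_bp` base pairs at each specified step force (the substrate
#' fully released reaches `L0_bp`), with Gaussian extension noise of the
#' theoretical per-point SD. A synthetic stand-in for stepwise-unwrapping
#' pulling data.
#'
#' @param L0_bp Substrate contour length (bp).
#' @param step_bp Step size (bp).
#' @param n_steps Number of steps; `n_steps * step_bp < L0_bp`.
#' @param force_pN Force ramp (pN), increasing.
#' @param step_forces_pN Forces at which steps occur (within the ramp).
#' @param p A [wlc_params()].
#' @param noise Logical: add the theoretical per-point noise.
#' @param seed Optional RNG seed.
#' @return List with `force_pN`, `ext_nm`, and `truth` (per-sample contour
#'   length in bp).
#' @export
synth_fe_curve <- function(L0_bp = 5000, step_bp = 80, n_steps = 10,
                           force_pN = seq(0.5, 25, length.out = 400),
                           step_forces_pN = NULL, p = wlc_params(),
                           noise = TRUE, seed = NULL) {
  stopifnot(n_steps * step_bp < L0_bp)
  if (is.null(step_forces_pN)) {
    step_forces_pN <- seq(5, max(force_pN) * 0.9, length.out = n_steps)
  }
  if (any(step_forces_pN < min(force_pN) |
          step_forces_pN > max(force_pN))) {
    stop("step forces must lie inside the force ramp")
  }
  if (!is.null(seed)) set.seed(seed)
  n_done <- vapply(force_pN, function(f) sum(step_forces_pN <= f),
                   numeric(1))
  L_bp <- (L0_bp - n_steps * step_bp) + n_done * step_bp
  L_nm <- L_bp * p$nm_per_bp
  ext <- wlc_extension(L_nm, force_pN, p)
  if (noise) {
    ext <- ext + stats::rnorm(length(ext)) * wlc_point_sd(force_pN, L_nm, p)
  }
  list(force_pN = force_pN, ext_nm = ext, truth = L_bp)
}
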