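---
title: "Holographic 3D bead tracking with phasor3d: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holographic 3D bead tracking with phasor3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Magnetic tweezers, tethered particle motion and acoustic force spectroscopy
all read out the conformation of a single molecule through the
three-dimensional position of a micron-sized bead imaged in wide field. A
defocused bead produces a hologram — concentric interference rings between
the illumination and the light scattered by the bead — whose center gives
the lateral position and whose ring structure encodes the height above
focus. `phasor3d` implements:

* a Lorenz-Mie forward model for these holograms (`render_hologram()`,
  `fit_lmst()`),
* the 3D phasor tracker: band-passed FFT cross correlation against
  computer-generated single-frequency reference images, lateral position
  from the correlation amplitude peak, height from the correlation phase
  with multi-frequency disambiguation (`reference_set()`,
  `phasor_fix()`, `calibrate_phase()`, `resolve_z()`, `track_video()`),
* a classical radial-profile look-up-table tracker as the baseline
  (`build_lut()`, `lut_track_video()`),
* an image-aberration robustness benchmark (`run_benchmark()`),
* spectral accuracy metrics and common-mode drift removal
  (`psd_estimate()`, `plateau_to_sd()`, `remove_common_mode()`),
* a worm-like-chain probability landscape for quantifying stepwise DNA
  unwrapping in force-extension curves (`state_probability()`,
  `find_steps()`, `fit_step_histogram()`).

# The hologram forward model

The scattered field of a homogeneous sphere is the Lorenz-Mie partial-wave
series. `mie_coefficients()` evaluates the coefficients by the
logarithmic-derivative downward recursion with a Wiscombe-style truncation
`N = x + 4x^(1/3) + 2`; the unit tests verify them against an independent
evaluation through half-integer Bessel functions to 1e-8 relative.
The field at a camera pixel is taken in the scalar, far-field
approximation:

$$ f_s(\mathbf d) = \tfrac12\,[S_1(\theta) + S_2(\theta)]\;
   \frac{e^{ikR}}{-ikR}, \qquad k = \frac{2\pi n_m}{\lambda}, $$

with $R$ the 3D distance from the bead and $\theta$ the scattering angle.
Polarization is dropped deliberately: the tracker exploits only the
circular symmetry of the pattern, and the scalar model preserves it
exactly. The pixel intensity is

$$ I(\rho) = \beta\left[1 + f_\gamma(r)\,
   \big(2\alpha\,\mathrm{Re}\{f_s e^{-ikz_p}\} +
   \alpha^2 |f_s|^2\big)\right], $$

where $f_\gamma(r) = (\cos(\pi r/\gamma)+1)/2$ for $r < \gamma$ (pixels
from the *bead* center) models the loss of fringe contrast away from the
pattern center caused by the limited spatial coherence of an LED source.
Two choices here deserve comment:

* **Envelope scope.** The envelope multiplies the scattering terms only;
  the constant background stays at $\beta$ across the ROI, as in real
  images. The literal alternative (envelope over the whole bracket,
  background decaying to zero at the ROI edge) is available via
  `envelope = "literal"`.
* **Envelope center.** The envelope is centred on the bead, not the ROI:
  it models the decay of the diffraction pattern from *its* center, and
  only this choice makes the rendered image exactly translation
  equivariant (verified by a resampling oracle in the tests).

Rendering evaluates the field on a 1D radial grid (0.25 px spacing) and
cubically interpolates to the raster; because the pattern is circularly
symmetric this is exact to well below one gray level and roughly
100 times faster than per-pixel series evaluation. Frames are quantized to
8 bits (round half away from zero, clip to 0-255) unless `quantize =
FALSE`.

Default optical parameters (`optical_model()`): bead radius 0.5 um, bead
index 1.9, water 1.33, wavelength 645 nm, alpha 1.0, beta 54 gray,
gamma 45 px, 112 nm pixels — a realistic 1.0 um paramagnetic bead on an
LED magnetic-tweezers setup. `fit_lmst()` fits the free pattern parameters
by Levenberg-Marquardt (`minpack.lm`), holding the bead radius and medium
index fixed by default.

# The phasor tracker

Each reference image is a Hann-windowed complex ring pattern of a single
radial period $k_n$ (pixels): $I_n(r) = f_{win}(r)\,e^{2\pi i r/k_n}$.
The cross correlation

$$ CC_n = \mathrm{IFFT}\big(f_B(q)\,\overline{\mathrm{FFT}(I_n)}\,
   \mathrm{FFT}(I_{bead})\big) $$

is cyclic (no zero padding) with a Gaussian annular bandpass centred at
radial frequency $1/k_n$ with width $w = 0.2/k_n$ cycles/px. The relative
width 0.2 keeps neighbouring log-spaced periods (7 to 16 px) spectrally
separated; much narrower annuli run into frequency-grid discretization at
the larger periods. Amplitude maps of two periods are multiplied and the
peak refined by a separable quadratic fitted to the *log* amplitude
(a Gaussian peak model): the plain quadratic pixel-locks by about 0.1 px
on the sharp multiplied peak, the log form is accurate to a few
hundredths of a pixel. The height-encoding phase is the amplitude-weighted
complex mean of $CC_n$ over a 10x10 px window at the rounded peak
(wrap-safe by construction). A 21x21 window was tried and rejected: it
swallows the phase rings and destroys the monotonicity of the phase-height
curves.

## Which periods carry signal

The local ring frequency of a hologram at radius $\rho$ is
$q(\rho) = k\rho/(2\pi R)$; the coherence envelope truncates the pattern
at $\rho \approx \gamma$, so periods shorter than $1/q(\gamma)$ px are
simply absent at a given height. With gamma = 45 px the 7 px period loses
its signal above roughly 8 um. This has three consequences in the design:

* `calibrate_phase()` marks a period unusable when its unwrapped phase is
  not strictly monotonic over the fit range — the authoritative gate.
* `track_video()` gates periods per frame by the *calibrated*
  amplitude-height profile (default: below 2% of the strongest period's
  amplitude at the current height). Gating on the per-frame measured
  amplitudes instead makes the selected set flicker with noise and
  injects tens of nanometers of switching noise — measured, and avoided.
  The threshold is intentionally a no-signal guard only: aggressive
  gating (10%+) discards high-sensitivity periods and worsens accuracy.
* The xy amplitude maps default to the two periods with the strongest
  calibrated amplitude at the current height (`n_xy = "auto"`); a fixed
  "first two" choice picks dead bands on wide ramps and corrupts the
  peak. `periods_for_height()` exposes the support calculation.

## Phase-height calibration and disambiguation

Along a focus ramp each period's phase unwraps trivially
(`unwrap_phase()`); a polynomial (default order 5; the standard protocol
uses 15, beyond ~10 the accuracy no longer improves) is fitted on an
orthogonal basis — raw powers are numerically singular at order 15 — and
inverted through a dense monotone table (10 nm grid). Residuals are
reported in nm through the local slope. Far from focus the phase grows
linearly with height with slope approximately proportional to
$1/k_n^2$ (the stationary-phase result); `calibrate_phase()` regresses
the measured slopes against the period and stores the empirical exponent
(about -2.2 over 7-16 px: larger periods bend away from the far-field
law) plus a focus estimate from the asymptote intercepts, both as
diagnostics only.

A single wrapped phase maps to a comb of candidate heights spaced by
$2\pi$; `resolve_z()` selects, over one candidate per period, the
combination with the smallest variance and returns its mean (anchor scan,
ties to the lowest mean). Tracking uses a height window of +/-1.5 um
around the previous frame (first frame: the full calibrated range). An
exhaustive sweep test verifies that noiseless phases resolve without any
$2\pi$ misassignment anywhere in the calibrated range.

# Accuracy metric

Tracking accuracy is quantified as the high-frequency plateau of the
power spectral density of the tracking error, in nm^2/Hz. The PSD
convention is chosen so that white noise of variance $\sigma^2$ has a
flat density $\sigma^2/f_s$ and therefore
$\sigma = \sqrt{\mathrm{plateau} \times f_s}$ (`plateau_to_sd()`):
a 0.2 nm^2/Hz plateau at 30 Hz imaging means 2.4 nm tracking accuracy,
or 1.0 nm at 5 Hz. Note this reports the *two-sided* density on the
positive half-axis: the textbook one-sided density would be twice as
large and the conversion $\sqrt{\mathrm{plateau}\,f_s/2}$. The plateau is
fitted as the mean density above 5 Hz by default (2 Hz is the common
alternative on quieter instruments), excluding the 1/f region from drift
and vibrations. `remove_common_mode()` implements the standard
multi-bead drift correction: subtract the 1 Hz-low-passed across-bead
mean trace (zero-phase 4th-order Butterworth, so the subtracted common
mode has no phase lag).

# The robustness benchmark

`run_benchmark()` reproduces the simulation protocol used throughout the
package's accuracy claims: 1.0 um bead holograms at height
12,000 +/- 5 nm and lateral jitter 0 +/- 5 nm, one 150x150 8-bit frame
per 30 Hz time step (600 frames per cell by default; 3600 frames — a
2-minute record — for the full protocol), tracked with 15 log-spaced
reference periods (7-16 px) calibrated at order 15 on a 300-frame ramp
from 5 to 15 um. Artifacts: intensity-scaled Poisson-like noise
(severity = image-mean SD in gray; variance-based variants available),
interlacing gain on alternate rows (100% = gain 2), an additive linear
light gradient along y (100% reaches white at the far edge), astigmatic
y-compression (100% = aspect ratio 2), and a mean ROI shift in x
(severity as % of the ROI). A cell is "lost" when more than half the
frames cannot be tracked.

Measured on this simulator, the noiseless 8-bit baseline plateau is
about 0.1-0.2 nm^2/Hz in z (quantization-limited: float frames reach
~0.002), sub-0.02 nm^2/Hz in x/y; interlacing at any severity and ROI
shifts to 30% leave it unchanged; a 45% ROI shift loses the bead; light
gradients to 20% stay below 1 nm^2/Hz; astigmatism is the most damaging
artifact. These are the quantities the acceptance tests assert.

## A known limitation: the absolute noise-response scale

The per-period phase noise of this implementation sits within about a
factor 2 of the matched-filter bound computed from the in-band ring
energy of the rendered images, so the *relative* robustness ordering of
the artifacts is trustworthy. The *absolute* scale of the noise response,
however, is a property of the rendered ring contrast: with the default
beta = 54 background the rings span only a few tens of gray levels, and
per-pixel noise of 3 gray costs about 10 nm^2/Hz in z. Real instruments
(and other simulators) with stronger fringe contrast will do
proportionally better; reported accuracy figures in this regime differ
by severals-fold depending on image normalization. The tests therefore
pin ratios and bounds where the physics is scale-free, and treat
absolute noise-response numbers as properties of these study conditions.

# The worm-like-chain stepping module

Force-extension curves of chromatin release DNA from the histone core in
discrete steps. Each curve point is compared to the Marko-Siggia
worm-like-chain extension of every candidate contour length $L$ (1 bp
grid), with a per-point SD from equipartition,
$\sigma^2 = k_BT\,(dz/dF) + \sigma_{track}^2$; the standard-normal
density of the z score is summed over points
(`state_probability()`). Stable states are landscape peaks (topographic
prominence >= 10% of the maximum, separation >= 20 bp); neighbor
spacings are single unwrapping steps; the step histogram (12 bp bins) is
fitted with a 3-component Gaussian sum whose k-th component is read as k
simultaneous steps, making the fundamental step the count-weighted mean
of $\mu_k/k$ (`fit_step_histogram()`). Defaults: persistence length
50 nm, $k_BT$ = 4.11 pN nm, 0.34 nm/bp — standard double-stranded DNA
values; tracking error 5 nm, matching the tracker's accuracy at 30 Hz.
The inextensible Marko-Siggia form is the default because the stepping
analysis operates on *differences* of contour length where the enthalpic
correction largely cancels; an extensible variant is available through
the stretch modulus `wlc_params(K0_pN = 1000)`. `synth_fe_curve()` generates stepped
piecewise-WLC curves with the theoretical per-point noise; the tests
recover programmed steps of 40, 80 and 120 bp within 5% through the full
pipeline. What synthetic curves do not emulate: instrument drift within
a curve, force-calibration error, and the heterogeneity of real
chromatin fibers — recovery on real data depends on those.

# Numerical choices and degenerate inputs

* Mie series: downward log-derivative recursion started 16 orders above
  the truncation; non-convergence raises a diagnostic error.
* Quantization: round half away from zero, clip to [0, 255].
* Sub-pixel ties at the correlation argmax break toward the smallest
  column-major index; peaks on the map border are flagged `edge`.
* An exactly zero correlation map flags `no_bead`; a flat 1D trace in
  the LUT center finder flags `flat` and returns the ROI center.
* Missing (flagged) frames stay in the track as `NA` and are excluded
  from PSD computation upstream.
* Empty LUT annuli are linearly interpolated; a LUT query whose minimum
  falls on the grid edge is clamped and flagged.
* All randomness flows through explicit seeds; benchmark tables are
  bit-for-bit reproducible for a fixed seed.

# Problem sizes used by the tests

The test-suite and the acceptance script size their simulations as: 600
frames per benchmark cell (plateau estimator spread about 7%, so
stochastic assertions use factor-2 to factor-3 bands), a 300-frame
calibration ramp for the standard setup, a 201-frame ramp for the
calibration-residual check, and 5-6 seeds per recovery experiment.
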