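# phasor3d

Nanometric 3D localization of microbeads from in-line holograms, for
single-molecule force spectroscopy (magnetic tweezers, tethered particle
motion, acoustic force spectroscopy). A defocused bead imaged in wide
field produces concentric interference rings; the ring center gives the
lateral position and the ring structure encodes the height above focus
over a range of more than 10 µm.

The package implements the **3D phasor tracking** algorithm together with
everything needed to exercise it on synthetic data:

* **Hologram simulator** — Lorenz–Mie scattering of a homogeneous sphere
  (scalar far field, partial-wave series with Wiscombe truncation), a
  raised-cosine coherence envelope for LED illumination, 8-bit
  quantization, and Levenberg–Marquardt fitting of the forward model to
  images (`render_hologram()`, `fit_lmst()`).
* **Phasor tracker** — complex reference images
  `I_n(r) = f_win(r)·exp(2πi r/k_n)` of single radial periods `k_n`;
  band-passed cyclic FFT cross correlation
  `CC_n = IFFT(f_B · conj(FFT(I_n)) · FFT(I_bead))`; sub-pixel xy from
  the multiplied amplitude peaks; height from the amplitude-weighted
  correlation phase, calibrated per period by polynomials `φ_n(z)` on a
  focus ramp and disambiguated across periods (`2π` candidate combs,
  minimum-variance selection). Far from focus `φ_n ≈ c·z/k_n²`.
* **LUT baseline** — the classical mirror-correlation center finder plus
  radial-profile look-up-table height interpolation.
* **Robustness benchmark** — shot noise, interlacing, light gradients,
  astigmatism and ROI shift at graded severities; accuracy quantified as
  the high-frequency plateau `σ²/f_s` of the tracking-error PSD, with
  `σ = sqrt(plateau · f_s)`.
* **Step detection** — worm-like-chain (Marko–Siggia) z-score
  probability landscapes over contour length for quantifying discrete
  DNA-unwrapping steps in force–extension curves, with a Gaussian-mixture
  step-size histogram fit.

See the vignette (`vignettes/phasor-tracking-methods.Rmd`) for the
models, parameter meanings and design decisions.

## Worked example

Simulate the standard tracking protocol — a 1.0 µm paramagnetic bead
12 µm above focus, wandering by 5 nm per axis, imaged at 30 Hz on 150×150
px 8-bit frames — calibrate, track, and quantify the accuracy:

```r
library(phasor3d)
set.seed(1)

model <- optical_model()      # 0.5 um radius, n_p 1.9, 645 nm, 112 nm px
setup <- standard_setup(model, seed = 1)   # 15 periods + order-15 ramp calibration

traj  <- trajectory_random(n_frames = 600, f_s = 30, seed = 2)
video <- render_video(model, traj, roi = 150, as_function = TRUE)
track <- track_video(video, setup$refs, setup$cal, z_window = c(10000, 14000))
print(track)

err     <- track$z_nm - traj$z_nm
plateau <- psd_plateau(psd_estimate(err - mean(err), f_s = 30), f_min = 5)
cat(sprintf("z error PSD plateau: %.3f nm^2/Hz -> %.2f nm at 30 Hz\n",
            plateau, plateau_to_sd(plateau, 30)))
```

```
3DPT bead track: 600 frames at 30 Hz (600 tracked, 0 flagged)
  mean position: x 0.5 nm, y 0.1 nm, z 12000 nm
  SD:            x 5.47 nm, y 5.26 nm, z 6.09 nm
z error PSD plateau: 0.194 nm^2/Hz -> 2.41 nm at 30 Hz
```

The per-axis SDs reproduce the simulated 5 nm Brownian wander (the
tracker adds ~0.1 nm laterally and ~2.4 nm in z on these 8-bit frames);
the PSD plateau of the *error* trace is the tracking accuracy: here
0.19 nm²/Hz, i.e. 2.4 nm at the full 30 Hz bandwidth, quantization-limited
(float frames reach ~0.002 nm²/Hz). Printing `setup$cal` shows the
per-period calibration: periods that lose their spectral support at these
heights are flagged non-monotonic and excluded automatically.

A command-line interface covering simulation, calibration, tracking, the
aberration benchmark and step quantification is provided in
`exec/phasor3d` (`phasor3d help`).

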