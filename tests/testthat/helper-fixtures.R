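# shared fixtures, memoised so the expensive ones build once per test run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the robustness-simulation bead (1.0 um paramagnetic bead on the 645 nm
# LED setup)
sim_model <- function() optical_model()

# the experimentally fitted bead used for calibration-residual checks
exp_model <- function() {
  optical_model(a_um = 0.5, n_p = 1.9, n_m = 1.33, lambda_nm = 645,
                alpha = 0.9, beta = 57, gamma_px = 57)
}

# full 15-period standard tracking setup (8-bit ramp, order-15 polynomials)
std_setup <- function() {
  memo("std_setup", suppressWarnings(standard_setup(sim_model(), seed = 1)))
}

# small 4-period calibration on a float ramp (for fast zcal tests)
small_cal <- function() {
  memo("small_cal", {
    refs <- reference_set(150, log_periods(4))
    tramp <- trajectory_ramp(5000, 15000, 201)
    gen <- function(i) {
      render_hologram(exp_model(), c(0, 0, tramp$z_nm[i]), roi = 150,
                      quantize = FALSE)
    }
    attr(gen, "n_frames") <- nrow(tramp)
    cal <- suppressWarnings(
      calibrate_from_video(gen, tramp$z_nm, refs, order = 5))
    list(refs = refs, cal = cal)
  })
}

# independent Mie oracle: Bohren-Huffman coefficient formulas evaluated with
# base R half-integer Bessel functions (a different route than the
# logarithmic-derivative recursion in the package)
mie_oracle <- function(x, m, nmax) {
  psi <- function(n, z) sqrt(pi * z / 2) * besselJ(z, n + 0.5)
  chi <- function(n, z) -sqrt(pi * z / 2) * besselY(z, n + 0.5)
  xi <- function(n, z) complex(real = psi(n, z), imaginary = -chi(n, z))
  dpsi <- function(n, z) psi(n - 1, z) - n / z * psi(n, z)
  dxi <- function(n, z) xi(n - 1, z) - n / z * xi(n, z)
  n <- seq_len(nmax)
  a <- (m * psi(n, m * x) * dpsi(n, x) - psi(n, x) * dpsi(n, m * x)) /
       (m * psi(n, m * x) * dxi(n, x) - xi(n, x) * dpsi(n, m * x))
  b <- (psi(n, m * x) * dpsi(n, x) - m * psi(n, x) * dpsi(n, m * x)) /
       (psi(n, m * x) * dxi(n, x) - m * xi(n, x) * dpsi(n, m * x))
  list(a = a, b = b)
}

# brute-force cyclic spatial-domain cross correlation with the band-passed
# reference (the direct evaluation of the frequency-domain product)
spatial_cc_oracle <- function(image, refs, which = 1L) {
  s <- refs$roi
  # band-passed reference in the spatial domain: kernels store
  # conj(FFT(ref)) * fB, so FFT(ref_bp) = conj(kernel)
  ref_bp <- stats::fft(Conj(refs$kernels[[which]]), inverse = TRUE) / s^2
  cc <- matrix(0 + 0i, s, s)
  for (dy in 0:(s - 1)) {
    for (dx in 0:(s - 1)) {
      ix <- ((0:(s - 1)) + dx) %% s + 1
      iy <- ((0:(s - 1)) + dy) %% s + 1
      cc[dy + 1, dx + 1] <- sum(Conj(ref_bp) * image[iy, ix])
    }
  }
  cc
}
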