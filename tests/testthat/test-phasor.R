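test_that("reference image takes the stated values at the center and edge", {
  refs <- reference_set(100, c(10, 16))
  ref <- reference_image(refs, 1)
  expect_equal(ref[51, 51], 1 + 0i)          # r = 0: full window, phase 0
  # any pixel at r >= s/2 is zero
  expect_equal(ref[51, 1], 0 + 0i)
  expect_equal(ref[1, 1], 0 + 0i)
  expect_error(reference_set(100, c(16, 10)), "increasing")
  expect_error(reference_set(100, 60), "roi/2")
  expect_warning(reference_set(64, 5), "7 pixels")
})

test_that("the reference transform peaks at the design frequency", {
  refs <- reference_set(100, c(10))
  F <- Mod(stats::fft(reference_image(refs, 1)))
  fr <- c(0:49, -50:-1) / 100
  q <- sqrt(outer(fr^2, fr^2, "+"))
  q_peak <- q[which.max(F)]
  expect_lt(abs(q_peak - 1 / 10), 1 / 100 + 1e-12)   # within one bin
})

test_that("frequency-domain correlation equals brute-force spatial correlation", {
  set.seed(7)
  refs <- reference_set(32, c(7))
  img <- matrix(runif(32 * 32, 0, 255), 32)
  cc <- cross_correlate(img, refs)
  oracle <- spatial_cc_oracle(img, refs, 1)
  sh <- c(17:32, 1:16)
  oracle_sh <- oracle[sh, sh]
  expect_lt(max(Mod(cc$maps[[1]] - oracle_sh)) / max(Mod(oracle_sh)), 1e-10)
})

test_that("the amplitude peak sits at the bead and follows cyclic shifts", {
  m <- sim_model()
  refs <- reference_set(150, c(12, 16))
  img <- render_hologram(m, c(0, 0, 12000), roi = 150)
  loc0 <- locate_xy(cross_correlate(img, refs))
  expect_equal(loc0$flag, "ok")
  expect_lt(abs(loc0$x), 0.01)
  expect_lt(abs(loc0$y), 0.01)
  # cyclic integer shifts move the peak by exactly the shift
  for (d in list(c(5, 0), c(0, -7), c(11, 3))) {
    shifted <- img[(seq_len(150) - 1 - d[2]) %% 150 + 1,
                   (seq_len(150) - 1 - d[1]) %% 150 + 1]
    loc <- locate_xy(cross_correlate(shifted, refs))
    expect_equal(c(loc$x, loc$y), d, tolerance = 1e-6)
  }
})

test_that("a featureless image has no correlation amplitude", {
  refs <- reference_set(64, c(8, 12))
  # constant image: only the Gaussian tail of the bandpass at DC leaks
  # through, orders of magnitude below any bead peak
  cc <- cross_correlate(matrix(100, 64, 64), refs)
  bead_cc <- cross_correlate(
    render_hologram(sim_model(), c(0, 0, 8000), roi = 64), refs)
  expect_lt(max(Mod(cc$maps[[1]])), 1e-4 * max(Mod(bead_cc$maps[[1]])))
  # an exactly zero map is flagged as bead-free
  loc <- locate_xy(cross_correlate(matrix(0, 64, 64), refs))
  expect_equal(loc$flag, "no_bead")
})

test_that("sub-pixel localization is accurate to a few hundredths of a pixel", {
  m <- sim_model()
  refs <- reference_set(150, c(12, 16))
  img3 <- render_hologram(m, c(3 * m$pixel_nm, 0, 12000), roi = 150)
  loc3 <- locate_xy(cross_correlate(img3, refs))
  expect_equal(loc3$x, 3, tolerance = 0.02)
  # 0.3 px = 33.6 nm at 112 nm pixels
  imgs <- render_hologram(m, c(0.3 * m$pixel_nm, 0, 12000), roi = 150)
  locs <- locate_xy(cross_correlate(imgs, refs))
  expect_equal(locs$x, 0.3, tolerance = 0.05)
  expect_lt(abs(locs$y), 0.05)
})

test_that("phase extraction is an amplitude-weighted circular mean", {
  # uniform phase across the window is returned exactly
  cc <- matrix(complex(modulus = 2, argument = 1.0), 64, 64)
  expect_equal(extract_phase(cc, c(0, 0))$phase, 1.0, tolerance = 1e-12)
  # two equal-amplitude phases straddling +/- pi average to pi, not 0
  cc2 <- matrix(0 + 0i, 64, 64)
  cc2[32, 32] <- complex(modulus = 1, argument = pi - 0.1)
  cc2[32, 33] <- complex(modulus = 1, argument = -(pi - 0.1))
  ph <- extract_phase(cc2, c(0, 0))$phase
  expect_equal(abs(ph), pi, tolerance = 1e-9)
  # a window that hits the border is shrunk and flagged
  out <- extract_phase(cc, c(30, 30))
  expect_equal(out$flag, "shrunk")
})

test_that("integer shifts move xy and leave the phases unchanged", {
  m <- sim_model()
  refs <- reference_set(150, log_periods(4, 10, 16))
  img <- render_hologram(m, c(0, 0, 12000), roi = 150)
  fix0 <- phasor_fix(img, refs, n_xy = 4)
  set.seed(3)
  for (i in 1:4) {
    d <- sample(-20:20, 2)
    shifted <- img[(seq_len(150) - 1 - d[2]) %% 150 + 1,
                   (seq_len(150) - 1 - d[1]) %% 150 + 1]
    fx <- phasor_fix(shifted, refs, n_xy = 4)
    expect_equal(c(fx$x, fx$y), c(fix0$x + d[1], fix0$y + d[2]),
                 tolerance = 1e-6)
    expect_equal(fx$phases, fix0$phases, tolerance = 1e-6)
  }
})

test_that("phase increments along z match the calibration slope", {
  sc <- small_cal()
  m <- exp_model()
  z0 <- 9000
  dz <- 100
  f1 <- phasor_fix(render_hologram(m, c(0, 0, z0), 150, quantize = FALSE),
                   sc$refs, n_xy = 4)
  f2 <- phasor_fix(render_hologram(m, c(0, 0, z0 + dz), 150,
                                   quantize = FALSE), sc$refs, n_xy = 4)
  for (j in which(sc$cal$usable)) {
    dphi <- (f2$phases[j] - f1$phases[j] + pi) %% (2 * pi) - pi
    pp <- sc$cal$per_period[[j]]
    slope <- diff(stats::approx(pp$grid_z, pp$grid_phi,
                                xout = c(z0, z0 + dz))$y) / dz
    expect_lt(abs(dphi / dz - slope) / abs(slope), 0.05)
  }
})
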