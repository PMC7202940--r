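test_that("mirror correlation finds the bead center", {
  m <- sim_model()
  c0 <- lut_locate_xy(render_hologram(m, c(0, 0, 12000), roi = 150))
  expect_lt(abs(c0$x), 0.05)
  expect_lt(abs(c0$y), 0.05)
  c2 <- lut_locate_xy(render_hologram(m, c(2 * m$pixel_nm, 0, 12000),
                                      roi = 150))
  expect_equal(c2$x, 2, tolerance = 0.1)
  c04 <- lut_locate_xy(render_hologram(m, c(0.4 * m$pixel_nm, 0, 12000),
                                       roi = 150))
  expect_equal(c04$x, 0.4, tolerance = 0.15)
  flat <- lut_locate_xy(matrix(100, 64, 64))
  expect_equal(flat$flag, "flat")
})

test_that("radial profiles average annuli and notice off-centering", {
  expect_equal(radial_profile(matrix(7, 64, 64)), rep(7, 32))
  m <- sim_model()
  img <- render_hologram(m, c(0, 0, 12000), roi = 150, quantize = FALSE)
  p0 <- radial_profile(img)
  # extrema count of the profile equals the visible ring count
  n_extrema <- sum(diff(sign(diff(p0))) != 0)
  expect_gt(n_extrema, 3)
  p3 <- radial_profile(img, c(3, 0))
  expect_gt(sqrt(mean((p3 - p0)^2)), 0)
  expect_error(radial_profile(img, c(200, 0)), "outside")
})

test_that("LUT height interpolation is exact at nodes and accurate between", {
  m <- sim_model()
  zg <- seq(10000, 14000, length.out = 64)
  gen <- function(i) render_hologram(m, c(0, 0, zg[i]), roi = 150)
  attr(gen, "n_frames") <- 64L
  lut <- memo("lut64", build_lut(gen, zg))
  # node fidelity: each node's own profile returns its height exactly
  for (j in c(1, 20, 64)) {
    expect_equal(lut_z(lut$profiles[j, ], lut)$z_nm, zg[j])
  }
  zmid <- (zg[30] + zg[31]) / 2
  pm <- radial_profile(render_hologram(m, c(0, 0, zmid), roi = 150))
  expect_lt(abs(lut_z(pm, lut)$z_nm - zmid), 20)
  # an out-of-range profile clamps with a flag
  plo <- radial_profile(render_hologram(m, c(0, 0, 9000), roi = 150))
  expect_equal(lut_z(plo, lut)$flag, "edge")
})

test_that("the LUT baseline is less accurate than 3DPT on identical frames", {
  # the classical comparison protocol: bead wandering with 100 nm spread,
  # shot noise of 5 gray; errors summarized as median +/- IQR because the
  # LUT's 1D center finder produces occasional large outliers
  m <- sim_model()
  zg <- seq(10000, 14000, length.out = 64)
  gen <- function(i) render_hologram(m, c(0, 0, zg[i]), roi = 150)
  attr(gen, "n_frames") <- 64L
  lut <- memo("lut64", build_lut(gen, zg))
  std <- std_setup()
  run_pair <- function(noise_sd) {
    set.seed(77)
    traj <- trajectory_random(120, 30, mean = c(0, 0, 12000),
                              sd = c(100, 100, 100), seed = 78)
    frames <- lapply(seq_len(120), function(i) {
      img <- render_hologram(m, as.numeric(traj[i, c("x_nm", "y_nm",
                                                     "z_nm")]),
                             roi = 150, quantize = FALSE)
      if (noise_sd > 0) {
        img <- img + rnorm(length(img), 0, noise_sd) * sqrt(img / mean(img))
      }
      quantize_image(img)
    })
    t3 <- track_video(frames, std$refs, std$cal, z_window = c(10000, 14000))
    tl <- lut_track_video(frames, lut)
    ok3 <- t3$flag %in% c("ok", "low_confidence")
    list(z3 = t3$z_nm[ok3] - traj$z_nm[ok3],
         zl = tl$z_nm - traj$z_nm,
         x3 = t3$x_nm[ok3] - traj$x_nm[ok3],
         xl = tl$x_nm - traj$x_nm)
  }
  clean <- run_pair(0)
  noisy <- run_pair(5)
  # noiseless: LUT height scatter and bias both exceed 3DPT
  expect_gt(stats::IQR(clean$zl), stats::IQR(clean$z3))
  expect_gt(abs(stats::median(clean$zl)), abs(stats::median(clean$z3)))
  # shot noise induces a systematic height error in the LUT larger than
  # 3DPT's, and degrades its xy localization more
  expect_gt(abs(stats::median(noisy$zl)), abs(stats::median(noisy$z3)))
  expect_gt(stats::IQR(noisy$xl), stats::IQR(noisy$x3))
  expect_gt(abs(stats::median(noisy$zl)), abs(stats::median(clean$zl)))
})
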