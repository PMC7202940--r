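test_that("phase unwrapping removes 2*pi jumps and nothing else", {
  expect_equal(unwrap_phase(c(0.1, 0.2, 0.3)), c(0.1, 0.2, 0.3))
  expect_equal(unwrap_phase(c(3.0, -3.1)), c(3.0, -3.1 + 2 * pi),
               tolerance = 1e-12)
  expect_equal(unwrap_phase(c(-3.0, 3.1)), c(-3.0, 3.1 - 2 * pi),
               tolerance = 1e-12)
  expect_length(unwrap_phase(1.5), 1)
  # a noiseless simulated ramp unwraps to a monotonic curve in every period
  sc <- small_cal()
  for (pp in sc$cal$per_period[sc$cal$usable]) {
    expect_true(all(diff(pp$grid_phi) > 0) || all(diff(pp$grid_phi) < 0))
  }
})

test_that("calibration recovers phases generated from its own model class", {
  z <- seq(5000, 15000, length.out = 200)
  zc <- (z - 10000) / 5000
  truth <- 3 + 2.5 * zc - 0.8 * zc^2 + 0.3 * zc^3 + 0.05 * zc^5
  phases <- cbind((truth + pi) %% (2 * pi) - pi,
                  (2 * truth + pi) %% (2 * pi) - pi)
  cal <- calibrate_phase(z, phases, c(10, 14), order = 5, dense_nm = 1)
  pred <- predict(cal, z)
  # the least-squares fit is exact for its own model class (sigma_res ~ 0);
  # the stored forward table adds only linear-interpolation error
  expect_equal(pred[, 1] - pred[1, 1], truth - truth[1], tolerance = 1e-7)
  expect_lt(max(cal$sigma_res_nm), 1e-6)
})

test_that("forward and inverse calibration are mutually consistent", {
  sc <- small_cal()
  zg <- seq(sc$cal$range[1] + 50, sc$cal$range[2] - 50, by = 97)
  for (j in which(sc$cal$usable)) {
    pp <- sc$cal$per_period[[j]]
    phi <- stats::approx(pp$grid_z, pp$grid_phi, xout = zg)$y
    z_back <- stats::approx(pp$grid_phi, pp$grid_z, xout = phi)$y
    expect_lt(max(abs(z_back - zg)), 1)
  }
})

test_that("calibration slopes follow an inverse-square-like power of the period", {
  sc <- small_cal()
  expect_true(all(sc$cal$usable))
  # the empirical exponent of the linear phase-height law: close to -2
  # (diffraction), slightly steeper because larger periods bend away from
  # the far-field law
  expect_gt(sc$cal$slope_exponent, -2.6)
  expect_lt(sc$cal$slope_exponent, -1.8)
  # each period's slope follows the fitted power law within 10%
  slopes <- vapply(sc$cal$per_period, `[[`, numeric(1), "asym_slope")
  fitted_law <- sc$cal$c_factor * sc$cal$periods^sc$cal$slope_exponent
  expect_lt(max(abs(abs(slopes) / fitted_law - 1)), 0.1)
  # the finest period's slope matches the stationary-phase prediction
  k <- 2 * pi * exp_model()$n_m / exp_model()$lambda_nm
  theory <- (2 * pi / (7 * exp_model()$pixel_nm))^2 / (2 * k)
  expect_equal(abs(slopes[1]), theory, tolerance = 0.1)
  # residual SD stays in the nanometer range for every period
  expect_lt(max(sc$cal$sigma_res_nm), 15)
})

test_that("multi-frequency resolution returns the generating height", {
  sc <- small_cal()
  phases <- predict(sc$cal, 9000, wrapped = TRUE)
  rz <- resolve_z(as.numeric(phases), sc$cal)
  expect_equal(rz$z_nm, 9000, tolerance = 1)
  expect_equal(rz$flag, "ok")
  # exhaustive sweep: no 2*pi misassignment anywhere in the range
  zg <- seq(sc$cal$range[1] + 100, sc$cal$range[2] - 100, by = 10)
  ph <- predict(sc$cal, zg, wrapped = TRUE)
  err <- vapply(seq_along(zg), function(i) {
    resolve_z(ph[i, ], sc$cal)$z_nm - zg[i]
  }, numeric(1))
  expect_lt(max(abs(err)), 2)
})

test_that("a single period with a narrow window is unambiguous", {
  sc <- small_cal()
  j <- which(sc$cal$usable)[1]
  phases <- rep(NA_real_, 4)
  phases[j] <- predict(sc$cal, 9000, wrapped = TRUE)[, j]
  use <- seq_len(4) == j
  rz <- resolve_z(phases, sc$cal, z_window = c(8800, 9200), use = use)
  expect_equal(length(rz$candidates), 1)
  expect_equal(rz$z_nm, 9000, tolerance = 1)
})

test_that("wrapped phase noise does not cause 2*pi misassignments", {
  sc <- small_cal()
  z_star <- 9000
  ph0 <- as.numeric(predict(sc$cal, z_star, wrapped = TRUE))
  # half the z spacing of the finest usable period
  slopes <- vapply(sc$cal$per_period, function(pp) {
    abs(diff(stats::approx(pp$grid_z, pp$grid_phi,
                           xout = c(z_star, z_star + 10))$y) / 10)
  }, numeric(1))
  guard <- pi / max(slopes[sc$cal$usable])
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    ph <- (ph0 + rnorm(4, 0, 0.05) + pi) %% (2 * pi) - pi
    rz <- resolve_z(ph, sc$cal, z_window = c(7000, 11000))
    worst <- max(worst, abs(rz$z_nm - z_star))
  }
  expect_lt(worst, guard)
})

test_that("a static video tracks with sub-0.1 nm spread", {
  std <- std_setup()
  img <- render_hologram(sim_model(), c(0, 0, 12000), roi = 150)
  trk <- track_video(rep(list(img), 8), std$refs, std$cal,
                     z_window = c(10000, 14000))
  expect_true(all(trk$flag == "ok"))
  expect_lt(stats::sd(trk$z_nm), 0.1)
  expect_lt(stats::sd(trk$x_nm), 0.1)
})

test_that("a ramp video recovers the true heights with unit slope", {
  std <- std_setup()
  traj <- trajectory_ramp(6500, 14000, 60)
  gen <- render_video(sim_model(), traj, roi = 150, as_function = TRUE)
  trk <- track_video(gen, std$refs, std$cal, z_window = c(6000, 14500))
  ok <- trk$flag %in% c("ok", "low_confidence")
  expect_gt(mean(ok), 0.95)
  fit <- stats::lm(trk$z_nm[ok] ~ traj$z_nm[ok])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.005)
  # the resolved height inherits the per-period calibration residuals
  # (sigma_res up to ~16 nm each) plus their mixing across the period set
  expect_lt(stats::sd(stats::residuals(fit)), 25)
})

test_that("height accuracy improves with more reference periods", {
  # PSD plateau of the tracking error with 5 periods beats 2 periods
  m <- sim_model()
  traj <- trajectory_random(300, 30, seed = 21)
  plateau_for <- function(np) {
    refs <- reference_set(150, log_periods(np, 10, 16))
    tramp <- trajectory_ramp(8000, 14000, 200)
    genc <- render_video(m, tramp, roi = 150, as_function = TRUE)
    cal <- suppressWarnings(
      calibrate_from_video(genc, tramp$z_nm, refs, order = 9))
    gen <- render_video(m, traj, roi = 150, as_function = TRUE)
    trk <- track_video(gen, refs, cal, z_window = c(11000, 13000))
    ok <- trk$flag %in% c("ok", "low_confidence")
    e <- trk$z_nm[ok] - traj$z_nm[ok]
    psd_plateau(psd_estimate(e - mean(e), 30))
  }
  p2 <- plateau_for(2)
  p5 <- plateau_for(5)
  expect_lt(p5, p2 / 3)
})
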