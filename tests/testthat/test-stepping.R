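test_that("the Marko-Siggia solution has the right limits and inverse", {
  p <- wlc_params()
  # half extension: F = 1.25 kBT / L_p exactly
  F_half <- (p$kBT_pNnm / p$L_p_nm) * (0.25 / 0.25 - 0.25 + 0.5)
  expect_equal(wlc_extension(1000, F_half, p) / 1000, 0.5,
               tolerance = 1e-10)
  # inextensible limit
  expect_gt(wlc_extension(1000, 1000, p) / 1000, 0.98)
  # monotone in force
  set.seed(2)
  Fs <- sort(runif(20, 0.05, 60))
  zs <- wlc_extension(1500, Fs, p)
  expect_true(all(diff(zs) > 0))
  # forward/inverse consistency at random points to 1e-8
  for (i in 1:10) {
    L <- runif(1, 300, 3000)
    z <- runif(1, 0.05, 0.95) * L
    F_of_z <- (p$kBT_pNnm / p$L_p_nm) *
      (0.25 / (1 - z / L)^2 - 0.25 + z / L)
    expect_equal(wlc_extension(L, F_of_z, p), z, tolerance = 1e-8)
  }
})

test_that("the per-point SD follows equipartition plus tracking error", {
  p <- wlc_params(sigma_track_nm = 0)
  # stiffer at higher force: monotone decrease
  sds <- wlc_point_sd(c(0.5, 2, 8, 30), 1500, p)
  expect_true(all(diff(sds) < 0))
  # analytic derivative against central differences
  for (i in 1:20) {
    set.seed(200 + i)
    F <- runif(1, 0.2, 40)
    L <- runif(1, 400, 4000)
    h <- F * 1e-6
    dzdF_num <- (wlc_extension(L, F + h, p) - wlc_extension(L, F - h, p)) /
      (2 * h)
    sd_num <- sqrt(p$kBT_pNnm * dzdF_num)
    expect_equal(wlc_point_sd(F, L, p), sd_num, tolerance = 1e-6)
  }
  # thermal term vanishes: only the tracking error remains
  p2 <- wlc_params(kBT_pNnm = 1e-9, sigma_track_nm = 4)
  expect_equal(wlc_point_sd(10, 1000, p2), 4, tolerance = 1e-3)
})

test_that("the landscape peaks at the generating contour length", {
  p <- wlc_params(sigma_track_nm = 2)
  cur <- synth_fe_curve(L0_bp = 2000, step_bp = 0, n_steps = 0,
                        force_pN = seq(2, 20, length.out = 150), p = p,
                        noise = FALSE)
  sa <- state_probability(cur$force_pN, cur$ext_nm, substrate_bp = 2100,
                          p = p)
  expect_equal(sa$grid_bp[which.max(sa$probability)], 2000,
               tolerance = 1e-9)
  # two-state curve gives two peaks at the stated spacing
  set.seed(12)
  cur2 <- synth_fe_curve(L0_bp = 2000, step_bp = 150, n_steps = 1,
                         force_pN = seq(4, 24, length.out = 400),
                         step_forces_pN = 12, p = p, noise = TRUE, seed = 5)
  sa2 <- find_steps(state_probability(cur2$force_pN, cur2$ext_nm,
                                      substrate_bp = 2100, p = p))
  expect_length(sa2$peaks_bp, 2)
  expect_equal(diff(sa2$peaks_bp), 150, tolerance = 2)
})

test_that("unstructured extensions produce no sharp landscape peaks", {
  p <- wlc_params(sigma_track_nm = 2)
  sharp <- function(prob) max(prob) / mean(prob)
  ratio_structured <- ratio_null <- numeric(20)
  for (s in 1:20) {
    cur <- synth_fe_curve(L0_bp = 1500, step_bp = 0, n_steps = 0,
                          force_pN = seq(3, 20, length.out = 120), p = p,
                          noise = TRUE, seed = s)
    sa <- state_probability(cur$force_pN, cur$ext_nm, substrate_bp = 1600,
                            p = p)
    ratio_structured[s] <- sharp(sa$probability)
    set.seed(1000 + s)
    ext_null <- runif(120, 0, 1500 * p$nm_per_bp)
    sa0 <- state_probability(cur$force_pN, ext_null, substrate_bp = 1600,
                             p = p)
    ratio_null[s] <- sharp(sa0$probability)
  }
  expect_gt(min(ratio_structured), max(ratio_null))
})

test_that("the landscape is invariant under reordering of curve points", {
  p <- wlc_params()
  cur <- synth_fe_curve(seed = 8)
  sa <- state_probability(cur$force_pN, cur$ext_nm, substrate_bp = 5000,
                          p = p)
  set.seed(4)
  perm <- sample(length(cur$force_pN))
  sa_p <- state_probability(cur$force_pN[perm], cur$ext_nm[perm],
                            substrate_bp = 5000, p = p)
  expect_equal(sa$probability, sa_p$probability, tolerance = 1e-12)
})

test_that("step histograms recover the fundamental step from mixtures", {
  set.seed(4)
  steps <- c(rnorm(105, 80, 6), rnorm(30, 160, 6), rnorm(15, 240, 6))
  hf <- fit_step_histogram(steps)
  expect_equal(hf$fundamental_bp, 80, tolerance = 2 / 80)
  expect_equal(hf$histogram$bin_bp, 12)
  # identical steps collapse to a single dominant component at delta
  steps1 <- rep(60, 40)
  hf1 <- fit_step_histogram(steps1, bin_bp = 12, K = 3)
  expect_equal(hf1$fundamental_bp, 60, tolerance = 0.6)
  expect_error(fit_step_histogram(rnorm(5, 80, 5)), "at least 10")
})

test_that("increasing tracking error washes out the landscape peaks", {
  prominences <- vapply(c(2, 4, 8), function(sig) {
    p <- wlc_params(sigma_track_nm = sig)
    cur <- synth_fe_curve(L0_bp = 2000, step_bp = 100, n_steps = 3,
                          force_pN = seq(4, 24, length.out = 300),
                          step_forces_pN = c(8, 13, 18), p = p,
                          noise = FALSE)
    sa <- state_probability(cur$force_pN, cur$ext_nm, substrate_bp = 2100,
                            p = p)
    max(sa$probability) / mean(sa$probability)
  }, numeric(1))
  expect_true(all(diff(prominences) < 0))
})

test_that("the full pipeline recovers the programmed step size", {
  p <- wlc_params(sigma_track_nm = 2)
  for (delta in c(40, 80, 120)) {
    rec <- numeric(6)
    for (s in 1:6) {
      cur <- synth_fe_curve(L0_bp = 2500, step_bp = delta, n_steps = 8,
                            force_pN = seq(5, 27, length.out = 700),
                            step_forces_pN = seq(7, 25, length.out = 8),
                            p = p, noise = TRUE, seed = 3000 + s)
      sa <- find_steps(state_probability(cur$force_pN, cur$ext_nm,
                                         substrate_bp = 2600, p = p),
                       min_sep_bp = min(20, delta / 2))
      rec[s] <- stats::median(sa$steps_bp)
    }
    expect_lt(abs(mean(rec) - delta) / delta, 0.05)
  }
})

test_that("the enthalpic stretch term lengthens the chain linearly in force", {
  p0 <- wlc_params(sigma_track_nm = 0)
  p1 <- wlc_params(sigma_track_nm = 0, K0_pN = 1000)
  F <- 10
  L <- 1000
  expect_equal(wlc_extension(L, F, p1) - wlc_extension(L, F, p0),
               L * F / 1000, tolerance = 1e-12)
  expect_gt(wlc_point_sd(F, L, p1), wlc_point_sd(F, L, p0))
})
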