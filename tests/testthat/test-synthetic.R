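chain <- build_default_rat_chain()
profile <- default_rat_profile()

test_that("the default profile reproduces the configured excursion envelope", {
  pct <- seq(0, 100, by = 0.05)
  env <- function(joint, axis, amplitude = 1)
    range(profile_value(profile, joint, axis, pct, amplitude))
  expect_equal(env("shoulder", "rz"), c(-97, 31))
  expect_equal(env("shoulder", "ry"), c(-36, 3))
  expect_equal(env("shoulder", "rx"), c(-14, 40))
  e <- env("elbow", "rz")
  expect_equal(e, c(30, 123))
  expect_equal(diff(e), 93)
  # base supination dip: 20 deg below the 180-deg pronation plateau,
  # scaled to 10-30 deg across a cohort
  expect_equal(env("radioulnar", "rx"), c(160, 180))
  expect_equal(env("radioulnar", "rx", amplitude = 1.5), c(150, 180))
  expect_equal(env("radioulnar", "rx", amplitude = 0.5), c(170, 180))
  # periodicity
  for (j in names(profile$waveforms)) for (a in names(profile$waveforms[[j]]))
    expect_equal(profile_value(profile, j, a, 0),
                 profile_value(profile, j, a, 100), tolerance = 1e-9)
})

test_that("the supination minimum sits near 75% of the cycle", {
  pct <- seq(0, 99.9, by = 0.1)
  v <- profile_value(profile, "radioulnar", "rx", pct)
  expect_equal(pct[which.min(v)], 75, tolerance = 1)
  # plateau through the first half of the cycle
  expect_true(all(v[pct <= 50] > 179.9))
})

test_that("simulated trials have the configured frame count and determinism", {
  tr <- simulate_trial(chain, profile, n_cycles = 2, seed = 1)
  expect_equal(nrow(tr$poses) / length(chain$segments), 250)
  tr2 <- simulate_trial(chain, profile, n_cycles = 2, seed = 1)
  expect_identical(tr$poses, tr2$poses)
  expect_identical(tr$angles, tr2$angles)
  m1 <- render_markers(tr$poses, chain, sigma_mm = 0.1, seed = 4)
  m2 <- render_markers(tr$poses, chain, sigma_mm = 0.1, seed = 4)
  expect_identical(m1$markers3d, m2$markers3d)
})

test_that("a zero-amplitude profile leaves the chain in its reference pose", {
  flat <- gait_profile(
    list(elbow = list(rz = cbind(c(0, 100), c(0, 0)))),
    stance_fraction = 0.64, cycle_duration = 0.5, frame_rate = 250,
    forward_speed = 0)
  tr <- simulate_trial(chain, flat, n_cycles = 1, seed = 1)
  expect_lt(max(abs(as.matrix(tr$angles[, 4:9]))), 1e-9)
  ref <- poses_to_df(forward_kinematics(chain, zero_joint_values(chain)))
  for (col in c("r11", "r22", "r33", "tx_mm", "ty_mm", "tz_mm")) {
    expect_equal(tr$poses[[col]],
                 rep(ref[[col]], times = 125), tolerance = 1e-9)
  }
})

test_that("noiseless markers reproduce poses and survive the camera path", {
  tr <- simulate_trial(chain, profile, n_cycles = 1, seed = 2)
  sub <- tr$poses[tr$poses$frame < 5, ]
  mk <- render_markers(sub, chain, sigma_mm = 0)$markers3d
  fit <- markers_to_poses(mk, chain)
  expect_lt(max(fit$fit_rms$rms_mm), 1e-10)
  for (i in seq_len(nrow(sub))) {
    got <- fit$poses[fit$poses$bone == sub$bone[i] &
                       fit$poses$frame == sub$frame[i], ]
    expect_equal(as.numeric(got[, 4:15]), as.numeric(sub[i, 4:15]),
                 tolerance = 1e-9)
  }
  cams <- default_camera_pair()
  both <- render_markers(sub, chain, cameras = cams, sigma_mm = 0,
                         sigma_px = 0)
  m3 <- triangulate_markers(both$markers2d, cams)
  key <- function(d) paste(d$frame, d$marker_id)
  m0 <- both$markers3d[match(key(m3), key(both$markers3d)), ]
  expect_lt(max(abs(as.matrix(m3[, c("x_mm", "y_mm", "z_mm")]) -
                    as.matrix(m0[, c("x_mm", "y_mm", "z_mm")]))), 1e-6)
})

test_that("marker noise has the requested magnitude", {
  tr <- simulate_trial(chain, profile, n_cycles = 1, seed = 2)
  sub <- tr$poses[tr$poses$frame < 50, ]
  clean <- render_markers(sub, chain, sigma_mm = 0)$markers3d
  noisy <- render_markers(sub, chain, sigma_mm = 0.1, seed = 6)$markers3d
  d <- as.matrix(noisy[, c("x_mm", "y_mm", "z_mm")]) -
    as.matrix(clean[, c("x_mm", "y_mm", "z_mm")])
  rmse <- sqrt(mean(rowSums(d^2)))
  expect_equal(rmse, 0.1 * sqrt(3), tolerance = 0.1)
})

test_that("trajectory filtering suppresses noise without moving the signal", {
  set.seed(61)
  n <- 400
  t <- (seq_len(n) - 1) / 250
  truth <- 10 * sin(2 * pi * 2 * t)
  mk <- data.frame(trial_id = "t", frame = seq_len(n) - 1L,
                   marker_id = "ulna.m01",
                   x_mm = truth + rnorm(n, sd = 0.1),
                   y_mm = rnorm(n, sd = 0.1), z_mm = 0)
  f <- filter_trajectories(mk, 250, cutoff_hz = 15)
  expect_lt(sd(f$y_mm), 0.5 * sd(mk$y_mm))          # noise shrinks
  expect_lt(sqrt(mean((f$x_mm - truth)^2)), 0.06)   # signal preserved
  expect_error(filter_trajectories(mk, 250, cutoff_hz = 200), "cutoff")
})

test_that("between-trial amplitudes follow the deterministic cohort schedule", {
  trials <- simulate_cohort(chain, profile, seeds = 1:5, n_cycles = 1)
  amps <- vapply(trials, `[[`, 0, "amplitude")
  expect_equal(amps, seq(0.5, 1.5, length.out = 5))
  ru_min <- vapply(trials, function(tr)
    min(tr$angles$rx_deg[tr$angles$joint == "radioulnar"]), 0)
  expect_equal(ru_min, 180 - 20 * amps, tolerance = 0.2)
})
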