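test_that("Euler ZYX composition matches elementary-rotation oracle", {
  expect_equal(compose_euler_zyx(0, 0, 0), diag(3))
  # 90 deg about Z maps x-hat onto y-hat (right-hand rule)
  expect_equal(as.vector(compose_euler_zyx(90, 0, 0) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  a <- c(27.3, -41.0, 113.6)
  expect_equal(compose_euler_zyx(a),
               oracle_euler_zyx(a[1], a[2], a[3]), tolerance = 1e-12)
  expect_error(compose_euler_zyx(NA, 0, 0), "finite")
})

test_that("Euler decomposition round-trips on the canonical branch", {
  expect_equal(unlist(decompose_euler_zyx(diag(3))[c("rz", "ry", "rx")]),
               c(rz = 0, ry = 0, rx = 0))
  d <- decompose_euler_zyx(compose_euler_zyx(30, 0, 0))
  expect_equal(d$rz, 30, tolerance = 1e-12)
  expect_false(d$gimbal)
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    R <- random_rotation()
    d <- decompose_euler_zyx(R)
    expect_true(d$ry >= -90 && d$ry <= 90)
    worst <- max(worst, max(abs(compose_euler_zyx(d$rz, d$ry, d$rx) - R)))
  }
  expect_lt(worst, 1e-9)
})

test_that("gimbal lock is resolved deterministically and flagged", {
  for (ry in c(90, -90)) {
    R <- oracle_euler_zyx(20, ry, 35)
    d <- decompose_euler_zyx(R)
    expect_true(d$gimbal)
    expect_identical(d$rx, 0)
    expect_equal(compose_euler_zyx(d$rz, d$ry, d$rx), R, tolerance = 1e-9)
  }
})

test_that("relative_pose inverts composition", {
  set.seed(7)
  P <- fk_pose(random_rotation(), rnorm(3, sd = 10))
  C <- fk_pose(random_rotation(), rnorm(3, sd = 10))
  expect_equal(relative_pose(P, P)$R, diag(3), tolerance = 1e-12)
  expect_equal(relative_pose(P, P)$t, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(relative_pose(fk_pose(), C), C, tolerance = 1e-12)
  T_ <- relative_pose(P, C)
  back <- pose_compose(P, T_)
  expect_equal(back$R, C$R, tolerance = 1e-10)
  expect_equal(back$t, C$t, tolerance = 1e-10)
})

test_that("rigid fit recovers exact poses and rejects degenerate input", {
  set.seed(11)
  local <- matrix(runif(12, -10, 10), 4, 3)
  truth <- fk_pose(random_rotation(), c(5, -3, 12))
  fit <- fit_rigid_pose(local, pose_apply(truth, local))
  expect_lt(fit$rms_residual, 1e-10)
  expect_equal(fit$pose$R, truth$R, tolerance = 1e-10)
  expect_equal(fit$pose$t, truth$t, tolerance = 1e-9)
  collinear <- cbind(1:3, 2 * (1:3), -(1:3))
  expect_error(fit_rigid_pose(collinear, collinear), "collinear")
  expect_error(fit_rigid_pose(local[1:2, ], local[1:2, ]), "3 markers")
})

test_that("rigid fit is invariant to rigid pre-transformation of the world", {
  set.seed(12)
  local <- matrix(runif(15, -8, 8), 5, 3)
  world <- pose_apply(fk_pose(random_rotation(), c(1, 2, 3)), local) +
    matrix(rnorm(15, sd = 0.2), 5, 3)
  f1 <- fit_rigid_pose(local, world)
  G <- fk_pose(random_rotation(), c(-20, 4, 9))
  f2 <- fit_rigid_pose(local, pose_apply(G, world))
  expect_equal(f2$rms_residual, f1$rms_residual, tolerance = 1e-10)
  comp <- pose_compose(G, f1$pose)
  expect_equal(f2$pose$R, comp$R, tolerance = 1e-9)
  expect_equal(f2$pose$t, comp$t, tolerance = 1e-8)
})

test_that("noisy rigid fit matches grid-search oracle and noise floor", {
  set.seed(13)
  local <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(0, 0, 8))
  truth <- fk_pose(random_rotation(), c(2, -7, 4))
  sigma <- 0.1
  # one instance against the exhaustive rotation-grid oracle
  world1 <- pose_apply(truth, local) + matrix(rnorm(12, sd = sigma), 4, 3)
  fit1 <- fit_rigid_pose(local, world1)
  oracle <- grid_rigid_fit(local, world1)
  expect_lte(fit1$rms_residual, oracle$cost + 1e-6)
  expect_lt(rotation_angle_deg(fit1$pose$R, oracle$R), 1.5)
  expect_lt(rotation_angle_deg(fit1$pose$R, truth$R), 1.5)
  # Monte Carlo mean residual against the closed-form noise floor:
  # E[rms^2] = sigma^2 (3N - 6) / N
  reps <- 400
  rms <- numeric(reps)
  for (i in seq_len(reps)) {
    w <- pose_apply(truth, local) + matrix(rnorm(12, sd = sigma), 4, 3)
    rms[i] <- fit_rigid_pose(local, w)$rms_residual
  }
  floor_rms <- sigma * sqrt((3 * 4 - 6) / 4)
  expect_lt(abs(mean(rms) - floor_rms) / floor_rms, 0.10)
})

test_that("angle series unwrap removes 360-degree jumps", {
  expect_equal(unwrap_angle_series(c(179, -179)), c(179, 181))
  expect_equal(unwrap_angle_series(rep(42, 10)), rep(42, 10))
  set.seed(14)
  smooth <- cumsum(rnorm(500, sd = 20))
  wrapped <- (smooth + 180) %% 360 - 180
  rec <- unwrap_angle_series(wrapped)
  # recover up to a constant multiple of 360
  rec <- rec - 360 * round((rec[1] - smooth[1]) / 360)
  expect_equal(rec, smooth, tolerance = 1e-9)
  expect_true(all(abs(diff(rec)) <= 180 + 1e-9))
})
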