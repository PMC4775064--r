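chain <- build_default_rat_chain()

test_that("the reference pose reads zero at every joint", {
  poses <- forward_kinematics(chain, zero_joint_values(chain))
  ang <- jcs_decompose(chain, poses_to_df(poses))
  expect_equal(max(abs(as.matrix(ang[, 4:9]))), 0, tolerance = 1e-10)
  # reference poses themselves are reproduced exactly
  for (b in names(chain$segments)) {
    expect_equal(poses[[b]]$R, chain$segments[[b]]$ref_pose$R,
                 tolerance = 1e-12)
    expect_equal(poses[[b]]$t, chain$segments[[b]]$ref_pose$t,
                 tolerance = 1e-12)
  }
})

test_that("forward and inverse kinematics are mutual inverses", {
  set.seed(31)
  for (rep in 1:25) {
    jv <- zero_joint_values(chain)
    for (j in names(jv))
      jv[[j]] <- c(tx = runif(1, -8, 8), ty = runif(1, -8, 8),
                   tz = runif(1, -8, 8), rz = runif(1, -150, 150),
                   ry = runif(1, -85, 85), rx = runif(1, -150, 150))
    ang <- jcs_decompose(chain, poses_to_df(forward_kinematics(chain, jv)))
    for (j in names(jv)) {
      row <- ang[ang$joint == j, ]
      got <- c(row$tx_mm, row$ty_mm, row$tz_mm,
               row$rz_deg, row$ry_deg, row$rx_deg)
      expect_equal(got, unname(jv[[j]]), tolerance = 1e-8)
    }
  }
})

test_that("a pure shoulder rotation appears only in the shoulder series", {
  jv <- zero_joint_values(chain)
  jv$shoulder["rz"] <- 5
  ang <- jcs_decompose(chain, poses_to_df(forward_kinematics(chain, jv)))
  sh <- ang[ang$joint == "shoulder", ]
  expect_equal(sh$rz_deg, 5, tolerance = 1e-9)
  others <- as.matrix(ang[ang$joint != "shoulder", 4:9])
  expect_lt(max(abs(others)), 1e-9)
  expect_lt(max(abs(c(sh$tx_mm, sh$ty_mm, sh$tz_mm, sh$ry_deg, sh$rx_deg))),
            1e-9)
})

test_that("full pronation reads 180 degrees at the radioulnar JCS", {
  jv <- zero_joint_values(chain)
  jv$radioulnar["rx"] <- 180
  ang <- jcs_decompose(chain, poses_to_df(forward_kinematics(chain, jv)))
  expect_equal(ang$rx_deg[ang$joint == "radioulnar"], 180, tolerance = 1e-8)
  # monotone approach to full pronation is preserved through the series
  frames <- lapply(0:20, function(i) {
    jv$radioulnar["rx"] <- 9 * i
    poses_to_df(forward_kinematics(chain, jv), frame = i)
  })
  ang <- jcs_decompose(chain, do.call(rbind, frames))
  ru <- ang[ang$joint == "radioulnar", ]
  expect_equal(ru$rx_deg[order(ru$frame)], 9 * (0:20), tolerance = 1e-8)
})

test_that("elbow flexion/extension is purely parasagittal in the default rig", {
  frames <- lapply(0:10, function(i) {
    jv <- zero_joint_values(chain)
    jv$elbow["rz"] <- 12 * i
    poses_to_df(forward_kinematics(chain, jv), frame = i)
  })
  ang <- jcs_decompose(chain, do.call(rbind, frames))
  other <- ang[ang$joint %in% c("shoulder", "radioulnar"), ]
  expect_lt(max(abs(as.matrix(other[, 4:9]))), 1e-9)
  ey <- ang[ang$joint == "elbow", c("ry_deg", "rx_deg")]
  expect_lt(max(abs(as.matrix(ey))), 1e-9)
})

test_that("a world-frame rigid transform is absorbed entirely by the root", {
  set.seed(32)
  jv <- zero_joint_values(chain)
  jv$shoulder["rz"] <- -40; jv$elbow["rz"] <- 70; jv$radioulnar["rx"] <- 160
  poses <- forward_kinematics(chain, jv)
  G <- fk_pose(compose_euler_zyx(25, 10, -15), c(30, -12, 5))
  moved <- lapply(poses, function(p) pose_compose(G, p))
  a1 <- jcs_decompose(chain, poses_to_df(poses))
  a2 <- jcs_decompose(chain, poses_to_df(moved))
  nonroot <- a1$joint != "body"
  expect_equal(as.matrix(a2[nonroot, 4:9]), as.matrix(a1[nonroot, 4:9]),
               tolerance = 1e-8)
  # the root absorbs G exactly: recompose its pose and compare
  rw <- a2[a2$joint == "body", ]
  body2 <- fk_pose(compose_euler_zyx(rw$rz_deg, rw$ry_deg, rw$rx_deg),
                   c(rw$tx_mm, rw$ty_mm, rw$tz_mm))
  expect_equal(body2$R, pose_compose(G, poses$body)$R, tolerance = 1e-9)
  expect_equal(body2$t, pose_compose(G, poses$body)$t, tolerance = 1e-8)
})

test_that("sign conventions are validated, flagged and involutive", {
  jv <- zero_joint_values(chain)
  jv$shoulder["rx"] <- -10   # medial rotation: reported negative
  raw <- jcs_decompose(chain, poses_to_df(forward_kinematics(chain, jv)))
  rep1 <- apply_sign_conventions(raw, chain)
  expect_equal(rep1$rx_deg[rep1$joint == "shoulder"], -10, tolerance = 1e-9)
  expect_true(attr(rep1, "sign_converted"))
  expect_error(apply_sign_conventions(rep1, chain), "already sign-converted")
  bad <- raw; bad$joint[1] <- "carpus"
  expect_error(apply_sign_conventions(bad, chain), "unknown joint")
  # a flipped-sign JCS actually flips the channel
  chain2 <- chain
  chain2$jcs$shoulder$axis_signs <- c(rz = 1, ry = 1, rx = -1)
  rep2 <- apply_sign_conventions(raw, chain2)
  expect_equal(rep2$rx_deg[rep2$joint == "shoulder"],
               -rep1$rx_deg[rep1$joint == "shoulder"])
})

test_that("chain construction validates structure and configuration", {
  expect_error(build_default_rat_chain(list(femur_length = 1)), "unknown")
  expect_error(build_default_rat_chain(list(humerus_length = -3)),
               "positive")
  # a missing joint value is refused
  jv <- zero_joint_values(chain)
  expect_error(forward_kinematics(chain, jv[-2]), "missing joint")
})
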