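test_that("degenerate trials collapse to a single flagged segment", {
  still <- matrix(rep(c(1, 2, 3), each = 60), ncol = 3)
  expect_warning(seg <- detect_stance_swing(still), "static|never moves")
  expect_equal(nrow(seg), 1)
  expect_equal(seg$phase, "stance")
  th <- seq(0, 6 * pi, length.out = 200)
  circling <- 50 * cbind(cos(th), sin(th), 0)  # constant speed, never static
  expect_warning(seg <- detect_stance_swing(circling), "moving")
  expect_equal(seg$phase, "swing")
})

test_that("stance fraction of a noiseless synthetic trial is recovered", {
  chain <- build_default_rat_chain()
  tr <- simulate_trial(chain, default_rat_profile(), n_cycles = 3, seed = 3,
                       partial_edges = 0.25)
  lm <- landmark_trajectory(chain, tr$poses)
  seg <- detect_stance_swing(lm, frame_rate = tr$frame_rate)
  cyc <- segment_cycles(seg)
  expect_equal(nrow(cyc), 3)
  st <- seg[seg$phase == "stance", ]
  sf <- 0; cf <- 0
  for (ci in seq_len(nrow(cyc))) {
    ov <- pmin(st$end_frame, cyc$end_frame[ci]) -
      pmax(st$start_frame, cyc$start_frame[ci]) + 1L
    sf <- sf + sum(ov[ov > 0])
    cf <- cf + cyc$end_frame[ci] - cyc$start_frame[ci] + 1L
  }
  expect_equal(100 * sf / cf, 64, tolerance = 2 / 64)
})

test_that("only complete touchdown-to-touchdown cycles are kept", {
  seg <- segments_fixture(c("swing", "stance", "swing", "stance", "swing"))
  expect_equal(nrow(segment_cycles(seg)), 1)
  # mid-cycle edges: opening stance is not a verified touchdown
  seg <- segments_fixture(c("stance", "swing", "stance", "swing", "stance",
                            "swing", "stance", "swing", "stance"))
  cyc <- segment_cycles(seg)
  expect_equal(nrow(cyc), 3)
  expect_equal(cyc$start_frame, c(160, 320, 480))
  expect_warning(out <- segment_cycles(segments_fixture("stance")),
                 "no complete")
  expect_equal(nrow(out), 0)
})

test_that("percent-of-cycle normalisation anchors touchdown at 0%", {
  ang <- data.frame(trial_id = "t", frame = 0:199, joint = "elbow",
                    tx_mm = 0, ty_mm = 0, tz_mm = 0,
                    rz_deg = seq(0, 199), ry_deg = 0, rx_deg = 0)
  cyc <- data.frame(trial_id = "t", cycle = 1L, start_frame = 0L,
                    end_frame = 199L, stance_end_frame = 127L)
  cs <- normalize_to_percent(ang, cyc)
  rz <- cs[cs$axis == "rz", ]
  expect_equal(rz$percent[rz$value == 0], 0)
  expect_equal(rz$percent[rz$value == 100], 50)
  expect_true(all(cs$percent >= 0 & cs$percent < 100))
  bad <- cyc; bad$end_frame <- 500L
  expect_error(normalize_to_percent(ang, bad), "outside")
})

test_that("binning pools samples into exact 5% bins and conserves counts", {
  ang <- data.frame(trial_id = "t", frame = 0:249, joint = "elbow",
                    tx_mm = 0, ty_mm = 0, tz_mm = 0,
                    rz_deg = 7, ry_deg = 0, rx_deg = 0)
  cyc <- data.frame(trial_id = "t", cycle = 1L, start_frame = 0L,
                    end_frame = 249L, stance_end_frame = 159L)
  cs <- normalize_to_percent(ang, cyc)
  b <- bin_cycles(cs, n_bins = 20)
  expect_equal(nrow(b[b$axis == "rz", ]), 20)
  expect_equal(diff(b$bin_center[b$axis == "rz"])[1], 5)
  expect_equal(b$mean[b$axis == "rz"], rep(7, 20))
  expect_equal(b$sd[b$axis == "rz"], rep(0, 20))
  expect_equal(sum(b$n), nrow(cs))
  # a linear ramp in percent bins to the bin centres
  cs$value <- cs$percent
  b2 <- bin_cycles(cs[cs$axis == "rz", ])
  expect_equal(b2$mean, seq(2.5, 97.5, by = 5), tolerance = 0.3)
  # binning is invariant to sample order
  b3 <- bin_cycles(cs[rev(seq_len(nrow(cs))), ])
  expect_equal(b3$mean, bin_cycles(cs)$mean)
  # an empty bin is flagged, not fabricated
  expect_warning(b4 <- bin_cycles(cs[cs$percent < 50, ]), "empty bin")
  expect_true(all(is.na(b4$mean[b4$bin > 10])))
})

test_that("excursion summaries implement pooled min/max/range/mean/median", {
  mk <- function(v) data.frame(trial_id = "t", frame = seq_along(v) - 1,
                               joint = "elbow", tx_mm = 0, ty_mm = 0,
                               tz_mm = 0, rz_deg = v, ry_deg = 0, rx_deg = 0)
  s <- summarize_excursions(mk(rep(4, 5)))
  srz <- s[s$axis == "rz", ]
  expect_equal(unlist(srz[c("min", "max", "range", "mean", "median")]),
               c(min = 4, max = 4, range = 0, mean = 4, median = 4))
  s <- summarize_excursions(mk(c(0, 10, 20)))[1:3, ]
  srz <- s[s$axis == "rz", ]
  expect_equal(unlist(srz[c("min", "max", "range", "mean", "median")]),
               c(min = 0, max = 20, range = 20, mean = 10, median = 10))
  # pooling across trials is order- and concatenation-invariant
  a <- mk(c(1, 5, 9)); b <- mk(c(-2, 3))
  b$trial_id <- "u"
  expect_equal(summarize_excursions(list(a, b)),
               summarize_excursions(list(b, a)))
})

test_that("elbow-supination correlation behaves like a Pearson coefficient", {
  set.seed(41)
  mkcs <- function(joint, axis, value, percent) {
    data.frame(trial_id = "t", cycle = 1L, joint = joint, axis = axis,
               percent = percent, value = value)
  }
  pct <- seq(0, 99.5, by = 0.5)
  ez <- mkcs("elbow", "rz", 70 + 40 * sin(2 * pi * pct / 100), pct)
  ru <- mkcs("radioulnar", "rx", 170 - 0.25 * ez$value, pct)
  expect_equal(abs(elbow_lar_correlation(ez, ru)), 1, tolerance = 1e-10)
  # null distribution at 20 bins: |r| concentrates well below 1
  r <- replicate(200, {
    e <- mkcs("elbow", "rz", rnorm(length(pct)), pct)
    u <- mkcs("radioulnar", "rx", rnorm(length(pct)), pct)
    elbow_lar_correlation(e, u)
  })
  expect_lt(stats::median(abs(r)), 0.3)
  expect_lt(stats::quantile(abs(r), 0.95), 0.6)
  suppressWarnings(expect_error(
    elbow_lar_correlation(ez[ez$percent < 10, ], ru[ru$percent < 10, ]),
    "fewer than 3"))
})

test_that("the default profile couples elbow flexion with supination", {
  chain <- build_default_rat_chain()
  tr <- simulate_trial(chain, default_rat_profile(), n_cycles = 2, seed = 5)
  cyc <- data.frame(trial_id = tr$trial_id, cycle = 1L, start_frame = 0L,
                    end_frame = 124L, stance_end_frame = 79L)
  cs <- normalize_to_percent(tr$angles, cyc)
  r <- elbow_lar_correlation(cs[cs$joint == "elbow" & cs$axis == "rz", ],
                             cs[cs$joint == "radioulnar" & cs$axis == "rx", ])
  expect_gt(r, 0)
})
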