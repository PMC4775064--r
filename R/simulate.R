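#' Gait profile
#'
#' Parametric description of one walking step cycle: per joint/axis
#' periodic waveforms as keypoints over percent-of-cycle, plus gait timing.
#' Waveforms are interpolated with monotone (Fritsch-Carlson) cubic
#' segments, so configured keypoint extrema are never overshot and the
#' excursion envelope of the profile is exact.
#'
#' Values are in the reported anatomical convention (see
#' [apply_sign_conventions()]).
#'
#' @param waveforms nested named list `waveforms[[joint]][[axis]]`, each a
#'   two-column matrix `cbind(percent, degrees)` with `percent` in
#'   \[0, 100\] and equal first/last values (periodicity).
#' @param stance_fraction fraction of the cycle in stance, in (0, 1).
#' @param cycle_duration step-cycle duration in seconds.
#' @param frame_rate sampling rate in Hz.
#' @param forward_speed mean forward speed of the body, mm/s; the stride
#'   length is `forward_speed * cycle_duration`.
#' @param trial_scaling optional between-trial amplitude structure: a list
#'   with `joint`, `axis`, `anchor` (degrees) and `range = c(lo, hi)`.
#'   Trial `i` of an `n`-trial cohort scales that waveform's deviation from
#'   `anchor` by a factor evenly spaced across `range` (see
#'   [simulate_cohort()]).
#' @return An object of class `fk_profile`.
#' @export
gait_profile <- function(waveforms, stance_fraction = 0.64,
                         cycle_duration = 0.5, frame_rate = 250,
                         forward_speed = 300, trial_scaling = NULL) {
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("stance_fraction must be in (0, 1)", call. = FALSE)
  if (cycle_duration <= 0 || frame_rate <= 0)
    stop("cycle_duration and frame_rate must be positive", call. = FALSE)
  for (j in names(waveforms)) for (a in names(waveforms[[j]])) {
    k <- waveforms[[j]][[a]]
    if (!is.matrix(k) || ncol(k) != 2L || nrow(k) < 2L)
      stop("waveform ", j, ":", a, " must be a keypoint matrix", call. = FALSE)
    if (abs(k[1, 2] - k[nrow(k), 2]) > 1e-9)
      stop("waveform ", j, ":", a, " is not periodic (value at 0% must equal ",
           "value at 100%)", call. = FALSE)
  }
  structure(list(waveforms = waveforms, stance_fraction = stance_fraction,
                 cycle_duration = cycle_duration, frame_rate = frame_rate,
                 forward_speed = forward_speed,
                 trial_scaling = trial_scaling),
            class = "fk_profile")
}

#' Default walking profile for the rat forelimb
#'
#' Keypoint waveforms whose pooled envelope matches the reported joint
#' excursions of walking rats: shoulder Z in \[-97, 31\], shoulder Y in
#' \[-36, 3\], shoulder X in \[-14, 40\], elbow Z in \[30, 123\] and
#' radioulnar X in \[149, 180\] degrees, with the published phase
#' structure: the humerus is maximally protracted near touchdown and
#' retracts through stance; the elbow extends at touchdown, yields ~10
#' degrees under load, peaks in extension just before toe-off and flexes
#' maximally in swing; the radius holds a fully pronated plateau near 180
#' degrees through the first half of the cycle and is most supinated
#' (~160 degrees on average) near 75% of the cycle, in phase with elbow
#' flexion.
#'
#' The radioulnar supination dip carries a between-trial amplitude
#' schedule (factors 0.5-1.5 about the 180-degree pronation anchor), so a
#' 10-trial cohort spans supination depths of 10-30 degrees while
#' averaging 20; this emulates the reported between-trial spread of radius
#' long-axis rotation.  The exact curve shapes between keypoints are a
#' package artifact, not measured data.
#'
#' @return An `fk_profile` with stance fraction 0.64, cycle duration
#'   0.5 s, 250 frames/s and forward speed 300 mm/s.
#' @export
default_rat_profile <- function() {
  wf <- list(
    shoulder = list(
      rz = cbind(c(0, 68, 100), c(-97, 31, -97)),
      ry = cbind(c(0, 30, 60, 92, 100), c(-10, 3, -8, -36, -10)),
      rx = cbind(c(0, 76, 100), c(40, -14, 40))
    ),
    elbow = list(
      rz = cbind(c(0, 8, 25, 60, 78, 100), c(70, 90, 80, 123, 30, 70))
    ),
    radioulnar = list(
      rx = cbind(c(0, 50, 64, 75, 92, 100), c(180, 180, 171, 160, 178, 180))
    )
  )
  gait_profile(wf,
               stance_fraction = 0.64, cycle_duration = 0.5,
               frame_rate = 250, forward_speed = 300,
               trial_scaling = list(joint = "radioulnar", axis = "rx",
                                    anchor = 180, range = c(0.5, 1.5)))
}

#' Evaluate a profile waveform
#'
#' Periodic monotone-cubic interpolation of a waveform's keypoints.
#'
#' @param profile an `fk_profile`.
#' @param joint,axis waveform selector.
#' @param percent numeric vector of percent-of-cycle values (any real;
#'   wrapped modulo 100).
#' @param amplitude trial amplitude factor applied to the deviation from
#'   the `trial_scaling` anchor when this waveform is the scaled one.
#' @return Numeric vector of waveform values in degrees.
#' @export
profile_value <- function(profile, joint, axis, percent, amplitude = 1) {
  k <- profile$waveforms[[joint]][[axis]]
  if (is.null(k)) return(rep(0, length(percent)))
  # periodic extension for smooth interpolation across the wrap point
  x <- c(k[-nrow(k), 1] - 100, k[, 1], k[-1, 1] + 100)
  y <- c(k[-nrow(k), 2], k[, 2], k[-1, 2])
  # shape-preserving Hermite interpolation: keypoint extrema are never
  # overshot, so the configured excursion envelope is exact
  v <- pracma::pchip(x, y, percent %% 100)
  ts <- profile$trial_scaling
  if (!is.null(ts) && identical(ts$joint, joint) && identical(ts$axis, axis))
    v <- ts$anchor + (v - ts$anchor) * amplitude
  v
}

# trapezoidal displacement profile on [0,1]: velocity ramps linearly over
# the first and last `ramp` fraction, constant in between; s(0)=0, s(1)=1
trapezoid_s <- function(w, ramp = 0.1) {
  vmax <- 1 / (1 - ramp)
  s <- numeric(length(w))
  a <- w < ramp
  b <- w >= ramp & w <= 1 - ramp
  c_ <- w > 1 - ramp
  s[a] <- vmax * w[a]^2 / (2 * ramp)
  s[b] <- vmax * (w[b] - ramp / 2)
  s[c_] <- 1 - vmax * (1 - w[c_])^2 / (2 * ramp)
  s
}

#' Simulate one walking trial by forward kinematics
#'
#' Samples the profile waveforms at the frame rate, drives the chain's
#' joints with them and solves the body-frame trajectory from the stance
#' constraint: during stance the world position of the distal-ulna
#' landmark is held fixed at the footfall point, and during swing it
#' advances one stride along +X under a trapezoidal speed profile (10%
#' ramps).  The body frame therefore translates forward at the configured
#' mean speed while the foot alternates static and moving phases, exactly
#' as the stance detector assumes.
#'
#' The trial is fully deterministic: measurement noise belongs to
#' [render_markers()], not to the trial itself.
#'
#' @param chain an `fk_chain` (see [build_default_rat_chain()]).
#' @param profile an `fk_profile`.
#' @param n_cycles number of complete step cycles (>= 1).
#' @param seed integer recorded with the trial and used downstream as the
#'   default noise seed.
#' @param partial_edges fraction of one cycle prepended and appended as
#'   partial cycles (emulating recordings that begin and end mid-cycle).
#' @param amplitude trial amplitude factor for the profile's
#'   `trial_scaling` waveform.
#' @param trial_id trial identifier string.
#' @return A list of class `fk_trial` with `angles` (ground-truth joint
#'   series, reported sign convention), `angles_raw` (rig convention),
#'   `poses` (pose table for every bone and frame), `frame_rate`,
#'   `profile`, `seed`, `amplitude` and `trial_id`.
#' @export
simulate_trial <- function(chain, profile, n_cycles = 3, seed = 1,
                           partial_edges = 0, amplitude = 1,
                           trial_id = sprintf("seed%03d", seed)) {
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  Tc <- profile$cycle_duration
  fps <- profile$frame_rate
  n <- round((n_cycles + 2 * partial_edges) * Tc * fps)
  t <- -partial_edges * Tc + (seq_len(n) - 1) / fps
  pct <- (t / Tc - floor(t / Tc)) * 100

  joints <- names(chain$jcs)
  # reported-space waveform values per frame
  rep_vals <- list()
  for (j in joints) {
    rep_vals[[j]] <- cbind(
      tx = 0, ty = 0, tz = 0,
      rz = profile_value(profile, j, "rz", pct, amplitude),
      ry = profile_value(profile, j, "ry", pct, amplitude),
      rx = profile_value(profile, j, "rx", pct, amplitude))
  }
  # reported -> raw via the JCS sign maps (signs are +/-1, so the map is an
  # involution)
  raw_vals <- rep_vals
  for (j in joints) {
    s <- chain$jcs[[j]]$axis_signs
    raw_vals[[j]][, "rz"] <- rep_vals[[j]][, "rz"] * s[["rz"]]
    raw_vals[[j]][, "ry"] <- rep_vals[[j]][, "ry"] * s[["ry"]]
    raw_vals[[j]][, "rx"] <- rep_vals[[j]][, "rx"] * s[["rx"]]
  }

  # distal-ulna trajectory with the body frame at the origin
  root <- names(which(vapply(chain$jcs, function(j) is.na(j$parent_bone), TRUE)))
  d_body <- matrix(NA_real_, n, 3)
  pose_rows <- vector("list", n)
  ulna_lm <- chain$segments$ulna$landmarks$distal_ulna
  for (i in seq_len(n)) {
    jv <- lapply(joints, function(j) {
      v <- raw_vals[[j]][i, ]
      names(v) <- c("tx", "ty", "tz", "rz", "ry", "rx")
      v
    })
    names(jv) <- joints
    poses <- forward_kinematics(chain, jv)
    d_body[i, ] <- pose_apply(poses$ulna, ulna_lm)
    pose_rows[[i]] <- poses
  }

  # stance constraint: world distal ulna pinned at the footfall during
  # stance, advancing one stride over swing
  stride <- profile$forward_speed * Tc
  sf <- profile$stance_fraction * 100
  cyc <- floor(t / Tc)
  f0 <- d_body[which.min(pmin(pct, 100 - pct)), ]  # body-frame ulna at touchdown
  u_world <- matrix(NA_real_, n, 3)
  stance <- pct < sf
  u_world[stance, ] <- cbind(cyc[stance] * stride + f0[1], f0[2], f0[3])
  w <- (pct[!stance] - sf) / (100 - sf)
  s <- trapezoid_s(w)
  u_world[!stance, ] <- cbind((cyc[!stance] + s) * stride + f0[1],
                              f0[2], f0[3])
  b <- u_world - d_body  # body translation solving the constraint

  # re-run forward kinematics with the body root translated
  out_poses <- vector("list", n)
  for (i in seq_len(n)) {
    poses <- lapply(pose_rows[[i]], function(p)
      fk_pose(p$R, p$t + b[i, ]))
    out_poses[[i]] <- poses_to_df(poses, trial_id = trial_id,
                                  frame = i - 1L)
  }
  poses_df <- do.call(rbind, out_poses)
  rownames(poses_df) <- NULL

  mk_angles <- function(vals) {
    rows <- lapply(joints, function(j) {
      v <- vals[[j]]
      tr <- if (j == root) b else
        cbind(v[, "tx"], v[, "ty"], v[, "tz"])
      data.frame(trial_id = trial_id, frame = seq_len(n) - 1L, joint = j,
                 tx_mm = tr[, 1], ty_mm = tr[, 2], tz_mm = tr[, 3],
                 rz_deg = v[, "rz"], ry_deg = v[, "ry"], rx_deg = v[, "rx"],
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  }
  angles <- mk_angles(rep_vals)
  attr(angles, "sign_converted") <- TRUE
  angles_raw <- mk_angles(raw_vals)
  attr(angles_raw, "sign_converted") <- FALSE

  structure(list(angles = angles, angles_raw = angles_raw,
                 poses = poses_df, frame_rate = fps, profile = profile,
                 seed = seed, amplitude = amplitude, trial_id = trial_id),
            class = "fk_trial")
}

#' Simulate a cohort of trials
#'
#' Runs [simulate_trial()] once per seed.  When the profile defines a
#' `trial_scaling` waveform, trial amplitudes are spaced evenly across the
#' scaling range so that the cohort reproduces the configured
#' between-trial spread deterministically.
#'
#' @param chain an `fk_chain`.
#' @param profile an `fk_profile`.
#' @param seeds integer vector, one seed per trial.
#' @param n_cycles complete cycles per trial.
#' @param partial_edges see [simulate_trial()].
#' @return List of `fk_trial` objects.
#' @export
simulate_cohort <- function(chain, profile, seeds = 1:10, n_cycles = 3,
                            partial_edges = 0) {
  nt <- length(seeds)
  amp <- if (!is.null(profile$trial_scaling) && nt > 1)
    seq(profile$trial_scaling$range[1], profile$trial_scaling$range[2],
        length.out = nt)
  else rep(1, nt)
  lapply(seq_len(nt), function(i)
    simulate_trial(chain, profile, n_cycles = n_cycles, seed = seeds[i],
                   partial_edges = partial_edges, amplitude = amp[i],
                   trial_id = sprintf("trial%02d_seed%03d", i, seeds[i])))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Render synthetic marker observations from bone poses
#'
#' Computes world marker positions from each bone's bone-fixed marker set
#' and the pose table, then adds isotropic Gaussian measurement noise.
#' When a pair of calibrated cameras is supplied, the noiseless world
#' markers are additionally projected into each view and pixel noise added
#' there, emulating image-space marker detection.
#'
#' @param poses pose table (from [simulate_trial()]).
#' @param chain the `fk_chain` defining the marker sets.
#' @param cameras optional list of two [dlt_camera()]s.
#' @param sigma_mm standard deviation of 3D marker noise (mm).
#' @param sigma_px standard deviation of image noise (px).
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return A list with `markers3d` (`trial_id, frame, marker_id, x_mm,
#'   y_mm, z_mm`) and, when cameras are given, `markers2d` (`trial_id,
#'   frame, camera_id, marker_id, u_px, v_px`).
#' @export
render_markers <- function(poses, chain, cameras = NULL, sigma_mm = 0.1,
                           sigma_px = 0.5, seed = 1) {
  check_pose_df(poses)
  with_seed(seed, {
    rows3 <- list()
    rows2 <- list()
    for (b in names(chain$segments)) {
      seg <- chain$segments[[b]]
      pb <- poses[poses$bone == b, , drop = FALSE]
      if (!nrow(pb)) next
      loc <- seg$markers$local_coords
      ids <- paste(b, seg$markers$marker_id, sep = ".")
      plist <- df_to_poses(pb)
      for (i in seq_along(plist)) {
        w <- pose_apply(plist[[i]], loc)
        wn <- w + matrix(stats::rnorm(length(w), 0, sigma_mm), ncol = 3)
        rows3[[length(rows3) + 1L]] <- data.frame(
          trial_id = pb$trial_id[i], frame = pb$frame[i], marker_id = ids,
          x_mm = wn[, 1], y_mm = wn[, 2], z_mm = wn[, 3],
          stringsAsFactors = FALSE)
        if (!is.null(cameras)) {
          for (ci in seq_along(cameras)) {
            uv <- project_point(cameras[[ci]], w)
            uv <- uv + matrix(stats::rnorm(length(uv), 0, sigma_px), ncol = 2)
            rows2[[length(rows2) + 1L]] <- data.frame(
              trial_id = pb$trial_id[i], frame = pb$frame[i],
              camera_id = ci, marker_id = ids,
              u_px = uv[, 1], v_px = uv[, 2], stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- list(markers3d = do.call(rbind, rows3))
    rownames(out$markers3d) <- NULL
    if (!is.null(cameras)) {
      out$markers2d <- do.call(rbind, rows2)
      rownames(out$markers2d) <- NULL
    }
    out
  })
}

#' Low-pass filter marker trajectories
#'
#' Zero-phase (forward-backward) Butterworth filtering of each marker
#' coordinate over frames, the standard treatment for marker jitter in
#' skeletal kinematics before rigid-body fitting.  Series are
#' reflection-padded before filtering to suppress edge transients.
#'
#' @param markers marker table (`trial_id, frame, marker_id, x_mm, y_mm,
#'   z_mm`).
#' @param frame_rate sampling rate, Hz.
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param order effective filter order of the zero-phase cascade (even).
#' @return The marker table with filtered coordinates.
#' @export
filter_trajectories <- function(markers, frame_rate, cutoff_hz = 15,
                                order = 4) {
  check_marker_df(markers)
  if (cutoff_hz <= 0 || cutoff_hz >= frame_rate / 2)
    stop("cutoff_hz must be in (0, frame_rate/2)", call. = FALSE)
  bf <- signal::butter(max(1L, order %/% 2L), cutoff_hz / (frame_rate / 2))
  ord <- base::order(markers$trial_id, markers$marker_id, markers$frame)
  out <- markers[ord, , drop = FALSE]
  key <- paste(out$trial_id, out$marker_id)
  for (k in unique(key)) {
    sel <- key == k
    for (col in c("x_mm", "y_mm", "z_mm")) {
      x <- out[[col]][sel]
      n <- length(x)
      if (n < 5L) next
      pad <- min(n - 1L, 50L)
      xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
      xf <- signal::filtfilt(bf, xp)
      out[[col]][sel] <- xf[(pad + 1):(pad + n)]
    }
  }
  rownames(out) <- NULL
  out
}
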