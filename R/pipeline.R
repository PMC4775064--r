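#' Fit bone poses from a marker table
#'
#' For every trial, frame and bone, performs the rigid-body (Kabsch) fit of
#' the bone's marker set to the observed world markers.  Marker identity
#' follows the `bone.marker` naming used by [render_markers()].
#'
#' @param markers marker table (`trial_id, frame, marker_id, x_mm, y_mm,
#'   z_mm`).
#' @param chain the `fk_chain` supplying the bone-fixed marker coordinates.
#' @return A list with `poses` (pose table) and `fit_rms` (data.frame of
#'   per-frame RMS residuals, mm).
#' @export
markers_to_poses <- function(markers, chain) {
  check_marker_df(markers)
  bone_of <- sub("\\..*$", "", markers$marker_id)
  mid_of <- sub("^[^.]*\\.", "", markers$marker_id)
  rows <- list()
  rms <- list()
  for (b in names(chain$segments)) {
    seg <- chain$segments[[b]]
    sel <- bone_of == b
    if (!any(sel)) next
    mb <- markers[sel, , drop = FALSE]
    mids <- mid_of[sel]
    idx <- match(mids, seg$markers$marker_id)
    if (anyNA(idx))
      stop("unknown marker id(s) for bone ", b, call. = FALSE)
    key <- paste(mb$trial_id, mb$frame)
    for (k in unique(key)) {
      fsel <- key == k
      world <- as.matrix(mb[fsel, c("x_mm", "y_mm", "z_mm")])
      local <- seg$markers$local_coords[idx[fsel], , drop = FALSE]
      fit <- fit_rigid_pose(local, world)
      rows[[length(rows) + 1L]] <- poses_to_df(
        stats::setNames(list(fit$pose), b),
        trial_id = mb$trial_id[fsel][1], frame = mb$frame[fsel][1])
      rms[[length(rms) + 1L]] <- data.frame(
        trial_id = mb$trial_id[fsel][1], frame = mb$frame[fsel][1],
        bone = b, rms_mm = fit$rms_residual, stringsAsFactors = FALSE)
    }
  }
  poses <- do.call(rbind, rows)
  poses <- poses[base::order(poses$trial_id, poses$frame,
                             match(poses$bone, names(chain$segments))), ,
                 drop = FALSE]
  rownames(poses) <- NULL
  list(poses = poses, fit_rms = do.call(rbind, rms))
}

#' Reconstruct 3D markers from two calibrated views
#'
#' Triangulates every marker observation present in both views.
#'
#' @param markers2d 2D marker table (`trial_id, frame, camera_id,
#'   marker_id, u_px, v_px`) with `camera_id` 1 and 2.
#' @param cameras list of the two [dlt_camera()]s.
#' @return Marker table (`trial_id, frame, marker_id, x_mm, y_mm, z_mm`)
#'   with per-point reprojection residuals in `attr(, "residual_px")`.
#' @export
triangulate_markers <- function(markers2d, cameras) {
  schema_check(markers2d, marker2d_cols, "2D marker")
  m1 <- markers2d[markers2d$camera_id == 1, , drop = FALSE]
  m2 <- markers2d[markers2d$camera_id == 2, , drop = FALSE]
  key1 <- paste(m1$trial_id, m1$frame, m1$marker_id)
  key2 <- paste(m2$trial_id, m2$frame, m2$marker_id)
  common <- intersect(key1, key2)
  i1 <- match(common, key1)
  i2 <- match(common, key2)
  pts <- matrix(NA_real_, length(common), 3)
  res <- numeric(length(common))
  for (i in seq_along(common)) {
    tr <- triangulate_pair(cameras[[1]], cameras[[2]],
                           c(m1$u_px[i1[i]], m1$v_px[i1[i]]),
                           c(m2$u_px[i2[i]], m2$v_px[i2[i]]))
    pts[i, ] <- tr$point
    res[i] <- tr$residual
  }
  out <- data.frame(trial_id = m1$trial_id[i1], frame = m1$frame[i1],
                    marker_id = m1$marker_id[i1],
                    x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "residual_px") <- res
  out
}

#' A default oblique biplanar camera pair
#'
#' Two ideal DLT cameras calibrated from the 48-sphere object, placed
#' obliquely to the left and right of the walkway with ~90 degrees between
#' their optical axes, focal distance ~600 mm and principal point at
#' (512, 512) px — a stand-in for a typical biplanar videoradiography
#' configuration.
#'
#' @param separation_deg angle between the two camera azimuths.
#' @param distance_mm camera distance from the working volume centre.
#' @param focal_px focal length in pixels.
#' @return List of two [dlt_camera()]s.
#' @export
default_camera_pair <- function(separation_deg = 90, distance_mm = 600,
                                focal_px = 1500) {
  mk <- function(azimuth_deg) {
    az <- deg2rad(azimuth_deg)
    centre <- c(0, 0, -30)   # roughly where the limb moves
    pos <- centre + distance_mm * c(sin(az), -cos(az), 0.25)
    look <- (centre - pos); look <- look / sqrt(sum(look^2))
    up0 <- c(0, 0, 1)
    right <- c(look[2] * up0[3] - look[3] * up0[2],
               look[3] * up0[1] - look[1] * up0[3],
               look[1] * up0[2] - look[2] * up0[1])
    right <- right / sqrt(sum(right^2))
    up <- c(right[2] * look[3] - right[3] * look[2],
            right[3] * look[1] - right[1] * look[3],
            right[1] * look[2] - right[2] * look[1])
    # ideal pinhole -> DLT coefficients
    Rt <- rbind(right, up, look)
    tvec <- -Rt %*% pos
    K <- rbind(c(focal_px, 0, 512), c(0, focal_px, 512), c(0, 0, 1))
    P <- K %*% cbind(Rt, tvec)
    L <- c(P[1, 1:4], P[2, 1:4], P[3, 1:3]) / P[3, 4]
    dlt_camera(L[c(1:8, 9:11)])
  }
  list(mk(90 - separation_deg / 2), mk(90 + separation_deg / 2))
}

#' Run the full synthetic reconstruction pipeline
#'
#' End-to-end exercise of every stage on simulated walking trials:
#' simulate a cohort by forward kinematics, render noisy bone-fixed
#' markers (optionally projected through a biplanar camera pair and
#' triangulated back), low-pass filter the trajectories, fit rigid poses,
#' decompose the joint coordinate systems, apply reporting sign
#' conventions, segment stance/swing from the distal-ulna landmark,
#' normalise complete cycles to percent-of-cycle, bin the averaged cycle
#' and summarise joint excursions.
#'
#' @param chain an `fk_chain`; default rig when `NULL`.
#' @param profile an `fk_profile`; default walking profile when `NULL`.
#' @param seeds integer vector, one per trial.
#' @param n_cycles complete cycles per trial.
#' @param sigma_mm 3D marker noise SD (mm).
#' @param use_cameras route markers through biplanar projection plus
#'   triangulation (`sigma_px` image noise) instead of direct 3D noise.
#' @param sigma_px image noise SD (px), used when `use_cameras = TRUE`.
#' @param filter_cutoff_hz marker low-pass cutoff (Hz) for the angle
#'   stream; `NA` disables filtering.  Stance/swing events are always
#'   detected from the unfiltered fit, because zero-phase smoothing blurs
#'   the static-to-moving transition of the landmark and would bias the
#'   detected phase durations, while the angle summaries need the noise
#'   suppression.
#' @param partial_edges partial-cycle padding fraction per trial.
#' @return A list with the per-trial truth (`trials`), reconstructed
#'   `angles` (sign-converted), `segments`, `cycles`, `cycle_series`,
#'   `binned`, `excursions`, `stance_percent`, `swing_percent` and
#'   `elbow_lar_r`.
#' @export
run_synthetic_pipeline <- function(chain = NULL, profile = NULL,
                                   seeds = 1:10, n_cycles = 3,
                                   sigma_mm = 0.1, use_cameras = FALSE,
                                   sigma_px = 0.5,
                                   filter_cutoff_hz = 15,
                                   partial_edges = 0.25) {
  if (is.null(chain)) chain <- build_default_rat_chain()
  if (is.null(profile)) profile <- default_rat_profile()
  trials <- simulate_cohort(chain, profile, seeds = seeds,
                            n_cycles = n_cycles,
                            partial_edges = partial_edges)
  cameras <- if (use_cameras) default_camera_pair() else NULL

  angles_list <- list()
  cycle_angles <- list()
  seg_list <- list()
  cyc_list <- list()
  series_list <- list()
  stance_frames <- 0
  cycle_frames <- 0
  for (tr in trials) {
    rm_out <- render_markers(tr$poses, chain, cameras = cameras,
                             sigma_mm = sigma_mm, sigma_px = sigma_px,
                             seed = tr$seed)
    mk0 <- if (use_cameras) triangulate_markers(rm_out$markers2d, cameras)
           else rm_out$markers3d
    mk <- if (is.finite(filter_cutoff_hz))
      filter_trajectories(mk0, tr$frame_rate, cutoff_hz = filter_cutoff_hz)
    else mk0
    fit <- markers_to_poses(mk, chain)
    raw <- jcs_decompose(chain, fit$poses)
    ang <- apply_sign_conventions(raw, chain)
    angles_list[[tr$trial_id]] <- ang

    # gait events from the unfiltered ulna fit: temporal sharpness matters
    # more than noise suppression for the static-landmark threshold
    mk_ulna <- mk0[startsWith(mk0$marker_id, "ulna."), , drop = FALSE]
    fit_u <- markers_to_poses(mk_ulna, chain)
    lm <- landmark_trajectory(chain, fit_u$poses)
    seg <- detect_stance_swing(lm, frame_rate = tr$frame_rate)
    cyc <- segment_cycles(seg)
    seg_list[[tr$trial_id]] <- seg
    cyc_list[[tr$trial_id]] <- cyc
    if (nrow(cyc)) {
      for (ci in seq_len(nrow(cyc))) {
        series_list[[length(series_list) + 1L]] <-
          normalize_to_percent(ang, cyc[ci, , drop = FALSE])
      }
      # excursions are step-cycle quantities: pool only frames belonging
      # to complete cycles, mirroring how partial leading/trailing cycles
      # are discarded from real recordings
      insel <- ang$frame >= min(cyc$start_frame) &
        ang$frame <= max(cyc$end_frame)
      cycle_angles[[tr$trial_id]] <- ang[insel, , drop = FALSE]
      st <- seg[seg$phase == "stance", , drop = FALSE]
      for (ci in seq_len(nrow(cyc))) {
        cstart <- cyc$start_frame[ci]; cend <- cyc$end_frame[ci]
        ov <- pmin(st$end_frame, cend) - pmax(st$start_frame, cstart) + 1L
        stance_frames <- stance_frames + sum(ov[ov > 0])
        cycle_frames <- cycle_frames + (cend - cstart + 1L)
      }
    }
  }
  cycle_series <- do.call(rbind, series_list)
  binned <- bin_cycles(cycle_series)
  excursions <- summarize_excursions(cycle_angles)
  stance_pct <- 100 * stance_frames / cycle_frames
  r <- elbow_lar_correlation(
    cycle_series[cycle_series$joint == "elbow" & cycle_series$axis == "rz", ],
    cycle_series[cycle_series$joint == "radioulnar" &
                   cycle_series$axis == "rx", ])
  list(trials = trials, angles = angles_list, segments = seg_list,
       cycles = cyc_list, cycle_series = cycle_series, binned = binned,
       excursions = excursions, stance_percent = stance_pct,
       swing_percent = 100 - stance_pct, elbow_lar_r = r)
}
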