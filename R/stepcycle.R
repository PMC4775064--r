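#' Stance/swing segmentation from a landmark trajectory
#'
#' Classifies frames of one trial as stance or swing from the speed of a
#' tracked landmark (by default the distal end of the ulna, a proxy for
#' the wrist): frames whose smoothed speed falls below a fraction of the
#' trial's peak smoothed speed are stance.  Segments shorter than
#' `min_duration_frames` are merged into their neighbours and strict
#' phase alternation is enforced.
#'
#' @param landmark_xyz per-frame landmark positions: a data.frame with
#'   `x_mm, y_mm, z_mm` (and optionally `frame`, `trial_id`) or an Nx3
#'   matrix, one trial, uniformly sampled.
#' @param frame_rate sampling rate, Hz.
#' @param speed_fraction stance threshold as a fraction of the trial peak
#'   smoothed speed.
#' @param smooth_window width (frames) of the centred moving average
#'   applied to the speed series.
#' @param min_duration_frames minimum accepted segment length.
#' @return A data.frame of class `fk_segments` with columns `trial_id,
#'   segment, phase, start_frame, end_frame` (frames inclusive,
#'   contiguous, alternating phase).  An all-static or all-moving trial
#'   yields a single segment with a warning.
#' @export
detect_stance_swing <- function(landmark_xyz, frame_rate = 250,
                                speed_fraction = 0.1, smooth_window = 5,
                                min_duration_frames = 10) {
  if (is.data.frame(landmark_xyz)) {
    trial_id <- if ("trial_id" %in% names(landmark_xyz))
      landmark_xyz$trial_id[1] else "trial"
    frames <- if ("frame" %in% names(landmark_xyz)) landmark_xyz$frame
      else seq_len(nrow(landmark_xyz)) - 1L
    pos <- as.matrix(landmark_xyz[, c("x_mm", "y_mm", "z_mm")])
  } else {
    trial_id <- "trial"
    pos <- rbind_points(landmark_xyz)
    frames <- seq_len(nrow(pos)) - 1L
  }
  n <- nrow(pos)
  if (n < 2 * min_duration_frames)
    stop("need at least 2 * min_duration_frames frames", call. = FALSE)
  if (any(diff(frames) != 1L))
    stop("frames must be uniformly sampled (consecutive)", call. = FALSE)

  v <- sqrt(rowSums(diff(pos)^2)) * frame_rate   # mm/s, forward difference
  v <- c(v, v[length(v)])
  vs <- moving_average(v, smooth_window)
  peak <- max(vs)
  if (peak <= 0) {
    warning("landmark never moves: single stance segment", call. = FALSE)
    return(segments_df(trial_id, "stance", frames[1], frames[n]))
  }
  stance <- vs < speed_fraction * peak
  stance <- enforce_min_duration(stance, min_duration_frames)
  if (all(stance) || all(!stance)) {
    warning("trial is entirely ", if (all(stance)) "static" else "moving",
            ": single segment", call. = FALSE)
    return(segments_df(trial_id, if (all(stance)) "stance" else "swing",
                       frames[1], frames[n]))
  }
  r <- rle(stance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments_df(trial_id, ifelse(r$values, "stance", "swing"),
              frames[starts], frames[ends])
}

segments_df <- function(trial_id, phase, start_frame, end_frame) {
  structure(data.frame(trial_id = trial_id,
                       segment = seq_along(phase), phase = phase,
                       start_frame = start_frame, end_frame = end_frame,
                       stringsAsFactors = FALSE),
            class = c("fk_segments", "data.frame"))
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

enforce_min_duration <- function(stance, min_dur) {
  repeat {
    r <- rle(stance)
    if (length(r$lengths) <= 1L) return(stance)
    short <- which(r$lengths < min_dur)
    if (!length(short)) return(stance)
    # flip the shortest run into its neighbours
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    stance[starts[k]:ends[k]] <- !r$values[k]
  }
}

#' Extract complete step cycles
#'
#' A step cycle runs from one touchdown (stance onset) to the frame before
#' the next.  A stance segment that opens the trial is not a verified
#' touchdown (the recording may begin mid-stance) and is discarded, as are
#' trailing partial cycles.
#'
#' @param segments an `fk_segments` table from [detect_stance_swing()].
#' @return data.frame `trial_id, cycle, start_frame, end_frame,
#'   stance_end_frame` with one row per complete cycle; empty (with a
#'   warning) when no complete cycle exists.
#' @export
segment_cycles <- function(segments) {
  st <- segments[segments$phase == "stance", , drop = FALSE]
  # drop a stance segment that starts the trial: its onset is unobserved
  if (nrow(st) && st$start_frame[1] == segments$start_frame[1] &&
      segments$phase[1] == "stance")
    st <- st[-1, , drop = FALSE]
  if (nrow(st) < 2L) {
    warning("no complete touchdown-to-touchdown cycle in trial", call. = FALSE)
    return(data.frame(trial_id = character(0), cycle = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      stance_end_frame = integer(0)))
  }
  td <- st$start_frame
  data.frame(trial_id = st$trial_id[1],
             cycle = seq_len(length(td) - 1L),
             start_frame = td[-length(td)],
             end_frame = td[-1] - 1L,
             stance_end_frame = st$end_frame[-nrow(st)],
             stringsAsFactors = FALSE)
}

#' Normalise a joint series to percent-of-cycle
#'
#' Maps the frames of one complete cycle onto the percent-of-cycle axis
#' (touchdown = 0%, next touchdown = 100%, excluded) and reshapes the
#' rotational channels to long form.
#'
#' @param series an angle table (one trial) as from [jcs_decompose()].
#' @param cycle one row of the table returned by [segment_cycles()].
#' @return data.frame `trial_id, cycle, joint, axis, percent, value` with
#'   `percent` in \[0, 100).
#' @export
normalize_to_percent <- function(series, cycle) {
  check_angle_df(series)
  len <- cycle$end_frame - cycle$start_frame + 1L
  if (len <= 0 || !all(c(cycle$start_frame, cycle$end_frame) %in%
                       series$frame))
    stop("cycle lies outside the series extent", call. = FALSE)
  sel <- series$frame >= cycle$start_frame & series$frame <= cycle$end_frame
  s <- series[sel, , drop = FALSE]
  pct <- 100 * (s$frame - cycle$start_frame) / len
  out <- rbind(
    data.frame(s[c("trial_id", "joint")], axis = "rz", percent = pct,
               value = s$rz_deg, stringsAsFactors = FALSE),
    data.frame(s[c("trial_id", "joint")], axis = "ry", percent = pct,
               value = s$ry_deg, stringsAsFactors = FALSE),
    data.frame(s[c("trial_id", "joint")], axis = "rx", percent = pct,
               value = s$rx_deg, stringsAsFactors = FALSE))
  out$cycle <- cycle$cycle
  rownames(out) <- NULL
  out[, c("trial_id", "cycle", "joint", "axis", "percent", "value")]
}

#' Bin normalised cycles into the averaged step cycle
#'
#' Pools percent-of-cycle samples across cycles and trials into
#' equal-width bins (20 bins of 5% by default) and reports the per-bin
#' mean, standard deviation and sample count per joint/axis.
#'
#' @param cycle_series one or more tables from [normalize_to_percent()]
#'   (a list or a single row-bound data.frame).
#' @param n_bins number of equal-duration bins.
#' @return data.frame `joint, axis, bin, bin_center, mean, sd, n`; empty
#'   bins carry `NA` means and raise a warning.
#' @export
bin_cycles <- function(cycle_series, n_bins = 20) {
  if (is.list(cycle_series) && !is.data.frame(cycle_series))
    cycle_series <- do.call(rbind, cycle_series)
  if (!nrow(cycle_series)) stop("no cycle samples to bin", call. = FALSE)
  width <- 100 / n_bins
  bin <- pmin(floor(cycle_series$percent / width), n_bins - 1) + 1L
  out <- expand.grid(bin = seq_len(n_bins),
                     axis = unique(cycle_series$axis),
                     joint = unique(cycle_series$joint),
                     stringsAsFactors = FALSE)[, c("joint", "axis", "bin")]
  out$bin_center <- (out$bin - 0.5) * width
  key_data <- paste(cycle_series$joint, cycle_series$axis, bin)
  key_out <- paste(out$joint, out$axis, out$bin)
  out$mean <- NA_real_
  out$sd <- NA_real_
  out$n <- 0L
  agg_mean <- tapply(cycle_series$value, key_data, mean)
  agg_sd <- tapply(cycle_series$value, key_data, stats::sd)
  agg_n <- tapply(cycle_series$value, key_data, length)
  m <- match(key_out, names(agg_mean))
  hit <- !is.na(m)
  out$mean[hit] <- agg_mean[m[hit]]
  out$sd[hit] <- agg_sd[m[hit]]
  out$n[hit] <- agg_n[m[hit]]
  if (any(!hit))
    warning(sum(!hit), " empty bin(s): mean recorded as NA", call. = FALSE)
  out
}

#' Joint excursion summary
#'
#' Pools frames across all supplied trials and reports, per joint and
#' rotational axis, the minimum, maximum, range, mean and median in
#' degrees — the headline excursion table of a gait study.
#'
#' @param angles an angle table or list of angle tables (all trials).
#' @return data.frame `joint, axis, min, max, range, mean, median`.
#' @export
summarize_excursions <- function(angles) {
  if (is.list(angles) && !is.data.frame(angles))
    angles <- do.call(rbind, angles)
  check_angle_df(angles)
  long <- rbind(
    data.frame(joint = angles$joint, axis = "rz", value = angles$rz_deg,
               stringsAsFactors = FALSE),
    data.frame(joint = angles$joint, axis = "ry", value = angles$ry_deg,
               stringsAsFactors = FALSE),
    data.frame(joint = angles$joint, axis = "rx", value = angles$rx_deg,
               stringsAsFactors = FALSE))
  sp <- split(long$value, paste(long$joint, long$axis, sep = ":"))
  out <- do.call(rbind, lapply(names(sp), function(k) {
    v <- sp[[k]]
    ja <- strsplit(k, ":", fixed = TRUE)[[1]]
    data.frame(joint = ja[1], axis = ja[2],
               min = min(v), max = max(v), range = max(v) - min(v),
               mean = mean(v), median = stats::median(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlation between elbow angle and radioulnar long-axis rotation
#'
#' Resamples the two normalised series onto a common grid of bin centres
#' and reports the Pearson correlation of the binned mean curves.  With
#' the reporting conventions used here (elbow angle smaller = more flexed;
#' radioulnar X smaller = more supinated), a coupling of elbow flexion
#' with supination appears as a positive coefficient.
#'
#' @param elbow_z cycle-series rows (from [normalize_to_percent()]) of the
#'   elbow Z channel; any extra joints/axes are ignored after filtering.
#' @param radioulnar_x cycle-series rows of the radioulnar X channel.
#' @param n_bins bins for the common grid.
#' @return Pearson correlation coefficient.
#' @export
elbow_lar_correlation <- function(elbow_z, radioulnar_x, n_bins = 20) {
  pick <- function(cs, joint, axis) {
    sel <- cs$joint == joint & cs$axis == axis
    if (any(sel)) cs[sel, , drop = FALSE] else cs
  }
  be <- bin_cycles(pick(elbow_z, "elbow", "rz"), n_bins)
  br <- bin_cycles(pick(radioulnar_x, "radioulnar", "rx"), n_bins)
  ok <- !is.na(be$mean) & !is.na(br$mean)
  if (sum(ok) < 3L)
    stop("fewer than 3 common bins with data", call. = FALSE)
  stats::cor(be$mean[ok], br$mean[ok])
}
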