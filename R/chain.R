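#' Bone segment
#'
#' One rigid element of the kinematic chain: its parent link, bone-fixed
#' markers, named bone-fixed landmarks and its reference ("zero") world
#' pose.  Bone-fixed coordinates are expressed in a local frame that
#' coincides with the world axes when the chain is in the reference pose.
#'
#' @param name bone name, e.g. `"humerus"`.
#' @param parent name of the parent bone, or `NA` for the root.
#' @param markers an [marker_set()] of bone-fixed marker coordinates (mm).
#' @param landmarks named list of bone-fixed points (mm); the ulna must
#'   carry a `distal_ulna` landmark for stance detection.
#' @param ref_pose the bone's world [fk_pose()] in the reference
#'   configuration.
#' @return An object of class `fk_bone`.
#' @export
bone_segment <- function(name, parent, markers, landmarks = list(),
                         ref_pose = fk_pose()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!inherits(markers, "fk_markerset"))
    markers <- marker_set(markers)
  lm <- lapply(landmarks, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop("landmarks must be finite length-3 points", call. = FALSE)
    p
  })
  structure(list(name = name, parent = parent, markers = markers,
                 landmarks = lm, ref_pose = ref_pose),
            class = "fk_bone")
}

#' Joint coordinate system definition
#'
#' A 6-DOF virtual joint between a parent and child bone.  The JCS frame is
#' given by its world origin and axis directions at the reference pose; the
#' parent- and child-side fixed transforms are derived from the bones'
#' reference poses so that all six DOF read exactly zero in the reference
#' configuration.  Joint rotations are intrinsic Euler ZYX in the JCS
#' frame; `axis_signs` map raw rig senses onto the reporting conventions
#' and `axis_labels` document what each axis measures.
#'
#' @param name joint name, e.g. `"shoulder"`.
#' @param parent_bone,child_bone bone names; `parent_bone = NA` anchors the
#'   joint to the world frame (the root joint).
#' @param origin world position of the JCS origin at reference (mm).
#' @param axes 3x3 matrix whose columns are the JCS x, y and z axis
#'   directions in world coordinates at reference (right-handed).
#' @param axis_signs named numeric `c(rz=, ry=, rx=)` of +/-1 applied by
#'   [apply_sign_conventions()].
#' @param axis_labels named character vector documenting the anatomical
#'   reading of each rotational axis.
#' @return An object of class `fk_jcs`.
#' @export
jcs_definition <- function(name, parent_bone, child_bone, origin, axes,
                           axis_signs = c(rz = 1, ry = 1, rx = 1),
                           axis_labels = c(rz = "z", ry = "y", rx = "x")) {
  axes <- as.matrix(axes)
  R <- axes[, c(1, 2, 3)]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("JCS axes must form a right-handed orthonormal triad", call. = FALSE)
  if (!all(sort(names(axis_signs)) == c("rx", "ry", "rz")) ||
      !all(abs(axis_signs) == 1))
    stop("axis_signs must be named rz, ry, rx with values +/-1", call. = FALSE)
  structure(list(name = name, parent_bone = parent_bone,
                 child_bone = child_bone, origin = as.numeric(origin),
                 axes = R, axis_signs = axis_signs,
                 axis_labels = axis_labels),
            class = "fk_jcs")
}

#' Kinematic chain
#'
#' Assembles bone segments and JCS definitions into a validated chain:
#' topologically ordered, acyclic, every joint connecting bones present in
#' the chain.  The fixed parent-side and child-side transforms of each JCS
#' are precomputed from the reference poses.
#'
#' @param segments list of [bone_segment()]s.
#' @param jcs list of [jcs_definition()]s, one per parent/child link
#'   (including the root joint).
#' @return An object of class `fk_chain`.
#' @export
kinematic_chain <- function(segments, jcs) {
  names(segments) <- vapply(segments, `[[`, "", "name")
  names(jcs) <- vapply(jcs, `[[`, "", "name")
  # topological order from parent links
  ordered <- character(0)
  remaining <- names(segments)
  while (length(remaining)) {
    ready <- vapply(segments[remaining], function(s)
      is.na(s$parent) || s$parent %in% ordered, TRUE)
    if (!any(ready)) stop("chain has a cycle or missing parent", call. = FALSE)
    ordered <- c(ordered, remaining[ready])
    remaining <- remaining[!ready]
  }
  segments <- segments[ordered]
  child_of <- vapply(jcs, `[[`, "", "child_bone")
  for (j in jcs) {
    if (!is.na(j$parent_bone) && !j$parent_bone %in% names(segments))
      stop("JCS '", j$name, "' parent bone not in chain", call. = FALSE)
    if (!j$child_bone %in% names(segments))
      stop("JCS '", j$name, "' child bone not in chain", call. = FALSE)
  }
  for (s in segments) {
    if (!s$name %in% child_of)
      stop("bone '", s$name, "' has no driving JCS", call. = FALSE)
  }
  # fixed transforms: G = JCS world frame at reference,
  # A = ref(parent)^-1 G (parent side), B = ref(child)^-1 G (child side)
  fixed <- lapply(jcs, function(j) {
    G <- fk_pose(j$axes, j$origin)
    pref <- if (is.na(j$parent_bone)) fk_pose()
            else segments[[j$parent_bone]]$ref_pose
    cref <- segments[[j$child_bone]]$ref_pose
    list(A = pose_compose(pose_inverse(pref), G),
         B = pose_compose(pose_inverse(cref), G))
  })
  structure(list(segments = segments, jcs = jcs, fixed = fixed),
            class = "fk_chain")
}

#' @export
print.fk_chain <- function(x, ...) {
  cat("Kinematic chain:", paste(names(x$segments), collapse = " -> "), "\n")
  for (j in x$jcs)
    cat(sprintf("  JCS %-12s %s -> %s\n", j$name,
                ifelse(is.na(j$parent_bone), "<world>", j$parent_bone),
                j$child_bone))
  invisible(x)
}

place_bone_markers <- function(length_mm, axis_dir, radius_mm, n = 6) {
  along <- seq(0.06, 0.94, length.out = n) * length_mm * axis_dir
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(along, radius_mm * cos(th), radius_mm * sin(th))
}

#' Default chain geometry configuration
#'
#' Bone lengths, marker placement and joint offsets of the packaged
#' forelimb rig.  The metric values are package plumbing chosen to be
#' plausible for a ~350 g rat; they are configurable and carry no claim of
#' anatomical accuracy.  Marker sets emulate beads implanted along each
#' bone shaft at the bone surface.
#'
#' @return A nested list accepted by [build_default_rat_chain()].
#' @export
default_chain_config <- function() {
  list(
    humerus_length = 30, ulna_length = 35, radius_length = 33,
    shoulder_drop = 6,            # manubrium to humeral head, mm
    radius_offset = c(2, 2, 0),   # proximal radius relative to notch, mm
    marker_radius = 4,            # transverse bead offset from shaft axis, mm
    markers_per_bone = 6L
  )
}

#' Build the default rat forelimb chain
#'
#' Constructs the body-humerus-ulna-radius chain with its reference
#' ("zero") pose and the shoulder, elbow and radioulnar joint coordinate
#' systems, plus a root JCS tracking the body frame in the world.
#'
#' The reference pose standardises the rig rather than depicting a feasible
#' posture: the humerus lies horizontal beneath the body frame with the
#' shoulder JCS centred between the sternal manubrium and the caudal
#' humeral head; the ulna is folded so its olecranon aligns with the
#' humeral shaft (the anatomical elbow angle reads 0 degrees); the radius
#' is rotated 180 degrees from its most pronated orientation (fully
#' supinated), so pronation is measured as radioulnar X rising towards 180.
#' All six DOF of every JCS read zero in this configuration.
#'
#' World frame: right-handed, +X cranial (direction of travel), +Y the
#' animal's left, +Z up.
#'
#' @param config geometry configuration as from [default_chain_config()];
#'   missing entries are filled with defaults.
#' @return An `fk_chain`.
#' @export
build_default_rat_chain <- function(config = NULL) {
  cfg <- default_chain_config()
  if (!is.null(config)) {
    if (!is.list(config)) stop("config must be a list", call. = FALSE)
    bad <- setdiff(names(config), names(cfg))
    if (length(bad))
      stop("unknown config entries: ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(config)] <- config
  }
  num <- c("humerus_length", "ulna_length", "radius_length", "shoulder_drop",
           "marker_radius")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar", call. = FALSE)

  Lh <- cfg$humerus_length; Lu <- cfg$ulna_length; Lr <- cfg$radius_length
  drop <- cfg$shoulder_drop
  r <- cfg$marker_radius; n <- cfg$markers_per_bone

  head_w <- c(0, 0, -drop)                 # humeral head (world, reference)
  notch_w <- head_w + c(-Lh, 0, 0)         # semi-lunar notch / elbow centre
  radprox_w <- notch_w + cfg$radius_offset # proximal radius head

  segments <- list(
    bone_segment("body", NA_character_,
                 marker_set(place_bone_markers(22, -1, 4, n)),
                 landmarks = list(manubrium = c(0, 0, 0)),
                 ref_pose = fk_pose()),
    bone_segment("humerus", "body",
                 marker_set(place_bone_markers(Lh, -1, r, n)),
                 landmarks = list(head = c(0, 0, 0),
                                  epicondyles = c(-Lh, 0, 0)),
                 ref_pose = fk_pose(diag(3), head_w)),
    bone_segment("ulna", "humerus",
                 marker_set(place_bone_markers(Lu, 1, r, n)),
                 landmarks = list(semilunar_notch = c(0, 0, 0),
                                  distal_ulna = c(Lu, 0, 0)),
                 ref_pose = fk_pose(diag(3), notch_w)),
    bone_segment("radius", "ulna",
                 marker_set(place_bone_markers(Lr, 1, r, n)),
                 landmarks = list(radial_head = c(0, 0, 0),
                                  distal_radius = c(Lr, 0, 0)),
                 ref_pose = fk_pose(diag(3), radprox_w))
  )

  # JCS axis triads (columns x, y, z in world coordinates at reference).
  # Shoulder/elbow: z along world +Y (flexion axis, sagittal-plane
  # rotations), x caudal along the shaft (long-axis rotation).
  ax_caudal <- cbind(c(-1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  # Radioulnar: x cranial along the radius shaft so pronation is positive.
  ax_cranial <- cbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))

  jcs <- list(
    jcs_definition("body", NA_character_, "body",
                   origin = c(0, 0, 0), axes = diag(3),
                   axis_labels = c(rz = "body yaw", ry = "body pitch",
                                   rx = "body roll")),
    jcs_definition("shoulder", "body", "humerus",
                   origin = head_w + c(0, 0, drop / 2), axes = ax_caudal,
                   axis_labels = c(
                     rz = "protraction (-) / retraction (+)",
                     ry = "abduction (-) / adduction (+)",
                     rx = "medial (-) / lateral (+) long-axis rotation")),
    jcs_definition("elbow", "humerus", "ulna",
                   origin = notch_w, axes = ax_caudal,
                   axis_labels = c(
                     rz = "elbow angle: flexion (-) / extension (+), <90 flexed",
                     ry = "abduction (-) / adduction (+)",
                     rx = "long-axis rotation")),
    jcs_definition("radioulnar", "ulna", "radius",
                   origin = radprox_w, axes = ax_cranial,
                   axis_labels = c(
                     rz = "flexion / extension",
                     ry = "abduction / adduction",
                     rx = "pronation (+) / supination (-), 180 = full pronation"))
  )
  kinematic_chain(segments, jcs)
}

#' All-zero joint values for a chain
#'
#' Convenience constructor of the 6-DOF value list that puts the chain in
#' its reference pose.
#'
#' @param chain an `fk_chain`.
#' @return Named list of `c(tx, ty, tz, rz, ry, rx)` vectors, all zero.
#' @export
zero_joint_values <- function(chain) {
  v <- stats::setNames(
    rep(list(c(tx = 0, ty = 0, tz = 0, rz = 0, ry = 0, rx = 0)),
        length(chain$jcs)),
    names(chain$jcs))
  v
}

joint_pose <- function(dof) {
  fk_pose(compose_euler_zyx(dof[["rz"]], dof[["ry"]], dof[["rx"]]),
          c(dof[["tx"]], dof[["ty"]], dof[["tz"]]))
}

#' Forward kinematics of the chain
#'
#' Computes the world pose of every bone from per-joint 6-DOF values
#' (raw rig convention, i.e. as returned by [jcs_decompose()] before sign
#' conversion).  The root joint is applied first and children composed
#' through their JCS transforms in chain order.
#'
#' @param chain an `fk_chain`.
#' @param joint_values named list, one entry per JCS, each a named numeric
#'   `c(tx, ty, tz, rz, ry, rx)` (mm / degrees).
#' @return Named list of [fk_pose()]s, one per bone.
#' @export
forward_kinematics <- function(chain, joint_values) {
  missing <- setdiff(names(chain$jcs), names(joint_values))
  if (length(missing))
    stop("missing joint values for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  poses <- list()
  for (j in chain$jcs) {
    fx <- chain$fixed[[j$name]]
    Wp <- if (is.na(j$parent_bone)) fk_pose() else poses[[j$parent_bone]]
    Tj <- joint_pose(joint_values[[j$name]])
    poses[[j$child_bone]] <-
      pose_compose(pose_compose(Wp, pose_compose(fx$A, Tj)),
                   pose_inverse(fx$B))
  }
  poses[names(chain$segments)]
}

decompose_one_jcs <- function(chain, jname, Wp, Wc) {
  fx <- chain$fixed[[jname]]
  Tj <- pose_compose(pose_inverse(fx$A),
                     pose_compose(pose_compose(pose_inverse(Wp), Wc), fx$B))
  e <- decompose_euler_zyx(Tj$R)
  c(tx = Tj$t[1], ty = Tj$t[2], tz = Tj$t[3],
    rz = e$rz, ry = e$ry, rx = e$rx, gimbal = as.numeric(e$gimbal))
}

#' Decompose bone pose series into JCS joint series
#'
#' For every frame and joint, expresses the child-side JCS frame relative
#' to the parent-side frame as three translations (mm, in JCS axes) and
#' intrinsic Euler ZYX rotations (degrees).  Rotation channels are
#' unwrapped over frames for continuity and re-centred so the channel
#' median lies in (-180, 180]; gimbal-flagged frames are propagated as a
#' warning and recorded in the `gimbal_frames` attribute.
#'
#' The output is in raw rig convention; apply
#' [apply_sign_conventions()] to obtain reported anatomical senses.
#'
#' @param chain an `fk_chain`.
#' @param poses a pose table as produced by [poses_to_df()] /
#'   [simulate_trial()]: columns `trial_id, frame, bone, r11..r33,
#'   tx_mm, ty_mm, tz_mm`, with a pose for every bone in every frame.
#' @return Angle table: `trial_id, frame, joint, tx_mm, ty_mm, tz_mm,
#'   rz_deg, ry_deg, rx_deg`, with attribute `sign_converted = FALSE`.
#' @export
jcs_decompose <- function(chain, poses) {
  check_pose_df(poses)
  bones <- names(chain$segments)
  out <- list()
  gimbal_frames <- integer(0)
  for (tid in unique(poses$trial_id)) {
    ptr <- poses[poses$trial_id == tid, , drop = FALSE]
    frames <- sort(unique(ptr$frame))
    # bone -> frame-indexed list of poses
    plist <- list()
    for (b in bones) {
      pb <- ptr[ptr$bone == b, , drop = FALSE]
      if (!all(frames %in% pb$frame))
        stop("missing pose for bone '", b, "' in trial ", tid, call. = FALSE)
      pb <- pb[match(frames, pb$frame), , drop = FALSE]
      plist[[b]] <- df_to_poses(pb)
    }
    for (j in chain$jcs) {
      vals <- matrix(NA_real_, length(frames), 7)
      for (i in seq_along(frames)) {
        Wp <- if (is.na(j$parent_bone)) fk_pose()
              else plist[[j$parent_bone]][[i]]
        Wc <- plist[[j$child_bone]][[i]]
        vals[i, ] <- decompose_one_jcs(chain, j$name, Wp, Wc)
      }
      if (any(vals[, 7] > 0))
        gimbal_frames <- c(gimbal_frames, frames[vals[, 7] > 0])
      ang <- vals[, 4:6, drop = FALSE]
      for (k in 1:3) ang[, k] <- recenter_series(unwrap_angle_series(ang[, k]))
      out[[length(out) + 1L]] <- data.frame(
        trial_id = tid, frame = frames, joint = j$name,
        tx_mm = vals[, 1], ty_mm = vals[, 2], tz_mm = vals[, 3],
        rz_deg = ang[, 1], ry_deg = ang[, 2], rx_deg = ang[, 3],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(gimbal_frames)) {
    warning("gimbal-adjacent frames flagged: rx forced to 0 there",
            call. = FALSE)
    attr(res, "gimbal_frames") <- sort(unique(gimbal_frames))
  }
  attr(res, "sign_converted") <- FALSE
  res
}

recenter_series <- function(x) {
  if (!length(x)) return(x)
  k <- round(stats::median(x) / 360)
  x - 360 * k
}

#' Apply reporting sign conventions to a raw joint series
#'
#' Maps raw rig-convention rotation channels onto the reported anatomical
#' senses recorded in each JCS definition (`axis_signs`): for the default
#' rig, shoulder Z protraction negative / retraction positive, shoulder Y
#' abduction negative / adduction positive, shoulder X medial negative /
#' lateral positive; the elbow Z scale is anatomical (0 = fully folded,
#' values under 90 degrees flexed); radioulnar X rises towards 180 with
#' pronation.  A series that has already been converted is rejected via its
#' `sign_converted` flag, so the map is never silently applied twice.
#'
#' @param raw angle table from [jcs_decompose()].
#' @param chain the `fk_chain` whose JCS definitions carry the sign maps.
#' @return The converted angle table with `sign_converted = TRUE`.
#' @export
apply_sign_conventions <- function(raw, chain) {
  check_angle_df(raw)
  if (isTRUE(attr(raw, "sign_converted")))
    stop("series is already sign-converted (flag set)", call. = FALSE)
  unknown <- setdiff(unique(raw$joint), names(chain$jcs))
  if (length(unknown))
    stop("unknown joint(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  out <- raw
  for (j in chain$jcs) {
    sel <- out$joint == j$name
    if (!any(sel)) next
    s <- j$axis_signs
    out$rz_deg[sel] <- s[["rz"]] * out$rz_deg[sel]
    out$ry_deg[sel] <- s[["ry"]] * out$ry_deg[sel]
    out$rx_deg[sel] <- s[["rx"]] * out$rx_deg[sel]
  }
  attr(out, "sign_converted") <- TRUE
  attr(out, "gimbal_frames") <- attr(raw, "gimbal_frames")
  out
}

#' World trajectory of a bone-fixed landmark
#'
#' @param chain an `fk_chain`.
#' @param poses pose table (see [jcs_decompose()]).
#' @param bone bone name carrying the landmark.
#' @param landmark landmark name, e.g. `"distal_ulna"`.
#' @return data.frame `trial_id, frame, x_mm, y_mm, z_mm`.
#' @export
landmark_trajectory <- function(chain, poses, bone = "ulna",
                                landmark = "distal_ulna") {
  check_pose_df(poses)
  seg <- chain$segments[[bone]]
  if (is.null(seg)) stop("bone '", bone, "' not in chain", call. = FALSE)
  p <- seg$landmarks[[landmark]]
  if (is.null(p))
    stop("landmark '", landmark, "' not defined on ", bone, call. = FALSE)
  pb <- poses[poses$bone == bone, , drop = FALSE]
  pb <- pb[order(pb$trial_id, pb$frame), , drop = FALSE]
  R <- as.matrix(pb[, c("r11", "r12", "r13", "r21", "r22", "r23",
                        "r31", "r32", "r33")])
  w <- cbind(
    R[, 1] * p[1] + R[, 2] * p[2] + R[, 3] * p[3] + pb$tx_mm,
    R[, 4] * p[1] + R[, 5] * p[2] + R[, 6] * p[3] + pb$ty_mm,
    R[, 7] * p[1] + R[, 8] * p[2] + R[, 9] * p[3] + pb$tz_mm)
  data.frame(trial_id = pb$trial_id, frame = pb$frame,
             x_mm = w[, 1], y_mm = w[, 2], z_mm = w[, 3],
             stringsAsFactors = FALSE)
}

#' Convert between pose lists and the pose table schema
#'
#' @param poses named list of [fk_pose()]s (one per bone).
#' @param trial_id trial identifier.
#' @param frame frame number (0-based).
#' @return `poses_to_df()`: one-row-per-bone data.frame in the pose schema;
#'   `df_to_poses()`: list of `fk_pose` in row order.
#' @export
poses_to_df <- function(poses, trial_id = "trial", frame = 0L) {
  rows <- lapply(names(poses), function(b) {
    p <- poses[[b]]
    data.frame(trial_id = trial_id, frame = frame, bone = b,
               r11 = p$R[1, 1], r12 = p$R[1, 2], r13 = p$R[1, 3],
               r21 = p$R[2, 1], r22 = p$R[2, 2], r23 = p$R[2, 3],
               r31 = p$R[3, 1], r32 = p$R[3, 2], r33 = p$R[3, 3],
               tx_mm = p$t[1], ty_mm = p$t[2], tz_mm = p$t[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname poses_to_df
#' @param df pose table rows.
#' @export
df_to_poses <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    R <- matrix(as.numeric(df[i, c("r11", "r12", "r13",
                                   "r21", "r22", "r23",
                                   "r31", "r32", "r33")]),
                3, 3, byrow = TRUE)
    fk_pose(R, as.numeric(df[i, c("tx_mm", "ty_mm", "tz_mm")]))
  })
}
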