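#' Rigid-body pose
#'
#' A pose is a proper rigid transform: a 3x3 rotation matrix together with a
#' translation vector in millimetres.  Poses map bone-fixed (local)
#' coordinates into the world frame: `x_world = R %*% x_local + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector (mm).
#' @return An object of class `fk_pose` with elements `R` and `t`.
#' @export
fk_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation)))
    stop("rotation must be a finite 3x3 matrix", call. = FALSE)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite length-3 vector", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (R'R != I within 1e-9)", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)", call. = FALSE)
  structure(list(R = rotation, t = translation), class = "fk_pose")
}

#' @export
print.fk_pose <- function(x, ...) {
  cat("Rigid pose (mm):\n")
  m <- cbind(x$R, x$t)
  dimnames(m) <- list(NULL, c("r.1", "r.2", "r.3", "t"))
  print(round(m, 6))
  invisible(x)
}

is_fk_pose <- function(x) inherits(x, "fk_pose")

#' Compose two poses
#'
#' Returns the pose `a` followed-by `b` in the usual transform sense:
#' `(a %o% b)(x) = a(b(x))`.
#'
#' @param a,b poses.
#' @return The composed `fk_pose`.
#' @export
pose_compose <- function(a, b) {
  fk_pose(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

#' Invert a pose
#' @param p a pose.
#' @return The inverse `fk_pose`.
#' @export
pose_inverse <- function(p) {
  fk_pose(t(p$R), as.vector(-t(p$R) %*% p$t))
}

#' Apply a pose to points
#' @param p a pose.
#' @param x Nx3 matrix (or length-3 vector) of local coordinates (mm).
#' @return Matrix of transformed world coordinates.
#' @export
pose_apply <- function(p, x) {
  x <- rbind_points(x)
  sweep(x %*% t(p$R), 2, p$t, "+")
}

#' Pose of a child frame relative to a parent frame
#'
#' Computes `parent^-1 o child`, the transform that expresses the child's
#' frame in the parent's coordinates (e.g. the humerus relative to the
#' sternum).
#'
#' @param parent,child poses in a common world frame.
#' @return The relative `fk_pose`; `relative_pose(P, P)` is the identity.
#' @export
relative_pose <- function(parent, child) {
  pose_compose(pose_inverse(parent), child)
}

rbind_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("points must be Nx3", call. = FALSE)
  x
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Compose a rotation from Euler ZYX angles
#'
#' Builds `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)` (intrinsic Z, then Y, then X,
#' right-hand rule), the rotation order used by every joint coordinate
#' system in this package: moving the Z-axis carries the Y- and X-axes with
#' it, moving the Y-axis carries the X-axis.
#'
#' @param rz,ry,rx angles in degrees.  `rz` may instead be a length-3 vector
#'   `c(rz, ry, rx)`.
#' @return 3x3 rotation matrix.
#' @export
compose_euler_zyx <- function(rz, ry = NULL, rx = NULL) {
  if (is.null(ry) && length(rz) == 3L) {
    ry <- rz[[2]]; rx <- rz[[3]]; rz <- rz[[1]]
  }
  a <- c(rz, ry, rx)
  if (length(a) != 3L || !all(is.finite(a)))
    stop("rz, ry, rx must be three finite angles (degrees)", call. = FALSE)
  rot_z(deg2rad(a[1])) %*% rot_y(deg2rad(a[2])) %*% rot_x(deg2rad(a[3]))
}

#' Decompose a rotation into Euler ZYX angles
#'
#' Inverse of [compose_euler_zyx()].  Returns the canonical branch with
#' `ry` in \[-90, 90\] degrees and `rz`, `rx` in (-180, 180\].  At gimbal
#' lock (`|cos(ry)| < 1e-8`) `rz` and `rx` are coupled; the convention here
#' is deterministic: `rx` is set to 0, the coupled rotation is absorbed into
#' `rz`, and the result is flagged.
#'
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @return A list with `rz`, `ry`, `rx` (degrees) and logical `gimbal`.
#' @export
decompose_euler_zyx <- function(rotation) {
  R <- as.matrix(rotation)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stop("input is not a proper rotation matrix", call. = FALSE)
  # R[3,1] = -sin(ry)
  sy <- -max(-1, min(1, R[3, 1]))
  ry <- asin(sy)
  if (abs(cos(ry)) < 1e-8) {
    # gimbal lock: only rz +/- rx observable; put everything into rz
    rx <- 0
    # with ry = +/-90: R[1,2] = -cos(rz +/- rx)*? derive via atan2 of the
    # remaining 2x2 block, which encodes rz -/+ rx
    if (sy > 0) rz <- atan2(R[2, 3], R[2, 2]) else rz <- -atan2(R[2, 3], R[2, 2])
    out <- list(rz = rad2deg(rz), ry = rad2deg(ry), rx = 0, gimbal = TRUE)
  } else {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
    out <- list(rz = rad2deg(rz), ry = rad2deg(ry), rx = rad2deg(rx),
                gimbal = FALSE)
  }
  # canonicalize (-180, 180]
  out$rz <- wrap_deg(out$rz)
  out$rx <- wrap_deg(out$rx)
  out
}

wrap_deg <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Bone-fixed marker set
#'
#' Marker coordinates in a bone-fixed frame.  At least three non-collinear
#' markers are required for rigid-body pose estimation.
#'
#' @param local_coords Nx3 matrix of marker coordinates (mm).
#' @param marker_id optional character vector of marker names.
#' @return An object of class `fk_markerset`.
#' @export
marker_set <- function(local_coords, marker_id = NULL) {
  local_coords <- rbind_points(local_coords)
  n <- nrow(local_coords)
  if (n < 3L) stop("at least 3 markers are required", call. = FALSE)
  if (is.null(marker_id)) marker_id <- sprintf("m%02d", seq_len(n))
  if (length(marker_id) != n) stop("marker_id length mismatch", call. = FALSE)
  sv <- svd(scale(local_coords, scale = FALSE))$d
  if (sv[2] <= 1e-6)
    stop("markers are collinear (degenerate configuration)", call. = FALSE)
  structure(list(marker_id = as.character(marker_id),
                 local_coords = local_coords),
            class = "fk_markerset")
}

#' Least-squares rigid pose from markers (Kabsch fit)
#'
#' Finds the proper rigid transform minimising the sum of squared distances
#' between transformed local markers and their observed world positions,
#' via SVD of the cross-covariance with a reflection guard on the smallest
#' singular vector.
#'
#' @param local an [marker_set()] or Nx3 matrix of bone-fixed coordinates
#'   (mm).
#' @param world Nx3 matrix of observed world coordinates (mm), same marker
#'   order.
#' @return A list with `pose` (the fitted [fk_pose()]) and `rms_residual`,
#'   the root-mean-square per-marker fit error in mm.
#' @export
fit_rigid_pose <- function(local, world) {
  if (inherits(local, "fk_markerset")) local <- local$local_coords
  local <- rbind_points(local)
  world <- rbind_points(world)
  n <- nrow(local)
  if (n < 3L) stop("at least 3 markers are required", call. = FALSE)
  if (nrow(world) != n) stop("local and world marker counts differ", call. = FALSE)
  sv <- svd(scale(local, scale = FALSE))$d
  if (sv[2] <= 1e-6)
    stop("markers are collinear (degenerate configuration)", call. = FALSE)
  cl <- colMeans(local)
  cw <- colMeans(world)
  A <- sweep(local, 2, cl)
  B <- sweep(world, 2, cw)
  H <- crossprod(A, B)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))  # reflection guard
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cw - as.vector(R %*% cl)
  fit <- sweep(local %*% t(R), 2, t, "+")
  rms <- sqrt(mean(rowSums((fit - world)^2)))
  list(pose = fk_pose(R, t), rms_residual = rms)
}

#' Unwrap an angle series
#'
#' Removes 360-degree discontinuities from a uniformly sampled angle series
#' so that successive differences never exceed 180 degrees in magnitude.
#' Values may leave (-180, 180].
#'
#' @param series numeric vector of angles in degrees.
#' @return Unwrapped numeric vector of the same length.
#' @export
unwrap_angle_series <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2L) return(series)
  d <- diff(series)
  jump <- round(d / 360)
  series - c(0, cumsum(jump)) * 360
}
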