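#' DLT camera
#'
#' An ideal 11-parameter direct linear transformation camera mapping world
#' millimetres to image pixels:
#' `u = (L1 x + L2 y + L3 z + L4) / (L9 x + L10 y + L11 z + 1)` and
#' `v = (L5 x + L6 y + L7 z + L8) / (L9 x + L10 y + L11 z + 1)`.
#' No lens-distortion terms are modelled; radiographic image distortion is
#' assumed to have been removed upstream.
#'
#' @param coefficients numeric vector of the 11 DLT parameters.
#' @return An object of class `fk_camera`.
#' @export
dlt_camera <- function(coefficients) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 11L || !all(is.finite(coefficients)))
    stop("a DLT camera has 11 finite coefficients", call. = FALSE)
  structure(list(coefficients = coefficients), class = "fk_camera")
}

#' Three-tier calibration object
#'
#' Builds the 48-sphere calibration object: three tiers of a 4x4 grid of
#' 3 mm steel spheres evenly distributed through an acrylic cube.  The
#' lowest tier sits at z = 0 and the grid origin at (0, 0).
#'
#' @param tier_spacing vertical distance between tiers (mm).
#' @param grid_pitch in-plane spacing between adjacent spheres (mm).
#' @return A list of class `fk_calobject` with `points` (48x3 matrix, mm)
#'   and `sphere_diameter_mm` metadata.
#' @export
make_calibration_object <- function(tier_spacing = 20, grid_pitch = 10) {
  if (tier_spacing <= 0 || grid_pitch <= 0)
    stop("tier_spacing and grid_pitch must be positive", call. = FALSE)
  g <- grid_pitch * (0:3)
  z <- tier_spacing * (0:2)
  pts <- as.matrix(expand.grid(x = g, y = g, z = z))
  dimnames(pts) <- NULL
  structure(list(points = pts, sphere_diameter_mm = 3),
            class = "fk_calobject")
}

check_noncoplanar <- function(world) {
  sv <- svd(scale(world, scale = FALSE))$d
  if (sv[3] <= 1e-6 * sv[1])
    stop("world points are coplanar (degenerate configuration)", call. = FALSE)
}

#' Calibrate an 11-parameter DLT camera
#'
#' Linear least-squares solution of the 11 DLT coefficients from matched
#' world / image points.  World coordinates are centred and scaled before
#' the solve for conditioning and the coefficients mapped back afterwards.
#'
#' @param world Nx3 matrix of calibration-point coordinates (mm), N >= 6,
#'   non-coplanar.  May also be an `fk_calobject`.
#' @param image Nx2 matrix of the corresponding image points (px).
#' @return A list with `camera` (an [dlt_camera()]) and `rms_reprojection`
#'   in pixels.
#' @export
calibrate_dlt <- function(world, image) {
  if (inherits(world, "fk_calobject")) world <- world$points
  world <- rbind_points(world)
  image <- as.matrix(image)
  storage.mode(image) <- "double"
  if (ncol(image) != 2L || nrow(image) != nrow(world))
    stop("image must be Nx2 and match world", call. = FALSE)
  n <- nrow(world)
  if (n < 6L) stop("at least 6 calibration points are required", call. = FALSE)
  check_noncoplanar(world)

  ctr <- colMeans(world)
  sc <- mean(sqrt(rowSums(sweep(world, 2, ctr)^2)))
  W <- sweep(world, 2, ctr) / sc

  u <- image[, 1]; v <- image[, 2]
  A <- matrix(0, 2 * n, 11)
  A[seq(1, 2 * n, 2), 1:3] <- W
  A[seq(1, 2 * n, 2), 4] <- 1
  A[seq(1, 2 * n, 2), 9:11] <- -u * W
  A[seq(2, 2 * n, 2), 5:7] <- W
  A[seq(2, 2 * n, 2), 8] <- 1
  A[seq(2, 2 * n, 2), 9:11] <- -v * W
  b <- as.vector(rbind(u, v))
  L <- qr.coef(qr(A), b)

  # undo normalization: x' = (x - ctr)/sc in both numerators and denominator
  denom0 <- 1 - sum(L[9:11] * ctr) / sc
  Lw <- numeric(11)
  Lw[1:3] <- L[1:3] / sc
  Lw[4] <- L[4] - sum(L[1:3] * ctr) / sc
  Lw[5:7] <- L[5:7] / sc
  Lw[8] <- L[8] - sum(L[5:7] * ctr) / sc
  Lw[9:11] <- L[9:11] / sc
  Lw <- Lw / denom0
  cam <- dlt_camera(Lw)

  proj <- project_point(cam, world)
  rms <- sqrt(mean(rowSums((proj - image)^2)))
  list(camera = cam, rms_reprojection = rms)
}

#' Project world points through a DLT camera
#'
#' @param camera an [dlt_camera()].
#' @param point length-3 vector or Nx3 matrix of world coordinates (mm).
#' @return Nx2 matrix of image coordinates (px).
#' @export
project_point <- function(camera, point) {
  L <- camera$coefficients
  P <- rbind_points(point)
  den <- P %*% L[9:11] + 1
  if (any(abs(den) <= 1e-12))
    stop("point lies on the camera plane (projection singular)", call. = FALSE)
  u <- (P %*% L[1:3] + L[4]) / den
  v <- (P %*% L[5:7] + L[8]) / den
  cbind(u = as.vector(u), v = as.vector(v))
}

#' Triangulate a 3D point from two calibrated views
#'
#' Stacks the linearised DLT projection equations of both cameras into a
#' 4x3 least-squares system and solves for the world point.
#'
#' @param cam1,cam2 calibrated [dlt_camera()] objects.
#' @param uv1,uv2 length-2 image coordinates (px) of the same point in each
#'   view.
#' @return A list with `point` (length-3, mm) and `residual`, the RMS
#'   reprojection error over both views (px).
#' @export
triangulate_pair <- function(cam1, cam2, uv1, uv2) {
  rows <- function(cam, uv) {
    L <- cam$coefficients
    rbind(c(L[1] - uv[1] * L[9], L[2] - uv[1] * L[10], L[3] - uv[1] * L[11]),
          c(L[5] - uv[2] * L[9], L[6] - uv[2] * L[10], L[7] - uv[2] * L[11]))
  }
  rhs <- function(cam, uv) {
    L <- cam$coefficients
    c(uv[1] - L[4], uv[2] - L[8])
  }
  A <- rbind(rows(cam1, uv1), rows(cam2, uv2))
  b <- c(rhs(cam1, uv1), rhs(cam2, uv2))
  sv <- svd(A)$d
  if (sv[3] <= 0 || sv[1] / sv[3] > 1e8)
    stop("ray geometry is ill-conditioned (near-parallel views)", call. = FALSE)
  x <- qr.coef(qr(A), b)
  r1 <- project_point(cam1, x) - rbind(uv1)
  r2 <- project_point(cam2, x) - rbind(uv2)
  res <- sqrt(mean(c(sum(r1^2), sum(r2^2))))
  list(point = as.vector(x), residual = res)
}
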