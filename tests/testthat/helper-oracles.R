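# Independent oracles used across the suite.  These deliberately avoid the
# package's own formulations so round-trip agreement is evidence, not
# tautology.

# Rodrigues rotation about an arbitrary unit axis (degrees)
rodrigues <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# brute-force ZYX product from elementary Rodrigues rotations
oracle_euler_zyx <- function(rz, ry, rx) {
  rodrigues(c(0, 0, 1), rz) %*% rodrigues(c(0, 1, 0), ry) %*%
    rodrigues(c(1, 0, 0), rx)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotation_angle_deg <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

# coarse-to-fine grid search for the best rigid fit of local -> world:
# minimises RMS over rotations (Euler grid) with the optimal translation
# at each node.  Slow and exhaustive by design.
grid_rigid_fit <- function(local, world, levels = 3, n_grid = 13) {
  cl <- colMeans(local); cw <- colMeans(world)
  A <- sweep(local, 2, cl); B <- sweep(world, 2, cw)
  cost <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  centre <- c(0, 0, 0); span <- 180
  best <- list(cost = Inf, R = diag(3))
  for (lev in seq_len(levels)) {
    g <- seq(-span, span, length.out = n_grid)
    for (az in centre[1] + g) for (ay in centre[2] + g / 2)
      for (ax in centre[3] + g) {
        R <- oracle_euler_zyx(az, ay, ax)
        cc <- cost(R)
        if (cc < best$cost) {
          best <- list(cost = cc, R = R)
          bestang <- c(az, ay, ax)
        }
      }
    centre <- bestang
    span <- span / (n_grid - 1) * 2.5
  }
  best
}

# nested grid search for two-view triangulation around a start point
grid_triangulate <- function(cam1, cam2, uv1, uv2, start, span = 5,
                             levels = 3, n_grid = 11) {
  cost <- function(p) {
    r1 <- project_point(cam1, p) - rbind(uv1)
    r2 <- project_point(cam2, p) - rbind(uv2)
    sum(r1^2) + sum(r2^2)
  }
  centre <- start
  best <- list(cost = Inf, p = start)
  for (lev in seq_len(levels)) {
    g <- seq(-span, span, length.out = n_grid)
    for (dx in g) for (dy in g) for (dz in g) {
      p <- centre + c(dx, dy, dz)
      cc <- cost(p)
      if (cc < best$cost) best <- list(cost = cc, p = p)
    }
    centre <- best$p
    span <- span / (n_grid - 1) * 2.5
  }
  best$p
}

# small ideal DLT camera built from an explicit homogeneous matrix
toy_camera <- function(azimuth_deg = 45, distance = 500, focal = 1200) {
  default_camera_pair(separation_deg = 2 * (90 - azimuth_deg),
                      distance_mm = distance, focal_px = focal)[[1]]
}
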