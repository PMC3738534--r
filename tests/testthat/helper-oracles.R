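# Independent oracles and generators shared across the suite. These
# deliberately avoid the package's own code paths: plane normals come from a
# direct SVD, rotations from quaternion algebra, and superposition residuals
# from bio3d.

# Best-fit plane normal of a point cloud (unit vector, sign arbitrary).
svd_plane_normal <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  svd(cc)$v[, 3]
}

# Angle between two unoriented directions, degrees.
dir_angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

# Quaternion rotation of vector v by `angle` about unit `axis`.
quat_rotate <- function(axis, angle, v) {
  q <- c(cos(angle / 2), sin(angle / 2) * axis)
  qmul <- function(a, b) c(
    a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
  qc <- c(q[1], -q[2:4])
  qmul(qmul(q, c(0, v)), qc)[2:4]
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Random proper rotation built from quaternion algebra (independent of the
# package's Rodrigues implementation).
random_rotation <- function() {
  ax <- random_unit()
  ang <- stats::runif(1, 0, pi)
  m <- sapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
              function(e) quat_rotate(ax, ang, e))
  m
}

# Apply a rigid motion to a coordinate matrix.
rigid_move <- function(coords, R, t) sweep(coords %*% t(R), 2, t, "+")

# A perturbed near-planar quartet: ideal quartet coordinates with small
# per-base rigid perturbations. Kept genuinely near-planar: rigid per-base
# out-of-plane shifts move the whole-cloud SVD plane but no base normal, so
# large shifts would make the two plane definitions legitimately diverge.
perturbed_quartet <- function(tilt_sd = 1, shift_sd = 0.1, z_shift_sd = 0.02) {
  q <- build_quartet(5.4, 0)
  lapply(q, function(b) {
    ax <- random_unit()
    R <- matrix(sapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                       function(e) quat_rotate(ax, stats::rnorm(1, 0, tilt_sd * pi / 180), e)),
                3, 3)
    ctr <- colMeans(b$coords)
    shift <- c(stats::rnorm(2, 0, shift_sd), stats::rnorm(1, 0, z_shift_sd))
    sweep(sweep(b$coords, 2, ctr) %*% t(R), 2, ctr + shift, "+")
  })
}

fit_quartet_frames <- function(coord_list) {
  std <- get_standard_base("G")
  lapply(coord_list, fit_base_frame, std = std)
}

# Geodesic bisector oracle via normalized vector sum (exact for unit
# vectors with dot > -1); independent of the half-angle rotation route.
bisector_oracle <- function(z1, z2) {
  s <- z1 + z2
  s / sqrt(sum(s^2))
}

# Quartet-axis oracle replicating the association contract through the
# normalized-sum bisector, on hemisphere-aligned SVD plane normals.
quartet_axis_oracle <- function(coord_list) {
  ns <- lapply(coord_list, svd_plane_normal)
  ns <- lapply(ns, function(n) if (sum(n * ns[[1]]) < 0) -n else n)
  bisector_oracle(bisector_oracle(ns[[1]], ns[[2]]),
                  bisector_oracle(ns[[3]], ns[[4]]))
}
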