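# Group frames: composing base Z-axes into pair and quartet frames by
# half-angle (geodesic bisector) rotation association. The combined Z-axis of
# two bases is obtained by rotating the first Z halfway toward the second
# about their mutual perpendicular; quartets associate (1,2) and (3,4) and
# then the two intermediates. The group origin is the arithmetic mean of the
# member origins.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero vector where a direction was expected")
  v / n
}

check_unit <- function(v, name) {
  if (length(v) != 3L || !is.numeric(v)) stop("'", name, "' must be a 3-vector")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6)
    stop("'", name, "' must be unit-norm (within 1e-6)")
  invisible(v)
}

#' Rotation matrix about an arbitrary axis (Rodrigues form)
#'
#' @param axis Unit 3-vector, the fixed axis of rotation.
#' @param angle Rotation angle in radians.
#' @return 3 x 3 proper rotation matrix (orthogonal, det +1) with
#'   `matrix %*% axis == axis`.
#' @export
rodrigues_matrix <- function(axis, angle) {
  check_unit(axis, "axis")
  u <- axis
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * tcrossprod(u)
}

#' Axis and angle between two base Z-axes
#'
#' The rotation carrying `z1` onto `z2`: angle from the (clamped) arc-cosine
#' of the dot product, axis from the normalized cross product, matrix in
#' Rodrigues form. Anti-parallel inputs have no unique axis and are rejected;
#' callers dealing with unoriented plane normals should flip one input into
#' the other's hemisphere first.
#'
#' @param z1,z2 Unit 3-vectors (within 1e-6).
#' @return An object of class `rotation_spec`: list with `axis` (unit
#'   3-vector), `angle` (radians) and `matrix` (3 x 3 rotation). For
#'   (near-)parallel inputs the axis is an arbitrary unit vector and the
#'   matrix is the identity.
#' @export
axis_angle <- function(z1, z2) {
  check_unit(z1, "z1"); check_unit(z2, "z2")
  d <- sum(z1 * z2)
  if (d <= -1 + 1e-9)
    stop("anti-parallel axes: rotation axis is degenerate; ",
         "flip one axis into the other's hemisphere first")
  cr <- c(z1[2] * z2[3] - z1[3] * z2[2],
          z1[3] * z2[1] - z1[1] * z2[3],
          z1[1] * z2[2] - z1[2] * z2[1])
  crn <- sqrt(sum(cr^2))
  # atan2 form of arccos(dot): identical in exact arithmetic, but immune to
  # the O(sqrt(eps)) blow-up of acos near parallel axes
  angle <- atan2(crn, d)
  axis <- if (crn < 1e-9) c(1, 0, 0) else cr / crn
  structure(list(axis = axis, angle = angle,
                 matrix = rodrigues_matrix(axis, angle)),
            class = "rotation_spec")
}

#' Associate two Z-axes into their combined (bisector) Z-axis
#'
#' Rotates `z1` by half the inter-axis angle about the mutual perpendicular,
#' yielding the geodesic bisector: the result makes equal angles with both
#' inputs. Parallel inputs return `z1` unchanged.
#'
#' @inheritParams axis_angle
#' @return Unit 3-vector, the combined Z-axis.
#' @export
associate_axes <- function(z1, z2) {
  aa <- axis_angle(z1, z2)
  if (aa$angle < 1e-12) return(z1)
  as.vector(rodrigues_matrix(aa$axis, aa$angle / 2) %*% z1)
}

new_group_frame <- function(origin, z_axis, member_count) {
  structure(list(member_count = as.integer(member_count),
                 origin = as.vector(origin), z_axis = unit(z_axis)),
            class = "group_frame")
}

#' @export
print.group_frame <- function(x, ...) {
  cat("group_frame (", x$member_count, " bases): origin [",
      paste(sprintf("%.3f", x$origin), collapse = ", "),
      "], Z = [", paste(sprintf("%.4f", x$z_axis), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

# Flip member Z-axes into the hemisphere of the first member. Fitted plane
# normals of an anti-parallel quadruplex anti-align; association is only
# meaningful after orienting them consistently. Near-perpendicular members
# cannot be reconciled and are an error.
orient_axes <- function(zs) {
  ref <- zs[[1]]
  out <- lapply(zs, function(z) {
    d <- sum(z * ref)
    if (abs(d) < 0.1)
      stop("near-perpendicular base Z-axes cannot be associated ",
           "(|dot| < 0.1 after hemisphere alignment)")
    if (d < 0) -z else z
  })
  out
}

#' Quartet reference frame from four base frames
#'
#' Builds the composite G-quartet frame: member Z-axes are first oriented
#' into a common hemisphere, the quartet is split into two pairs, each pair's
#' Z-axes are associated by half-angle rotation, and the two intermediate
#' axes are associated again to give the quartet Z-axis. The quartet origin
#' is the mean of the four base origins.
#'
#' @param frames List of four `base_frame` objects.
#' @param pairing `"sequential"` pairs (1,2) and (3,4); `"diagonal"` pairs
#'   (1,3) and (2,4). For near-parallel members the difference is below a
#'   degree.
#' @return A `group_frame` with `member_count = 4`.
#' @export
quartet_frame <- function(frames, pairing = c("sequential", "diagonal")) {
  pairing <- match.arg(pairing)
  if (length(frames) != 4L)
    stop("'frames' must contain exactly 4 base frames")
  zs <- orient_axes(lapply(frames, `[[`, "z_axis"))
  pr <- if (pairing == "sequential") list(c(1, 2), c(3, 4))
        else list(c(1, 3), c(2, 4))
  za <- associate_axes(zs[[pr[[1]][1]]], zs[[pr[[1]][2]]])
  zb <- associate_axes(zs[[pr[[2]][1]]], zs[[pr[[2]][2]]])
  zq <- associate_axes(za, zb)
  origin <- rowMeans(sapply(frames, `[[`, "origin"))
  new_group_frame(origin, zq, 4L)
}

#' Pair reference frame from two base frames
#'
#' The two-base analogue of [quartet_frame()]: hemisphere-aligned Z-axes are
#' associated by half-angle rotation; the origin is the midpoint of the two
#' base origins. Used for base pairs (e.g. a loop T:A pair) serving as a
#' reference group.
#'
#' @param frames List of two `base_frame` objects.
#' @return A `group_frame` with `member_count = 2`.
#' @export
pair_frame <- function(frames) {
  if (length(frames) != 2L)
    stop("'frames' must contain exactly 2 base frames")
  zs <- orient_axes(lapply(frames, `[[`, "z_axis"))
  z12 <- associate_axes(zs[[1]], zs[[2]])
  origin <- rowMeans(sapply(frames, `[[`, "origin"))
  new_group_frame(origin, z12, 2L)
}

# Build the group frame for 1, 2 or 4 residues of one trajectory frame.
group_frame_for <- function(traj, resnos, frame, pairing = "sequential") {
  bf <- lapply(resnos, fit_residue_frame, traj = traj, frame = frame)
  if (length(bf) == 1L)
    new_group_frame(bf[[1]]$origin, bf[[1]]$z_axis, 1L)
  else if (length(bf) == 2L)
    pair_frame(bf)
  else if (length(bf) == 4L)
    quartet_frame(bf, pairing = pairing)
  else stop("a base group must have 1, 2 or 4 members, got ", length(bf))
}
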