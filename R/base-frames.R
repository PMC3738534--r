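# Base-triad fitting: rigid least-squares superposition of a standard planar
# base onto its observed image, yielding the per-base reference frame
# (origin + orthonormal right-handed axes) that all group-level geometry
# builds on.

# Closed-form rigid least squares (Kabsch). Returns the proper rotation R and
# translation t minimising sum ||R s_i + t - o_i||^2. The smallest singular
# direction's sign is corrected so det(R) = +1 even for planar atom sets,
# which would otherwise invite a reflection.
kabsch <- function(S, O) {
  stopifnot(nrow(S) == nrow(O), ncol(S) == 3L, ncol(O) == 3L)
  cs <- colMeans(S)
  co <- colMeans(O)
  Sc <- sweep(S, 2, cs)
  Oc <- sweep(O, 2, co)
  sv_obs <- svd(Oc)$d
  if (sv_obs[2] < 1e-8 * max(sv_obs[1], 1))
    stop("degenerate (collinear) observed coordinates: cannot fit a frame")
  H <- crossprod(Sc, Oc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- co - as.vector(R %*% cs)
  fitted <- sweep(S %*% t(R), 2, t, "+")
  list(R = R, t = t,
       rmsd = sqrt(mean(rowSums((fitted - O)^2))))
}

#' Fit a base reference frame (base triad)
#'
#' Superposes the standard planar base onto the observed base by rigid
#' (rotation + translation, reflection-free) least squares over the ring
#' heavy atoms. The base triad is the image of the standard frame under the
#' fitted motion: the origin is the image of the standard origin (the ring
#' centroid) and the axes are the images of the standard unit axes, so the
#' Z-axis is perpendicular to the base plane.
#'
#' @param obs_coords Numeric matrix of observed coordinates (Angstrom) with
#'   rownames giving atom names; must contain all ring atoms of `std`
#'   (names matched case-insensitively).
#' @param std A `std_base` from [get_standard_base()].
#' @return An object of class `base_frame`: list with `origin` (3-vector,
#'   Angstrom), unit vectors `x_axis`, `y_axis`, `z_axis` (right-handed,
#'   x cross y = z), `fit_rmsd` (Angstrom) and `base_code`.
#' @examples
#' std <- get_standard_base("G")
#' f <- fit_base_frame(std$coords, std)   # identity fit
#' f$fit_rmsd                              # 0
#' @export
fit_base_frame <- function(obs_coords, std) {
  stopifnot(inherits(std, "std_base"))
  if (is.null(rownames(obs_coords)))
    stop("'obs_coords' must have atom names as rownames")
  nm <- toupper(trimws(rownames(obs_coords)))
  take <- match(std$atom_names, nm)
  if (anyNA(take))
    stop("missing ring atom(s) for base ", std$base_code, ": ",
         paste(std$atom_names[is.na(take)], collapse = ", "))
  O <- obs_coords[take, , drop = FALSE]
  storage.mode(O) <- "double"
  k <- kabsch(std$coords, O)
  structure(list(origin = as.vector(k$t + k$R %*% c(0, 0, 0)),
                 x_axis = k$R[, 1], y_axis = k$R[, 2], z_axis = k$R[, 3],
                 fit_rmsd = k$rmsd, base_code = std$base_code),
            class = "base_frame")
}

#' @export
print.base_frame <- function(x, ...) {
  cat("base_frame (", x$base_code, "): origin [",
      paste(sprintf("%.3f", x$origin), collapse = ", "),
      "], z = [", paste(sprintf("%.4f", x$z_axis), collapse = ", "),
      "], fit RMSD ", sprintf("%.4f", x$fit_rmsd), " A\n", sep = "")
  invisible(x)
}

# Fit the frame of one residue of a trajectory frame.
fit_residue_frame <- function(traj, resno, frame) {
  rc <- residue_ring_coords(traj, resno, frame)
  fit_base_frame(rc$coords, rc$std)
}
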