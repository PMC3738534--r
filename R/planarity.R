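# Quartet planarity: root-mean-square displacement of ring atoms along the
# quartet Z-axis, measured in the quartet's own per-frame reference frame.
# RMSD_Z is zero for a perfectly coplanar quartet and grows with buckling
# and out-of-plane base displacement.

#' Quartet planarity (RMSD along the quartet Z-axis)
#'
#' Each ring atom of the four bases is expressed relative to the quartet
#' origin and projected onto the quartet Z-axis, giving its out-of-plane
#' displacement `z_ij` (base i, atom j). The pooled statistic is
#' `sqrt( sum_ij z_ij^2 / sum_i N_i )` over all ring atoms (36 for a
#' guanine quartet). `normalize = "per_base"` instead averages the four
#' per-base RMSDs `sqrt(mean_j z_ij^2)`.
#'
#' @param base_coords List of 4 matrices of ring-atom coordinates (Angstrom),
#'   one per base.
#' @param frame A `group_frame` built from the same four bases (see
#'   [quartet_frame()]).
#' @param normalize `"pooled"` (default) or `"per_base"`.
#' @return Object of class `planarity`: list with `rmsd_z` (Angstrom),
#'   `per_base_contrib` (4 values, Angstrom^2 x atoms: per-base sums of
#'   squared Z-displacements) and `n_atoms_total`.
#' @export
rmsd_z <- function(base_coords, frame, normalize = c("pooled", "per_base")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(frame, "group_frame"))
  if (!is.list(base_coords) || length(base_coords) != 4L)
    stop("'base_coords' must be a list of 4 ring-atom coordinate matrices")
  if (frame$member_count != 4L)
    stop("'frame' must be a quartet frame (member_count 4), got ",
         frame$member_count)
  zsq <- lapply(base_coords, function(m) {
    stopifnot(is.matrix(m), ncol(m) == 3L)
    (sweep(m, 2, frame$origin) %*% frame$z_axis)^2
  })
  n_i <- vapply(zsq, length, integer(1))
  contrib <- vapply(zsq, sum, numeric(1))
  val <- if (normalize == "pooled") sqrt(sum(contrib) / sum(n_i))
         else mean(sqrt(contrib / n_i))
  structure(list(rmsd_z = val, per_base_contrib = contrib,
                 n_atoms_total = sum(n_i), normalize = normalize),
            class = "planarity")
}

#' @export
print.planarity <- function(x, ...) {
  cat(sprintf("quartet planarity: RMSD_Z = %.4f A (%s over %d atoms)\n",
              x$rmsd_z, x$normalize, x$n_atoms_total))
  invisible(x)
}

#' Per-frame quartet planarity over a trajectory
#'
#' Fits the four base frames, rebuilds the quartet frame in every frame and
#' evaluates [rmsd_z()].
#'
#' @param traj A `g4_trajectory`.
#' @param quartet_sel Residue numbers of the four quartet guanines.
#' @inheritParams rmsd_z
#' @param pairing Quartet pairing scheme, see [quartet_frame()].
#' @return Numeric vector of per-frame RMSD_Z values (Angstrom), with the
#'   per-frame table available via attribute `"series"`.
#' @export
quartet_planarity <- function(traj, quartet_sel, normalize = "pooled",
                              pairing = "sequential") {
  stopifnot(inherits(traj, "g4_trajectory"))
  resnos <- if (inherits(quartet_sel, "g4_selection")) quartet_sel$resno
            else as.integer(quartet_sel)
  if (length(resnos) != 4L) stop("'quartet_sel' must name 4 residues")
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    rc <- lapply(resnos, residue_ring_coords, traj = traj, frame = f)
    bf <- lapply(rc, function(r) fit_base_frame(r$coords, r$std))
    qf <- quartet_frame(bf, pairing = pairing)
    out[f] <- rmsd_z(lapply(rc, `[[`, "coords"), qf,
                     normalize = normalize)$rmsd_z
  }
  attr(out, "series") <- data.frame(
    frame = seq_len(nf), time_ps = (seq_len(nf) - 1) * traj$frame_spacing,
    rmsd_z = as.vector(out))
  out
}

#' Probability distribution of quartet planarity over a trajectory
#'
#' Normalized histogram (probabilities summing to one) of per-frame RMSD_Z,
#' with the mode bin center (the distribution's peak, reflecting the typical
#' quartet distortion) and the standard deviation (its width, reflecting the
#' fluctuation).
#'
#' @inheritParams quartet_planarity
#' @param n_bins Number of histogram bins.
#' @return Object of class `planarity_distribution`: `histogram` data frame
#'   (`bin_center`, `probability`), `mode` (Angstrom), `sd` (Angstrom),
#'   `mean` (Angstrom) and the per-frame `series`.
#' @export
planarity_distribution <- function(traj, quartet_sel, n_bins = 50,
                                   normalize = "pooled",
                                   pairing = "sequential") {
  if (n_frames(traj) < 2L)
    stop("a distribution needs at least 2 frames")
  r <- quartet_planarity(traj, quartet_sel, normalize, pairing)
  series <- attr(r, "series")
  v <- as.vector(r)
  rng <- range(v)
  if (diff(rng) < 1e-12) rng <- rng + c(-5e-4, 5e-4)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  prob <- counts / length(v)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(histogram = data.frame(bin_center = centers,
                                        probability = prob),
                 mode = centers[which.max(prob)],
                 sd = stats::sd(v), mean = mean(v), series = series),
            class = "planarity_distribution")
}

#' @export
print.planarity_distribution <- function(x, ...) {
  cat(sprintf(
    "planarity distribution over %d frames: peak %.3f A, mean %.3f A, width (SD) %.3f A\n",
    nrow(x$series), x$mode, x$mean, x$sd))
  invisible(x)
}
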