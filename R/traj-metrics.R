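# Trajectory-level summaries: pairwise RMSD matrices, RMSD against a
# reference structure (fit on one region, compute on another), and backbone
# torsion rotamer series.

sel_resnos <- function(sel) {
  if (inherits(sel, "g4_selection")) sel else selection(sel)
}

xyz_inds <- function(atom_idx) bio3d::atom2xyz(atom_idx)

traj_xyz <- function(traj) {
  nf <- n_frames(traj)
  matrix(aperm(traj$coords, c(1, 3, 2)), nrow = nf)
}

rmsd_rows <- function(fitted, ref_row, calc_xyz) {
  d <- sweep(fitted[, calc_xyz, drop = FALSE], 2, ref_row[calc_xyz])
  sqrt(rowSums(d^2) / (length(calc_xyz) / 3))
}

#' Pairwise RMSD matrix over trajectory frames
#'
#' For every retained frame pair, superposes the frames by rigid least
#' squares over `fit_sel` and computes the RMSD over `calc_sel`. Fitting on
#' the rigid G-stem while computing over all atoms (the defaults are the
#' caller's selections) isolates loop motion. Note that per-pair superposed
#' RMSD is not a metric (no triangle inequality).
#'
#' @param traj A `g4_trajectory`.
#' @param fit_sel Selection (residues, or [selection()]) to superpose on.
#' @param calc_sel Selection to compute RMSD over; defaults to `fit_sel`.
#' @param stride Keep every `stride`-th frame (>= 1).
#' @return Object of class `rmsd_matrix`: `matrix` (symmetric, zero
#'   diagonal, Angstrom) with retained frame indices as dimnames, and
#'   `frames`, `stride`.
#' @export
pairwise_rmsd <- function(traj, fit_sel, calc_sel = fit_sel, stride = 1L) {
  stopifnot(inherits(traj, "g4_trajectory"), stride >= 1L)
  fit_idx <- select_atoms(traj, sel_resnos(fit_sel))
  calc_idx <- select_atoms(traj, sel_resnos(calc_sel))
  frames <- seq.int(1L, n_frames(traj), by = stride)
  xyz <- traj_xyz(traj)
  fx <- xyz_inds(fit_idx); cx <- xyz_inds(calc_idx)
  n <- length(frames)
  M <- matrix(0, n, n, dimnames = list(frames, frames))
  for (i in seq_len(n)) {
    # identical frames make bio3d's quaternion eigenvalues dip below zero
    # by rounding; the resulting sqrt warning is benign
    fitted <- suppressWarnings(
      bio3d::fit.xyz(fixed = xyz[frames[i], ],
                     mobile = xyz[frames, , drop = FALSE],
                     fixed.inds = fx, mobile.inds = fx))
    M[i, ] <- rmsd_rows(fitted, xyz[frames[i], ], cx)
  }
  M <- (M + t(M)) / 2   # de-noise numeric asymmetry of per-pair fits
  diag(M) <- 0
  structure(list(matrix = M, frames = frames, stride = as.integer(stride)),
            class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat("pairwise RMSD matrix:", nrow(x$matrix), "frames (stride",
      x$stride, "), mean off-diagonal",
      sprintf("%.3f A\n", mean(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

#' Write an RMSD matrix as plain text
#'
#' Square whitespace-separated matrix with a frame-index header row and
#' column.
#'
#' @param x An `rmsd_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmsd_matrix <- function(x, path) {
  stopifnot(inherits(x, "rmsd_matrix"))
  df <- data.frame(frame = x$frames, round(x$matrix, 4),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-frame RMSD to a reference structure
#'
#' Superposes every frame on the reference over `fit_sel` and computes the
#' RMSD over `calc_sel`, supporting the fit-on-stem / compute-on-loop
#' pattern used to monitor loop departure from an experimental structure.
#'
#' @param traj A `g4_trajectory`.
#' @param ref_coords Reference coordinates: an `n_atoms x 3` matrix over the
#'   same roster as `traj` (e.g. `frame 1` coordinates, or another
#'   structure with identical roster).
#' @param fit_sel,calc_sel Selections as in [pairwise_rmsd()].
#' @return Numeric vector of per-frame RMSD (Angstrom) with a `series`
#'   data-frame attribute.
#' @export
rmsd_to_reference <- function(traj, ref_coords, fit_sel,
                              calc_sel = fit_sel) {
  stopifnot(inherits(traj, "g4_trajectory"))
  if (!is.matrix(ref_coords) || nrow(ref_coords) != nrow(traj$atoms) ||
      ncol(ref_coords) != 3L)
    stop("'ref_coords' roster mismatch: need an ", nrow(traj$atoms),
         " x 3 matrix over the trajectory's atom roster")
  fit_idx <- select_atoms(traj, sel_resnos(fit_sel))
  calc_idx <- select_atoms(traj, sel_resnos(calc_sel))
  xyz <- traj_xyz(traj)
  ref <- as.vector(t(ref_coords))
  fx <- xyz_inds(fit_idx); cx <- xyz_inds(calc_idx)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = ref, mobile = xyz,
                   fixed.inds = fx, mobile.inds = fx))
  out <- rmsd_rows(fitted, ref, cx)
  attr(out, "series") <- data.frame(
    frame = seq_len(n_frames(traj)),
    time_ps = (seq_len(n_frames(traj)) - 1) * traj$frame_spacing,
    rmsd = as.vector(out))
  out
}

# torsion atom definitions: list of (residue offset, atom name)
.torsion_defs <- list(
  alpha   = list(c(-1L, "O3'"), c(0L, "P"), c(0L, "O5'"), c(0L, "C5'")),
  beta    = list(c(0L, "P"), c(0L, "O5'"), c(0L, "C5'"), c(0L, "C4'")),
  gamma   = list(c(0L, "O5'"), c(0L, "C5'"), c(0L, "C4'"), c(0L, "C3'")),
  delta   = list(c(0L, "C5'"), c(0L, "C4'"), c(0L, "C3'"), c(0L, "O3'")),
  epsilon = list(c(0L, "C4'"), c(0L, "C3'"), c(0L, "O3'"), c(1L, "P")),
  zeta    = list(c(0L, "C3'"), c(0L, "O3'"), c(1L, "P"), c(1L, "O5'"))
)

#' Backbone/glycosidic torsion angle series with rotamer labels
#'
#' Computes one named nucleic-acid torsion per frame (standard backbone
#' definitions; `alpha` = O3'(i-1)-P-O5'-C5'; `chi` uses O4'-C1'-N9-C4 for
#' purines and O4'-C1'-N1-C2 for pyrimidines), wrapped to \[0, 360)
#' degrees, and labels each frame's rotamer well: `g+` = \[0, 120),
#' `t` = \[120, 240), `g-` = \[240, 360).
#'
#' @param traj A `g4_trajectory`.
#' @param resno Residue number.
#' @param torsion One of `"alpha"`, `"beta"`, `"gamma"`, `"delta"`,
#'   `"epsilon"`, `"zeta"`, `"chi"`.
#' @return Object of class `torsion_series`: `series` data frame (`frame`,
#'   `time_ps`, `angle`, `rotamer`), `torsion`, `resno`.
#' @export
torsion_series <- function(traj, resno,
                           torsion = c("alpha", "beta", "gamma", "delta",
                                       "epsilon", "zeta", "chi")) {
  stopifnot(inherits(traj, "g4_trajectory"))
  torsion <- match.arg(torsion)
  norm_name <- function(x) gsub("\\*", "'", toupper(x))
  names_norm <- norm_name(traj$atoms$name)
  if (torsion == "chi") {
    i <- which(traj$atoms$resno == resno)
    if (!length(i)) stop("residue ", resno, " not found")
    code <- base_code_from_resname(traj$atoms$resname[i[1]])
    def <- if (!is.na(code) && code %in% c("A", "G"))
      list(c(0L, "O4'"), c(0L, "C1'"), c(0L, "N9"), c(0L, "C4"))
    else
      list(c(0L, "O4'"), c(0L, "C1'"), c(0L, "N1"), c(0L, "C2"))
  } else def <- .torsion_defs[[torsion]]
  idx <- vapply(def, function(d) {
    r <- resno + as.integer(d[1])
    i <- which(traj$atoms$resno == r & names_norm == d[2])
    if (length(i) != 1L)
      stop("torsion ", torsion, " of residue ", resno, ": atom ", d[2],
           " of residue ", r, if (length(i)) " is ambiguous" else " is absent")
    i
  }, integer(1))
  xyz <- traj_xyz(traj)
  cols <- as.vector(vapply(idx, xyz_inds, numeric(3)))
  ang <- apply(xyz[, cols, drop = FALSE], 1,
               function(v) bio3d::torsion.xyz(v, atm.inc = 4))
  ang <- ang %% 360
  rot <- cut(ang, breaks = c(0, 120, 240, 360), right = FALSE,
             labels = c("g+", "t", "g-"))
  structure(list(series = data.frame(
    frame = seq_len(n_frames(traj)),
    time_ps = (seq_len(n_frames(traj)) - 1) * traj$frame_spacing,
    angle = as.vector(ang), rotamer = as.character(rot)),
    torsion = torsion, resno = resno),
    class = "torsion_series")
}

#' @export
print.torsion_series <- function(x, ...) {
  tab <- table(x$series$rotamer)
  cat(sprintf("torsion %s of residue %d over %d frames: ", x$torsion,
              x$resno, nrow(x$series)),
      paste(sprintf("%s %.0f%%", names(tab),
                    100 * as.vector(tab) / nrow(x$series)),
            collapse = ", "), "\n")
  invisible(x)
}
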