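# Trajectory container and atom selection.
#
# A g4_trajectory holds a fixed atom roster and per-frame coordinates.
# Coordinates are stored as an [n_frames, n_atoms, 3] array in Angstrom;
# residue numbering is 1-based as in PDB. Frames are addressed 1-based.

new_trajectory <- function(atoms, coords, frame_spacing = 5) {
  stopifnot(is.data.frame(atoms), length(dim(coords)) == 3L,
            dim(coords)[2] == nrow(atoms), dim(coords)[3] == 3L)
  if (dim(coords)[1] < 1L) stop("a trajectory needs at least one frame")
  if (!is.numeric(frame_spacing) || frame_spacing <= 0)
    stop("'frame_spacing' must be > 0 (ps)")
  structure(list(atoms = atoms, coords = coords,
                 frame_spacing = frame_spacing),
            class = "g4_trajectory")
}

#' Read a (multi-model) PDB structure as a trajectory
#'
#' Parses a PDB file into a trajectory object. `MODEL`/`ENDMDL` records
#' delimit frames; a file without `MODEL` records is a single-frame
#' trajectory. Every model must carry an identical atom roster (same count
#' and order); a mismatch is a hard error naming the first offending frame.
#' Hydrogens are retained if present.
#'
#' @param path Path to a PDB file.
#' @param frame_spacing Time between stored frames in ps. Defaults to 5 ps,
#'   a common trajectory-writing interval for production MD.
#' @return A `g4_trajectory`: list with `atoms` (data frame: `name`, `resno`,
#'   `resname`, `chain`), `coords` (`n_frames x n_atoms x 3` array, Angstrom)
#'   and `frame_spacing` (ps).
#' @seealso [select_atoms()], [write_trajectory_pdb()]
#' @export
read_structure <- function(path, frame_spacing = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atom_lines)) stop("no ATOM/HETATM records in ", path)
  # roster pre-check across MODEL blocks
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_id <- findInterval(seq_along(lines), model_starts)
    counts <- tapply(atom_lines[model_id > 0], model_id[model_id > 0], sum)
    bad <- which(counts != counts[1])
    if (length(bad))
      stop("inconsistent atom roster across models: frame ", bad[1],
           " has ", counts[bad[1]], " atoms, frame 1 has ", counts[1])
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_frames <- nrow(pdb$xyz)
  n_atoms <- nrow(pdb$atom)
  coords <- aperm(array(t(pdb$xyz), dim = c(3, n_atoms, n_frames)),
                  c(3, 2, 1))
  atoms <- data.frame(name = trimws(pdb$atom$elety),
                      resno = pdb$atom$resno,
                      resname = trimws(pdb$atom$resid),
                      chain = ifelse(is.na(pdb$atom$chain), "A",
                                     pdb$atom$chain),
                      stringsAsFactors = FALSE)
  new_trajectory(atoms, coords, frame_spacing)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `g4_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "g4_trajectory"))
  nf <- n_frames(traj)
  na <- nrow(traj$atoms)
  xyz <- matrix(aperm(traj$coords, c(1, 3, 2)), nrow = nf)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$atoms$resno,
                   resid = traj$atoms$resname,
                   elety = traj$atoms$name,
                   chain = traj$atoms$chain)
  invisible(path)
}

#' @export
print.g4_trajectory <- function(x, ...) {
  cat("g4_trajectory:", n_frames(x), "frame(s),", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues; frame spacing",
      x$frame_spacing, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `g4_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# one frame as an n_atoms x 3 matrix
frame_coords <- function(traj, frame) {
  m <- traj$coords[frame, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Atom selection by residue and atom name
#'
#' Constructs a selection (residue indices plus an optional atom-name
#' filter) and resolves it against a trajectory's roster. Resolution to
#' zero atoms is always an error, never a silent empty result.
#'
#' @param resno Integer vector of 1-based residue numbers.
#' @param atoms Optional character vector of atom names (e.g. ring atoms);
#'   `NULL` selects all atoms of the residues.
#' @return For `selection()`, an object of class `g4_selection`.
#' @examples
#' sel <- selection(2:4)
#' @export
selection <- function(resno, atoms = NULL) {
  stopifnot(is.numeric(resno), length(resno) >= 1L)
  structure(list(resno = as.integer(resno),
                 atoms = if (!is.null(atoms)) toupper(atoms)),
            class = "g4_selection")
}

#' @rdname selection
#' @param traj A `g4_trajectory`.
#' @param sel A `g4_selection` (or bare residue-number vector).
#' @return For `select_atoms()`, an integer vector of atom indices in roster
#'   order (residues concatenated in the order given).
#' @export
select_atoms <- function(traj, sel) {
  stopifnot(inherits(traj, "g4_trajectory"))
  if (!inherits(sel, "g4_selection")) sel <- selection(sel)
  idx <- unlist(lapply(sel$resno, function(r) {
    i <- which(traj$atoms$resno == r)
    if (!is.null(sel$atoms))
      i <- i[toupper(traj$atoms$name[i]) %in% sel$atoms]
    i
  }))
  if (length(idx) == 0L)
    stop("selection matched no atoms (residues ",
         paste(sel$resno, collapse = ","),
         if (!is.null(sel$atoms)) paste0("; atoms ",
                                         paste(sel$atoms, collapse = ",")),
         ")")
  as.integer(idx)
}

# Ring-atom coordinates of one residue in one frame, as a named matrix
# matched to the residue's standard base. Errors if the resname is not a
# recognised DNA base or ring atoms are missing.
residue_ring_coords <- function(traj, resno, frame) {
  i <- which(traj$atoms$resno == resno)
  if (length(i) == 0L) stop("residue ", resno, " not found")
  code <- base_code_from_resname(traj$atoms$resname[i[1]])
  if (is.na(code))
    stop("residue ", resno, " (", traj$atoms$resname[i[1]],
         ") is not a recognised DNA base")
  std <- get_standard_base(code)
  nm <- toupper(traj$atoms$name[i])
  take <- match(std$atom_names, nm)
  if (anyNA(take))
    stop("residue ", resno, " is missing ring atom(s): ",
         paste(std$atom_names[is.na(take)], collapse = ", "))
  fc <- frame_coords(traj, frame)[i[take], , drop = FALSE]
  rownames(fc) <- std$atom_names
  list(coords = fc, std = std, code = code)
}
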