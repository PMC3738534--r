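# Standard planar reference geometries for the four DNA bases.
#
# Ring heavy-atom coordinates (Angstrom) in the standard frame: the base lies
# exactly in the XY plane (z = 0) with the origin at the ring-atom centroid.
# Values derive from ideal component geometries projected onto their best-fit
# plane; only the ring system is kept (9 atoms for purines, 6 for pyrimidines)
# because exocyclic substituents bias plane fitting.

.purine_ring <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
.pyrimidine_ring <- c("N1", "C2", "N3", "C4", "C5", "C6")

.std_base_xy <- list(
  A = matrix(c(
    -2.0819,  0.6430,
    -2.0397, -0.6756,
    -0.9080, -1.3471,
     0.2584, -0.7093,
     0.2669,  0.6960,
    -0.9672,  1.3669,
     1.5642,  1.0858,
     2.3327,  0.0358,
     1.5745, -1.0955), ncol = 2, byrow = TRUE),
  G = matrix(c(
    -2.0990,  0.6620,
    -2.0501, -0.6992,
    -0.9100, -1.3527,
     0.2603, -0.7045,
     0.2754,  0.6954,
    -0.9589,  1.3863,
     1.5742,  1.0829,
     2.3378,  0.0288,
     1.5704, -1.0988), ncol = 2, byrow = TRUE),
  C = matrix(c(
    -0.6527,  1.1781,
     0.6913,  1.1448,
     1.3504, -0.0128,
     0.6952, -1.1654,
    -0.7145, -1.1644,
    -1.3698,  0.0197), ncol = 2, byrow = TRUE),
  T = matrix(c(
    -0.9925, -0.9763,
    -1.3916,  0.3774,
    -0.3437,  1.3038,
     1.0150,  1.0264,
     1.3571, -0.4209,
     0.3557, -1.3105), ncol = 2, byrow = TRUE)
)

#' Standard reference base geometry
#'
#' Returns the embedded standard geometry of a DNA base: the ring heavy atoms
#' (9 for the purines A and G, 6 for the pyrimidines C and T) with coordinates
#' in the standard frame, where the base plane is the XY plane (all z exactly 0)
#' and the origin is the ring-atom centroid. These are the fixed targets of the
#' least-squares base fitting step (see [fit_base_frame()]).
#'
#' @param base_code Single letter, one of `"A"`, `"C"`, `"G"`, `"T"`.
#'   Lower case is accepted.
#' @return An object of class `std_base`: a list with `base_code`,
#'   `atom_names` (ordered ring atom names) and `coords` (n x 3 matrix,
#'   Angstrom, rownames = atom names, third column identically zero).
#' @examples
#' g <- get_standard_base("G")
#' nrow(g$coords)        # 9 ring atoms
#' all(g$coords[, 3] == 0)
#' @export
get_standard_base <- function(base_code) {
  if (!is.character(base_code) || length(base_code) != 1L)
    stop("'base_code' must be a single character")
  code <- toupper(base_code)
  if (!code %in% names(.std_base_xy))
    stop("unsupported base code '", base_code,
         "': supported bases are A, C, G, T")
  xy <- .std_base_xy[[code]]
  atoms <- if (code %in% c("A", "G")) .purine_ring else .pyrimidine_ring
  coords <- cbind(xy, 0)
  dimnames(coords) <- list(atoms, c("x", "y", "z"))
  structure(list(base_code = code, atom_names = atoms, coords = coords),
            class = "std_base")
}

#' @export
print.std_base <- function(x, ...) {
  cat("Standard base", x$base_code, "-", length(x$atom_names),
      "ring atoms, planar (z = 0)\n")
  invisible(x)
}

# Map a PDB residue name to a base code, or NA.
base_code_from_resname <- function(resname) {
  code <- c(DA = "A", A = "A", ADE = "A",
            DG = "G", G = "G", GUA = "G",
            DC = "C", C = "C", CYT = "C",
            DT = "T", T = "T", THY = "T")[toupper(trimws(resname))]
  unname(code)
}
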