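# Synthetic quadruplex structures and trajectories with known ground truth.
#
# The generator builds idealized stacked G-quartet layers from the standard
# planar guanine, places loop bases at prescribed poses (Z-distance, tilt,
# in-plane offset) relative to an anchor quartet, and evolves the structure
# over frames with per-base rigid-body noise and an optional two-state
# Markov conformational switch of one loop base. Every nominal pose written
# by the generator is recovered exactly by the analysis operators on the
# noiseless structure, which is what makes it a trustworthy test fixture.

#' Specification of a synthetic quadruplex trajectory
#'
#' @param n_layers Number of stacked G-quartet layers.
#' @param rise Vertical spacing between layers, Angstrom (default 3.3, the
#'   typical quartet stacking rise).
#' @param twist Helical twist between successive layers, degrees (default 30).
#' @param quartet_radius Distance from the quartet center to each base
#'   origin, Angstrom (default 5.4).
#' @param loop_bases List of loop-base poses, each
#'   `list(base =, d_z =, tilt =, offset =, anchor =)`: base code, Z-distance
#'   (Angstrom) from the anchor layer along the combined axis, plane tilt
#'   (degrees), in-plane offset (Angstrom), and the anchor layer index
#'   (anchor 1 places the base below the stem, any other anchor above it).
#' @param noise_t Per-base rigid-body translation noise SD per coordinate,
#'   Angstrom.
#' @param noise_r Per-base rigid-body rotation noise SD, degrees (random
#'   axis through the base center).
#' @param markov Optional two-state conformational switch for one loop base:
#'   `list(p_leave =, p_enter =, alt_pose = list(d_z =, tilt =, offset =),
#'   base =)` with `base` indexing into `loop_bases`. The chain starts in
#'   its stationary distribution; the stationary stacked probability is
#'   `p_enter / (p_leave + p_enter)`.
#' @param n_frames Number of frames.
#' @param frame_spacing Frame spacing, ps.
#' @param seed Integer seed fixing the full output bit-for-bit.
#' @param per_atom_noise Optional per-atom Gaussian noise SD (Angstrom) for
#'   stress-testing the base fitter; default 0 keeps bases internally rigid.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_layers = 3, rise = 3.3, twist = 30,
                           quartet_radius = 5.4, loop_bases = list(),
                           noise_t = 0, noise_r = 0, markov = NULL,
                           n_frames = 1, frame_spacing = 5, seed = 1,
                           per_atom_noise = 0) {
  stopifnot(n_layers >= 1, rise > 0, quartet_radius > 2, n_frames >= 1,
            frame_spacing > 0, noise_t >= 0, noise_r >= 0,
            per_atom_noise >= 0)
  if (!is.null(markov)) {
    stopifnot(all(c("p_leave", "p_enter", "alt_pose", "base") %in%
                    names(markov)),
              markov$p_leave >= 0, markov$p_leave <= 1,
              markov$p_enter >= 0, markov$p_enter <= 1,
              markov$base >= 1, markov$base <= length(loop_bases))
  }
  lb <- lapply(loop_bases, function(b) {
    b <- utils::modifyList(list(base = "A", d_z = 3.4, tilt = 0,
                                offset = 0, anchor = 1L), b)
    b$anchor <- as.integer(b$anchor)
    stopifnot(b$d_z > 0, b$anchor >= 1, b$anchor <= n_layers)
    b
  })
  structure(list(n_layers = as.integer(n_layers), rise = rise,
                 twist = twist, quartet_radius = quartet_radius,
                 loop_bases = lb, noise_t = noise_t, noise_r = noise_r,
                 markov = markov, n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing, seed = as.integer(seed),
                 per_atom_noise = per_atom_noise),
            class = "synthetic_spec")
}

rot_z <- function(deg) rodrigues_matrix(c(0, 0, 1), deg * pi / 180)
rot_y <- function(deg) rodrigues_matrix(c(0, 1, 0), deg * pi / 180)

#' Build an idealized G-quartet
#'
#' Places four standard guanines at 90-degree increments about the Z-axis,
#' base origins at the given radius, coplanar at tilt 0. A non-zero tilt
#' rotates each base about its local tangential axis in a 4-fold symmetric
#' pattern (tilting the base plane toward the quartet axis), which leaves
#' the quartet Z-axis at (0,0,1) by symmetry while making the quartet
#' non-planar.
#'
#' @param radius Center-to-base-origin distance, Angstrom (> 2).
#' @param tilt Per-base tilt toward the axis, degrees.
#' @return List of four base records `list(base = "G", coords = 9 x 3
#'   matrix)` (ring atoms, rownames set).
#' @export
build_quartet <- function(radius = 5.4, tilt = 0) {
  stopifnot(radius > 2)
  std <- get_standard_base("G")
  lapply(0:3, function(k) {
    theta <- 90 * k
    center <- radius * c(cos(theta * pi / 180), sin(theta * pi / 180), 0)
    tangent <- c(-sin(theta * pi / 180), cos(theta * pi / 180), 0)
    R <- rodrigues_matrix(tangent, tilt * pi / 180) %*% rot_z(theta)
    coords <- sweep(std$coords %*% t(R), 2, center, "+")
    rownames(coords) <- std$atom_names
    list(base = "G", coords = coords)
  })
}

# Place one loop base at a nominal pose relative to an anchor group frame
# (origin o_q, axis z_q assumed (0,0,1) in construction space). The pose is
# constructed so the analyzers recover it exactly: the base plane is tilted
# by `tilt` about the y-axis, and the base center sits at
# o_q + s*d_z*z_bisector + offset*y, with z_bisector the half-angle
# combination of the quartet and base normals; s = -1 places it below.
place_loop_base <- function(base_code, pose, o_q, side) {
  std <- get_standard_base(base_code)
  R <- rot_y(side * pose$tilt)
  z_base <- as.vector(R %*% c(0, 0, 1))
  z_bis <- associate_axes(c(0, 0, 1), z_base)
  center <- o_q + side * pose$d_z * z_bis + pose$offset * c(0, 1, 0)
  coords <- sweep(std$coords %*% t(R), 2, center, "+")
  rownames(coords) <- std$atom_names
  list(base = base_code, coords = coords)
}

#' Build a single-frame idealized quadruplex
#'
#' Stacks `n_layers` quartets at the specified rise and twist and places the
#' loop bases of `spec` at their nominal poses. Deterministic; atoms of
#' different residues closer than 1 Angstrom are a construction error.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `trajectory` (single-frame `g4_trajectory`) and
#'   `ground_truth` (data frame of nominal loop poses: `resno`, `base`,
#'   `d_z`, `tilt`, `offset`, `anchor`).
#' @export
build_quadruplex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bases <- list()
  for (l in seq_len(spec$n_layers)) {
    q <- build_quartet(spec$quartet_radius, 0)
    Rz <- rot_z((l - 1) * spec$twist)
    shift <- c(0, 0, (l - 1) * spec$rise)
    for (b in q) {
      b$coords <- sweep(b$coords %*% t(Rz), 2, shift, "+")
      bases[[length(bases) + 1L]] <- b
    }
  }
  gt <- NULL
  for (lb in spec$loop_bases) {
    o_q <- c(0, 0, (lb$anchor - 1) * spec$rise)
    side <- if (lb$anchor == 1L) -1 else 1
    bases[[length(bases) + 1L]] <- place_loop_base(lb$base, lb, o_q, side)
    gt <- rbind(gt, data.frame(resno = length(bases), base = lb$base,
                               d_z = lb$d_z, tilt = lb$tilt,
                               offset = lb$offset, anchor = lb$anchor))
  }
  atoms <- do.call(rbind, lapply(seq_along(bases), function(i) {
    data.frame(name = rownames(bases[[i]]$coords),
               resno = i,
               resname = paste0("D", bases[[i]]$base),
               chain = "A", stringsAsFactors = FALSE)
  }))
  coords <- do.call(rbind, lapply(bases, `[[`, "coords"))
  # clash check between residues
  dm <- as.matrix(stats::dist(coords))
  same_res <- outer(atoms$resno, atoms$resno, "==")
  if (any(dm[!same_res] < 1))
    stop("construction error: atoms of different residues closer than 1 A")
  arr <- array(0, dim = c(1, nrow(coords), 3))
  arr[1, , ] <- coords
  list(trajectory = new_trajectory(atoms, arr, spec$frame_spacing),
       ground_truth = gt)
}

#' Simulate a two-state Markov chain
#'
#' States 1 (e.g. stacked) and 2 (unstacked); per-step switch probabilities
#' `p_leave` (1 to 2) and `p_enter` (2 to 1). The chain starts in its
#' stationary distribution, whose state-1 probability is
#' `p_enter / (p_leave + p_enter)`. Uses the current RNG state.
#'
#' @param n Number of steps.
#' @param p_leave,p_enter Transition probabilities in \[0, 1\].
#' @return Integer vector of states (1/2) of length `n`.
#' @export
markov_states <- function(n, p_leave, p_enter) {
  stopifnot(n >= 1, p_leave >= 0, p_leave <= 1, p_enter >= 0, p_enter <= 1)
  p_stat <- if (p_leave + p_enter > 0) p_enter / (p_leave + p_enter) else 1
  s <- integer(n)
  s[1] <- if (stats::runif(1) < p_stat) 1L else 2L
  if (n > 1) for (i in 2:n) {
    u <- stats::runif(1)
    s[i] <- if (s[i - 1] == 1L) {
      if (u < p_leave) 2L else 1L
    } else {
      if (u < p_enter) 1L else 2L
    }
  }
  s
}

random_rotation_noise <- function(sd_deg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rodrigues_matrix(ax, stats::rnorm(1, 0, sd_deg * pi / 180))
}

#' Simulate a synthetic quadruplex trajectory
#'
#' Per frame: (1) if a Markov switch is configured, advance the two-state
#' chain and place the switching loop base at its nominal (state 1) or
#' alternate (state 2) pose; (2) perturb every base by an independent
#' rigid-body motion (translation SD `noise_t` per coordinate, rotation SD
#' `noise_r` about the base center); (3) record the frame. Fully
#' deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param path Optional path; when given, the trajectory is also written as
#'   a multi-model PDB.
#' @return List with `trajectory` (`g4_trajectory`), `state` (per-frame
#'   Markov state, all 1 when no switch is configured), `ground_truth`
#'   (nominal poses, plus `stationary_stacked` when a switch is configured).
#' @export
simulate_trajectory <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  base0 <- build_quadruplex(spec)
  traj0 <- base0$trajectory
  n_atoms <- nrow(traj0$atoms)
  resnos <- unique(traj0$atoms$resno)
  nominal <- frame_coords(traj0, 1)

  alt_coords <- NULL
  switch_res <- NULL
  if (!is.null(spec$markov)) {
    lb <- spec$loop_bases[[spec$markov$base]]
    switch_res <- spec$n_layers * 4L + spec$markov$base
    alt <- utils::modifyList(lb, spec$markov$alt_pose)
    o_q <- c(0, 0, (lb$anchor - 1) * spec$rise)
    side <- if (lb$anchor == 1L) -1 else 1
    alt_coords <- place_loop_base(lb$base, alt, o_q, side)$coords
  }

  state <- if (!is.null(spec$markov))
    markov_states(spec$n_frames, spec$markov$p_leave, spec$markov$p_enter)
  else rep(1L, spec$n_frames)

  coords <- array(0, dim = c(spec$n_frames, n_atoms, 3))
  res_idx <- lapply(resnos, function(r) which(traj0$atoms$resno == r))
  for (f in seq_len(spec$n_frames)) {
    fc <- nominal
    if (!is.null(switch_res) && state[f] == 2L)
      fc[res_idx[[switch_res]], ] <- alt_coords
    for (ri in res_idx) {
      m <- fc[ri, , drop = FALSE]
      if (spec$noise_r > 0 || spec$noise_t > 0) {
        ctr <- colMeans(m)
        R <- if (spec$noise_r > 0) random_rotation_noise(spec$noise_r)
             else diag(3)
        shift <- if (spec$noise_t > 0) stats::rnorm(3, 0, spec$noise_t)
                 else c(0, 0, 0)
        m <- sweep(sweep(m, 2, ctr) %*% t(R), 2, ctr + shift, "+")
      }
      if (spec$per_atom_noise > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, spec$per_atom_noise),
                        ncol = 3)
      fc[ri, ] <- m
    }
    coords[f, , ] <- fc
  }
  traj <- new_trajectory(traj0$atoms, coords, spec$frame_spacing)
  gt <- base0$ground_truth
  out <- list(trajectory = traj, state = state,
              ground_truth = list(
                poses = gt,
                stationary_stacked = if (!is.null(spec$markov))
                  spec$markov$p_enter /
                    (spec$markov$p_leave + spec$markov$p_enter)))
  if (!is.null(path)) write_trajectory_pdb(traj, path)
  out
}

#' Synthetic donor-hydrogen-acceptor distance series
#'
#' Minimal 3-atom fixture for hydrogen-bond statistics: donor (N3) and
#' hydrogen (H3) in residue 1, acceptor (O4) in residue 2, collinear so the
#' D-H...A angle is always 180 degrees. The donor--acceptor distance follows
#' a bonded/unbonded schedule with optional Gaussian jitter; the schedule is
#' the ground-truth bonded mask.
#'
#' @param schedule Logical vector: ground-truth bonded state per frame.
#' @param bonded_d,unbonded_d Donor--acceptor distance levels, Angstrom;
#'   must straddle the 3.5 Angstrom cutoff.
#' @param jitter Gaussian SD added to the distance, Angstrom.
#' @param frame_spacing Frame spacing, ps.
#' @param seed Integer seed (jitter only).
#' @return List with `trajectory` (`g4_trajectory`) and `mask` (the
#'   ground-truth logical schedule).
#' @export
synth_hbond_series <- function(schedule, bonded_d = 2.9, unbonded_d = 4.2,
                               jitter = 0, frame_spacing = 5, seed = 1) {
  stopifnot(is.logical(schedule), length(schedule) >= 1,
            bonded_d < 3.5, unbonded_d > 3.5, jitter >= 0)
  set.seed(as.integer(seed))
  n <- length(schedule)
  d <- ifelse(schedule, bonded_d, unbonded_d)
  if (jitter > 0) d <- d + stats::rnorm(n, 0, jitter)
  atoms <- data.frame(name = c("N3", "H3", "O4"),
                      resno = c(1L, 1L, 2L),
                      resname = c("DT", "DT", "DA"),
                      chain = "A", stringsAsFactors = FALSE)
  coords <- array(0, dim = c(n, 3, 3))
  coords[, 2, 1] <- 1          # hydrogen at (1,0,0)
  coords[, 3, 1] <- d          # acceptor at (d,0,0)
  list(trajectory = new_trajectory(atoms, coords, frame_spacing),
       mask = schedule)
}
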