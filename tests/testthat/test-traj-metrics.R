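test_that("identical frames give an all-zero pairwise matrix", {
  st <- simulate_trajectory(synthetic_spec(n_layers = 2, n_frames = 6,
                                           seed = 71))
  pm <- pairwise_rmsd(st$trajectory, 1:8)
  expect_lt(max(abs(pm$matrix)), 1e-6)
})

test_that("pairwise matrices are symmetric with zero diagonal", {
  st <- simulate_trajectory(synthetic_spec(n_layers = 2, noise_t = 0.2,
                                           n_frames = 20, seed = 72))
  pm <- pairwise_rmsd(st$trajectory, 1:8)
  expect_identical(pm$matrix, t(pm$matrix))
  expect_identical(diag(pm$matrix), stats::setNames(rep(0, 20),
                                                    rownames(pm$matrix)))
  expect_true(all(pm$matrix >= 0))
})

test_that("a mid-trajectory conformational switch shows block structure", {
  sp <- synthetic_spec(
    n_layers = 1,
    loop_bases = list(list(base = "A", d_z = 3.4, tilt = 10, offset = 0.5,
                           anchor = 1)),
    markov = list(p_leave = 0, p_enter = 0,
                  alt_pose = list(d_z = 7, tilt = 60, offset = 3), base = 1),
    noise_t = 0.1, n_frames = 40, seed = 73)
  st <- simulate_trajectory(sp)
  # impose a deterministic one-switch state path: rebuild coordinates by
  # concatenating two constant-state runs from the same generator
  sp_a <- sp; sp_a$markov <- NULL
  a <- simulate_trajectory(sp_a)
  sp_b <- sp_a
  sp_b$loop_bases[[1]] <- utils::modifyList(sp_b$loop_bases[[1]],
                                            list(d_z = 7, tilt = 60,
                                                 offset = 3))
  sp_b$seed <- 74L
  b <- simulate_trajectory(sp_b)
  stopifnot(identical(a$trajectory$atoms$name, b$trajectory$atoms$name))
  coords <- array(0, dim = c(40, nrow(a$trajectory$atoms), 3))
  coords[1:20, , ] <- a$trajectory$coords[1:20, , ]
  coords[21:40, , ] <- b$trajectory$coords[1:20, , ]
  tr <- g4geom:::new_trajectory(a$trajectory$atoms, coords, 5)
  pm <- pairwise_rmsd(tr, fit_sel = 1:4, calc_sel = 1:5)
  w <- c(pm$matrix[1:20, 1:20][upper.tri(diag(20))],
         pm$matrix[21:40, 21:40][upper.tri(diag(20))])
  b_ <- pm$matrix[1:20, 21:40]
  expect_lt(mean(w), mean(b_))
})

test_that("stride submatrices and superposition bounds hold", {
  st <- simulate_trajectory(synthetic_spec(n_layers = 2, noise_t = 0.25,
                                           n_frames = 16, seed = 75))
  p1 <- pairwise_rmsd(st$trajectory, 1:8)
  p3 <- pairwise_rmsd(st$trajectory, 1:8, stride = 3)
  keep <- as.character(seq(1, 16, by = 3))
  expect_equal(p3$matrix, p1$matrix[keep, keep], tolerance = 1e-9)
  # superposed RMSD never exceeds the unsuperposed one
  xyz <- g4geom:::traj_xyz(st$trajectory)
  idx <- g4geom:::xyz_inds(select_atoms(st$trajectory, selection(1:8)))
  for (i in 1:8) for (j in 1:8) {
    raw <- sqrt(mean(colSums(
      (matrix(xyz[i, idx], nrow = 3) - matrix(xyz[j, idx], nrow = 3))^2)))
    expect_lte(p1$matrix[i, j], raw + 1e-9)
  }
})

test_that("reference RMSD is zero for self and rigidly moved references", {
  st <- simulate_trajectory(synthetic_spec(n_layers = 2, n_frames = 5,
                                           seed = 76))
  ref <- g4geom:::frame_coords(st$trajectory, 1)
  expect_lt(max(rmsd_to_reference(st$trajectory, ref, 1:8)), 1e-6)
  set.seed(77)
  moved <- rigid_move(ref, random_rotation(), stats::rnorm(3, 0, 20))
  expect_lt(max(rmsd_to_reference(st$trajectory, moved, 1:8)), 1e-6)
})

test_that("fit and calc selections separate stem fitting from loop RMSD", {
  sp <- synthetic_spec(
    n_layers = 1,
    loop_bases = list(list(base = "A", d_z = 3.4, tilt = 10, offset = 0.5,
                           anchor = 1)),
    noise_t = 0.2, n_frames = 300, seed = 78)
  st <- simulate_trajectory(sp)
  ref <- g4geom:::frame_coords(st$trajectory, 1)
  r <- rmsd_to_reference(st$trajectory, ref, fit_sel = 1:4, calc_sel = 5)
  # oracle: per-frame brute-force bio3d superposition on the stem
  xyz <- g4geom:::traj_xyz(st$trajectory)
  fx <- g4geom:::xyz_inds(select_atoms(st$trajectory, selection(1:4)))
  cx <- g4geom:::xyz_inds(select_atoms(st$trajectory, selection(5)))
  refv <- as.vector(t(ref))
  oracle <- sapply(seq_len(300), function(f) {
    fit <- bio3d::fit.xyz(fixed = refv, mobile = xyz[f, ],
                          fixed.inds = fx, mobile.inds = fx)
    sqrt(mean(colSums((matrix(fit[cx], nrow = 3) -
                         matrix(refv[cx], nrow = 3))^2)))
  })
  expect_equal(as.vector(r), oracle, tolerance = 1e-9)
  se <- stats::sd(oracle) / sqrt(length(oracle))
  expect_lt(abs(mean(r) - mean(oracle)), 3 * se + 1e-9)
  # roster mismatch is an error
  expect_error(rmsd_to_reference(st$trajectory, ref[-1, ], 1:4), "roster")
})

backbone_traj <- function(angles_deg) {
  n <- length(angles_deg)
  atoms <- data.frame(name = c("O3'", "P", "O5'", "C5'"),
                      resno = c(1L, 2L, 2L, 2L),
                      resname = "DT", chain = "A", stringsAsFactors = FALSE)
  coords <- array(0, dim = c(n, 4, 3))
  for (f in seq_len(n)) {
    a <- angles_deg[f] * pi / 180
    coords[f, 1, ] <- c(1.4, 0, 0)
    coords[f, 2, ] <- c(0, 0, 0)
    coords[f, 3, ] <- c(0, 0, 1.6)
    coords[f, 4, ] <- c(1.5 * cos(a), 1.5 * sin(a), 1.6)
  }
  g4geom:::new_trajectory(atoms, coords, 5)
}

test_that("torsion wells label g+, t and g- at their centers", {
  ts <- torsion_series(backbone_traj(c(60, 180, 300, 0)), 2, "alpha")
  expect_equal(ts$series$angle, c(60, 180, 300, 0), tolerance = 1e-6)
  expect_identical(ts$series$rotamer, c("g+", "t", "g-", "g+"))
})

test_that("torsions are invariant under rigid motion", {
  set.seed(79)
  tr <- backbone_traj(c(60, 135, 300))
  t0 <- torsion_series(tr, 2, "alpha")$series$angle
  for (i in 1:5) {
    R0 <- random_rotation(); tvec <- stats::rnorm(3, 0, 10)
    tr2 <- tr
    for (f in 1:3)
      tr2$coords[f, , ] <- rigid_move(tr$coords[f, , ], R0, tvec)
    expect_equal(torsion_series(tr2, 2, "alpha")$series$angle, t0,
                 tolerance = 1e-9)
  }
})

test_that("missing torsion atoms are named in the error", {
  tr <- backbone_traj(60)
  expect_error(torsion_series(tr, 2, "gamma"), "C4'")
  # alpha of the first residue lacks the upstream O3'
  atoms2 <- tr$atoms; atoms2$resno <- c(2L, 2L, 2L, 2L)
  tr2 <- g4geom:::new_trajectory(atoms2, tr$coords, 5)
  expect_error(torsion_series(tr2, 2, "alpha"), "O3'")
})
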