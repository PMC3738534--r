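flat_frame <- function(origin = c(0, 0, 0), z = c(0, 0, 1)) {
  g4geom:::new_group_frame(origin, z, 1L)
}

test_that("pure rise and coincident frames give the expected geometry", {
  g <- group_geometry(flat_frame(), flat_frame(origin = c(0, 0, 3.4)))
  expect_equal(g$d_z, 3.4, tolerance = 1e-12)
  expect_equal(g$angle, 0, tolerance = 1e-12)
  same <- group_geometry(flat_frame(), flat_frame())
  expect_equal(same$d_z, 0)
  expect_equal(same$angle, 0)
})

test_that("geometry is symmetric in argument order and rigid-invariant", {
  set.seed(41)
  for (i in 1:40) {
    g1 <- flat_frame(stats::rnorm(3, 0, 5), random_unit())
    g2 <- flat_frame(stats::rnorm(3, 0, 5), random_unit())
    a <- group_geometry(g1, g2)
    b <- group_geometry(g2, g1)
    expect_lt(abs(a$d_z - b$d_z), 1e-9)
    expect_lt(abs(a$angle - b$angle), 1e-9)
    R0 <- random_rotation(); t0 <- stats::rnorm(3, 0, 10)
    mg <- function(g) flat_frame(as.vector(R0 %*% g$origin + t0),
                                 as.vector(R0 %*% g$z_axis))
    m <- group_geometry(mg(g1), mg(g2))
    expect_lt(abs(a$d_z - m$d_z), 1e-9)
    expect_lt(abs(a$angle - m$angle), 1e-9)
  }
})

test_that("angles use the acute convention and stay in [0, 90]", {
  g <- group_geometry(flat_frame(), flat_frame(c(0, 0, 3), c(0, 0, -1)))
  expect_equal(g$angle, 0, tolerance = 1e-9)
  set.seed(42)
  for (i in 1:50) {
    g <- group_geometry(flat_frame(z = random_unit()),
                        flat_frame(stats::rnorm(3), random_unit()))
    expect_gte(g$angle, 0)
    expect_lte(g$angle, 90)
    expect_gte(g$d_z, 0)
  }
})

test_that("tilted base over a quartet matches the SVD projection oracle", {
  set.seed(43)
  qcoords <- lapply(build_quartet(5.4, 0), `[[`, "coords")
  std <- get_standard_base("A")
  for (tilt in c(5, 10, 20)) {
    R <- rodrigues_matrix(c(0, 1, 0), tilt * pi / 180)
    obs <- sweep(std$coords %*% t(R), 2, c(1.0, 0.4, 3.6), "+")
    rownames(obs) <- rownames(std$coords)
    qf <- quartet_frame(fit_quartet_frames(qcoords))
    bf <- fit_base_frame(obs, std)
    g <- group_geometry(qf, bf)
    # oracle: SVD plane normals of both groups, bisector, projected centers
    n1 <- svd_plane_normal(do.call(rbind, qcoords))
    n2 <- svd_plane_normal(obs)
    if (sum(n1 * n2) < 0) n2 <- -n2
    bis <- bisector_oracle(n1, n2)
    d_oracle <- abs(sum((colMeans(obs) -
                           colMeans(do.call(rbind, qcoords))) * bis))
    a_oracle <- dir_angle_deg(n1, n2)
    expect_lt(abs(g$d_z - d_oracle), 0.1)
    expect_lt(abs(g$angle - a_oracle), 1)
  }
})

test_that("stacking classification honours inclusive printed thresholds", {
  crit <- stacking_criterion()
  geom <- function(d, a) structure(list(d_z = d, angle = a),
                                   class = "pair_geometry")
  # printed mean geometries of stacked loop bases classify as stacked
  expect_true(classify_stacking(geom(3.2, 21.9), crit))
  expect_true(classify_stacking(geom(3.1, 14.6), crit))
  # the loop base resting on a pair at 4.8 A is not stacked
  expect_false(classify_stacking(geom(4.8, 27.4), crit))
  expect_true(classify_stacking(geom(3.5, 0), crit))
  # inclusive bounds
  expect_true(classify_stacking(geom(3.0, 30), crit))
  expect_true(classify_stacking(geom(4.0, 0), crit))
  expect_false(classify_stacking(geom(2.999, 0), crit))
  expect_false(classify_stacking(geom(3.5, 30.001), crit))
  # loose preset admits tight stacking
  expect_true(classify_stacking(geom(2.6, 13.7), stacking_criterion(preset = "loose")))
  expect_false(classify_stacking(geom(2.6, 13.7), crit))
})

test_that("classification is monotone in angle at in-range distance", {
  crit <- stacking_criterion()
  prev <- TRUE
  for (a in seq(0, 90, by = 5)) {
    cur <- classify_stacking(list(d_z = 3.5, angle = a), crit)
    expect_true(!cur || prev)   # once false, never true again
    prev <- cur
  }
})

test_that("criterion constructor validates its bounds", {
  expect_error(stacking_criterion(d_lo = 4, d_hi = 3), "d_lo < d_hi")
  expect_error(stacking_criterion(a_max = 0), "degrees")
})

test_that("a rigid stacked pose gives zero spread and full occupancy", {
  sp <- synthetic_spec(n_layers = 1, loop_bases = list(
    list(base = "A", d_z = 3.4, tilt = 10, offset = 0.5, anchor = 1)),
    n_frames = 5, seed = 5)
  st <- simulate_trajectory(sp)
  gs <- geometry_series(st$trajectory, 1:4, 5)
  expect_equal(gs$sd_dz, 0, tolerance = 1e-9)
  expect_equal(gs$sd_angle, 0, tolerance = 1e-9)
  expect_identical(gs$stacked_fraction, 1)
  expect_equal(gs$mean_dz, 3.4, tolerance = 1e-9)
  expect_equal(gs$mean_angle, 10, tolerance = 1e-9)
})

test_that("rigid-noise trajectories recover the nominal rise", {
  sp <- synthetic_spec(n_layers = 1, loop_bases = list(
    list(base = "A", d_z = 3.4, tilt = 8, offset = 0.5, anchor = 1)),
    noise_t = 0.3, noise_r = 5, n_frames = 2000, seed = 17)
  st <- simulate_trajectory(sp)
  gs <- geometry_series(st$trajectory, 1:4, 5)
  se <- gs$sd_dz / sqrt(nrow(gs$series))
  expect_lt(abs(gs$mean_dz - 3.4), 3 * se + 0.02)
})

test_that("Markov switching occupancy matches the stationary value", {
  sp <- synthetic_spec(n_layers = 1, loop_bases = list(
    list(base = "A", d_z = 3.4, tilt = 10, offset = 0.5, anchor = 1)),
    markov = list(p_leave = 0.1, p_enter = 0.3,
                  alt_pose = list(d_z = 7, tilt = 60, offset = 3), base = 1),
    noise_t = 0.05, noise_r = 1, n_frames = 2000, seed = 19)
  st <- simulate_trajectory(sp)
  gs <- geometry_series(st$trajectory, 1:4, 5)
  # stationary probability 0.75; autocorrelated two-state chain SE
  rho <- 1 - 0.1 - 0.3
  se <- sqrt(0.75 * 0.25 / 2000 * (1 + rho) / (1 - rho))
  expect_lt(abs(gs$stacked_fraction - 0.75), 3 * se)
  # classified series equals the simulated state sequence
  expect_identical(gs$series$stacked, st$state == 1L)
})

test_that("series TSV output round-trips", {
  sp <- synthetic_spec(n_layers = 1, loop_bases = list(
    list(base = "A", d_z = 3.4, tilt = 10, offset = 0.5, anchor = 1)),
    n_frames = 3, seed = 5)
  gs <- geometry_series(simulate_trajectory(sp)$trajectory, 1:4, 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_series_tsv(gs, f)
  back <- utils::read.delim(f)
  expect_identical(names(back), c("frame", "time_ps", "d_z", "angle", "stacked"))
  expect_equal(back$d_z, gs$series$d_z, tolerance = 1e-6)
  expect_identical(back$stacked, as.integer(gs$series$stacked))
})
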