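z_axis <- channel_axis(c(0, 0, 0), c(0, 0, 1))

test_that("cylinder profile matches the analytic clearance R - r", {
  toy <- make_toy_channel(seq(-6, 6, 0.5), 6, atoms_per_ring = 28)
  p <- profile_pore(toy$structure, z_axis, bounds = c(-4, 4), rng_seed = 1)
  interior <- p$flag == ""
  expect_true(all(interior))
  expect_true(all(abs(p$radius - 4.3) <= max(0.05, attr(p, "step") / 2)))
  expect_true(all(diff(p$s) > 0))
  # center continuity invariant
  steps <- sqrt(diff(p$cx)^2 + diff(p$cy)^2 + diff(p$cz)^2)
  expect_true(all(steps <= attr(p, "step") * 3))
})

test_that("hourglass profile finds the waist and matches a grid oracle", {
  zs <- seq(-5, 5, 0.5)
  radii <- 8 - 4 * (1 - abs(zs) / 5)         # 8 -> 4 -> 8 linear
  toy <- make_toy_channel(zs, radii, atoms_per_ring = 28)
  p <- profile_pore(toy$structure, z_axis, step = 0.5, bounds = c(-4, 4),
                    rng_seed = 2)
  m <- min_radius(p)
  expect_equal(m$station, 0)
  expect_equal(m$radius, 4 - 1.7, tolerance = 0.1)
  # every station agrees with a brute-force 3D grid search over the pore
  # lumen (within the waist ring radius, so the probe cannot jump to bulk)
  for (i in seq_len(nrow(p))) {
    expect_equal(p$radius[i], grid_clearance(toy$structure, p$s[i], lim = 4),
                 tolerance = 0.1)
  }
})

test_that("min_radius equals a linear-scan oracle and honors windows", {
  prof <- structure(data.frame(
    s = seq(0, 10, 0.5),
    cx = 0, cy = 0, cz = seq(0, 10, 0.5),
    radius = c(5, 4, 6, 3.2, 7, 3.2, 8, 5, 4.5, 4.4, 4.3, 4.2, 4.1,
               4.0, 3.9, 3.8, 3.7, 3.6, 3.55, 3.5, 3.45),
    flag = "", hydrophobicity = NA_real_),
    class = c("path_profile", "data.frame"))
  m <- min_radius(prof)
  i <- which.min(prof$radius)
  expect_equal(m$radius, prof$radius[i])
  # tie at 3.2: smallest station wins
  expect_equal(min_radius(prof, c(1, 3))$station, 1.5)
  # monotone tail: boundary station
  expect_equal(min_radius(prof, c(4, 10))$station, 10)
  expect_error(min_radius(prof, c(50, 60)), "overlap")
  # random profiles equal the scan oracle
  set.seed(5)
  for (k in 1:10) {
    prof$radius <- runif(nrow(prof), 1, 9)
    expect_equal(min_radius(prof)$radius, min(prof$radius))
    expect_equal(min_radius(prof)$station,
                 prof$s[which.min(prof$radius)])
  }
})

test_that("portal through a wall: minimum radius = aperture - atom radius", {
  # flat pseudo-atom wall at x = 20 (yz grid) with a circular 8 Å hole
  # rimmed by atoms exactly at the aperture radius
  g <- expand.grid(y = seq(-14, 14, 0.4), z = seq(-14, 14, 0.4))
  keep <- g$y^2 + g$z^2 > 8^2
  rim_ang <- seq(0, 2 * pi, length.out = 400)[-1]
  wall <- quick_structure(data.frame(
    x = 20, y = c(g$y[keep], 8 * cos(rim_ang)),
    z = c(g$z[keep], 8 * sin(rim_ang))))
  wall$atoms$vdw <- 1.7
  p <- profile_portal(wall, z_axis, seed = c(20, 0, 0), step = 0.25,
                      bounds = c(-3, 6), rng_seed = 3)
  expect_equal(min_radius(p)$radius, 8 - 1.7, tolerance = 0.1)
})

test_that("C7 portal profiles agree pairwise after symmetry rotation", {
  holes <- data.frame(z = 0, azimuth_deg = (0:6) * 360 / 7, aperture = 5)
  toy <- make_toy_channel(seq(-8, 8, 0.4), 14, atoms_per_ring = 140,
                          portal_holes = holes)
  profs <- lapply(holes$azimuth_deg, function(a) {
    seed <- c(14 * cos(a * pi / 180), 14 * sin(a * pi / 180), 0)
    profile_portal(toy$structure, z_axis, seed = seed, step = 0.5,
                   bounds = c(-2, 6), rng_seed = 4, n_starts = 4)
  })
  r1 <- profs[[1]]$radius
  for (k in 2:7) {
    expect_equal(length(profs[[k]]$radius), length(r1))
    expect_true(max(abs(profs[[k]]$radius - r1)) < 1e-3)
  }
})

test_that("hydrophobicity scoring and the hydration-barrier heuristic", {
  # wide serine-lined pore: no barrier
  ser <- make_toy_channel(seq(-3, 3, 0.5), 5.7, atoms_per_ring = 28,
                          resname = "SER")
  p <- profile_pore(ser$structure, z_axis, bounds = c(-2, 2), rng_seed = 1)
  p <- hydrophobicity_profile(ser$structure, p)
  expect_true(all(p$hydrophobicity < 0, na.rm = TRUE))
  expect_false(barrier_flag(p))

  # 2 Å leucine waist: barrier under the default thresholds
  zs <- seq(-3, 3, 0.5)
  leu <- make_toy_channel(zs, 3.7 + 2 * abs(zs) / 3, atoms_per_ring = 28,
                          resname = "LEU")
  q <- profile_pore(leu$structure, z_axis, bounds = c(-2, 2), rng_seed = 1)
  q <- hydrophobicity_profile(leu$structure, q)
  expect_lt(min_radius(q)$radius, 3.5)
  expect_true(barrier_flag(q))

  # a station with no lining residue stays undefined
  far <- structure(data.frame(s = c(0, 50), cx = c(0, 0), cy = c(0, 0),
                              cz = c(0, 50), radius = c(2, 12),
                              flag = c("", "open_to_bulk"),
                              hydrophobicity = NA_real_),
                   class = c("path_profile", "data.frame"))
  far2 <- hydrophobicity_profile(leu$structure, far)
  expect_false(is.na(far2$hydrophobicity[1]))
  expect_true(is.na(far2$hydrophobicity[2]))
})

test_that("envelope statistics: trivial cases and hand arithmetic", {
  toy <- make_toy_channel(seq(-3, 3, 0.5), 6, atoms_per_ring = 28)
  env1 <- profile_envelope(list(toy$structure, toy$structure,
                                toy$structure),
                           z_axis, bounds = c(-2, 2), rng_seed = 1)
  expect_true(all(env1$sd == 0))
  expect_equal(env1$min, env1$mean)
  expect_equal(env1$max, env1$mean)
  expect_equal(attr(env1, "n_frames"), 3)

  # two hourglass frames with waist radii 2.0 and 3.0 Å
  zs <- seq(-3, 3, 0.5)
  fA <- make_toy_channel(zs, 3.7 + 2 * abs(zs) / 3, atoms_per_ring = 28)
  fB <- make_toy_channel(zs, 4.7 + 2 * abs(zs) / 3, atoms_per_ring = 28)
  env2 <- profile_envelope(list(fA$structure, fB$structure), z_axis,
                           bounds = c(-2, 2), rng_seed = 1)
  w <- which.min(abs(env2$s))
  expect_equal(env2$mean[w], 2.5, tolerance = 0.05)
  expect_equal(env2$sd[w], abs(3 - 2) / sqrt(2), tolerance = 0.05)
  expect_equal(env2$min[w], 2.0, tolerance = 0.05)
  expect_equal(env2$max[w], 3.0, tolerance = 0.05)
  expect_true(all(env2$min <= env2$mean + 1e-12) &&
                all(env2$mean <= env2$max + 1e-12))
})

test_that("envelope equals recompute-and-aggregate over jittered frames", {
  set.seed(11)
  zs <- seq(-3, 3, 0.5)
  frames <- lapply(1:6, function(k) {
    toy <- make_toy_channel(zs, 6, atoms_per_ring = 28)
    toy$structure$atoms$x <- toy$structure$atoms$x + rnorm(nrow(toy$structure$atoms), sd = 0.05)
    toy$structure$atoms$y <- toy$structure$atoms$y + rnorm(nrow(toy$structure$atoms), sd = 0.05)
    toy$structure
  })
  env <- profile_envelope(frames, z_axis, bounds = c(-2, 2), rng_seed = 9)
  profs <- lapply(frames, function(f)
    profile_pore(f, z_axis, bounds = c(-2, 2), rng_seed = 9))
  s_ref <- profs[[1]]$s
  R <- sapply(profs, function(p) approx(p$s, p$radius, xout = s_ref)$y)
  expect_equal(env$mean, rowMeans(R), tolerance = 1e-12)
  expect_equal(env$sd, apply(R, 1, sd), tolerance = 1e-12)
  expect_equal(env$min, apply(R, 1, min), tolerance = 1e-12)
  expect_equal(env$max, apply(R, 1, max), tolerance = 1e-12)
})

test_that("profiles are seed-deterministic, rotation-invariant, and shift
           exactly under uniform radius changes", {
  toy <- make_toy_channel(seq(-4, 4, 0.5), c(8, 7, 6, 5, 4.5, 4, 4.5, 5,
                                             6, 7, 8, 8, 8, 8, 8, 8, 8),
                          atoms_per_ring = 28)
  p1 <- profile_pore(toy$structure, z_axis, bounds = c(-3, 3), rng_seed = 7)
  p2 <- profile_pore(toy$structure, z_axis, bounds = c(-3, 3), rng_seed = 7)
  expect_identical(p1$radius, p2$radius)
  expect_identical(p1$cx, p2$cx)

  # rigid rotation with the axis rotated accordingly
  R <- rot3(c(1, 0.3, 0), 0.6)
  rot <- rotate_structure(toy$structure, R)
  ax_r <- channel_axis(c(0, 0, 0), drop(R %*% c(0, 0, 1)))
  p3 <- profile_pore(rot, ax_r, bounds = c(-3, 3), rng_seed = 7)
  expect_equal(p3$radius, p1$radius, tolerance = 1e-3)

  # shrinking every vdW radius by delta widens every station by delta
  delta <- 0.3
  shrunk <- toy$structure
  shrunk$atoms$vdw <- shrunk$atoms$vdw - delta
  p4 <- profile_pore(shrunk, z_axis, bounds = c(-3, 3), rng_seed = 7)
  expect_equal(p4$radius, p1$radius + delta, tolerance = 1e-6)
})

test_that("profiling refuses structures without radii and bad seeds", {
  s <- quick_structure(data.frame(x = 0, y = 0, z = 0))
  expect_error(profile_pore(s, z_axis), "radii")
  toy <- make_toy_channel(seq(-2, 2, 0.5), 6)
  expect_error(profile_pore(toy$structure, z_axis, seed = c(0, 0, 99),
                            bounds = c(-2, 2)), "bounds")
})
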