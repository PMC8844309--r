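z_axis <- channel_axis(c(0, 0, 0), c(0, 0, 1))

demo_geom <- channel_geometry(
  cylinder_radius = 8, z_extracellular = 15 + 1e-9, z_pore_top = 15,
  z_pore_bottom = 0, z_cage_bottom = -20,
  portals = data.frame(r_min = 7.5, r_max = 10.5, z_min = -14, z_max = -6))

traj_from_positions <- function(P, dt = 0.1, charge = -1, box = NULL,
                                axis = z_axis, protein = NULL) {
  # P: list of per-ion [n_frames, 3] matrices
  n_frames <- nrow(P[[1]])
  arr <- array(NA_real_, dim = c(n_frames, length(P), 3))
  for (j in seq_along(P)) arr[, j, ] <- P[[j]]
  ion_trajectory((seq_len(n_frames) - 1) * dt, arr, charge = charge,
                 axis = axis, box = box, protein_frames = protein)
}

test_that("compartment labels follow the geometry and tie precedence", {
  pts <- rbind(c(0, 0, 20),     # above extracellular boundary
               c(0, 0, 0),      # exactly on z_pore_bottom, inside cylinder
               c(0, 0, -5),     # cage interior
               c(9, 0, -10),    # portal annulus
               c(25, 0, -10),   # outside everything below membrane
               c(0, 0, 7))      # mid-pore
  tr <- traj_from_positions(lapply(seq_len(nrow(pts)), function(i)
    matrix(pts[i, ], 1, 3)))
  cs <- assign_compartments(tr, demo_geom)
  expect_equal(as.vector(cs[1, ]),
               c("BULK_EXT", "PORE", "CAGE", "PORTAL", "BULK_CYT", "PORE"))
})

test_that("labels of random points equal the containment oracle exactly", {
  set.seed(21)
  P <- cbind(runif(1000, -30, 30), runif(1000, -30, 30),
             runif(1000, -40, 30))
  tr <- traj_from_positions(lapply(seq_len(1000), function(i)
    matrix(P[i, ], 1, 3)))
  cs <- assign_compartments(tr, demo_geom)
  oracle <- vapply(seq_len(1000), function(i)
    containment_oracle(P[i, ], z_axis, demo_geom), character(1))
  expect_identical(as.vector(cs[1, ]), oracle)
})

test_that("crossing detection: scripted passages and incomplete paths", {
  s1 <- c("BULK_CYT", "PORTAL", "CAGE", "PORE", "BULK_EXT")
  ev <- detect_crossings(label_series(list(s1)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_entry, 0.1)
  expect_equal(ev$t_exit, 0.4)
  expect_equal(ev$transit, 0.3)

  # partial passage: no event
  s2 <- c("PORTAL", "CAGE", "PORTAL", "BULK_CYT")
  expect_equal(nrow(detect_crossings(label_series(list(s2)))), 0)

  # pore entry without portal: no event
  s3 <- c("BULK_CYT", "CAGE", "PORE", "BULK_EXT")
  expect_equal(nrow(detect_crossings(label_series(list(s3)))), 0)

  # re-entry restarts the clock: entry time is the portal visit of the
  # completed passage
  s4 <- c("PORTAL", "CAGE", "BULK_CYT", "PORTAL", "CAGE", "PORE",
          "BULK_EXT")
  ev4 <- detect_crossings(label_series(list(s4)))
  expect_equal(nrow(ev4), 1)
  expect_equal(ev4$t_entry, 0.3)

  # two completed passages by one ion
  s5 <- c(s1, "BULK_CYT", s1)
  expect_equal(nrow(detect_crossings(label_series(list(s5)))), 2)
})

test_that("crossing detection equals the regex oracle on random walks", {
  set.seed(33)
  labels <- c("BULK_CYT", "PORTAL", "CAGE", "PORE", "BULK_EXT")
  runs <- lapply(seq_len(200), function(j)
    sample(labels, 60, replace = TRUE,
           prob = c(0.25, 0.2, 0.25, 0.2, 0.1)))
  cs <- label_series(runs)
  ev <- detect_crossings(cs)
  oracle <- regex_crossings(cs)
  ev <- ev[order(ev$ion, ev$t_entry), ]
  oracle <- oracle[order(oracle$ion, oracle$t_entry), ]
  expect_equal(nrow(ev), nrow(oracle))
  expect_equal(ev$ion, oracle$ion)
  expect_equal(ev$t_entry, oracle$t_entry)
  expect_equal(ev$t_exit, oracle$t_exit)
  # no ion contributes overlapping events
  if (nrow(ev) > 1) {
    by_ion <- split(ev, ev$ion)
    for (b in by_ion) if (nrow(b) > 1)
      expect_true(all(b$t_entry[-1] >= b$t_exit[-nrow(b)]))
  }
})

test_that("conductance estimator: arithmetic, scaling laws, errors", {
  g <- estimate_conductance(1, 1, 1, 1000)
  expect_equal(g$conductance_pS, 160.218, tolerance = 1e-5)
  # linearity and inverse scaling to machine precision
  g1 <- estimate_conductance(12, 1, 100, 200)$conductance_pS
  expect_equal(estimate_conductance(24, 1, 100, 200)$conductance_pS,
               2 * g1, tolerance = 1e-12)
  expect_equal(estimate_conductance(12, 1, 200, 200)$conductance_pS,
               g1 / 2, tolerance = 1e-12)
  expect_equal(estimate_conductance(12, 1, 100, 400)$conductance_pS,
               g1 / 2, tolerance = 1e-12)
  expect_equal(estimate_conductance(12, 2, 100, 200)$conductance_pS,
               2 * g1, tolerance = 1e-12)
  # sign of the potential is discarded
  expect_equal(estimate_conductance(12, 1, 100, -200)$conductance_pS, g1)
  # closed-form invariant
  expect_equal(g1, 12 * 1.602176634e-19 / (100e-9 * 0.2) * 1e12,
               tolerance = 1e-12)
  expect_error(estimate_conductance(1, 1, 0, 100), "duration")
  expect_error(estimate_conductance(1, 1, 100, 0), "potential")
})

test_that("z tracks: projection, antisymmetry, periodic unwrapping", {
  zpath <- seq(-30, 30, 1)
  P <- cbind(0, 0, zpath)
  tr <- traj_from_positions(list(P))
  zt <- z_tracks(tr)
  expect_equal(zt$z, zpath)
  expect_equal(diff(zt$z), rep(1, length(zpath) - 1))

  flipped <- traj_from_positions(list(P),
                                 axis = channel_axis(c(0, 0, 0), c(0, 0, -1)))
  expect_equal(z_tracks(flipped)$z, -zpath)

  # wrapped trajectory across a 100 Å box: true path 0 -> 150
  true_z <- seq(0, 150, 2.5)
  wrapped <- ((true_z + 50) %% 100) - 50
  trw <- traj_from_positions(list(cbind(0, 0, wrapped)), box = c(100, 100, 100))
  ztw <- z_tracks(trw)$z
  # hand-unwrapped oracle
  dz <- diff(wrapped)
  dz <- dz - 100 * round(dz / 100)
  oracle <- cumsum(c(wrapped[1], dz))
  expect_equal(ztw, oracle, tolerance = 1e-12)
  expect_true(all(abs(diff(ztw)) < 50))
  expect_error(z_tracks(tr, ions = 99), "unknown ion")
})

test_that("contact ladder order and handover direction", {
  # three basic residues along the entry path
  prot <- quick_structure(data.frame(
    x = c(20, 12, 4), y = 0, z = c(-10, -10, -10),
    name = c("NZ", "NH1", "NZ"), element = "N",
    resname = c("LYS", "ARG", "LYS"), resno = c(624, 599, 606),
    chain = "A"))
  residues <- data.frame(chain = "A", resno = c(624, 599, 606),
                         label = c("K624", "R599", "K606"))
  # ion sweeps past each residue within 3 Å, in order
  xpath <- seq(22, 2, -1)
  P <- cbind(xpath, 0, -10)
  tr <- traj_from_positions(list(P), protein = prot)
  ev <- data.frame(ion = 1, t_entry = 0, t_exit = max(tr$times))
  lad <- contact_ladder(tr, ev, residues, cutoff = 4)
  expect_equal(lad$ladder$label, c("K624", "R599", "K606"))
  expect_true(all(diff(lad$ladder$t_first) > 0))
  expect_true(lad$unidirectional)

  # bounce back to R599 after the K606 contact
  Pb <- cbind(c(seq(22, 2, -1), 8, 12, 8), 0, -10)
  trb <- traj_from_positions(list(Pb), protein = prot)
  evb <- data.frame(ion = 1, t_entry = 0, t_exit = max(trb$times))
  expect_false(contact_ladder(trb, evb, residues, cutoff = 4)$unidirectional)

  # widening the cutoff can only make first contacts earlier
  lad6 <- contact_ladder(tr, ev, residues, cutoff = 6)
  expect_true(all(lad6$ladder$t_first[match(residues$label,
                                            lad6$ladder$label)] <=
                    lad$ladder$t_first[match(residues$label,
                                             lad$ladder$label)]))
  expect_error(contact_ladder(traj_from_positions(list(P)), ev, residues),
               "protein")
})

test_that("chi1 dihedrals are classified into rotamer bins", {
  build_res <- function(chi1) {
    Npos <- c(1.45, 0, 0); CA <- c(0, 0, 0)
    CB <- place_dihedral(c(2, 1, 0), Npos, CA, 1.53, 110, -120)
    CG <- place_dihedral(Npos, CA, CB, 1.52, 114, chi1)
    quick_structure(data.frame(
      x = c(Npos[1], CA[1], CB[1], CG[1]),
      y = c(Npos[2], CA[2], CB[2], CG[2]),
      z = c(Npos[3], CA[3], CB[3], CG[3]),
      name = c("N", "CA", "CB", "CG"), element = c("N", "C", "C", "C"),
      resname = "PHE", resno = 572))
  }
  cases <- data.frame(chi1 = c(-178, -60, 60, 150, -120, 0, 119.9),
                      label = c("trans", "gauche-", "gauche+", "trans",
                                "gauche-", "gauche+", "gauche+"))
  for (k in seq_len(nrow(cases))) {
    rs <- chi1_series(build_res(cases$chi1[k]), list(resno = 572))
    expect_equal(rs$chi1, cases$chi1[k], tolerance = 1e-6)
    expect_equal(rs$label, cases$label[k])
  }
  # series over frames
  frames <- lapply(c(-178, -60, -65, -178), build_res)
  rs <- chi1_series(frames, list(resno = 572))
  expect_equal(rs$label, c("trans", "gauche-", "gauche-", "trans"))
  # missing atom is a data error naming the atom
  broken <- build_res(-60)
  broken$atoms <- broken$atoms[broken$atoms$name != "CG", ]
  expect_error(chi1_series(broken, list(resno = 572)), "CG")
})

test_that("wetting occupancy counts frames with enough waters", {
  region <- list(z = c(-2, 2), r = c(0, 5))
  inside <- c(0, 0, 0); outside <- c(0, 0, 30)
  mk <- function(seq_inside) {
    P <- lapply(1:3, function(j)
      do.call(rbind, lapply(seq_inside, function(w)
        if (w) inside + (j - 2) * c(0.5, 0, 0) else outside)))
    traj_from_positions(P, charge = 0)
  }
  expect_equal(wetting_occupancy(mk(rep(TRUE, 10)), region, 3), 1.0)
  expect_equal(wetting_occupancy(mk(rep(FALSE, 10)), region, 1), 0.0)
  alternating <- rep(c(TRUE, FALSE), 5)
  expect_equal(wetting_occupancy(mk(alternating), region, 3), 0.5)
  # counting oracle
  expect_equal(wetting_occupancy(mk(alternating), region, 1),
               mean(alternating))
  expect_error(wetting_occupancy(mk(alternating),
                                 list(z = c(2, -2), r = c(0, 5))), "empty")
})
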