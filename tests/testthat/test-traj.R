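# Kabsch superposition, RMSD, hydrogen-bond populations, dihedrals,
# zinc geometry, and the synthetic trajectory generator.

test_that("Kabsch superposition is exact for rigid motions and optimal overall", {
  set.seed(31)
  P <- matrix(rnorm(30), ncol = 3)

  # identical frames
  fit0 <- superpose_kabsch(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  # a rigidly moved copy superposes to numerical zero
  R <- random_rotation()
  moved <- P %*% t(R) + matrix(c(3, -1, 7), nrow(P), 3, byrow = TRUE)
  expect_lt(superpose_kabsch(P, moved)$rmsd, 1e-9)

  # optimality: no rotation from a dense random grid beats the Kabsch rmsd
  Q <- P + matrix(rnorm(30, 0, 0.5), ncol = 3)
  best <- superpose_kabsch(Q, P)$rmsd
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  grid_rmsd <- replicate(2000, {
    G <- random_rotation()
    sqrt(mean(rowSums((Pc %*% t(G) - Qc)^2)))
  })
  expect_true(all(best <= grid_rmsd + 1e-12))

  expect_error(superpose_kabsch(P[1:2, ], P[1:2, ]), "3 atoms")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose_kabsch(line, line), "collinear")
})

test_that("RMSD series are zero at the reference and invariant to rigid motion", {
  tmpl <- make_template(4)
  traj <- synth_trajectory(tmpl, n_frames = 10, jitter = 0.3, seed = 4)
  s <- rmsd_series(traj)
  expect_equal(s$rmsd[1], 0)
  expect_true(all(s$rmsd >= 0))

  # whole-trajectory rigid motion leaves the series untouched
  R <- random_rotation()
  moved <- traj
  for (f in seq_len(dim(traj$coords)[1]))
    moved$coords[f, , ] <- traj$coords[f, , ] %*% t(R) +
      matrix(c(10, 20, 30), dim(traj$coords)[2], 3, byrow = TRUE)
  expect_equal(rmsd_series(moved)$rmsd, s$rmsd, tolerance = 1e-9)

  # empty trajectory
  empty <- trajectory(tmpl$atoms, array(0, dim = c(0, nrow(tmpl$atoms), 3)))
  expect_equal(nrow(rmsd_series(empty)), 0)
})

test_that("mean RMSD of an isotropically jittered trajectory approaches sigma*sqrt(3)", {
  set.seed(77)
  sigma <- 0.2
  na <- 60
  base <- matrix(rnorm(3 * na, sd = 4), ncol = 3)
  atoms <- tibble::tibble(name = paste0("X", seq_len(na)), resname = "XXX",
                          resid = seq_len(na), chain = "A")
  nf <- 400
  coords <- array(0, dim = c(nf, na, 3))
  coords[1, , ] <- base
  for (f in 2:nf) coords[f, , ] <- base + rnorm(3 * na, sd = sigma)
  s <- rmsd_series(trajectory(atoms, coords))
  expect_equal(mean(s$rmsd[-1]), sigma * sqrt(3), tolerance = 0.1)
})

test_that("hydrogen-bond populations recover the construction schedule", {
  tmpl <- make_template(3)
  spec <- hbond_spec("B:4:D", "B:4:HD", "B:4:ACC")

  on <- rep(c(TRUE, FALSE), times = c(60, 40))
  traj <- synth_trajectory(tmpl, 100, schedule = list(list(spec = spec, on = on)))
  pop <- hbond_populations(traj, spec)
  expect_equal(pop$population, 0.60)

  all_on <- synth_trajectory(tmpl, 20,
                             schedule = list(list(spec = spec, on = rep(TRUE, 20))))
  expect_equal(hbond_populations(all_on, spec)$population, 1.0)

  on30 <- sample(rep(c(TRUE, FALSE), times = c(30, 70)))
  t30 <- synth_trajectory(tmpl, 100, schedule = list(list(spec = spec, on = on30)))
  expect_equal(hbond_populations(t30, spec)$population, 0.30)

  expect_error(hbond_populations(traj, hbond_spec("B:9:D", "B:4:HD", "B:4:ACC")),
               "matches no atom")
})

test_that("boundary geometry counts as satisfied (closed cutoffs)", {
  atoms <- tibble::tibble(name = c("D", "HD", "ACC"), resname = "XXX",
                          resid = 1L, chain = "A")
  # acceptor exactly at the 3.5 A cutoff, angle exactly 0
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.5, 0, 0))
  traj <- trajectory(atoms, xyz)
  spec <- hbond_spec("A:1:D", "A:1:HD", "A:1:ACC")
  expect_equal(hbond_populations(traj, spec)$population, 1)
  # a hair beyond the cutoff does not
  xyz2 <- xyz; xyz2[3, 1] <- 3.5001
  expect_equal(hbond_populations(trajectory(atoms, xyz2), spec)$population, 0)
  # angle exactly at 30 degrees counts
  d <- 3.0
  xyz3 <- rbind(c(0, 0, 0), c(1, 0, 0),
                c(d * cos(pi / 6), d * sin(pi / 6), 0))
  expect_equal(hbond_populations(trajectory(atoms, xyz3), spec)$population, 1)
})

test_that("population of concatenated trajectories is the frame-weighted mean", {
  tmpl <- make_template(3)
  spec <- hbond_spec("B:4:D", "B:4:HD", "B:4:ACC")
  t1 <- synth_trajectory(tmpl, 40,
                         schedule = list(list(spec = spec, on = rep(c(TRUE, FALSE), 20))))
  t2 <- synth_trajectory(tmpl, 60,
                         schedule = list(list(spec = spec, on = rep(TRUE, 60))))
  p1 <- hbond_populations(t1, spec)$population
  p2 <- hbond_populations(t2, spec)$population
  cat_traj <- trajectory(tmpl$atoms,
                         array(c(aperm(t1$coords, c(2, 3, 1)),
                                 aperm(t2$coords, c(2, 3, 1))),
                               dim = c(nrow(tmpl$atoms), 3, 100)) |>
                           aperm(c(3, 1, 2)))
  pc <- hbond_populations(cat_traj, spec)$population
  expect_equal(pc, (40 * p1 + 60 * p2) / 100)
})

test_that("backbone dihedrals match an independent torsion implementation", {
  tmpl <- make_template(4)
  # planar zigzag: psi of every internal residue is 180 (all-trans)
  psi <- dihedral_series(tmpl, 2, "psi")
  expect_equal(abs(psi$angle), 180, tolerance = 1e-9)

  # four coplanar cis atoms give 0
  expect_equal(acecleave:::dihedral_deg(c(0, 0, 0), c(1, 0, 0),
                                        c(1, 1, 0), c(0, 1, 0)), 0)

  # random geometries against bio3d torsion
  skip_if_not_installed("bio3d")
  set.seed(12)
  for (i in 1:20) {
    pts <- matrix(rnorm(12), ncol = 3)
    mine <- acecleave:::dihedral_deg(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(pts)))
    ref <- ref[!is.na(ref)]
    d <- (mine - ref) %% 360
    expect_lt(min(d, 360 - d), 1e-7)
  }
})

test_that("dihedrals are invariant under rigid motion and uniform scaling", {
  set.seed(13)
  pts <- matrix(rnorm(12), ncol = 3)
  base <- acecleave:::dihedral_deg(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  R <- random_rotation()
  moved <- pts %*% t(R) + matrix(c(5, 6, 7), 4, 3, byrow = TRUE)
  expect_equal(acecleave:::dihedral_deg(moved[1, ], moved[2, ], moved[3, ],
                                        moved[4, ]), base, tolerance = 1e-9)
  scaled <- pts * 7.3
  expect_equal(acecleave:::dihedral_deg(scaled[1, ], scaled[2, ], scaled[3, ],
                                        scaled[4, ]), base, tolerance = 1e-9)
})

test_that("circular statistics handle wraparound", {
  cs <- circular_stats(c(179, -179))
  expect_equal(abs(cs$mean), 180, tolerance = 1e-9)
  expect_lt(cs$var, 1e-3)
  cs2 <- circular_stats(c(0, 90, 180, 270))
  expect_equal(cs2$var, 1, tolerance = 1e-9)
})

test_that("zinc coordination is retained for near-ideal tetrahedra only", {
  # ideal tetrahedron at 2.1 A
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  tet <- tet / sqrt(3) * 2.1
  atoms <- tibble::tibble(
    name = c("ZN", "L1", "L2", "L3", "L4"),
    resname = c("ZN", rep("LIG", 4)), resid = 1:5, chain = "A"
  )
  xyz <- rbind(c(0, 0, 0), tet)
  traj <- trajectory(atoms, xyz)
  chk <- zinc_geometry_check(traj, "A:1:ZN",
                             c("A:2:L1", "A:3:L2", "A:4:L3", "A:5:L4"))
  expect_true(chk$retained)
  expect_equal(chk$angle_dev, 0, tolerance = 1e-2)
  expect_equal(unlist(chk[, c("d1", "d2", "d3", "d4")]), rep(2.1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)

  # one ligand pulled to 4 A breaks it
  xyz2 <- xyz; xyz2[2, ] <- xyz2[2, ] / 2.1 * 4
  chk2 <- zinc_geometry_check(trajectory(atoms, xyz2), "A:1:ZN",
                              c("A:2:L1", "A:3:L2", "A:4:L3", "A:5:L4"))
  expect_false(chk2$retained)

  # jittered tetrahedron (sigma 0.05 A) retains coordination in >99% of frames
  set.seed(8)
  nf <- 1000
  coords <- array(0, dim = c(nf, 5, 3))
  for (f in seq_len(nf)) coords[f, , ] <- xyz + rnorm(15, 0, 0.05)
  chk3 <- zinc_geometry_check(trajectory(atoms, coords), "A:1:ZN",
                              c("A:2:L1", "A:3:L2", "A:4:L3", "A:5:L4"))
  expect_gt(mean(chk3$retained), 0.99)

  expect_error(zinc_geometry_check(traj, "A:1:ZN", c("A:2:L1")), "4 ligand")
})

test_that("synthetic trajectories are reproducible and selections resolve", {
  tmpl <- make_template(3)
  a <- synth_trajectory(tmpl, 5, jitter = 0.2, seed = 55)
  b <- synth_trajectory(tmpl, 5, jitter = 0.2, seed = 55)
  expect_identical(a$coords, b$coords)

  idx <- select_atoms(tmpl, "A:2:CA")
  expect_equal(tmpl$atoms$name[idx], "CA")
  expect_equal(tmpl$atoms$resid[idx], 2L)
  expect_equal(length(select_atoms(tmpl, "*:*:CA")), 3)
  expect_error(select_atoms(tmpl, "A:2"), "chain:resid:atom")
})

test_that("multi-model PDB and XYZ trajectories read back correctly", {
  tmpl <- make_template(2)
  traj <- synth_trajectory(tmpl, 3, jitter = 0.1, seed = 2)

  # write a small multi-model PDB by hand and read it with the package
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  lines <- character()
  for (f in 1:3) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    for (i in seq_len(nrow(traj$atoms))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, traj$atoms$name[i], traj$atoms$resname[i], traj$atoms$chain[i],
        traj$atoms$resid[i], traj$coords[f, i, 1], traj$coords[f, i, 2],
        traj$coords[f, i, 3]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), pdb_path)
  skip_if_not_installed("bio3d")
  back <- read_pdb_trajectory(pdb_path)
  expect_equal(dim(back$coords), dim(traj$coords))
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)

  # XYZ round trip with nm conversion
  xyz_path <- withr::local_tempfile(fileext = ".xyz")
  lines <- character()
  for (f in 1:3) {
    lines <- c(lines, nrow(traj$atoms), paste("frame", f))
    for (i in seq_len(nrow(traj$atoms)))
      lines <- c(lines, sprintf("%s %.6f %.6f %.6f", traj$atoms$name[i],
                                traj$coords[f, i, 1] / 10,
                                traj$coords[f, i, 2] / 10,
                                traj$coords[f, i, 3] / 10))
  }
  writeLines(lines, xyz_path)
  back2 <- read_xyz_trajectory(xyz_path, units = "nm")
  expect_equal(back2$coords, traj$coords, tolerance = 1e-5)
})
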