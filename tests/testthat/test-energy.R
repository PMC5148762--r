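test_that("Lennard-Jones pair energy hits its landmarks", {
  eps_i <- 0.3; eps_j <- 0.5
  rh_i <- 2.0; rh_j <- 1.7
  eps <- sqrt(eps_i * eps_j)
  rmin <- rh_i + rh_j
  expect_equal(lj_pair_energy(rmin, eps_i, eps_j, rh_i, rh_j), -eps,
               tolerance = 1e-12)
  expect_equal(lj_pair_energy(rmin * 2^(-1 / 6), eps_i, eps_j, rh_i, rh_j),
               0, tolerance = 1e-12)
  # independent arithmetic at an arbitrary distance
  r <- 3 * rmin
  expect_equal(lj_pair_energy(r, eps_i, eps_j, rh_i, rh_j),
               eps * ((rmin / r)^12 - 2 * (rmin / r)^6), tolerance = 1e-12)
  expect_error(lj_pair_energy(0, eps_i, eps_j, rh_i, rh_j), "coincident")
})

test_that("SASA of isolated and well-separated atoms is the sphere area", {
  one <- sasa(matrix(0, 1, 3), probe_radius = 1.4, n_points = 960,
              radii = 1.7)
  expect_equal(one, 4 * pi * 3.1^2, tolerance = 0.01)
  two <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), probe_radius = 1.4,
              n_points = 960, radii = c(1.7, 1.52))
  expect_equal(two, 4 * pi * c(3.1^2, 2.92^2), tolerance = 0.01)
})

test_that("SASA handles coincident centers and occluder approach", {
  same <- sasa(matrix(0, 2, 3), probe_radius = 1.4, n_points = 240,
               radii = c(1.7, 1.7))
  expect_true(all(is.finite(same)))
  expect_equal(same[1], same[2])
  # area of atom 1 decreases monotonically as an occluder approaches
  prev <- Inf
  for (d in c(8, 6, 5, 4.5, 4, 3.5, 3)) {
    a <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), probe_radius = 1.4,
              n_points = 960, radii = c(1.7, 1.7))[1]
    expect_lte(a, prev + 1e-9)
    prev <- a
  }
})

test_that("two-sphere SASA matches the closed-form cap areas", {
  # exact exposed area of two intersecting equal spheres of radius R at
  # distance d: each loses a cap of height h = R - d/2
  R <- 1.7 + 1.4
  for (d in c(3.0, 4.0, 5.0)) {
    h <- R - d / 2
    exact <- 4 * pi * R^2 - 2 * pi * R * h
    got <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), probe_radius = 1.4,
                n_points = 960, radii = c(1.7, 1.7))
    expect_equal(got[1], exact, tolerance = 0.01)
    expect_equal(got[2], exact, tolerance = 0.01)
  }
})

test_that("solvation energy weights areas by group tension", {
  expect_equal(solvation_energy(20, "hydrophobic_sidechain"), 2000)
  expect_equal(solvation_energy(20, "hydrophilic_sidechain"), -2000)
  expect_equal(solvation_energy(c(0, 0), c("hydrophobic_sidechain",
                                           "surface_carbon")), 0)
  expect_equal(solvation_energy(10, "excluded"), 0)
  expect_error(solvation_energy(1, "no_such_group"), "no sigma entry")
  expect_error(solvation_energy(c(1, 2), "hydrophobic_sidechain"),
               "aligned")
})

test_that("vdw energy vanishes beyond the cutoff and matches brute force", {
  xyz <- rbind(c(0.3, 0.2, 3.1), c(1.1, 0.9, 4.0), c(0.7, 1.6, 5.2))
  toy <- toy_structure(xyz)
  s <- build_graphene(14, 14)
  far <- rigid_pose(c(0, 0, 30))
  expect_equal(vdw_energy(toy, far, s, cutoff = 10), 0)

  # brute-force image sum: replicate the finite lattice over images and
  # accumulate pairwise 12-6 terms within the cutoff
  cutoff <- 10
  surf_xy <- as.matrix(s$atoms[, c("x", "y")])
  images <- expand.grid(i = -1:1, j = -1:1)
  brute <- 0
  for (m in seq_len(nrow(images))) {
    img <- sweep(surf_xy, 2,
                 images$i[m] * s$box_a[1:2] + images$j[m] * s$box_b[1:2],
                 "+")
    for (a in seq_len(nrow(xyz))) {
      d <- sqrt(rowSums(sweep(img, 2, xyz[a, 1:2])^2) + xyz[a, 3]^2)
      keep <- d <= cutoff
      if (any(keep)) {
        brute <- brute + sum(lj_pair_energy(
          d[keep], toy$atoms$eps[a], 0.29288,
          toy$atoms$rmin_half[a], 1.9924))
      }
    }
  }
  got <- vdw_energy(toy, rigid_pose(), s, cutoff = cutoff)
  expect_equal(got, brute, tolerance = 1e-9)
})

test_that("energy is invariant under lattice-vector translations", {
  h <- build_alpha_helix("LKLA")
  s <- graphene_for_protein(h, margin = 12)
  p0 <- start_pose(h, height = 2.5)
  e0 <- total_energy(h, p0, s)
  for (shift in list(s$box_a, s$box_b, 2 * s$box_a - s$box_b)) {
    p1 <- rigid_pose(p0$translation + shift, p0$rotation)
    e1 <- total_energy(h, p1, s)
    expect_equal(e1$total, e0$total, tolerance = 1e-9)
    expect_equal(e1$vdw, e0$vdw, tolerance = 1e-9)
  }
})

test_that("energy respects the lattice point symmetry", {
  xyz <- rbind(c(0, 0, 3.0), c(1.2, 0.4, 3.8), c(0.5, 1.1, 4.6))
  toy <- toy_structure(xyz)
  s <- build_graphene(16, 16)
  e0 <- total_energy(toy, rigid_pose(), s)
  ctr <- toy$reference_centroid
  b <- s$bond_length
  # the honeycomb has threefold symmetry about an atom and sixfold about a
  # hexagon centre; a rigid rotation of the pose about either axis leaves
  # the energy unchanged
  cases <- list(list(p = c(0, 0, 0), ang = 120),
                list(p = c(sqrt(3) * b / 2, b / 2, 0), ang = 60))
  for (cs in cases) {
    q <- quat_z(cs$ang)
    R <- surfmc:::.quat_rotmat(q)
    t_eq <- (cs$p - as.numeric(R %*% cs$p)) -
      (ctr - as.numeric(R %*% ctr))
    e1 <- total_energy(toy, rigid_pose(t_eq, q), s)
    # the lattice sum is exactly symmetric; the solvation term is
    # symmetric to within the area quantum of the point-sampled SASA
    expect_equal(e1$vdw, e0$vdw, tolerance = 1e-9)
    quantum <- 4 * pi * 3.1^2 / 240 * 0.01 * 100  # one point, sigma 100/nm2
    expect_lt(abs(e1$total - e0$total), 3 * quantum)
  }
})

test_that("total energy components: additivity at separation, sign
           property, determinism", {
  h <- build_alpha_helix(lk_alpha14_sequence)
  s <- graphene_for_protein(h)
  far <- start_pose(h, height = 30)
  efar <- total_energy(h, far, s)
  expect_equal(efar$vdw, 0)
  # far from the surface the solvation term is the protein-alone term
  # (areas in nm^2 under the default convention)
  alone <- solvation_energy(sasa(h, 1.4, 240) / 100, h$atoms$group)
  expect_equal(efar$solvation, alone, tolerance = 1e-9)
  expect_equal(efar$total, efar$vdw + efar$solvation)

  # burying the hydrophobic face is better than burying the hydrophilic one
  eL <- total_energy(h, face_down_pose(h, "LEU", height = 3), s)
  eK <- total_energy(h, face_down_pose(h, "LYS", height = 3), s)
  expect_lt(eL$total, eK$total)
  # and adsorbing leucines-down beats floating free
  expect_lt(eL$total, efar$total)

  # bit-identical re-evaluation
  again <- total_energy(h, face_down_pose(h, "LEU", height = 3), s)
  expect_identical(again$total, eL$total)
})

test_that("solvation responds to area unit convention", {
  h <- build_alpha_helix("LKLA")
  s <- graphene_for_protein(h, margin = 12)
  pose <- start_pose(h, height = 3)
  e_nm <- total_energy(h, pose, s, energy_config(area_unit = "nm2"))
  e_a2 <- total_energy(h, pose, s, energy_config(area_unit = "A2"))
  expect_equal(e_a2$solvation, 100 * e_nm$solvation, tolerance = 1e-9)
  expect_equal(e_a2$vdw, e_nm$vdw)
})
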