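test_that("orientation angles follow the axis geometry", {
  # an elongated flat slab along x: axis1 = x, axis2 = y
  grid <- expand.grid(x = seq(0, 12, 1.5), y = seq(0, 4, 1), z = c(0, 0.5))
  slab <- toy_structure(as.matrix(grid))
  ang0 <- orientation_angles(slab, rigid_pose())
  expect_equal(ang0$phi, 90, tolerance = 1e-6)
  expect_equal(ang0$psi, 90, tolerance = 1e-6)
  # rotate the long axis onto z
  up <- orientation_angles(slab, rigid_pose(rotation = rot_of(c(0, 1, 0),
                                                              90)))
  expect_equal(up$phi, 0, tolerance = 1e-6)
  expect_equal(up$psi, 90, tolerance = 1e-6)
  # tilt by a known angle
  tilt <- orientation_angles(slab, rigid_pose(rotation = rot_of(c(0, 1, 0),
                                                                30)))
  expect_equal(tilt$phi, 60, tolerance = 1e-6)
})

test_that("free-energy maps conserve counts and log-ratios", {
  orient <- data.frame(phi = c(rep(85, 100), rep(15, 10)),
                       psi = c(rep(115, 100), rep(45, 10)))
  fe <- free_energy_map(orient, temperature = 300, bin_width = 10)
  expect_equal(sum(fe$counts), 110)
  # Delta G between the 100- and 10-count bins
  g1 <- fe$G[9, 12]   # phi 80-90, psi 110-120
  g2 <- fe$G[2, 5]    # phi 10-20, psi 40-50
  expect_equal(g2 - g1, kB * 300 * log(10), tolerance = 1e-12)
  # argmin of G is argmax of counts; empty bins are masked
  expect_equal(which.max(fe$counts), which.min(replace(fe$G, is.na(fe$G),
                                                       Inf)))
  expect_equal(sum(!is.na(fe$G)), 2)
  expect_error(free_energy_map(orient, bin_width = 7), "divide")
})

test_that("temperature scales the free-energy map", {
  orient <- data.frame(phi = c(rep(85, 50), rep(15, 5)),
                       psi = c(rep(115, 50), rep(45, 5)))
  fe150 <- free_energy_map(orient, temperature = 150)
  fe300 <- free_energy_map(orient, temperature = 300)
  d150 <- diff(range(fe150$G, na.rm = TRUE))
  d300 <- diff(range(fe300$G, na.rm = TRUE))
  expect_equal(d300, 2 * d150, tolerance = 1e-12)
})

test_that("minima detection finds basins, honors ties, ignores flat maps", {
  mk <- function(phi, psi, n) data.frame(phi = rep(phi, n),
                                         psi = rep(psi, n))
  # single basin with shallow background
  one <- rbind(mk(85, 115, 200), mk(45, 45, 6), mk(125, 65, 6),
               mk(25, 155, 6), mk(155, 25, 6))
  m1 <- find_minima(free_energy_map(one))
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$phi_lo, m1$psi_lo), c(80, 110))

  # two equal basins: lexicographic (phi, psi) tie-break
  two <- rbind(mk(85, 115, 200), mk(105, 75, 200), mk(45, 45, 6),
               mk(25, 155, 6), mk(155, 25, 6), mk(125, 135, 6))
  m2 <- find_minima(free_energy_map(two))
  expect_equal(nrow(m2), 2)
  expect_equal(m2$phi_lo, c(80, 100))

  # flat map: no minimum exceeds any positive depth threshold
  flat <- rbind(mk(15, 15, 10), mk(55, 55, 10), mk(95, 95, 10),
                mk(135, 135, 10))
  expect_equal(nrow(find_minima(free_energy_map(flat),
                                depth_threshold = 0.1)), 0)
})

test_that("contact profiles count adsorbed frames per residue", {
  h <- build_alpha_helix("LKLK")
  s <- graphene_for_protein(h, margin = 12)
  # hand-built poses: two adsorbed flat, one adsorbed tilted, one far away
  flat <- face_down_pose(h, "LEU", height = 2.5)
  far <- start_pose(h, height = 50)
  poses <- rbind(
    c(flat$translation, flat$rotation),
    c(flat$translation, flat$rotation),
    c(far$translation, far$rotation)
  )
  colnames(poses) <- c("tx", "ty", "tz", "qw", "qx", "qy", "qz")
  tr <- fake_trajectory(rep(1, 3), poses = poses, protein = h, surface = s)
  prof <- contact_profile(tr, cutoff = 6)
  expect_equal(attr(prof, "denominator"), 2)  # the far frame is excluded
  expect_true(all(prof$ratio >= 0 & prof$ratio <= 1))
  expect_equal(nrow(prof), 4)

  # monotone in the cutoff
  prof7 <- contact_profile(tr, cutoff = 7)
  expect_true(all(prof7$ratio >= prof$ratio - 1e-12))

  # all-far trajectories are an error
  allfar <- fake_trajectory(rep(1, 2),
                            poses = poses[c(3, 3), , drop = FALSE],
                            protein = h, surface = s)
  expect_error(contact_profile(allfar, cutoff = 6), "no adsorbed frames")
})

test_that("relative rotation recovers constructed twists", {
  h <- build_alpha_helix(lk_alpha14_sequence)
  pa <- principal_axes(h)
  p0 <- rigid_pose(rotation = rot_of(c(1, 1, 0), 25))
  same <- relative_rotation(p0, p0, pa)
  expect_equal(same$total_angle, 0, tolerance = 1e-9)
  expect_equal(same$angle_about_axis2, 0, tolerance = 1e-9)

  q180 <- surfmc:::.quat_normalize(
    surfmc:::.quat_mult(rot_of(pa$axes[, 2], 180), p0$rotation))
  p1 <- rigid_pose(rotation = q180)
  flip <- relative_rotation(p0, p1, pa)
  expect_equal(flip$angle_about_axis2, 180, tolerance = 1e-6)
  expect_equal(flip$total_angle, 180, tolerance = 1e-6)
  # symmetry in the argument order
  rev <- relative_rotation(p1, p0, pa)
  expect_equal(rev$angle_about_axis2, flip$angle_about_axis2,
               tolerance = 1e-9)

  q70 <- surfmc:::.quat_normalize(
    surfmc:::.quat_mult(rot_of(pa$axes[, 2], 70), p0$rotation))
  part <- relative_rotation(p0, rigid_pose(rotation = q70), pa)
  expect_equal(part$angle_about_axis2, 70, tolerance = 1e-6)
})

test_that("merged trajectories pool frames for analysis", {
  h <- build_alpha_helix("LKLK")
  s <- graphene_for_protein(h, margin = 12)
  t1 <- run_mc(h, s, mc_config(target_accepted_moves = 10, seed = 1),
               initial_pose = start_pose(h, height = 4))
  t2 <- run_mc(h, s, mc_config(target_accepted_moves = 15, seed = 2),
               initial_pose = start_pose(h, height = 4))
  merged <- merge_trajectories(list(t1, t2))
  expect_equal(nrow(merged$frames), 25)
  fe <- free_energy_map(merged$frames)
  expect_equal(sum(fe$counts), 25)
})
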