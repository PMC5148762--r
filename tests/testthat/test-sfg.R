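# two-site helper: parallel dipoles at a set separation, built by hand so
# closed-form exciton results are available
two_site_system <- function(sep = 4, J = NULL, freq = 1650) {
  pos <- rbind(c(0, 0, 0), c(sep, 0, 0))
  mu <- rbind(c(0, 0, 1), c(0, 0, 1))
  raman <- array(0, c(3, 3, 2))
  for (s in 1:2) raman[, , s] <- diag(3) + 2 * tcrossprod(mu[s, ])
  sys <- structure(list(positions = pos, dipoles = mu, raman = raman,
                        site_freq = rep(freq, 2), n_sites = 2),
                   class = "amide_system")
  sys$hamiltonian <- amide_hamiltonian(sys)
  if (!is.null(J)) {
    sys$hamiltonian[1, 2] <- sys$hamiltonian[2, 1] <- J
  }
  sys
}

test_that("amide sites count one per peptide bond", {
  h4 <- build_alpha_helix("AAAA")
  sys <- build_amide_sites(h4)
  expect_equal(sys$n_sites, 3)
  expect_equal(dim(sys$hamiltonian), c(3, 3))
  expect_equal(diag(sys$hamiltonian), rep(1650, 3))
  h14 <- build_alpha_helix(lk_alpha14_sequence)
  expect_equal(build_amide_sites(h14)$n_sites, 13)
})

test_that("site dipoles are translation-invariant and rotation-equivariant", {
  h <- build_alpha_helix("AKLA")
  s0 <- build_amide_sites(h)
  s_t <- build_amide_sites(h, rigid_pose(c(5, -3, 8)))
  expect_equal(s_t$dipoles, s0$dipoles, tolerance = 1e-9)
  expect_equal(s_t$positions, sweep(s0$positions, 2, c(5, -3, 8), "+"),
               tolerance = 1e-9)
  q <- rot_of(c(1, 2, 0.5), 65)
  R <- surfmc:::.quat_rotmat(q)
  s_r <- build_amide_sites(h, rigid_pose(rotation = q))
  expect_equal(s_r$dipoles, s0$dipoles %*% t(R), tolerance = 1e-9)
})

test_that("missing backbone atoms are reported by residue", {
  h <- build_alpha_helix("AAAA")
  h$atoms <- h$atoms[!(h$atoms$resid == 2 & h$atoms$name == "O"), ]
  expect_error(build_amide_sites(h), "residue 2")
})

test_that("transition dipole coupling follows the dipole-dipole form", {
  mu_z <- c(0, 0, 1)
  # side-by-side parallel dipoles (mu perpendicular to r): positive J
  side <- tdc_coupling(c(0, 0, 0), c(4, 0, 0), mu_z, mu_z)
  expect_gt(side, 0)
  # in-line parallel dipoles: negative and twice the magnitude
  inline <- tdc_coupling(c(0, 0, 0), c(0, 0, 4), mu_z, mu_z)
  expect_lt(inline, 0)
  expect_equal(inline / side, -2, tolerance = 1e-12)
  # 1/r^3 scaling
  expect_equal(tdc_coupling(c(0, 0, 0), c(8, 0, 0), mu_z, mu_z),
               side / 8, tolerance = 1e-12)
  # orthogonal dipoles both perpendicular to r couple to zero
  expect_equal(tdc_coupling(c(0, 0, 0), c(4, 0, 0), c(0, 1, 0), mu_z), 0)
  expect_error(tdc_coupling(c(0, 0, 0), c(0, 0, 0), mu_z, mu_z),
               "coincident")
})

test_that("the exciton Hamiltonian is symmetric and trace-preserving", {
  h <- build_alpha_helix(lk_alpha14_sequence)
  sys <- build_amide_sites(h)
  H <- sys$hamiltonian
  expect_equal(H, t(H))
  ev <- eigen(H, symmetric = TRUE)$values
  expect_true(all(abs(Im(ev)) == 0))
  expect_equal(sum(ev), sum(sys$site_freq), tolerance = 1e-9)
  # a nearest-neighbor coupling plug-in overrides sequential pairs only
  H2 <- amide_hamiltonian(sys, nn_coupling = function(i, j, system) -7.5)
  expect_true(all(abs(diag(H2[-1, ]) + 7.5) < 1e-12))
  expect_equal(H2[1, 3], H[1, 3])
})

test_that("a single uncoupled site yields one Lorentzian at its frequency", {
  h <- build_alpha_helix("AAAA")  # take one site from a real geometry
  sys <- build_amide_sites(h)
  one <- structure(list(positions = sys$positions[1, , drop = FALSE],
                        dipoles = sys$dipoles[1, , drop = FALSE],
                        raman = sys$raman[, , 1, drop = FALSE],
                        site_freq = 1650, n_sites = 1),
                   class = "amide_system")
  one$hamiltonian <- matrix(1650, 1, 1)
  sp <- compute_spectrum(one, "ssp", background_amplitude = 0,
                         linewidth = 8)
  expect_equal(sp$wavenumber[which.max(sp$intensity)], 1650, tolerance = 1)
  # half-width at half-maximum of |chi|^2 equals the linewidth
  half <- max(sp$intensity) / 2
  span <- range(sp$wavenumber[sp$intensity >= half])
  expect_equal(diff(span), 2 * 8, tolerance = 2)
})

test_that("two coupled parallel sites split into bright and dark modes", {
  J <- 12
  sys <- two_site_system(sep = 4, J = J)
  sp <- compute_spectrum(sys, "ssp", background_amplitude = 0,
                         linewidth = 4, grid = seq(1550, 1750, 0.5))
  # eigenfrequencies 1650 +/- J; the symmetric (bright) mode carries the
  # intensity for parallel dipoles
  i_plus <- sp$intensity[sp$wavenumber == 1650 + J]
  i_minus <- sp$intensity[sp$wavenumber == 1650 - J]
  expect_gt(i_plus, 20 * i_minus)
  expect_equal(sp$wavenumber[which.max(sp$intensity)], 1650 + J,
               tolerance = 1)
})

test_that("background phase defaults and empty systems", {
  empty <- structure(list(positions = matrix(0, 0, 3),
                          dipoles = matrix(0, 0, 3),
                          raman = array(0, c(3, 3, 0)),
                          site_freq = numeric(0), n_sites = 0,
                          hamiltonian = matrix(0, 0, 0)),
                     class = "amide_system")
  ssp <- compute_spectrum(empty, "ssp", background_amplitude = 2)
  ppp <- compute_spectrum(empty, "ppp", background_amplitude = 2)
  expect_equal(ssp$background_phase, 3.5)
  expect_equal(ppp$background_phase, 1.5)
  expect_true(all(ssp$intensity == 4))
  expect_true(all(ppp$intensity == 4))
})

test_that("spectra are invariant to the azimuthal placement of the protein", {
  h <- build_alpha_helix("LKLAK")
  pose <- rigid_pose(rotation = rot_of(c(1, 0.3, 0.2), 40))
  sp0 <- compute_spectrum(build_amide_sites(h, pose), "ppp")
  qz <- surfmc:::.quat_normalize(surfmc:::.quat_mult(quat_z(77),
                                                     pose$rotation))
  sp1 <- compute_spectrum(build_amide_sites(h, rigid_pose(rotation = qz)),
                          "ppp")
  expect_equal(sp1$intensity, sp0$intensity, tolerance = 0.02)
})

test_that("coherent mixing adds amplitudes, not intensities", {
  sysA <- two_site_system(sep = 4, J = 10)
  sysB <- two_site_system(sep = 4, J = -10)
  a <- compute_spectrum(sysA, "ssp", linewidth = 6)
  b <- compute_spectrum(sysB, "ssp", linewidth = 6)
  mix <- mix_spectra(list(a, b), c(0.5, 0.5))
  # identity at weight 1
  expect_equal(mix_spectra(list(a, b), c(1, 0))$intensity, a$intensity)
  # mixing identical spectra is idempotent
  expect_equal(mix_spectra(list(a, a), c(0.5, 0.5))$intensity, a$intensity)
  # the coherent mixture differs from any incoherent average
  incoherent <- 0.5 * a$intensity + 0.5 * b$intensity
  expect_gt(max(abs(mix$intensity - incoherent)), 1e-4)
  # exact cancellation of opposite-phase responses
  flipA <- a
  flipA$chi2 <- -a$chi2
  bg0_a <- a; bg0_a$background_amplitude <- 0
  bg0_f <- flipA; bg0_f$background_amplitude <- 0
  z <- mix_spectra(list(bg0_a, bg0_f), c(0.5, 0.5))
  expect_true(all(abs(z$intensity) < 1e-20))
  expect_error(mix_spectra(list(a, b), c(0.7, 0.6)), "sum to 1")
  short <- a
  short$wavenumber <- a$wavenumber[-1]
  expect_error(mix_spectra(list(a, short), c(0.5, 0.5)), "grids")
})
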