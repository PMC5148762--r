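# Amide-I exciton SFG spectra: site construction from backbone geometry,
# transition-dipole couplings, Hamiltonian diagonalization, and coherent
# ssp/ppp response with a fixed nonresonant background phase.

#' Build amide-I exciton sites from a posed structure
#'
#' Places one vibrational site per peptide bond: the chromophore sits at
#' the C=O midpoint, the transition dipole lies in the O=C-N plane tilted
#' from the C=O bond toward the nitrogen, and an axially symmetric Raman
#' tensor is aligned with the dipole. All sites share the amide-I site
#' frequency.
#'
#' @param protein a `mol_structure` with backbone atoms N, CA, C, O.
#' @param pose optional `rigid_pose`; `NULL` uses reference coordinates.
#' @param site_frequency site frequency in cm^-1 (default 1650).
#' @param dipole_tilt tilt of the dipole from the C=O direction toward N,
#'   degrees (default 20).
#' @param dipole_magnitude transition dipole magnitude, arbitrary units.
#' @param raman_anisotropy ratio of the Raman tensor component along the
#'   dipole to the perpendicular components (default 3).
#' @return an `amide_system`: `positions`, `dipoles` (rows scaled by
#'   magnitude), `raman` (3x3xN array), `site_freq`, and a coupling matrix
#'   filled with transition-dipole couplings.
#' @export
build_amide_sites <- function(protein, pose = NULL, site_frequency = 1650,
                              dipole_tilt = 20, dipole_magnitude = 1,
                              raman_anisotropy = 3) {
  xyz <- coords(protein)
  if (!is.null(pose)) {
    xyz <- apply_pose(xyz, pose, protein$reference_centroid)
  }
  at <- protein$atoms
  res_ids <- sort(unique(at$resid))
  n_sites <- length(res_ids) - 1
  if (n_sites < 0) stop("structure has no residues")
  pick <- function(rid, nm) {
    i <- which(at$resid == rid & at$name == nm)
    if (length(i) != 1) {
      stop("missing backbone atom ", nm, " in residue ", rid)
    }
    xyz[i, ]
  }
  pos <- mu <- matrix(NA_real_, max(n_sites, 0), 3)
  raman <- array(NA_real_, c(3, 3, max(n_sites, 0)))
  tilt <- dipole_tilt * pi / 180
  for (s in seq_len(n_sites)) {
    Cc <- pick(res_ids[s], "C")
    Oo <- pick(res_ids[s], "O")
    Nn <- pick(res_ids[s + 1], "N")
    u <- .unit(Oo - Cc)
    w <- Nn - Cc
    p <- w - sum(w * u) * u
    if (sqrt(sum(p^2)) < 1e-9) stop("degenerate amide plane at residue ",
                                    res_ids[s])
    p <- .unit(p)
    d <- cos(tilt) * u + sin(tilt) * p
    pos[s, ] <- (Cc + Oo) / 2
    mu[s, ] <- dipole_magnitude * d
    raman[, , s] <- diag(3) + (raman_anisotropy - 1) * tcrossprod(d)
  }
  sys <- structure(
    list(positions = pos, dipoles = mu, raman = raman,
         site_freq = rep(site_frequency, n_sites), n_sites = n_sites),
    class = "amide_system"
  )
  sys$hamiltonian <- amide_hamiltonian(sys)
  sys
}

#' Transition dipole coupling between two sites
#'
#' Coulomb-like dipole-dipole coupling
#' \eqn{J = \kappa [\mu_i \cdot \mu_j - 3 (\mu_i \cdot \hat r)(\mu_j \cdot
#' \hat r)] / r^3}.
#'
#' @param pos_i,pos_j site positions, Angstrom.
#' @param mu_i,mu_j transition dipole vectors (magnitude included).
#' @param kappa prefactor in cm^-1 Angstrom^3 per unit dipole^2
#'   (default 5034).
#' @return coupling in cm^-1.
#' @export
tdc_coupling <- function(pos_i, pos_j, mu_i, mu_j, kappa = 5034) {
  r <- pos_j - pos_i
  d <- sqrt(sum(r^2))
  if (d < 1e-9) stop("coincident amide sites")
  rh <- r / d
  kappa * (sum(mu_i * mu_j) - 3 * sum(mu_i * rh) * sum(mu_j * rh)) / d^3
}

#' Exciton Hamiltonian of an amide system
#'
#' Site frequencies on the diagonal; transition-dipole couplings off the
#' diagonal for every pair. A nearest-neighbor coupling function (e.g. a
#' dihedral-binned ab initio map) may replace the TDC value for sequential
#' neighbors.
#'
#' @param system an `amide_system`.
#' @param kappa TDC prefactor, cm^-1 Angstrom^3.
#' @param nn_coupling optional `function(i, j, system)` returning the
#'   coupling in cm^-1 for nearest-neighbor pairs (|i - j| == 1).
#' @return symmetric matrix, cm^-1.
#' @export
amide_hamiltonian <- function(system, kappa = 5034, nn_coupling = NULL) {
  n <- system$n_sites
  H <- diag(system$site_freq, n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        J <- if (!is.null(nn_coupling) && j - i == 1) {
          nn_coupling(i, j, system)
        } else {
          tdc_coupling(system$positions[i, ], system$positions[j, ],
                       system$dipoles[i, ], system$dipoles[j, ], kappa)
        }
        H[i, j] <- H[j, i] <- J
      }
    }
  }
  H
}

.default_bg_phase <- c(ssp = 3.5, ppp = 1.5)

#' Calculate an amide-I SFG spectrum
#'
#' Diagonalizes the exciton Hamiltonian; each eigenmode's IR dipole and
#' Raman tensor are the eigenvector-weighted sums over sites, and the
#' second-order response is their product. Lab-frame chi(2) elements are
#' azimuthally averaged about the surface normal (isotropic in-plane
#' monolayer) and combined for the ssp (xxz-type) or ppp polarization with
#' the beam geometry below; Fresnel factors are unity. Each mode carries a
#' complex Lorentzian lineshape, and the intensity includes a nonresonant
#' background of fixed phase.
#'
#' @param system an `amide_system` (or a list with a `hamiltonian`,
#'   `dipoles`, `raman`).
#' @param polarization `"ssp"` or `"ppp"`.
#' @param background_phase radians; default 3.5 (ssp) / 1.5 (ppp).
#' @param background_amplitude nonresonant amplitude, arbitrary units.
#' @param linewidth Lorentzian half-width, cm^-1 (> 0).
#' @param grid frequency grid, cm^-1.
#' @param beam_angles input angles of the visible and IR beams from the
#'   surface normal, degrees.
#' @param vis_wavenumber visible beam wavenumber, cm^-1 (532 nm).
#' @param n_azimuth points in the azimuthal average.
#' @return an `sfg_spectrum`: `wavenumber`, complex `chi2`, `intensity`,
#'   and the settings used.
#' @export
compute_spectrum <- function(system, polarization = c("ssp", "ppp"),
                             background_phase = NULL,
                             background_amplitude = 1, linewidth = 10,
                             grid = seq(1550, 1750, by = 1),
                             beam_angles = c(vis = 47, ir = 58),
                             vis_wavenumber = 18797, n_azimuth = 36) {
  polarization <- match.arg(polarization)
  stopifnot(linewidth > 0)
  if (is.null(background_phase)) {
    background_phase <- .default_bg_phase[[polarization]]
  }
  n <- system$n_sites
  chi <- complex(real = numeric(length(grid)),
                 imaginary = numeric(length(grid)))
  if (n > 0) {
    H <- system$hamiltonian
    if (max(abs(H - t(H))) > 1e-9) stop("non-symmetric Hamiltonian")
    ev <- eigen(H, symmetric = TRUE)
    thetas <- 2 * pi * (seq_len(n_azimuth) - 1) / n_azimuth
    # azimuthal rotations applied to each mode's dipole and Raman tensor
    for (m in seq_len(n)) {
      v <- ev$vectors[, m]
      mu_m <- drop(t(system$dipoles) %*% v)
      al_m <- matrix(0, 3, 3)
      for (s in seq_len(n)) al_m <- al_m + v[s] * system$raman[, , s]
      xxz <- xzx <- zxx <- zzz <- 0
      for (th in thetas) {
        ct <- cos(th); st <- sin(th)
        R <- matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3, 3, byrow = TRUE)
        mu_r <- drop(R %*% mu_m)
        al_r <- R %*% al_m %*% t(R)
        xxz <- xxz + al_r[1, 1] * mu_r[3]
        xzx <- xzx + al_r[1, 3] * mu_r[1]
        zxx <- zxx + al_r[3, 1] * mu_r[1]
        zzz <- zzz + al_r[3, 3] * mu_r[3]
      }
      xxz <- xxz / n_azimuth; xzx <- xzx / n_azimuth
      zxx <- zxx / n_azimuth; zzz <- zzz / n_azimuth
      A <- if (polarization == "ssp") {
        xxz
      } else {
        b_vis <- beam_angles[["vis"]] * pi / 180
        b_ir <- beam_angles[["ir"]] * pi / 180
        ir_wn <- mean(system$site_freq)
        sfg_wn <- vis_wavenumber + ir_wn
        s_sfg <- (vis_wavenumber * sin(b_vis) + ir_wn * sin(b_ir)) / sfg_wn
        b_sfg <- asin(min(1, s_sfg))
        -cos(b_sfg) * cos(b_vis) * sin(b_ir) * xxz -
          cos(b_sfg) * sin(b_vis) * cos(b_ir) * xzx +
          sin(b_sfg) * cos(b_vis) * cos(b_ir) * zxx +
          sin(b_sfg) * sin(b_vis) * sin(b_ir) * zzz
      }
      chi <- chi + A / complex(real = ev$values[m] - grid,
                               imaginary = -linewidth)
    }
  }
  bg <- background_amplitude * exp(1i * background_phase)
  structure(
    list(wavenumber = grid, chi2 = chi, intensity = Mod(chi + bg)^2,
         polarization = polarization, background_phase = background_phase,
         background_amplitude = background_amplitude,
         linewidth = linewidth),
    class = "sfg_spectrum"
  )
}

#' @export
print.sfg_spectrum <- function(x, ...) {
  pk <- x$wavenumber[which.max(x$intensity)]
  cat("SFG spectrum (", x$polarization, "): ",
      length(x$wavenumber), " points, background phase ",
      x$background_phase, " rad, intensity max near ", pk, " cm^-1\n",
      sep = "")
  invisible(x)
}

#' @export
plot.sfg_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumber, x$intensity, type = "l",
                 xlab = expression(wavenumber ~ (cm^-1)),
                 ylab = "SFG intensity (a.u.)", ...)
  invisible(x)
}

#' Coherent mixture of SFG spectra
#'
#' Orientations coexisting in one ordered monolayer interfere coherently:
#' the mixed response is the weighted sum of the complex chi(2) *before*
#' squaring, and the intensity is recomputed with the shared background.
#'
#' @param spectra list of `sfg_spectrum` objects on identical grids and
#'   polarization.
#' @param weights non-negative fractions summing to 1.
#' @return an `sfg_spectrum`.
#' @export
mix_spectra <- function(spectra, weights) {
  stopifnot(length(spectra) >= 1, length(weights) == length(spectra))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  ref <- spectra[[1]]
  for (s in spectra[-1]) {
    if (!identical(s$wavenumber, ref$wavenumber)) {
      stop("frequency grids do not match")
    }
    if (!identical(s$polarization, ref$polarization)) {
      stop("polarizations do not match")
    }
    if (s$background_phase != ref$background_phase ||
          s$background_amplitude != ref$background_amplitude) {
      stop("background settings do not match")
    }
  }
  chi <- Reduce(`+`, Map(function(s, w) w * s$chi2, spectra,
                         as.list(weights)))
  bg <- ref$background_amplitude * exp(1i * ref$background_phase)
  out <- ref
  out$chi2 <- chi
  out$intensity <- Mod(chi + bg)^2
  out
}

#' Write a spectrum as CSV
#'
#' @param spectrum an `sfg_spectrum`.
#' @param path output CSV path (wavenumber_cm1, re_chi2, im_chi2,
#'   intensity).
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "sfg_spectrum"))
  df <- data.frame(wavenumber_cm1 = spectrum$wavenumber,
                   re_chi2 = Re(spectrum$chi2),
                   im_chi2 = Im(spectrum$chi2),
                   intensity = spectrum$intensity)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
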