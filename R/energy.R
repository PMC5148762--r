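# Pose energy: Lennard-Jones protein-surface term plus sigma-weighted SASA
# nonpolar solvation.

#' Energy evaluation settings
#'
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param vdw_cutoff Lennard-Jones cutoff in Angstrom (default 10, plain
#'   truncation; only pose-to-pose differences matter).
#' @param sasa_points Shrake-Rupley test points per atom (default 240 for
#'   sampling; 960 for validation-grade areas).
#' @param sigma surface-tension table from [sigma_table()].
#' @param patch_margin extra patch radius beyond the protein bounding
#'   radius; `NULL` means the protein-to-surface occlusion reach.
#' @param area_unit areas the surface tensions multiply: `"nm2"` (default)
#'   applies the sigma table to SASA expressed in nm^2, matching the
#'   gromacs-based workflow the tension table was built for; `"A2"` applies
#'   it to Angstrom^2 areas (a 100-fold stronger solvation term).
#' @return list of settings, class `energy_config`.
#' @export
energy_config <- function(probe_radius = 1.4, vdw_cutoff = 10,
                          sasa_points = 240, sigma = sigma_table(),
                          patch_margin = NULL, area_unit = c("nm2", "A2")) {
  stopifnot(probe_radius >= 0, vdw_cutoff > 0, sasa_points >= 32)
  area_unit <- match.arg(area_unit)
  structure(list(probe_radius = probe_radius, vdw_cutoff = vdw_cutoff,
                 sasa_points = as.integer(sasa_points), sigma = sigma,
                 patch_margin = patch_margin, area_unit = area_unit),
            class = "energy_config")
}

#' Lennard-Jones 12-6 pair energy with CHARMM combining rules
#'
#' \eqn{E = \epsilon [(R_{min}/r)^{12} - 2 (R_{min}/r)^6]} with
#' \eqn{\epsilon = \sqrt{\epsilon_i \epsilon_j}} and
#' \eqn{R_{min} = R_{min,i}/2 + R_{min,j}/2}.
#'
#' @param r distance in Angstrom (> 0), vectorized.
#' @param eps_i,eps_j well depths, kJ/mol.
#' @param rmin_half_i,rmin_half_j Rmin/2 values, Angstrom.
#' @return energy in kJ/mol.
#' @export
lj_pair_energy <- function(r, eps_i, eps_j, rmin_half_i, rmin_half_j) {
  if (any(r <= 0)) stop("coincident atoms: r must be > 0")
  eps <- sqrt(eps_i * eps_j)
  rmin <- rmin_half_i + rmin_half_j
  s6 <- (rmin / r)^6
  eps * (s6^2 - 2 * s6)
}

.check_assigned <- function(protein) {
  if (anyNA(protein$atoms$group) || anyNA(protein$atoms$eps)) {
    stop("structure has unassigned groups/parameters; call assign_groups()")
  }
}

#' Protein-surface van der Waals energy
#'
#' Sums the 12-6 pair energy over all protein-surface atom pairs within the
#' cutoff, treating the lattice as infinite in the plane (equivalent to the
#' minimum-image sum for boxes at least twice the cutoff). Intramolecular
#' terms are constant for a rigid body and excluded.
#'
#' @param protein a `mol_structure` with parameters assigned.
#' @param pose a `rigid_pose`.
#' @param surface a `surface_model`.
#' @param cutoff cutoff distance in Angstrom.
#' @return energy in kJ/mol.
#' @export
vdw_energy <- function(protein, pose, surface, cutoff = 10) {
  .check_assigned(protein)
  stopifnot(cutoff > 0)
  xyz <- apply_pose(coords(protein), pose, protein$reference_centroid)
  .vdw_lattice(xyz, protein$atoms$eps, protein$atoms$rmin_half,
               .surface_lj[["eps"]], .surface_lj[["rmin_half"]],
               surface$bond_length, cutoff)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA from a deterministic golden-spiral point set on each
#' solvent-expanded sphere (radius + probe): the exposed-point fraction
#' times the sphere area. No randomness is involved.
#'
#' @param atoms a `mol_structure`, or a data.frame/matrix with columns
#'   x, y, z and a `radius` column (matrix input requires `radii`).
#' @param probe_radius probe radius in Angstrom.
#' @param n_points test points per atom (>= 32).
#' @param radii per-atom radii, required for plain coordinate input.
#' @return numeric vector of per-atom areas, Angstrom^2.
#' @export
sasa <- function(atoms, probe_radius = 1.4, n_points = 240, radii = NULL) {
  stopifnot(probe_radius >= 0, n_points >= 32)
  if (inherits(atoms, "mol_structure")) {
    xyz <- coords(atoms)
    radii <- atoms$atoms$radius
  } else if (is.data.frame(atoms)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (is.null(radii)) radii <- atoms$radius
  } else {
    xyz <- as.matrix(atoms)
  }
  if (is.null(radii) || anyNA(radii)) stop("per-atom radii are required")
  if (any(radii <= 0)) stop("radii must be positive")
  as.numeric(.shrake_rupley(xyz, radii, probe_radius, as.integer(n_points)))
}

#' Nonpolar solvation energy from areas and group labels
#'
#' \eqn{E_{solv} = \sum_i \sigma(group_i) \cdot SASA_i}. Atoms in the
#' `excluded` group contribute zero.
#'
#' @param areas per-atom SASA, Angstrom^2.
#' @param groups per-atom group labels, same length.
#' @param sigma table from [sigma_table()].
#' @return energy in kJ/mol.
#' @export
solvation_energy <- function(areas, groups, sigma = sigma_table()) {
  if (length(areas) != length(groups)) {
    stop("areas and groups must be aligned")
  }
  bad <- setdiff(unique(groups), names(sigma))
  if (length(bad)) {
    stop("no sigma entry for group(s): ", paste(bad, collapse = ", "))
  }
  sum(sigma[groups] * areas)
}

.patch_radius <- function(protein, config) {
  xyz <- coords(protein)
  ctr <- colMeans(xyz)
  rmax <- sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
  margin <- config$patch_margin
  if (is.null(margin)) {
    # protein-to-surface occlusion reach: every surface atom the protein
    # can shadow must be inside the patch
    margin <- max(protein$atoms$radius) + unname(.sasa_radii["C"]) +
      2 * config$probe_radius + 1
  }
  rmax + margin
}

#' Total pose energy: van der Waals plus nonpolar solvation
#'
#' SASA is evaluated over the posed protein together with a pose-anchored
#' circular surface patch centred on the protein xy centroid, sized from
#' the protein's orientation-independent bounding radius. The solvation
#' term is the sigma-weighted protein SASA plus, for each surface atom the
#' protein can occlude, the sigma-weighted change of its area relative to
#' the bare lattice: the infinite surface's own area is the energy zero,
#' so the surface contribution vanishes when the protein is far away and
#' the energy is a smooth function of the pose. Pose-to-pose differences
#' are unaffected by this choice of reference. With the default
#' `area_unit = "nm2"` the tension table multiplies areas in nm^2 (the
#' convention of the gromacs SASA workflow the table was designed around);
#' see [energy_config()].
#'
#' @param protein a `mol_structure` with groups assigned.
#' @param pose a `rigid_pose`.
#' @param surface a `surface_model`.
#' @param config an [energy_config()].
#' @return list with components `vdw`, `solvation`, `total` (kJ/mol),
#'   class `energy_components`.
#' @export
total_energy <- function(protein, pose, surface, config = energy_config()) {
  comp <- .pose_energy(protein, pose, surface, config,
                       cache = .energy_cache(protein, config))
  structure(list(vdw = comp[1], solvation = comp[2],
                 total = comp[1] + comp[2]),
            class = "energy_components")
}

# Pose-invariant precomputations: the body-fixed golden-spiral point set
# and the intramolecular burial mask of the rigid structure.
.energy_cache <- function(protein, config) {
  sigma <- config$sigma
  bad <- setdiff(unique(protein$atoms$group), names(sigma))
  if (length(bad)) {
    stop("no sigma entry for group(s): ", paste(bad, collapse = ", "))
  }
  scale <- if (config$area_unit == "nm2") 0.01 else 1
  sigma_atom <- unname(sigma[protein$atoms$group]) * scale
  solv_off <- all(sigma_atom == 0) && sigma[["surface_carbon"]] == 0
  if (solv_off) {
    return(list(solv_off = TRUE, sigma_atom = sigma_atom))
  }
  list(
    solv_off = FALSE, sigma_atom = sigma_atom, sigma_scale = scale,
    ref_coords = coords(protein),
    base_points = .sphere_point_set(config$sasa_points),
    mask = .burial_mask(coords(protein), protein$atoms$radius,
                        config$probe_radius, config$sasa_points),
    patch_radius = .patch_radius(protein, config)
  )
}

.pose_energy <- function(protein, pose, surface, config, cache) {
  .check_assigned(protein)
  if (cache$solv_off) {
    xyz <- apply_pose(coords(protein), pose, protein$reference_centroid)
    vdw <- .vdw_lattice(xyz, protein$atoms$eps, protein$atoms$rmin_half,
                        .surface_lj[["eps"]], .surface_lj[["rmin_half"]],
                        surface$bond_length, config$vdw_cutoff)
    return(c(vdw, 0))
  }
  .total_energy_posed(
    cache$ref_coords, cache$base_points, protein$reference_centroid,
    pose$translation, pose$rotation, cache$mask,
    protein$atoms$eps, protein$atoms$rmin_half,
    protein$atoms$radius, cache$sigma_atom,
    .surface_lj[["eps"]], .surface_lj[["rmin_half"]],
    unname(.sasa_radii["C"]), config$sigma[["surface_carbon"]] *
      cache$sigma_scale,
    surface$bond_length, config$vdw_cutoff, config$probe_radius,
    cache$patch_radius
  )
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf("Energy (kJ/mol): total %.3f = vdw %.3f + solvation %.3f\n",
              x$total, x$vdw, x$solvation))
  invisible(x)
}
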