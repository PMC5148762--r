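# Shared fixtures: all synthetic structures are built in code at test time.

# a bare structure from raw coordinates with uniform carbon parameters and
# a single group label; bypasses PDB reading for geometric tests
toy_structure <- function(xyz, group = "hydrophobic_sidechain",
                          radius = 1.7, eps = 0.29288, rmin_half = 1.9924,
                          element = "C") {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), name = paste0("C", seq_len(n)), element = element,
    resname = "ALA", resid = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    eps = eps, rmin_half = rmin_half, radius = radius,
    group = group, stringsAsFactors = FALSE
  )
  surfmc:::.mol_structure(atoms)
}

# one-residue alanine PDB text (heavy atoms only, 5 atoms + duplicates to
# reach 10 records across two conformer-like entries is unnecessary; plain
# 5-atom residue plus a second residue gives parser coverage)
write_ala_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  ALA A   2       3.984   2.837   0.000  1.00  0.00           C",
    "ATOM      8  C   ALA A   2       5.497   2.705   0.000  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       6.040   1.601   0.000  1.00  0.00           O",
    "ATOM     10  CB  ALA A   2       3.513   3.683   1.199  1.00  0.00           C",
    "END"
  )
  writeLines(lines, path)
  path
}

# fake trajectory with hand-set frames/poses for escape and contact tests
fake_trajectory <- function(min_dist, poses = NULL, protein = NULL,
                            surface = NULL, config = mc_config()) {
  n <- length(min_dist)
  frames <- data.frame(
    accepted = seq_len(n), e_vdw = 0, e_solv = 0, e_total = 0,
    min_dist = min_dist, phi = 90, psi = 90, proposals = seq_len(n)
  )
  if (is.null(poses)) {
    poses <- cbind(tx = 0, ty = 0, tz = min_dist, qw = 1, qx = 0, qy = 0,
                   qz = 0)
  }
  structure(list(frames = frames, poses = poses, config = config,
                 protein = protein, surface = surface),
            class = "mc_trajectory")
}

quat_z <- function(angle_deg) {
  surfmc:::.quat_from_axis_angle(c(0, 0, 1), angle_deg)
}

rot_of <- function(axis, angle_deg) {
  surfmc:::.quat_from_axis_angle(axis, angle_deg)
}
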