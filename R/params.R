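# Packaged parameter tables: solvation surface tensions, per-element SASA
# radii and Lennard-Jones parameters, residue classification, and the
# idealized sidechain geometry used by the helix fixture builder.

#' Solvation surface-tension table
#'
#' Surface tension \eqn{\sigma} in kJ/(mol \eqn{\AA^2}) applied to the SASA
#' of each atom group to form the nonpolar solvation energy. Positive values
#' penalize solvent exposure (hydrophobic groups), negative values reward it
#' (hydrophilic groups). The `excluded` group contributes nothing.
#'
#' @param overrides named numeric vector of per-group replacements.
#' @return named numeric vector over the group labels.
#' @export
sigma_table <- function(overrides = NULL) {
  sigma <- c(
    hydrophobic_sidechain = 100,
    hydrophilic_sidechain = -100,
    hydrophobic_backbone = 100,
    hydrophilic_backbone = -100,
    surface_carbon = 100,
    excluded = 0
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(sigma))
    if (length(bad)) {
      stop("unknown sigma group(s): ", paste(bad, collapse = ", "))
    }
    sigma[names(overrides)] <- overrides
  }
  sigma
}

# united-atom van der Waals radii used for SASA, by element
.sasa_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# representative CHARMM-type LJ parameters by element (kJ/mol, Angstrom);
# the aromatic-carbon entry is used for graphene lattice atoms
.lj_defaults <- data.frame(
  element = c("C", "N", "O", "S"),
  eps = c(0.29288, 0.83680, 0.50208, 1.88280),
  rmin_half = c(1.9924, 1.8500, 1.7000, 2.0000),
  stringsAsFactors = FALSE
)
.surface_lj <- c(eps = 0.29288, rmin_half = 1.9924)

.hydrophobic_res <- c("GLY", "ALA", "VAL", "LEU", "ILE", "MET", "PRO",
                      "PHE", "TRP")
.hydrophilic_res <- c("SER", "THR", "ASN", "GLN", "CYS", "ARG", "ASP",
                      "HIS", "LYS", "GLU")

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Leucine-lysine amphipathic 14-mer benchmark sequence
#'
#' The alternating leucine/lysine sequence whose ideal \eqn{\alpha}-helix
#' places all leucines on one helical face and all lysines on the other.
#' @export
lk_alpha14_sequence <- "LKKLLKLLKKLLKL"

# idealized sidechain topology: per heavy atom, its extension level past CB
# (level 0 = CB itself) and branch offset (-1, 0, +1) perpendicular to the
# radial sidechain direction. Geometry is schematic but preserves element
# identity, reach and branching, which is what the SASA/LJ terms see.
.sidechain_topology <- list(
  ALA = list(c("CB", 0, 0)),
  ARG = list(c("CB", 0, 0), c("CG", 1, 0), c("CD", 2, 0), c("NE", 3, 0),
             c("CZ", 4, 0), c("NH1", 5, 1), c("NH2", 5, -1)),
  ASN = list(c("CB", 0, 0), c("CG", 1, 0), c("OD1", 2, 1), c("ND2", 2, -1)),
  ASP = list(c("CB", 0, 0), c("CG", 1, 0), c("OD1", 2, 1), c("OD2", 2, -1)),
  CYS = list(c("CB", 0, 0), c("SG", 1, 0)),
  GLN = list(c("CB", 0, 0), c("CG", 1, 0), c("CD", 2, 0), c("OE1", 3, 1),
             c("NE2", 3, -1)),
  GLU = list(c("CB", 0, 0), c("CG", 1, 0), c("CD", 2, 0), c("OE1", 3, 1),
             c("OE2", 3, -1)),
  GLY = list(),
  HIS = list(c("CB", 0, 0), c("CG", 1, 0), c("ND1", 2, 1), c("CD2", 2, -1),
             c("CE1", 3, 1), c("NE2", 3, -1)),
  ILE = list(c("CB", 0, 0), c("CG1", 1, 1), c("CG2", 1, -1), c("CD1", 2, 1)),
  LEU = list(c("CB", 0, 0), c("CG", 1, 0), c("CD1", 2, 1), c("CD2", 2, -1)),
  LYS = list(c("CB", 0, 0), c("CG", 1, 0), c("CD", 2, 0), c("CE", 3, 0),
             c("NZ", 4, 0)),
  MET = list(c("CB", 0, 0), c("CG", 1, 0), c("SD", 2, 0), c("CE", 3, 0)),
  PHE = list(c("CB", 0, 0), c("CG", 1, 0), c("CD1", 2, 1), c("CD2", 2, -1),
             c("CE1", 3, 1), c("CE2", 3, -1), c("CZ", 4, 0)),
  PRO = list(c("CB", 0, 0), c("CG", 1, 0), c("CD", 2, 0)),
  SER = list(c("CB", 0, 0), c("OG", 1, 0)),
  THR = list(c("CB", 0, 0), c("OG1", 1, 1), c("CG2", 1, -1)),
  TRP = list(c("CB", 0, 0), c("CG", 1, 0), c("CD1", 2, 1), c("CD2", 2, -1),
             c("NE1", 3, 1), c("CE2", 3, -1), c("CE3", 3, 0),
             c("CZ2", 4, -1), c("CZ3", 4, 1), c("CH2", 5, 0)),
  TYR = list(c("CB", 0, 0), c("CG", 1, 0), c("CD1", 2, 1), c("CD2", 2, -1),
             c("CE1", 3, 1), c("CE2", 3, -1), c("CZ", 4, 0), c("OH", 5, 0)),
  VAL = list(c("CB", 0, 0), c("CG1", 1, 1), c("CG2", 1, -1))
)

# Tyr ring carbons (hydrophobic); its hydroxyl oxygen is hydrophilic
.tyr_ring <- c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")

.element_from_name <- function(name) {
  first <- substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)), 1, 1)
  toupper(first)
}

#' Read a parameter override table
#'
#' Reads a TSV with columns `residue`, `atom`, `epsilon_kJmol`,
#' `rmin_half_A`, `radius_A`, `group`. A `residue` of `"*"` matches any
#' residue; empty cells leave the packaged default in place.
#'
#' @param path path to the TSV file.
#' @return data.frame of overrides.
#' @export
read_parameter_overrides <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("residue", "atom", "epsilon_kJmol", "rmin_half_A", "radius_A",
            "group")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("parameter file lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab
}
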