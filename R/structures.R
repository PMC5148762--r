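# Molecular structures: PDB input, Table-style group assignment, the ideal
# amphipathic helix fixture builder, and principal axes.

.mol_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  structure(
    list(
      atoms = atoms,
      n_residues = length(unique(paste(atoms$chain, atoms$resid))),
      reference_centroid = colMeans(xyz)
    ),
    class = "mol_structure"
  )
}

#' Extract the coordinate matrix of a structure
#'
#' @param x a `mol_structure`.
#' @return numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "mol_structure"))
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' @export
print.mol_structure <- function(x, ...) {
  cat("Molecular structure:", nrow(x$atoms), "atoms,",
      x$n_residues, "residues\n")
  grp <- x$atoms$group
  if (all(is.na(grp))) {
    cat("  groups: not assigned (call assign_groups())\n")
  } else {
    tab <- table(grp)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records via bio3d. Hydrogens are dropped (the energy model is
#' heavy-atom based with united-atom SASA radii); non-standard residues are
#' kept and flagged in the `unknown_residues` attribute rather than silently
#' removed -- group assignment will refuse them explicitly.
#'
#' @param path path to a PDB file with at least one ATOM record.
#' @return a `mol_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- vapply(at$elety, .element_from_name, character(1))
  }
  elem <- toupper(trimws(elem))
  blank <- is.na(elem) | elem == ""
  elem[blank] <- vapply(at$elety[blank], .element_from_name, character(1))
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0) stop("no heavy atoms in ", path)
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    resname = toupper(trimws(at$resid)),
    resid = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    eps = NA_real_, rmin_half = NA_real_, radius = NA_real_,
    group = NA_character_,
    stringsAsFactors = FALSE
  )
  out <- .mol_structure(atoms)
  known <- c(names(.sidechain_topology), "TYR")
  attr(out, "unknown_residues") <-
    sort(unique(atoms$resname[!atoms$resname %in% known]))
  out
}

#' Assign solvation groups and force-field parameters
#'
#' Labels every atom with one of the solvation groups (hydrophobic or
#' hydrophilic sidechain/backbone) following the residue classification:
#' sidechains of Gly, Ala, Val, Leu, Ile, Met, Pro, Phe, Trp and the Tyr
#' aromatic ring are hydrophobic; sidechains of Ser, Thr, Asn, Gln, Cys,
#' Arg, Asp, His, Lys, Glu and the Tyr hydroxyl are hydrophilic; C-alpha and
#' carbonyl carbon are hydrophobic backbone; carbonyl oxygen and amide
#' nitrogen are hydrophilic backbone. Also fills per-element SASA radii and
#' Lennard-Jones parameters, optionally overridden per (residue, atom).
#'
#' @param x a `mol_structure`.
#' @param overrides optional data.frame from [read_parameter_overrides()].
#' @return the structure with `group`, `eps`, `rmin_half`, `radius` filled.
#' @export
assign_groups <- function(x, overrides = NULL) {
  stopifnot(inherits(x, "mol_structure"))
  atoms <- x$atoms
  known <- c(.hydrophobic_res, .hydrophilic_res, "TYR")
  bad <- setdiff(unique(atoms$resname), known)
  if (length(bad)) {
    stop("unknown residue name(s): ", paste(bad, collapse = ", "))
  }
  backbone_map <- c(N = "hydrophilic_backbone", CA = "hydrophobic_backbone",
                    C = "hydrophobic_backbone", O = "hydrophilic_backbone",
                    OXT = "hydrophilic_backbone")
  group <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    nm <- atoms$name[i]
    rn <- atoms$resname[i]
    if (nm %in% names(backbone_map)) {
      group[i] <- backbone_map[[nm]]
    } else if (rn == "TYR") {
      if (nm %in% .tyr_ring) {
        group[i] <- "hydrophobic_sidechain"
      } else if (nm == "OH") {
        group[i] <- "hydrophilic_sidechain"
      } else {
        stop("ambiguous TYR atom '", nm, "': not in ring or hydroxyl")
      }
    } else if (rn %in% .hydrophobic_res) {
      group[i] <- "hydrophobic_sidechain"
    } else {
      group[i] <- "hydrophilic_sidechain"
    }
  }
  atoms$group <- group
  idx <- match(atoms$element, .lj_defaults$element)
  if (anyNA(idx)) {
    stop("no LJ parameters for element(s): ",
         paste(unique(atoms$element[is.na(idx)]), collapse = ", "))
  }
  atoms$eps <- .lj_defaults$eps[idx]
  atoms$rmin_half <- .lj_defaults$rmin_half[idx]
  atoms$radius <- unname(.sasa_radii[atoms$element])
  if (!is.null(overrides)) {
    for (k in seq_len(nrow(overrides))) {
      sel <- atoms$name == overrides$atom[k] &
        (overrides$residue[k] == "*" | atoms$resname == overrides$residue[k])
      if (!any(sel)) next
      if (!is.na(overrides$epsilon_kJmol[k]))
        atoms$eps[sel] <- overrides$epsilon_kJmol[k]
      if (!is.na(overrides$rmin_half_A[k]))
        atoms$rmin_half[sel] <- overrides$rmin_half_A[k]
      if (!is.na(overrides$radius_A[k]))
        atoms$radius[sel] <- overrides$radius_A[k]
      if (!is.na(overrides$group[k])) atoms$group[sel] <- overrides$group[k]
    }
  }
  x$atoms <- atoms
  x
}

# NeRF placement: position D from A-B-C with bond length r at C, bond angle
# theta (B-C-D) and dihedral chi (A-B-C-D), angles in degrees.
.place_atom <- function(A, B, C, r, theta, chi) {
  theta <- theta * pi / 180
  chi <- chi * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- r * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  C + cbind(bc, m, n) %*% d_local
}

.unit <- function(v) v / sqrt(sum(v^2))
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build an ideal alpha-helix from a one-letter sequence
#'
#' Constructs an ideal alpha-helical backbone (phi = -57, psi = -47,
#' omega = 180 degrees, standard bond geometry) with schematic sidechains
#' extended radially from each C-alpha. For alternating leucine/lysine
#' sequences this reproduces the amphipathic geometry of the benchmark
#' peptide: all leucine sidechains on one helical face, lysines on the
#' other. Coordinates are deterministic (no randomness).
#'
#' @param sequence one-letter amino-acid string, length >= 4.
#' @param phi,psi backbone dihedrals in degrees.
#' @return a `mol_structure` with groups and parameters already assigned.
#' @export
build_alpha_helix <- function(sequence, phi = -57, psi = -47) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, names(.aa1to3))
  if (length(bad)) {
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  n <- length(letters1)
  if (n < 4) stop("sequence too short to form a helical turn (need >= 4)")
  res3 <- unname(.aa1to3[letters1])

  Np <- CA <- Cc <- Ox <- matrix(NA_real_, n, 3)
  Np[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- (180 - 111.2) * pi / 180
  Cc[1, ] <- CA[1, ] + 1.525 * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    Np[i + 1, ] <- .place_atom(Np[i, ], CA[i, ], Cc[i, ], 1.329, 116.2, psi)
    CA[i + 1, ] <- .place_atom(CA[i, ], Cc[i, ], Np[i + 1, ], 1.458, 121.7,
                               180)
    Cc[i + 1, ] <- .place_atom(Cc[i, ], Np[i + 1, ], CA[i + 1, ], 1.525,
                               111.2, phi)
  }
  for (i in seq_len(n)) {
    Ox[i, ] <- .place_atom(Np[i, ], CA[i, ], Cc[i, ], 1.231, 120.8, psi + 180)
  }

  rows <- list()
  serial <- 0L
  add <- function(name, element, resname, resid, p) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resid = resid, chain = "A", x = p[1], y = p[2], z = p[3],
      eps = NA_real_, rmin_half = NA_real_, radius = NA_real_,
      group = NA_character_, stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n)) {
    rn <- res3[i]
    add("N", "N", rn, i, Np[i, ])
    add("CA", "C", rn, i, CA[i, ])
    add("C", "C", rn, i, Cc[i, ])
    add("O", "O", rn, i, Ox[i, ])
    topo <- .sidechain_topology[[rn]]
    if (length(topo) == 0) next
    u <- .unit(Np[i, ] - CA[i, ])
    v <- .unit(Cc[i, ] - CA[i, ])
    bis <- -.unit(u + v)
    nrm <- .unit(.cross(v, u))
    cb_dir <- .unit(0.618 * bis + 0.786 * nrm)
    cb <- CA[i, ] + 1.53 * cb_dir
    d <- .unit(cb - CA[i, ])
    p1 <- .unit(.cross(d, u))
    for (entry in topo) {
      nm <- entry[1]
      level <- as.numeric(entry[2])
      branch <- as.numeric(entry[3])
      pos <- cb + d * (1.35 * level) +
        p1 * (0.9 * branch + 0.35 * (level %% 2))
      add(nm, .element_from_name(nm), rn, i, pos)
    }
  }
  out <- .mol_structure(do.call(rbind, rows))
  assign_groups(out)
}

#' Principal axes of a structure
#'
#' Eigen-decomposition of the coordinate covariance (gyration) tensor about
#' the centroid. Axes are ordered by descending eigenvalue and sign-fixed to
#' have non-negative dot product with a reference direction (by default the
#' vector from the centroid to the N-terminal C-alpha; ties broken by +z);
#' the third axis then completes a right-handed frame.
#'
#' @param x a `mol_structure` or an n-by-3 coordinate matrix.
#' @param ref optional 3-vector reference for sign fixing.
#' @return list with `axes` (3x3 matrix, columns axis1..axis3) and
#'   `eigenvalues` (descending, Angstrom^2), class `principal_axes`.
#' @export
principal_axes <- function(x, ref = NULL) {
  if (inherits(x, "mol_structure")) {
    xyz <- coords(x)
    if (is.null(ref)) {
      ica <- which(x$atoms$name == "CA" & x$atoms$resid ==
                     min(x$atoms$resid[x$atoms$name == "CA"]))
      if (length(ica) >= 1) {
        ref <- xyz[ica[1], ] - colMeans(xyz)
      }
    }
  } else {
    xyz <- as.matrix(x)
  }
  if (nrow(xyz) < 3) stop("need at least 3 atoms for principal axes")
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  gyr <- crossprod(cc) / nrow(cc)
  ev <- eigen(gyr, symmetric = TRUE)
  vals <- ev$values
  if (vals[2] < 1e-10 * max(vals[1], 1)) {
    stop("degenerate inertia: atoms are (near-)collinear")
  }
  axes <- ev$vectors
  if (is.null(ref) || sqrt(sum(ref^2)) < 1e-12) ref <- NULL
  for (k in 1:2) {
    d <- if (is.null(ref)) 0 else sum(axes[, k] * ref)
    if (abs(d) < 1e-9) d <- axes[3, k]  # tie-break by +z
    if (d < 0) axes[, k] <- -axes[, k]
  }
  axes[, 3] <- .cross(axes[, 1], axes[, 2])
  structure(list(axes = axes, eigenvalues = vals), class = "principal_axes")
}

#' Write the group annotation sidecar
#'
#' @param x a `mol_structure` with groups assigned.
#' @param path output TSV path (columns serial, group).
#' @export
write_groups_tsv <- function(x, path) {
  stopifnot(inherits(x, "mol_structure"))
  if (anyNA(x$atoms$group)) stop("groups not assigned")
  write.table(x$atoms[, c("serial", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
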