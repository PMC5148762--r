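# Periodic graphene surface: honeycomb lattice builder, patch extraction,
# and PDB/JSON export. The lattice lives in the z = 0 plane with outward
# normal +z; primitive vectors a1 = (sqrt(3) b, 0), a2 = (sqrt(3) b/2,
# 1.5 b) and a two-atom basis at (0, 0) and (0, b).

#' Build a periodic graphene surface
#'
#' Generates an `n_cells_x` by `n_cells_y` honeycomb lattice of neutral
#' carbon atoms (2 atoms per primitive cell) at z = 0, carrying
#' aromatic-carbon Lennard-Jones parameters and the `surface_carbon`
#' solvation group. The box vectors tile the plane seamlessly, so energy
#' evaluation treats the surface as infinite.
#'
#' @param n_cells_x,n_cells_y number of primitive cells in each lattice
#'   direction (>= 1).
#' @param bond_length carbon-carbon bond length in Angstrom (default 1.42).
#' @return a `surface_model`: atoms, box vectors `box_a`/`box_b`, `plane_z`,
#'   `normal`, and `bond_length`.
#' @export
build_graphene <- function(n_cells_x, n_cells_y, bond_length = 1.42) {
  if (n_cells_x < 1 || n_cells_y < 1) stop("lattice dimensions must be >= 1")
  if (bond_length <= 0) stop("bond_length must be positive")
  b <- bond_length
  a1 <- c(sqrt(3) * b, 0)
  a2 <- c(sqrt(3) * b / 2, 1.5 * b)
  ij <- expand.grid(j = seq_len(n_cells_y) - 1L, i = seq_len(n_cells_x) - 1L)
  ox <- ij$i * a1[1] + ij$j * a2[1]
  oy <- ij$j * a2[2]
  x <- c(rbind(ox, ox))
  y <- c(rbind(oy, oy + b))
  n <- length(x)
  atoms <- data.frame(
    serial = seq_len(n), name = "C", element = "C", resname = "GRA",
    resid = 1L, chain = "S", x = x, y = y, z = 0,
    eps = .surface_lj[["eps"]], rmin_half = .surface_lj[["rmin_half"]],
    radius = unname(.sasa_radii["C"]), group = "surface_carbon",
    stringsAsFactors = FALSE
  )
  structure(
    list(atoms = atoms,
         box_a = n_cells_x * c(a1, 0),
         box_b = n_cells_y * c(a2, 0),
         plane_z = 0, normal = c(0, 0, 1), bond_length = b),
    class = "surface_model"
  )
}

#' @export
print.surface_model <- function(x, ...) {
  cat("Graphene surface:", nrow(x$atoms), "carbon atoms, bond length",
      x$bond_length, "A\n")
  cat("  box vectors: a =", paste(signif(x$box_a, 6), collapse = " "),
      "; b =", paste(signif(x$box_b, 6), collapse = " "), "\n")
  invisible(x)
}

#' Extract a circular surface patch
#'
#' Returns all lattice atoms (including periodic images) whose xy distance
#' to `footprint_center` is at most `footprint_radius`, in deterministic
#' lattice-cell order. This is the finite piece of the infinite surface over
#' which SASA is evaluated.
#'
#' @param surface a `surface_model`.
#' @param footprint_center 3-vector (only x, y used).
#' @param footprint_radius patch radius in Angstrom (> 0).
#' @return data.frame of atom records.
#' @export
surface_patch <- function(surface, footprint_center, footprint_radius) {
  stopifnot(inherits(surface, "surface_model"))
  if (footprint_radius <= 0) stop("footprint_radius must be positive")
  xyz <- .graphene_disk(footprint_center[1], footprint_center[2],
                        footprint_radius, surface$bond_length)
  n <- nrow(xyz)
  data.frame(
    serial = seq_len(n), name = "C", element = "C", resname = "GRA",
    resid = 1L, chain = "S", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    eps = .surface_lj[["eps"]], rmin_half = .surface_lj[["rmin_half"]],
    radius = unname(.sasa_radii["C"]), group = "surface_carbon",
    stringsAsFactors = FALSE
  )
}

#' Size a graphene surface to a protein footprint
#'
#' Chooses lattice repeats so the box extends at least `margin` beyond the
#' protein's bounding radius in x and y, keeping periodic images outside the
#' van der Waals cutoff.
#'
#' @param protein a `mol_structure`.
#' @param margin extra clearance in Angstrom (default 20).
#' @param bond_length carbon-carbon bond length in Angstrom.
#' @return a `surface_model`.
#' @export
graphene_for_protein <- function(protein, margin = 20, bond_length = 1.42) {
  xyz <- coords(protein)
  ctr <- colMeans(xyz)
  rmax <- sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
  span <- 2 * (rmax + margin)
  nx <- ceiling(span / (sqrt(3) * bond_length))
  ny <- ceiling(span / (1.5 * bond_length))
  build_graphene(nx, ny, bond_length)
}

#' Write a surface as PDB plus a JSON box sidecar
#'
#' @param surface a `surface_model`.
#' @param path output PDB path; the sidecar is written to `<path>.json`.
#' @export
write_surface_pdb <- function(surface, path) {
  stopifnot(inherits(surface, "surface_model"))
  at <- surface$atoms
  lines <- sprintf(
    "HETATM%5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    at$serial %% 100000, at$name, at$resname, at$chain, at$resid,
    at$x, at$y, at$z
  )
  writeLines(c(lines, "END"), path)
  jsonlite::write_json(
    list(box_a = surface$box_a, box_b = surface$box_b,
         plane_z = surface$plane_z, normal = surface$normal,
         bond_length = surface$bond_length),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
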