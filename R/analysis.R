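# Orientation descriptors, contact profiles, free-energy maps, minima
# detection and relative rotations between poses.

#' Principal-axis orientation angles of a posed structure
#'
#' phi is the angle between the sign-fixed largest principal axis and the
#' surface normal (+z); psi likewise for the second axis. Both are reported
#' in degrees in the 0-180 range.
#'
#' @param protein a `mol_structure`.
#' @param pose a `rigid_pose`.
#' @return list with `phi` and `psi` (degrees), class
#'   `orientation_descriptor`.
#' @export
orientation_angles <- function(protein, pose) {
  xyz <- apply_pose(coords(protein), pose, protein$reference_centroid)
  ca <- which(protein$atoms$name == "CA")
  ref_idx <- if (length(ca)) ca[which.min(protein$atoms$resid[ca])] else 1L
  pa <- principal_axes(xyz, ref = xyz[ref_idx, ] - colMeans(xyz))
  structure(
    list(phi = acos(max(-1, min(1, pa$axes[3, 1]))) * 180 / pi,
         psi = acos(max(-1, min(1, pa$axes[3, 2]))) * 180 / pi),
    class = "orientation_descriptor"
  )
}

#' Per-residue surface-contact profile
#'
#' For every frame in which any protein atom lies within `cutoff` of a
#' surface atom, records which residues have an atom within `cutoff`; the
#' profile is the per-residue fraction of those adsorbed frames. Distances
#' are atom-to-atom against the periodic lattice.
#'
#' @param trajectory an `mc_trajectory`, or a merged frame set from
#'   [merge_trajectories()].
#' @param protein a `mol_structure`; defaults to the trajectory's own.
#' @param cutoff contact distance in Angstrom (default 6).
#' @return data.frame (resid, resname, ratio) with attribute `denominator`
#'   (number of adsorbed frames), class `contact_profile`.
#' @export
contact_profile <- function(trajectory, protein = NULL, cutoff = 6) {
  stopifnot(cutoff > 0)
  if (is.null(protein)) protein <- trajectory$protein
  surface <- trajectory$surface
  poses <- trajectory$poses
  xyz0 <- coords(protein)
  ctr <- protein$reference_centroid
  resid <- protein$atoms$resid
  res_ids <- sort(unique(resid))
  res_names <- protein$atoms$resname[match(res_ids, resid)]
  hits <- setNames(numeric(length(res_ids)), res_ids)
  denom <- 0L
  for (k in seq_len(nrow(poses))) {
    pose <- rigid_pose(poses[k, 1:3], poses[k, 4:7])
    xyz <- apply_pose(xyz0, pose, ctr)
    d <- .min_surface_dist(xyz, surface$bond_length)
    if (min(d) > cutoff) next
    denom <- denom + 1L
    touching <- unique(resid[d <= cutoff])
    hits[as.character(touching)] <- hits[as.character(touching)] + 1
  }
  if (denom == 0L) stop("no adsorbed frames within ", cutoff, " A")
  structure(
    data.frame(resid = res_ids, resname = res_names,
               ratio = unname(hits) / denom, stringsAsFactors = FALSE),
    denominator = denom, class = c("contact_profile", "data.frame")
  )
}

#' @export
plot.contact_profile <- function(x, ...) {
  graphics::barplot(x$ratio, names.arg = x$resid, xlab = "residue",
                    ylab = "contact ratio", ylim = c(0, 1), ...)
  invisible(x)
}

#' Free-energy map over orientation angles
#'
#' Histograms (phi, psi) on square bins and converts counts to free energy
#' via \eqn{G = -k_B T \ln N}; empty bins are masked (`NA`), never infinite.
#'
#' @param orientations data.frame or matrix with columns `phi` and `psi`
#'   in degrees (an `mc_trajectory`'s `frames` works directly).
#' @param temperature temperature in K used for the thermal scale.
#' @param bin_width bin width in degrees; must divide 180 (default 10).
#' @return class `fe_map`: `counts` and `G` matrices (phi rows, psi
#'   columns), `breaks`, `mids`, `bin_width`, `temperature`.
#' @export
free_energy_map <- function(orientations, temperature = 300,
                            bin_width = 10) {
  if (inherits(orientations, "mc_trajectory")) {
    orientations <- orientations$frames
  }
  phi <- orientations[, "phi"]
  psi <- orientations[, "psi"]
  if (length(phi) < 1) stop("need at least one orientation")
  if (180 %% bin_width != 0) stop("bin_width must divide 180")
  breaks <- seq(0, 180, by = bin_width)
  nb <- length(breaks) - 1
  bi <- pmin(pmax(findInterval(phi, breaks, rightmost.closed = TRUE), 1), nb)
  bj <- pmin(pmax(findInterval(psi, breaks, rightmost.closed = TRUE), 1), nb)
  counts <- matrix(0L, nb, nb)
  for (k in seq_along(bi)) counts[bi[k], bj[k]] <- counts[bi[k], bj[k]] + 1L
  G <- matrix(NA_real_, nb, nb)
  pos <- counts > 0
  G[pos] <- -kB * temperature * log(counts[pos])
  structure(list(counts = counts, G = G, breaks = breaks,
                 mids = breaks[-1] - bin_width / 2, bin_width = bin_width,
                 temperature = temperature),
            class = "fe_map")
}

#' @export
print.fe_map <- function(x, ...) {
  cat("Free-energy map:", sum(x$counts), "frames in",
      sum(x$counts > 0), "populated", paste0(x$bin_width, "-degree"),
      "bins at", x$temperature, "K\n")
  idx <- which(x$counts == max(x$counts), arr.ind = TRUE)[1, ]
  cat(sprintf("  global minimum G = %.2f kJ/mol at phi %g-%g, psi %g-%g\n",
              min(x$G, na.rm = TRUE),
              x$breaks[idx[1]], x$breaks[idx[1] + 1],
              x$breaks[idx[2]], x$breaks[idx[2] + 1]))
  invisible(x)
}

#' @export
plot.fe_map <- function(x, ...) {
  G <- x$G
  G[is.na(G)] <- max(G, na.rm = TRUE) + kB * x$temperature
  graphics::image(x$mids, x$mids, G, xlab = "phi (deg)", ylab = "psi (deg)",
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  ...)
  invisible(x)
}

#' Locate free-energy minima
#'
#' Local minima of G over the 8-neighborhood of populated bins, keeping
#' those deeper than `depth_threshold` below the populated-bin median.
#' Ordered by depth (deepest first); ties broken by (phi, psi) bin order.
#'
#' @param map an `fe_map`.
#' @param depth_threshold minimum depth below the median, kJ/mol (default
#'   one kB T at the map temperature).
#' @return data.frame: phi_lo, psi_lo, count, G, depth.
#' @export
find_minima <- function(map, depth_threshold = NULL) {
  stopifnot(inherits(map, "fe_map"))
  if (is.null(depth_threshold)) depth_threshold <- kB * map$temperature
  G <- map$G
  nb <- nrow(G)
  med <- median(G[!is.na(G)])
  res <- list()
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (is.na(G[i, j])) next
      nbrs <- c()
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nb && jj >= 1 && jj <= nb &&
                !is.na(G[ii, jj])) {
            nbrs <- c(nbrs, G[ii, jj])
          }
        }
      }
      if (length(nbrs) && any(nbrs < G[i, j])) next
      depth <- med - G[i, j]
      if (depth > depth_threshold) {
        res[[length(res) + 1]] <- data.frame(
          phi_lo = map$breaks[i], psi_lo = map$breaks[j],
          count = map$counts[i, j], G = G[i, j], depth = depth
        )
      }
    }
  }
  if (!length(res)) {
    return(data.frame(phi_lo = numeric(0), psi_lo = numeric(0),
                      count = integer(0), G = numeric(0),
                      depth = numeric(0)))
  }
  out <- do.call(rbind, res)
  out[order(-out$depth, out$phi_lo, out$psi_lo), , drop = FALSE]
}

#' Relative rotation between two poses
#'
#' Decomposes `pose_b` relative to `pose_a` into a total rotation
#' (angle + axis) and the twist angle about the structure's second
#' principal axis. Angles are in degrees in the 0-180 range and symmetric in the
#' argument order.
#'
#' @param pose_a,pose_b `rigid_pose`s of the same rigid structure.
#' @param axes a `principal_axes` of the reference structure.
#' @return list: `angle_about_axis2`, `total_angle`, `axis`.
#' @export
relative_rotation <- function(pose_a, pose_b, axes) {
  q <- .quat_normalize(.quat_mult(pose_b$rotation,
                                  .quat_conj(pose_a$rotation)))
  total <- 2 * acos(min(1, abs(q[1]))) * 180 / pi
  v <- q[2:4]
  axis <- if (sqrt(sum(v^2)) > 1e-12) v / sqrt(sum(v^2)) else c(0, 0, 1)
  u <- axes$axes[, 2]
  # twist-swing decomposition: twist of q about u
  proj <- sum(v * u)
  tw <- c(q[1], proj * u)
  ntw <- sqrt(sum(tw^2))
  angle2 <- if (ntw < 1e-12) 180 else 2 * acos(min(1, abs(tw[1] / ntw))) *
    180 / pi
  list(angle_about_axis2 = angle2, total_angle = total, axis = axis)
}

#' Merge trajectories into one frame set
#'
#' Concatenates the frames and poses of several runs of the same system
#' (e.g., all runs assigned to one basin) for pooled analyses.
#'
#' @param trajectories list of `mc_trajectory` objects.
#' @return an `mc_trajectory`-like object with pooled frames.
#' @export
merge_trajectories <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  out <- trajectories[[1]]
  out$frames <- do.call(rbind, lapply(trajectories, function(t) t$frames))
  out$poses <- do.call(rbind, lapply(trajectories, function(t) t$poses))
  out$escaped <- FALSE
  out$escape_index <- NA_integer_
  out
}
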