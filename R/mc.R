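# Metropolis Monte Carlo engine over rigid-body poses.

# quaternion helpers (w, x, y, z convention)
.quat_identity <- c(1, 0, 0, 0)

.quat_mult <- function(q, p) {
  c(q[1] * p[1] - q[2] * p[2] - q[3] * p[3] - q[4] * p[4],
    q[1] * p[2] + q[2] * p[1] + q[3] * p[4] - q[4] * p[3],
    q[1] * p[3] - q[2] * p[4] + q[3] * p[1] + q[4] * p[2],
    q[1] * p[4] + q[2] * p[3] - q[3] * p[2] + q[4] * p[1])
}

.quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

.quat_normalize <- function(q) q / sqrt(sum(q^2))

.quat_from_axis_angle <- function(axis, angle_deg) {
  a <- angle_deg * pi / 360  # half angle in radians
  u <- axis / sqrt(sum(axis^2))
  c(cos(a), sin(a) * u)
}

.quat_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# quaternion from a rotation matrix (Shepperd's method)
.quat_from_mat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  .quat_normalize(q)
}

#' Create a rigid-body pose
#'
#' A pose is a translation plus a unit quaternion rotation applied about the
#' protein's reference centroid; applying it never changes internal
#' distances.
#'
#' @param translation 3-vector, Angstrom.
#' @param rotation unit quaternion (w, x, y, z).
#' @return a `rigid_pose`.
#' @export
rigid_pose <- function(translation = c(0, 0, 0),
                       rotation = c(1, 0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 4)
  nq <- sqrt(sum(rotation^2))
  if (abs(nq - 1) > 1e-6) stop("rotation quaternion must be unit norm")
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation) / nq),
            class = "rigid_pose")
}

#' Apply a rigid pose to coordinates
#'
#' Rotates about `centroid` then translates: `R (x - c) + c + t`.
#'
#' @param xyz n-by-3 coordinate matrix.
#' @param pose a `rigid_pose`.
#' @param centroid rotation centre (the structure's reference centroid).
#' @return transformed n-by-3 matrix.
#' @export
apply_pose <- function(xyz, pose, centroid) {
  R <- .quat_rotmat(pose$rotation)
  shift <- centroid + pose$translation - as.numeric(R %*% centroid)
  sweep(xyz %*% t(R), 2, shift, "+")
}

#' Monte Carlo run settings
#'
#' @param temperature Metropolis temperature, K.
#' @param max_translation_step per-component maximum displacement, Angstrom.
#' @param max_rotation_step maximum rotation angle per move, degrees.
#' @param target_accepted_moves accepted moves to collect (>= 1).
#' @param seed RNG seed for the chain.
#' @param escape_distance minimum protein-surface distance beyond which a
#'   frame counts as detached, Angstrom.
#' @param escape_patience consecutive detached accepted frames, ending at
#'   the final frame, that flag the run as escaped.
#' @param stall_limit consecutive rejected proposals that abort the run.
#' @return list of settings, class `mc_config`.
#' @export
mc_config <- function(temperature = 300, max_translation_step = 1.0,
                      max_rotation_step = 5.0, target_accepted_moves = 10000,
                      seed = 1, escape_distance = 15, escape_patience = 500,
                      stall_limit = 20000) {
  stopifnot(temperature > 0, max_translation_step >= 0,
            max_rotation_step >= 0, target_accepted_moves >= 1)
  structure(list(temperature = temperature,
                 max_translation_step = max_translation_step,
                 max_rotation_step = max_rotation_step,
                 target_accepted_moves = as.integer(target_accepted_moves),
                 seed = as.integer(seed),
                 escape_distance = escape_distance,
                 escape_patience = as.integer(escape_patience),
                 stall_limit = as.integer(stall_limit)),
            class = "mc_config")
}

#' Propose a symmetric rigid-body move
#'
#' Displaces the translation by a uniform vector in the cube
#' `[-max_translation_step, +max_translation_step]^3` and composes the
#' rotation with a rotation about a uniformly random axis by a uniform
#' angle in `[0, max_rotation_step]` degrees. The proposal density is
#' symmetric, as plain Metropolis requires. Uses R's global RNG stream.
#'
#' @param pose current `rigid_pose`.
#' @param config an [mc_config()].
#' @return proposed `rigid_pose`.
#' @export
propose_move <- function(pose, config) {
  dt <- runif(3, -config$max_translation_step, config$max_translation_step)
  # uniform random axis via normal deviates (inversion-sampled for RNG
  # stream stability)
  u <- runif(3)
  axis <- c(qnorm(u[1]), qnorm(u[2]), qnorm(u[3]))
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) axis <- c(0, 0, 1) else axis <- axis / nrm
  ang <- runif(1, 0, config$max_rotation_step)
  dq <- .quat_from_axis_angle(axis, ang)
  structure(list(translation = pose$translation + dt,
                 rotation = .quat_normalize(.quat_mult(dq,
                                                       pose$rotation))),
            class = "rigid_pose")
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(-delta_e / (kB * temperature)))`.
#'
#' @param delta_e energy change, kJ/mol (finite).
#' @param temperature temperature, K (> 0).
#' @return logical.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (!is.finite(delta_e)) stop("non-finite energy difference")
  stopifnot(temperature > 0)
  if (delta_e <= 0) return(TRUE)
  runif(1) < exp(-delta_e / (kB * temperature))
}

.min_surface_distance <- function(xyz, surface) {
  min(.min_surface_dist(xyz, surface$bond_length))
}

#' Pose placing the structure at a given height
#'
#' Keeps (or sets) the orientation and shifts the pose vertically so the
#' lowest atom sits `height` Angstrom above the surface plane.
#'
#' @param protein a `mol_structure`.
#' @param rotation unit quaternion orientation (default: identity).
#' @param height minimum atom height above the plane, Angstrom.
#' @return a `rigid_pose`.
#' @export
start_pose <- function(protein, rotation = c(1, 0, 0, 0), height = 5) {
  pose <- rigid_pose(c(0, 0, 0), rotation)
  xyz <- apply_pose(coords(protein), pose, protein$reference_centroid)
  rigid_pose(c(0, 0, height - min(xyz[, 3])), rotation)
}

#' Pose with a chosen residue face toward the surface
#'
#' Orients the structure so its largest principal axis lies in the surface
#' plane and the sidechain centroid of the selected residues points at the
#' surface (-z), then places the lowest atom `height` Angstrom above the
#' plane. Used to start benchmark chains e.g. lysines-down.
#'
#' @param protein a `mol_structure`.
#' @param residues residue names (3-letter) whose face points down.
#' @param height starting clearance, Angstrom.
#' @return a `rigid_pose`.
#' @export
face_down_pose <- function(protein, residues, height = 5) {
  xyz <- coords(protein)
  ctr <- colMeans(xyz)
  pa <- principal_axes(protein)
  a <- pa$axes[, 1]
  sel <- protein$atoms$resname %in% toupper(residues) &
    !(protein$atoms$name %in% c("N", "CA", "C", "O", "OXT"))
  if (!any(sel)) stop("no sidechain atoms for residues: ",
                      paste(residues, collapse = ", "))
  f <- colMeans(xyz[sel, , drop = FALSE]) - ctr
  f <- f - sum(f * a) * a  # face direction perpendicular to the long axis
  if (sqrt(sum(f^2)) < 1e-9) stop("face direction degenerate")
  f <- f / sqrt(sum(f^2))
  src <- cbind(a, f, .cross(a, f))
  tgt <- cbind(c(1, 0, 0), c(0, 0, -1), .cross(c(1, 0, 0), c(0, 0, -1)))
  R <- tgt %*% t(src)
  start_pose(protein, .quat_from_mat(R), height)
}

#' Run a Metropolis Monte Carlo chain
#'
#' Iterates propose / evaluate / accept until `target_accepted_moves` frames
#' are accepted, logging the pose, energy components, minimum
#' protein-surface distance and principal-axis orientation angles of every
#' accepted frame. Rejected proposals are discarded without advancing the
#' frame counter. The chain is deterministic given (structure, surface,
#' config, seed).
#'
#' @param protein a `mol_structure` with groups assigned.
#' @param surface a `surface_model`.
#' @param config an [mc_config()].
#' @param initial_pose starting `rigid_pose`; `NULL` draws a random
#'   orientation (from the chain's seed) placed 5 Angstrom above the plane.
#' @param energy an [energy_config()].
#' @return an `mc_trajectory`: `frames` data.frame (accepted, e_vdw,
#'   e_solv, e_total, min_dist, phi, psi), `poses` matrix (tx, ty, tz, qw,
#'   qx, qy, qz), the configs, the inputs, and escape flags.
#' @export
run_mc <- function(protein, surface, config = mc_config(),
                   initial_pose = NULL, energy = energy_config()) {
  .check_assigned(protein)
  set.seed(config$seed)
  if (is.null(initial_pose)) {
    u <- runif(3)
    axis <- c(qnorm(u[1]), qnorm(u[2]), qnorm(u[3]))
    axis <- axis / sqrt(sum(axis^2))
    initial_pose <- start_pose(protein,
                               .quat_from_axis_angle(axis, runif(1, 0, 360)),
                               height = 5)
  }
  n <- config$target_accepted_moves
  pose <- initial_pose
  ctr <- protein$reference_centroid
  cache <- .energy_cache(protein, energy)
  e_cur <- .pose_energy(protein, pose, surface, energy, cache)
  if (!is.finite(sum(e_cur))) stop("non-finite energy at the initial pose")

  frames <- matrix(NA_real_, n, 8,
                   dimnames = list(NULL, c("accepted", "e_vdw", "e_solv",
                                           "e_total", "min_dist", "phi",
                                           "psi", "proposals")))
  poses <- matrix(NA_real_, n, 7,
                  dimnames = list(NULL, c("tx", "ty", "tz", "qw", "qx",
                                          "qy", "qz")))
  acc <- 0L
  rejected_streak <- 0L
  n_prop <- 0L
  ref_ca <- which(protein$atoms$name == "CA")
  ref_idx <- if (length(ref_ca)) {
    ref_ca[which.min(protein$atoms$resid[ref_ca])]
  } else 1L
  while (acc < n) {
    n_prop <- n_prop + 1L
    cand <- propose_move(pose, config)
    e_new <- .pose_energy(protein, cand, surface, energy, cache)
    if (!is.finite(sum(e_new))) stop("non-finite energy during sampling")
    if (metropolis_accept(sum(e_new) - sum(e_cur), config$temperature)) {
      pose <- cand
      e_cur <- e_new
      acc <- acc + 1L
      rejected_streak <- 0L
      xyz <- apply_pose(coords(protein), pose, ctr)
      pa <- principal_axes(xyz, ref = xyz[ref_idx, ] - colMeans(xyz))
      phi <- acos(max(-1, min(1, pa$axes[3, 1]))) * 180 / pi
      psi <- acos(max(-1, min(1, pa$axes[3, 2]))) * 180 / pi
      frames[acc, ] <- c(acc, e_cur[1], e_cur[2], sum(e_cur),
                         .min_surface_distance(xyz, surface), phi, psi,
                         n_prop)
      poses[acc, ] <- c(pose$translation, pose$rotation)
    } else {
      rejected_streak <- rejected_streak + 1L
      if (rejected_streak >= config$stall_limit) {
        stop("chain stalled: ", config$stall_limit,
             " consecutive rejected proposals")
      }
    }
  }
  traj <- structure(
    list(frames = as.data.frame(frames), poses = poses, config = config,
         energy = energy, protein = protein, surface = surface,
         initial_pose = initial_pose),
    class = "mc_trajectory"
  )
  esc <- detect_escape(traj, config)
  traj$escaped <- esc$escaped
  traj$escape_index <- esc$index
  traj
}

#' Detect an escaped (desorbed) run
#'
#' A run is escaped when its final stretch of at least `escape_patience`
#' accepted frames all have minimum surface distance beyond
#' `escape_distance` -- the protein left and did not return. Brief
#' excursions that return are not escapes.
#'
#' @param trajectory an `mc_trajectory`.
#' @param config an [mc_config()]; defaults to the trajectory's own.
#' @return list with `escaped` (logical) and `index` (first frame of the
#'   terminal detached streak, or `NA`).
#' @export
detect_escape <- function(trajectory, config = NULL) {
  stopifnot(inherits(trajectory, "mc_trajectory") ||
              is.data.frame(trajectory))
  frames <- if (is.data.frame(trajectory)) trajectory else trajectory$frames
  if (is.null(config)) config <- trajectory$config
  if (nrow(frames) == 0) stop("empty trajectory")
  far <- frames$min_dist > config$escape_distance
  n <- length(far)
  if (!far[n]) return(list(escaped = FALSE, index = NA_integer_))
  streak <- rle(rev(far))$lengths[1]
  if (streak >= config$escape_patience) {
    list(escaped = TRUE, index = n - streak + 1L)
  } else {
    list(escaped = FALSE, index = NA_integer_)
  }
}

#' @export
print.mc_trajectory <- function(x, ...) {
  n <- nrow(x$frames)
  cat("Monte Carlo trajectory:", n, "accepted moves at",
      x$config$temperature, "K\n")
  cat(sprintf("  final energy %.1f kJ/mol; final min distance %.2f A\n",
              x$frames$e_total[n], x$frames$min_dist[n]))
  cat(sprintf("  final orientation phi %.1f deg, psi %.1f deg\n",
              x$frames$phi[n], x$frames$psi[n]))
  if (isTRUE(x$escaped)) {
    cat("  ESCAPED at frame", x$escape_index, "\n")
  }
  invisible(x)
}

#' @export
summary.mc_trajectory <- function(object, ...) {
  f <- object$frames
  half <- f[seq(floor(nrow(f) / 2) + 1, nrow(f)), ]
  out <- list(
    n_frames = nrow(f),
    temperature = object$config$temperature,
    escaped = isTRUE(object$escaped),
    final_energy = f$e_total[nrow(f)],
    mean_energy_second_half = mean(half$e_total),
    modal_phi = .modal_bin_center(half$phi, 2),
    modal_psi = .modal_bin_center(half$psi, 2)
  )
  class(out) <- "summary.mc_trajectory"
  out
}

#' @export
print.summary.mc_trajectory <- function(x, ...) {
  cat("MC trajectory summary\n")
  cat("  frames:", x$n_frames, " temperature:", x$temperature, "K\n")
  cat(sprintf("  final E %.1f kJ/mol; mean E (2nd half) %.1f kJ/mol\n",
              x$final_energy, x$mean_energy_second_half))
  cat(sprintf("  modal phi %.1f deg, modal psi %.1f deg (2nd half)\n",
              x$modal_phi, x$modal_psi))
  if (x$escaped) cat("  run escaped the surface\n")
  invisible(x)
}

#' @export
plot.mc_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$frames$accepted, x$frames$e_total, type = "l",
                 xlab = "accepted move", ylab = "E total (kJ/mol)", ...)
  graphics::plot(x$frames$accepted, x$frames$phi, type = "l", ylim = c(0, 180),
                 xlab = "accepted move", ylab = "phi (deg)", col = "black")
  graphics::lines(x$frames$accepted, x$frames$psi, col = "red")
  graphics::legend("topright", c("phi", "psi"), col = c("black", "red"),
                   lty = 1, bty = "n")
  invisible(x)
}

.modal_bin_center <- function(x, width) {
  brk <- seq(0, 180 + width, by = width)
  h <- hist(x, breaks = brk, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Write a trajectory TSV log
#'
#' @param trajectory an `mc_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "mc_trajectory"))
  hdr <- c(
    "# surfmc trajectory log",
    paste0("# temperature_K=", trajectory$config$temperature,
           " seed=", trajectory$config$seed,
           " max_translation_A=", trajectory$config$max_translation_step,
           " max_rotation_deg=", trajectory$config$max_rotation_step)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  out <- cbind(trajectory$frames, as.data.frame(trajectory$poses))
  write.table(format(out, digits = 10), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a trajectory TSV log
#'
#' @param path path written by [write_trajectory()].
#' @return data.frame of frames (poses included when present).
#' @export
read_trajectory_log <- function(path) {
  if (!file.exists(path)) stop("trajectory log not found: ", path)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
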