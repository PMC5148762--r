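# Multi-run orchestration: independent chains, escape screening, basin
# assignment, and merged analyses.

#' Run and pool multiple Monte Carlo chains
#'
#' Runs `n_runs` independent chains seeded `seed_base + 1 .. seed_base +
#' n_runs`, discards escaped (and stalled) runs from analysis, pools the
#' remaining orientations into a free-energy map, locates its minima, and
#' assigns each run to a basin by the modal orientation bin of its final
#' 10% of frames. Contact profiles are computed on the merged frames of
#' each basin.
#'
#' @param protein a `mol_structure` with groups assigned.
#' @param surface a `surface_model`.
#' @param base_config an [mc_config()]; each run gets its own seed.
#' @param n_runs number of chains (>= 1).
#' @param seed_base integer seed offset.
#' @param initial_pose shared starting `rigid_pose` (the runs differ only
#'   by seed), or `NULL` for per-seed random starts.
#' @param energy an [energy_config()].
#' @param contact_cutoff contact distance for profiles, Angstrom.
#' @param verbose print per-run progress lines.
#' @return an `mc_ensemble`: `manifest` data.frame, `trajectories`,
#'   pooled `fe_map`, `minima`, per-basin `contact_profiles`.
#' @export
orchestrate <- function(protein, surface, base_config = mc_config(),
                        n_runs = 3, seed_base = 0, initial_pose = NULL,
                        energy = energy_config(), contact_cutoff = 6,
                        verbose = FALSE) {
  stopifnot(n_runs >= 1)
  trajectories <- vector("list", n_runs)
  status <- character(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- base_config
    cfg$seed <- as.integer(seed_base + i)
    t0 <- Sys.time()
    tr <- tryCatch(
      run_mc(protein, surface, cfg, initial_pose = initial_pose,
             energy = energy),
      error = function(e) e
    )
    if (inherits(tr, "error")) {
      status[i] <- "stalled"
      trajectories[i] <- list(NULL)
      if (verbose) message("run ", i, ": stalled (", conditionMessage(tr),
                           ")")
      next
    }
    trajectories[[i]] <- tr
    status[i] <- if (isTRUE(tr$escaped)) "escaped" else "converged"
    if (verbose) {
      message(sprintf("run %d: %s in %.1f s (final E %.1f)", i, status[i],
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      tr$frames$e_total[nrow(tr$frames)]))
    }
  }
  usable <- which(status == "converged")
  if (!length(usable)) stop("no adsorbed runs: all chains escaped or stalled")

  pooled <- merge_trajectories(trajectories[usable])
  fe <- free_energy_map(pooled$frames, temperature = base_config$temperature)
  minima <- find_minima(fe)
  if (nrow(minima) == 0) {
    # single shallow landscape: fall back to the global count maximum
    idx <- which(fe$counts == max(fe$counts), arr.ind = TRUE)[1, , drop = TRUE]
    minima <- data.frame(phi_lo = fe$breaks[idx[1]],
                         psi_lo = fe$breaks[idx[2]],
                         count = fe$counts[idx[1], idx[2]],
                         G = fe$G[idx[1], idx[2]], depth = 0)
  }

  bw <- fe$bin_width
  basin_of <- integer(n_runs)
  final_phi <- final_psi <- final_e <- rep(NA_real_, n_runs)
  for (i in seq_len(n_runs)) {
    tr <- trajectories[[i]]
    if (is.null(tr)) next
    f <- tr$frames
    final_phi[i] <- f$phi[nrow(f)]
    final_psi[i] <- f$psi[nrow(f)]
    final_e[i] <- f$e_total[nrow(f)]
    if (status[i] != "converged") next
    lastq <- f[seq(max(1, floor(0.9 * nrow(f))), nrow(f)), ]
    key <- paste(floor(pmin(lastq$phi, 180 - 1e-9) / bw),
                 floor(pmin(lastq$psi, 180 - 1e-9) / bw))
    modal <- names(sort(table(key), decreasing = TRUE))[1]
    ij <- as.numeric(strsplit(modal, " ")[[1]])
    d2 <- (minima$phi_lo / bw - ij[1])^2 + (minima$psi_lo / bw - ij[2])^2
    basin_of[i] <- which.min(d2)
  }

  manifest <- data.frame(
    run = seq_len(n_runs), seed = seed_base + seq_len(n_runs),
    status = status,
    basin = ifelse(status == "converged", basin_of, NA_integer_),
    final_phi = final_phi, final_psi = final_psi, final_energy = final_e
  )

  profiles <- list()
  for (b in sort(unique(basin_of[usable]))) {
    runs_b <- usable[basin_of[usable] == b]
    merged <- merge_trajectories(trajectories[runs_b])
    profiles[[as.character(b)]] <-
      tryCatch(contact_profile(merged, cutoff = contact_cutoff),
               error = function(e) NULL)
  }

  structure(list(manifest = manifest, trajectories = trajectories,
                 fe_map = fe, minima = minima,
                 contact_profiles = profiles,
                 temperature = base_config$temperature),
            class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat("Monte Carlo ensemble:", nrow(x$manifest), "runs (",
      sum(x$manifest$status == "converged"), "converged,",
      sum(x$manifest$status == "escaped"), "escaped,",
      sum(x$manifest$status == "stalled"), "stalled )\n")
  cat("  free-energy minima:\n")
  print(x$minima, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mc_ensemble <- function(object, ...) {
  print(object)
  cat("\nPer-run manifest:\n")
  print(object$manifest, row.names = FALSE)
  invisible(object)
}

#' Load a flat-key YAML configuration
#'
#' Reads sampling/energy settings from a flat YAML file; keys absent from
#' the file keep package defaults. Recognized keys are the arguments of
#' [mc_config()] and [energy_config()] plus `sigma_<group>` overrides.
#'
#' @param path YAML file path.
#' @return list with elements `mc` ([mc_config()]) and `energy`
#'   ([energy_config()]).
#' @export
load_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files")
  }
  vals <- yaml::read_yaml(path)
  take <- function(fn, names_) {
    args <- vals[intersect(names(vals), names_)]
    do.call(fn, args)
  }
  mc <- take(mc_config, names(formals(mc_config)))
  sig_keys <- grep("^sigma_", names(vals), value = TRUE)
  sigma <- sigma_table(
    if (length(sig_keys)) {
      setNames(unlist(vals[sig_keys]), sub("^sigma_", "", sig_keys))
    } else NULL
  )
  en_args <- vals[intersect(names(vals),
                            c("probe_radius", "vdw_cutoff", "sasa_points",
                              "patch_margin"))]
  en <- do.call(energy_config, c(en_args, list(sigma = sigma)))
  list(mc = mc, energy = en)
}

#' Write selected trajectory frames as a multi-model PDB
#'
#' @param trajectory an `mc_trajectory`.
#' @param path output PDB path.
#' @param every write every k-th accepted frame (default 100).
#' @export
write_poses_pdb <- function(trajectory, path, every = 100) {
  stopifnot(inherits(trajectory, "mc_trajectory"))
  protein <- trajectory$protein
  at <- protein$atoms
  xyz0 <- coords(protein)
  ctr <- protein$reference_centroid
  idx <- seq(1, nrow(trajectory$poses), by = every)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(idx)) {
    k <- idx[m]
    pose <- rigid_pose(trajectory$poses[k, 1:3], trajectory$poses[k, 4:7])
    xyz <- apply_pose(xyz0, pose, ctr)
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      at$serial %% 100000, at$name, at$resname, at$chain, at$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
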