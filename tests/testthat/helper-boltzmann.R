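# Boltzmann-sampling check for the Metropolis engine: a rigid three-atom
# toy with solvation off feels only the Lennard-Jones height potential
# above the lattice. The long-run height histogram, restricted to a window
# (conditional distributions of a Boltzmann sampler are Boltzmann), is
# compared against a brute-force grid integration of exp(-E(z)/kT).

zero_sigma <- function() {
  sigma_table(overrides = c(hydrophobic_sidechain = 0,
                            hydrophilic_sidechain = 0,
                            hydrophobic_backbone = 0,
                            hydrophilic_backbone = 0,
                            surface_carbon = 0))
}

boltzmann_toy_check <- function(n_accept = 60000, seed = 314,
                                temperature = 200, thin = 150,
                                z_range = c(3.2, 5.2), bin_width = 0.4) {
  xyz <- rbind(c(0, 0, 0), c(1.8, 0, 0), c(0.9, 1.5, 0))
  toy <- toy_structure(xyz)
  s <- build_graphene(10, 10)
  en <- energy_config(sigma = zero_sigma())
  cfg <- mc_config(temperature = temperature, max_translation_step = 0.8,
                   max_rotation_step = 0, target_accepted_moves = n_accept,
                   seed = seed, escape_distance = 100,
                   escape_patience = n_accept + 1)
  tr <- run_mc(toy, s, cfg, initial_pose = rigid_pose(c(0.3, 0.2, 4)),
               energy = en)
  z <- tr$poses[seq(thin, n_accept, by = thin), "tz"]
  z <- z[z >= z_range[1] & z < z_range[2]]

  # brute-force partition function on a height grid, with the in-plane
  # coordinates integrated over one primitive cell (Boltzmann-weighted
  # xy average captures the lattice corrugation near the well mouth)
  grid <- seq(z_range[1], z_range[2], by = 0.02)
  cache <- surfmc:::.energy_cache(toy, en)
  frac <- seq(0, 0.8, by = 0.2)
  cellxy <- as.matrix(expand.grid(f1 = frac, f2 = frac)) %*%
    rbind(c(sqrt(3) * 1.42, 0), c(sqrt(3) * 1.42 / 2, 1.5 * 1.42))
  e_min <- Inf
  emat <- matrix(NA_real_, length(grid), nrow(cellxy))
  for (k in seq_len(nrow(cellxy))) {
    emat[, k] <- vapply(grid, function(zz) {
      sum(surfmc:::.pose_energy(
        toy, rigid_pose(c(cellxy[k, 1], cellxy[k, 2], zz)), s, en, cache))
    }, numeric(1))
  }
  e_min <- min(emat)
  w <- rowMeans(exp(-(emat - e_min) / (kB * temperature)))

  breaks <- seq(z_range[1], z_range[2], by = bin_width)
  obs <- table(cut(z, breaks))
  p <- vapply(seq_len(length(breaks) - 1), function(i) {
    sel <- grid >= breaks[i] & grid < breaks[i + 1]
    sum(w[sel])
  }, numeric(1))
  p <- p / sum(p)
  list(obs = as.numeric(obs), p = p, n = length(z), breaks = breaks)
}
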