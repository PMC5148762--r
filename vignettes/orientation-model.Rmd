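---
title: "Predicting adsorbed protein orientation by rigid-body Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting adsorbed protein orientation by rigid-body Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfmc)
```

## The problem and the model

When a soluble protein adsorbs onto a hydrophobic material it tends to
settle into a small number of preferred orientations, determined by which
patches of its surface can be buried against the material. surfmc samples
those orientations with a Metropolis Monte Carlo walk over rigid-body
poses of the protein above a single-layer graphene lattice.

The pose energy has two terms:

* **van der Waals**: a 12-6 Lennard-Jones sum over protein-surface atom
  pairs, `E = eps[(Rmin/r)^12 - 2 (Rmin/r)^6]`, with CHARMM-style
  combining (`eps = sqrt(eps_i eps_j)`, `Rmin = Rmin_i/2 + Rmin_j/2`),
  truncated at a 10 A cutoff. Intramolecular terms are constant for a
  rigid body and excluded. Electrostatics are omitted: graphene carries
  neutral carbons only.
* **nonpolar solvation**: each atom group's solvent-accessible surface
  area (SASA, 1.4 A probe) is weighted by a surface-tension coefficient
  `sigma`. Hydrophobic sidechains (Gly, Ala, Val, Leu, Ile, Met, Pro,
  Phe, Trp and the Tyr ring), the C-alpha and carbonyl carbon, and the
  surface carbons carry `sigma = +100`; hydrophilic sidechains (Ser, Thr,
  Asn, Gln, Cys, Arg, Asp, His, Lys, Glu and the Tyr hydroxyl) and the
  carbonyl oxygen / amide nitrogen carry `sigma = -100`. Exposing
  hydrophobic area therefore costs energy and exposing hydrophilic area
  is rewarded, which is what drives a hydrophobic protein face onto the
  hydrophobic surface.

Two standing assumptions: the protein is rigid (poses only translate and
rotate the reference coordinates; internal distances never change), and
the surface is frozen and effectively infinite (periodic honeycomb
lattice; energies are evaluated against the infinite lattice enumerated
analytically, which is identical to minimum-image arithmetic whenever the
box is at least twice the cutoff).

### The area unit behind the tension table

The tension table is printed in units of kJ/mol per area, with a
magnitude (100) that is two orders larger than typical
SASA-proportional solvation coefficients. surfmc resolves this by making
the area unit explicit: with the default `area_unit = "nm2"` the table
multiplies areas expressed in nm^2 -- the native unit of the
gromacs-based SASA workflow this kind of tension table is built around --
giving an effective 1 kJ/(mol A^2). The literal reading
(`area_unit = "A2"`) is available but makes the landscape so stiff that a
300 K Metropolis walk degenerates into a zero-temperature quench (every
orientational move costs hundreds of kT, chains freeze at the first
contact geometry and acceptance collapses). Under the nm^2 convention
chains show healthy acceptance, flip between faces within a run, and
produce thermally populated orientation histograms -- the sampling regime
the method is designed for. `solvation_energy()` itself is a plain
`sigma * area` product on whatever areas the caller provides.

### SASA evaluation on an infinite surface

SASA is computed with the Shrake-Rupley construction: a deterministic
golden-spiral set of test points on each solvent-expanded sphere
(default 240 points per atom while sampling, 960 for validation-grade
areas; no randomness anywhere). Two implementation choices matter:

* **Body-fixed test points.** The protein's point sets rotate with the
  pose. The intramolecular burial pattern of a rigid body is then exactly
  pose-invariant and is precomputed once per run; only genuine
  protein-surface occlusion enters energy differences. Lab-fixed points
  would instead re-quantize the internal SASA at every rotation,
  injecting artificial noise of one area quantum (about 0.5 A^2 per
  point flip) per atom into Delta-E.
* **Bare-lattice reference for surface atoms.** The surface is infinite,
  so "the SASA of the surface" is ill-defined. Each surface atom within
  the protein's occlusion reach contributes
  `sigma * (area - bare lattice area)`, where the bare area is that of an
  interior lattice atom occluded only by its own neighbors. Far from the
  protein the contribution is exactly zero, the solvation term is a
  smooth function of the pose, and the protein-free energy zero is the
  intact surface. (A naive fixed-radius patch cut from the lattice
  around the moving centroid would gain and lose whole far-field atoms
  as the protein translates, producing order-sigma*30 A^2 jumps in
  Delta-E that have nothing to do with the pose.)

The patch of surface atoms examined at each evaluation is a disk around
the protein's xy centroid whose radius is the protein's bounding radius
plus the occlusion reach -- orientation-independent, so no pose is
favored by patch geometry.

## The sampler

Moves displace the pose translation by a uniform vector in
`[-d, +d]^3` and compose the rotation with a uniformly oriented axis and
a uniform angle in `[0, a]`; the proposal is symmetric, so plain
Metropolis acceptance `min(1, exp(-dE/kT))` (kB = 0.0083145 kJ/mol/K)
samples the Boltzmann distribution. Defaults: `d = 1.0` A, `a = 5`
degrees, 300 K. The temperature is also used for the free-energy maps.
Acceptance is not uniform along a run: while the protein approaches the
surface and rolls downhill toward its preferred face most proposals are
accepted, whereas inside a deep adsorption basin the solvation landscape
is stiff and acceptance settles at a few percent -- the chain then mostly
explores in-plane displacement and rotation about the normal, which is
exactly the degenerate direction of the adsorbed state. Shrinking the
step sizes does not buy acceptance back in proportion (the landscape
roughness, not the step, dominates) but does slow the initial
reorientation, so the defaults favor reliable convergence of the
benchmark within a few thousand accepted moves.
Only accepted moves are logged (the frame stream is the accepted-move
stream, which is what the orientation histograms are built from).

Runs whose final stretch of at least `escape_patience = 500` accepted
frames all sit beyond `escape_distance = 15` A are flagged *escaped* and
excluded from pooled analyses -- the protein left the surface and did not
return. Escaped runs are never restrained back; a restraint would change
the sampled ensemble.

Each chain is fully determined by (structure, surface, config, seed):
the R RNG stream drives proposals and acceptances, so trajectories are
bit-reproducible.

## Analyses

Orientation is summarized by the angles `phi` and `psi` between the two
largest principal axes of the posed coordinates (eigenvectors of the
gyration tensor) and the surface normal. Axis signs are fixed by the
vector from the centroid to the N-terminal C-alpha (ties broken toward
+z), making the angles single-valued on [0, 180] across frames;
collinear atom sets are refused rather than silently assigned axes.

* `free_energy_map()` histograms (phi, psi) on 10-degree bins and
  reports `G = -kB T ln N`; empty bins are masked, never infinite.
* `find_minima()` takes local minima over the 8-neighborhood of
  populated bins and keeps those deeper than one kT below the
  populated-bin median (the threshold is a package choice -- by eye on a
  heatmap one would do the same); ties are broken lexicographically.
* `contact_profile()` counts, per residue, the fraction of adsorbed
  frames (any protein atom within the 6 A cutoff of a surface atom) in
  which that residue touches the surface, with strict atom-to-atom
  distances against the periodic lattice.
* `orchestrate()` runs independent chains, discards escaped ones,
  assigns each run to a free-energy basin by the modal orientation bin
  of its final 10% of frames, and merges frames basin-wise before
  profiling -- automating what would otherwise be done by inspecting
  energy traces.

## The amide-I SFG module

To compare predicted orientations against sum-frequency generation
spectroscopy, surfmc builds one vibrational site per peptide bond (at
the C=O midpoint, transition dipole tilted 20 degrees from the C=O bond
toward the nitrogen in the O=C-N plane, axially symmetric Raman tensor
of 3:1 anisotropy, site frequency 1650 cm^-1), couples all pairs with a
transition-dipole coupling `kappa [mu_i mu_j - 3 (mu_i r)(mu_j r)] / r^3`
(`kappa = 5034` cm^-1 A^3), and diagonalizes the exciton Hamiltonian. A
dihedral-based nearest-neighbor coupling map can be plugged in where one
is available; the packaged default uses TDC for all pairs, so calculated
lineshapes are qualitative rather than quantitative. Mode amplitudes are
the Raman-tensor / IR-dipole products, azimuthally averaged over 36
rotations about the surface normal (an in-plane isotropic monolayer),
combined into ssp (xxz) or ppp (beam angles 47 and 58 degrees from the
normal, Fresnel factors set to 1), given complex Lorentzian lineshapes
(10 cm^-1), and squared together with a nonresonant background of fixed
phase (3.5 rad for ssp, 1.5 rad for ppp). Orientation mixtures are
coherent: `mix_spectra()` averages the complex response before squaring,
because coexisting orientations radiate into the same field.

## The synthetic fixture generator

`build_alpha_helix()` produces an ideal alpha-helix backbone
(phi = -57, psi = -47, omega = 180, standard bond geometry) with
schematic sidechains: each sidechain extends radially from its C-alpha
with correct heavy-atom count, element identity, reach and branching,
but idealized internal geometry. For the alternating leucine/lysine
14-mer this yields the amphipathic benchmark peptide -- all leucines on
one helical face, all lysines on the other -- without any structure
download. What the fixture does *not* emulate: real sidechain rotamer
states, backbone irregularity, and the packing detail of a crystal
structure. Tests passing on the fixture therefore validate the energy
model, sampler and analyses, not the atomic detail of any particular
protein; analyses of real proteins should start from a PDB structure
via `read_pdb()` (pre-minimized coordinates are the user's
responsibility).

A worked benchmark: chains started with the *lysines* facing the surface
flip to leucines-down and settle with the helix axis nearly parallel to
the plane. The package's acceptance script reruns exactly this
experiment (three chains of 5000 accepted moves) and reports the modal
helix-axis angle.

## Numerical choices and degenerate inputs

* Golden-spiral points make every SASA number deterministic; areas are
  quantized at `4 pi R^2 / n_points` per point.
* Hydrogens are dropped on input; united-atom radii (C 1.70, N 1.55,
  O 1.52, S 1.80 A) absorb them. The Table's C-alpha-H and N-H entries
  ride on the heavy atom. Glycine contributes backbone groups only.
* Lennard-Jones parameters default to representative CHARMM-type values
  per element (aromatic-carbon values for the lattice) and can be
  replaced per (residue, atom) via a TSV override file.
* Degenerate inertia (collinear structures) raises an error; pose
  quaternions are renormalized after every composition; coincident
  atoms in the pair sum raise an error rather than returning infinities.
* The honeycomb lattice has threefold point symmetry about an atom and
  sixfold about a ring center; the lattice sum respects both exactly,
  the solvation term to within the SASA area quantum.

## Problem sizes in the shipped tests

The test suite exercises the full pipeline at sizes chosen to keep a
complete run in the minutes range on one core: benchmark chains of
2500-5000 accepted moves (three seeds), a 60 000-move toy chain for the
Boltzmann cross-check against a brute-force partition function, 960-point
SASA for closed-form and cross-implementation comparisons, and short
multi-run orchestrations. The same code paths scale to the
10 000-accepted-move, 13-run protocol used for a 56-residue protein
domain by changing two configuration numbers.

## Known limitations

* No electrostatics: hydrophilic or charged surfaces are out of scope.
* Solvation is strictly area-based; no generalized-Born term, no
  water structure.
* The SFG module's nearest-neighbor couplings default to TDC, so
  spectral positions of strongly coupled backbone modes are approximate
  unless an ab initio coupling map is supplied.
* Orientation prediction says nothing about adsorption kinetics or
  protein-protein crowding; each chain models one isolated molecule.
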