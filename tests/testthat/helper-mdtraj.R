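# Independent SASA reference: mdtraj's Shrake-Rupley implementation, called
# through the command-line python of the analysis stack. mdtraj's built-in
# atomic radii (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom) match the packaged
# table, so per-atom areas are directly comparable.

mdtraj_sasa <- function(xyz, elements, probe = 1.4, n_points = 960) {
  xin <- tempfile(fileext = ".csv")
  xout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(xin, xout)), add = TRUE)
  utils::write.table(data.frame(elements, xyz), xin, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  script <- sprintf(paste0(
    "import numpy as np, mdtraj as md\n",
    "rows = [l.strip().split(',') for l in open('%s')]\n",
    "els = [r[0] for r in rows]\n",
    "xyz = np.array([[float(v) for v in r[1:4]] for r in rows]) / 10.0\n",
    "top = md.Topology(); ch = top.add_chain()\n",
    "res = top.add_residue('UNK', ch)\n",
    "import mdtraj.core.element as elem\n",
    "for i, e in enumerate(els):\n",
    "    top.add_atom('X%%d' %% i, elem.get_by_symbol(e), res)\n",
    "t = md.Trajectory(xyz[None, :, :], top)\n",
    "a = md.shrake_rupley(t, probe_radius=%f, n_sphere_points=%d,",
    " mode='atom')[0] * 100.0\n",
    "np.savetxt('%s', a)\n"), xin, probe / 10, n_points, xout)
  status <- system2("python", c("-c", shQuote(script)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(xout)) {
    stop("mdtraj reference SASA call failed")
  }
  as.numeric(readLines(xout))
}
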