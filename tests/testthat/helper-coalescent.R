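# Run a neutral coalescent simulation with msprime (via the python
# interpreter) and write ms-style output. Returns the output path.
# Parameters: diploid sample count, Ne, per-bp mutation and
# recombination rates, segment length in bp.
simulate_coalescent_ms <- function(out, n_diploid = 200, ne = 10000,
                                   mu = 1.29e-8, rho = 1e-8,
                                   length_bp = 1e7, seed = 1) {
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "import msprime",
    "out, n, ne, mu, rho, L, seed = sys.argv[1], int(sys.argv[2]), float(sys.argv[3]), float(sys.argv[4]), float(sys.argv[5]), float(sys.argv[6]), int(sys.argv[7])",
    "ts = msprime.sim_ancestry(samples=n, population_size=ne, sequence_length=L, recombination_rate=rho, random_seed=seed)",
    "mts = msprime.sim_mutations(ts, rate=mu, random_seed=seed + 1, model=msprime.BinaryMutationModel())",
    "G = np.minimum(mts.genotype_matrix(), 1)",
    "with open(out, 'w') as fh:",
    "    fh.write('msprime %d 1\\n\\n//\\n' % mts.num_samples)",
    "    fh.write('segsites: %d\\n' % mts.num_sites)",
    "    fh.write('positions: ' + ' '.join('%.10f' % (s.position / L) for s in mts.sites()) + '\\n')",
    "    for h in range(G.shape[1]):",
    "        fh.write(''.join(map(str, G[:, h])) + '\\n')"
  ), py)
  status <- system2("python",
                    c(py, out, n_diploid, ne, mu, rho,
                      sprintf("%.0f", length_bp), seed),
                    stdout = FALSE, stderr = "")
  stopifnot(status == 0)
  out
}
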