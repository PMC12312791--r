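# Shared small fixtures, built in code at test time.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Toy PDB: chain A with 3 CA residues (one with altlocs), chain B with 2,
# plus waters and a zinc ion as HETATM records.
toy_pdb_lines <- function() {
  c(
    "HEADER    TOY STRUCTURE",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2       4.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA BGLY A   2       4.500   0.000   0.000  0.60  0.00           C",
    "ATOM      5  CA  SER A   3       8.000   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CA  LEU B   1      20.000   0.000   0.000  1.00  0.00           C",
    "ATOM      7  CA  LYS B   2      24.000   0.000   0.000  1.00  0.00           C",
    "HETATM    8  O   HOH A 101      30.000   0.000   0.000  1.00  0.00           O",
    "HETATM    9  O   HOH A 102      31.000   0.000   0.000  1.00  0.00           O",
    "HETATM   10 ZN    ZN A 103      32.000   0.000   0.000  1.00  0.00          ZN",
    "TER",
    "END"
  )
}

# Class-shifted Gaussian feature matrix: `s` informative columns carry a
# mean shift of `delta` SDs in the positive class.
shifted_matrix <- function(n_per_class, p, s, delta) {
  X <- matrix(stats::rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(c(1, 0), each = n_per_class)
  X[y == 1, seq_len(s)] <- X[y == 1, seq_len(s)] + delta
  list(X = X, y = y)
}

# Small simulated dataset shared by evaluation tests.
small_signal_dataset <- function(seed = 42, n_per_class = 100) {
  generate_dataset(sim_config(n_pos = n_per_class, n_neg = n_per_class,
                              seed = seed))
}
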