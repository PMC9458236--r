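# In-code text fixtures for the format readers.

write_toy_pdb <- function(path) {
  # 3-residue peptide stub (coordinates arbitrary but fixed)
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   SER A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  SER A   2       3.988   2.840   0.000  1.00  0.00           C",
    "ATOM      8  C   SER A   2       5.504   2.697   0.000  1.00  0.00           C",
    "ATOM      9  O   SER A   2       6.030   1.584   0.000  1.00  0.00           O",
    "ATOM     10  CB  SER A   2       3.562   3.651   1.230  1.00  0.00           C",
    "ATOM     11  OG  SER A   2       2.160   3.850   1.211  1.00  0.00           O",
    "ATOM     12  N   GLY A   3       6.224   3.815   0.000  1.00  0.00           N",
    "ATOM     13  CA  GLY A   3       7.676   3.785   0.000  1.00  0.00           C",
    "ATOM     14  C   GLY A   3       8.254   5.192   0.000  1.00  0.00           C",
    "ATOM     15  O   GLY A   3       7.520   6.180   0.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

write_het_pdb <- function(path) {
  lines <- c(
    "HETATM    1  C1  LIG A 900       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O1  LIG A 900       1.230   0.000   0.000  1.00  0.00           O",
    "HETATM    3  N   LIG A 900      -1.300   0.000   0.000  1.00  0.00           N",
    "END")
  writeLines(lines, path)
  path
}

write_toy_mol2 <- function(path, with_bonds = TRUE) {
  th <- seq(0, 300, by = 60) * pi / 180
  atom_lines <- sprintf("%7d C%d %12.4f %9.4f %9.4f C.ar     1  BNZ1   %8.4f",
                        1:6, 1:6, 1.39 * cos(th), 1.39 * sin(th), 0, -0.06)
  lines <- c("@<TRIPOS>MOLECULE", "benzene",
             sprintf(" 6 %d 0 0 0", if (with_bonds) 6L else 0L),
             "SMALL", "GASTEIGER", "@<TRIPOS>ATOM", atom_lines)
  if (with_bonds) {
    bond_lines <- sprintf("%6d %4d %4d ar", 1:6, 1:6, c(2:6, 1L))
    lines <- c(lines, "@<TRIPOS>BOND", bond_lines)
  }
  writeLines(lines, path)
  path
}

write_toy_ism <- function(path, names = c("CHEMBL1", "CHEMBL2", "CHEMBL3")) {
  writeLines(sprintf("c1ccccc1%s %s", seq_along(names), names), path)
  path
}

# a toy vina multi-model file with known scores, via the package writer once
# and via raw text here (independent of the generator)
write_raw_vina <- function(path, scores) {
  lines <- unlist(lapply(seq_along(scores), function(m) {
    c(sprintf("MODEL %d", m),
      sprintf("REMARK VINA RESULT: %8.1f      0.000      0.000", scores[m]),
      "ROOT",
      sprintf("ATOM      1  C1  LIG     1    %8.3f%8.3f%8.3f  1.00  0.00    -0.060 C ",
              1.0 * m, 0, 0),
      sprintf("ATOM      2  C2  LIG     1    %8.3f%8.3f%8.3f  1.00  0.00    -0.060 C ",
              1.0 * m + 1.5, 0, 0),
      "ENDROOT", "TORSDOF 0", "ENDMDL")
  }))
  writeLines(lines, path)
  path
}

expect_same_coords <- function(a, b, tol = 1e-3) {
  expect_equal(coords(a), coords(b), tolerance = tol, ignore_attr = TRUE)
}
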