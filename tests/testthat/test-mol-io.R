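# Format readers: PDB, PDBQT, multi-model Vina output, MOL2, label lists.

test_that("PDB reading preserves atoms, residues and backbone flags", {
  path <- write_toy_pdb(withr::local_tempfile(fileext = ".pdb"))
  mol <- read_pdb(path)
  expect_equal(nrow(mol$atoms), 15L)
  rt <- residue_table(mol)
  expect_equal(rt$resno, 1:3)
  expect_equal(rt$display, c("Ala1", "Ser2", "Gly3"))
  expect_equal(mol$atoms$x[2L], 1.458)
  # backbone flags: N/CA/C/O true, CB/OG false
  expect_true(all(mol$atoms$is_backbone[mol$atoms$name %in%
                                          c("N", "CA", "C", "O")]))
  expect_false(any(mol$atoms$is_backbone[mol$atoms$name %in% c("CB", "OG")]))

  # round trip through the writer
  out <- withr::local_tempfile(fileext = ".pdb")
  write_molecule(mol, out, "pdb")
  expect_same_coords(mol, read_pdb(out))

  # cross-check against an independent PDB reader
  bp <- bio3d::read.pdb(path)
  expect_equal(nrow(mol$atoms), nrow(bp$atom))
  expect_equal(unname(coords(mol)), unname(cbind(bp$atom$x, bp$atom$y,
                                                 bp$atom$z)))
  expect_equal(mol$atoms$resno, bp$atom$resno)
})

test_that("PDB edge cases: empty file, HETATM non-polymer, bad coordinates", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_pdb(empty), "no ATOM/HETATM")

  het <- write_het_pdb(withr::local_tempfile(fileext = ".pdb"))
  mol <- read_pdb(het)
  expect_false(any(mol$atoms$is_backbone))
  expect_equal(mol$atoms$element, c("C", "O", "N"))

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       xxx.xxx   0.000   0.000  1.00  0.00           C"),
    bad)
  expect_error(read_pdb(bad), "line 2")
})

test_that("PDBQT reading recovers charges and skips tree records", {
  lig <- ligand_probe("ammonium")
  path <- withr::local_tempfile(fileext = ".pdbqt")
  write_molecule(lig, path, "pdbqt", hetatm = TRUE)
  back <- read_pdbqt(path)
  expect_equal(back$atoms$charge, lig$atoms$charge, tolerance = 1e-3)
  expect_same_coords(lig, back)

  # receptor fragment: backbone flags survive the pdbqt round trip
  res <- residue_template("SER")
  p2 <- withr::local_tempfile(fileext = ".pdbqt")
  write_molecule(res, p2, "pdbqt")
  r2 <- read_pdbqt(p2)
  expect_equal(r2$atoms$is_backbone, res$atoms$is_backbone)

  only_tree <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c("ROOT", "ENDROOT", "TORSDOF 0"), only_tree)
  expect_error(read_pdbqt(only_tree), "no ATOM/HETATM")

  no_charge <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00",
    no_charge)
  expect_error(read_pdbqt(no_charge), "charge")
})

test_that("Vina multi-model output yields one scored pose per MODEL", {
  scores <- c(-9.1, -8.6, -8.0, -7.4, -7.0)
  path <- write_raw_vina(withr::local_tempfile(fileext = ".pdbqt"), scores)
  ps <- read_vina_poses(path)
  expect_length(ps$poses, 5L)
  expect_equal(ps$scores, scores)
  expect_equal(nrow(ps$poses[[3L]]$atoms), 2L)
  # file order is preserved, not re-sorted
  shuffled <- write_raw_vina(withr::local_tempfile(fileext = ".pdbqt"),
                             c(-7.0, -9.1))
  expect_equal(read_vina_poses(shuffled)$scores, c(-7.0, -9.1))

  single <- write_raw_vina(withr::local_tempfile(fileext = ".pdbqt"), -8.2)
  expect_length(read_vina_poses(single)$poses, 1L)
})

test_that("Vina reader rejects malformed model structure", {
  p <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c("MODEL 1", "REMARK VINA RESULT: -9.0 0 0", "MODEL 2"), p)
  expect_error(read_vina_poses(p), "MODEL")

  p2 <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c("MODEL 1",
               "ATOM      1  C1  LIG     1       0.000   0.000   0.000  1.00  0.00    -0.060 C ",
               "ENDMDL"), p2)
  expect_error(read_vina_poses(p2), "VINA RESULT")

  p3 <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines("REMARK nothing here", p3)
  expect_error(read_vina_poses(p3), "no MODEL")
})

test_that("MOL2 reading populates bonds and tolerates their absence", {
  path <- write_toy_mol2(withr::local_tempfile(fileext = ".mol2"))
  mol <- read_mol2(path)
  expect_equal(nrow(mol$atoms), 6L)
  expect_equal(nrow(mol$bonds), 6L)
  expect_true(all(mol$bonds$order == 1.5))   # aromatic ring
  expect_equal(mol$atoms$element, rep("C", 6L))
  expect_equal(mol$atoms$type, rep("C.ar", 6L))

  nb <- write_toy_mol2(withr::local_tempfile(fileext = ".mol2"),
                       with_bonds = FALSE)
  expect_equal(nrow(read_mol2(nb)$bonds), 0L)

  trunc <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "x", "1 0", "SMALL", "NONE",
               "@<TRIPOS>ATOM", "      1 C1  0.0 0.0"), trunc)
  expect_error(read_mol2(trunc), "truncated")

  noatom <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "x"), noatom)
  expect_error(read_mol2(noatom), "ATOM section")
})

test_that("label lists map names to caller-supplied labels", {
  p <- write_toy_ism(withr::local_tempfile(fileext = ".ism"))
  lab <- read_label_list(p, 1L)
  expect_equal(lab, c(CHEMBL1 = 1L, CHEMBL2 = 1L, CHEMBL3 = 1L))

  dup <- write_toy_ism(withr::local_tempfile(fileext = ".ism"),
                       names = c("A", "B", "A"))
  expect_error(read_label_list(dup, 0L), "duplicate.*A")

  noname <- withr::local_tempfile(fileext = ".ism")
  writeLines("c1ccccc1", noname)
  expect_error(read_label_list(noname, 1L), "no name")
  expect_equal(names(read_label_list(noname, 1L, auto_name = TRUE)), "line1")

  # union of actives + decoys keeps per-source labels
  act <- write_toy_ism(withr::local_tempfile(), c("A1", "A2"))
  dec <- write_toy_ism(withr::local_tempfile(), c("D1", "D2", "D3"))
  all_lab <- c(read_label_list(act, 1L), read_label_list(dec, 0L))
  expect_equal(sum(all_lab == 1L), 2L)
  expect_equal(sum(all_lab == 0L), 3L)
  expect_equal(length(all_lab), 5L)
})
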