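# Fingerprint computation: descriptor indexing and geometric detection.

test_that("bit indexing reproduces the published descriptor numbering", {
  rl <- ache_consensus_residues()
  t1 <- table1_descriptors()
  pos <- match(t1$residue, rl)
  expect_false(anyNA(pos))
  expect_equal(bit_index(pos, t1$type, n_residues = length(rl)), t1$index)
  expect_equal(bit_index(1L, "apolar"), 1L)

  # inverse mapping
  d <- describe_bit(t1$index, rl)
  expect_equal(d$residue, t1$residue)
  expect_equal(d$type, t1$type)

  # round trip over every (position, type) pair
  for (p in c(1L, 4L, 23L, 57L)) for (o in 1:7) {
    idx <- bit_index(p, o, n_residues = 57L)
    dd <- describe_bit(idx, rl)
    expect_equal(dd$residue, rl[p])
    expect_equal(dd$type, interaction_types()$label[o])
  }
  expect_error(bit_index(58L, "apolar", n_residues = 57L), "out of range")
  expect_error(describe_bit(400L, rl), "out of range")
  expect_error(describe_bit(0L, rl), "out of range")
})

test_that("planted geometries set exactly the expected detector bits", {
  # ammonium N ~3 A from the Asp carboxylate: residue-anion ionic, not cation
  cx <- make_complex(list(list(residue = "ASP", type = "ionic_protein_anion",
                               distance = 3.0)))
  b <- compute_plif(cx$receptor, cx$ligand, cx$residues, nobb = TRUE)
  blk <- b$bits[1:7]
  expect_true(blk[7L])
  expect_false(blk[6L])

  # stacked benzene over Phe: face-to-face at parallel planes, edge-to-face
  # after a 60 degree tilt
  cxf <- make_complex(list(list(residue = "PHE",
                                type = "aromatic_face_to_face",
                                distance = 3.6)))
  bf <- compute_plif(cxf$receptor, cxf$ligand, cxf$residues, nobb = TRUE)
  expect_true(bf$bits[2L]); expect_false(bf$bits[3L])
  cxe <- make_complex(list(list(residue = "PHE",
                                type = "aromatic_face_to_face",
                                distance = 3.6, angle = 60)))
  be <- compute_plif(cxe$receptor, cxe$ligand, cxe$residues, nobb = TRUE)
  expect_false(be$bits[2L]); expect_true(be$bits[3L])

  # remote ligand: all-zero fingerprint
  cx0 <- make_complex(list())
  b0 <- compute_plif(cx0$receptor, cx0$ligand, cx0$residues, nobb = FALSE)
  expect_false(any(b0$bits))

  expect_error(compute_plif(cx$receptor, cx$ligand, c("Asp1", "Lys99")),
               "Lys99")
})

test_that("nobb suppresses backbone-only hydrogen bonds", {
  # methanol donating to the backbone carbonyl O of an Ala residue
  res <- residue_template("ALA")
  o_pos <- unlist(res$atoms[res$atoms$name == "O", c("x", "y", "z")])
  ca <- unlist(res$atoms[res$atoms$name == "CA", c("x", "y", "z")])
  dir <- (o_pos - ca) / sqrt(sum((o_pos - ca)^2))
  probe <- ligand_probe("methanol")
  pf <- perceive_ligand(probe)
  d <- pf$donors[[1L]]
  pxyz <- as.matrix(probe$atoms[, c("x", "y", "z")])
  hvec <- pxyz[d$h[1L], ] - pxyz[d$heavy, ]
  R <- ensplif:::rotation_between(hvec, -dir)
  probe <- transform_molecule(probe, R, -as.vector(R %*% pxyz[d$heavy, ]))
  probe <- transform_molecule(probe, diag(3), o_pos + dir * 2.9)
  rec <- plif_mol(res$atoms, name = "ala")
  with_bb <- compute_plif(rec, probe, "Ala1", nobb = FALSE)
  no_bb <- compute_plif(rec, probe, "Ala1", nobb = TRUE)
  expect_true(with_bb$bits[5L])
  expect_false(no_bb$bits[5L])
})

test_that("fingerprints are invariant under rigid motion of the complex", {
  types <- interaction_types()$label
  for (seed in 1:5) {
    tp <- types[(seed %% 7L) + 1L]
    cx <- make_complex(list(list(type = tp, distance = 3.0,
                                 angle = if (tp == "aromatic_edge_to_face")
                                   60 else 0)), seed = seed)
    b0 <- compute_plif(cx$receptor, cx$ligand, cx$residues, nobb = TRUE)
    R <- random_rotation(seed = seed + 100L)
    t <- c(3.5, -12, 7)
    b1 <- compute_plif(transform_molecule(cx$receptor, R, t),
                       transform_molecule(cx$ligand, R, t),
                       cx$residues, nobb = TRUE)
    expect_equal(b1$bits, b0$bits)
  }
})

test_that("side-chain-only bits are a subset of the all-atom bits", {
  for (seed in 1:8) {
    tp <- interaction_types()$label[(seed %% 7L) + 1L]
    cx <- make_complex(list(list(type = tp, distance = 2.8 + 0.2 * seed,
                                 jitter = 0.05)), seed = seed)
    bn <- compute_plif(cx$receptor, cx$ligand, cx$residues, nobb = TRUE)
    bf <- compute_plif(cx$receptor, cx$ligand, cx$residues, nobb = FALSE)
    expect_true(all(!bn$bits | bf$bits))
  }
})

test_that("the detector agrees with a brute-force geometric oracle", {
  types <- interaction_types()$label
  for (seed in 1:25) {
    tp <- types[(seed %% 7L) + 1L]
    cx <- make_complex(list(list(type = tp,
                                 distance = 2.6 + (seed %% 5L) * 0.6,
                                 angle = (seed %% 3L) * 40,
                                 jitter = 0.1)),
                       seed = seed, rotate = TRUE)
    for (nobb in c(TRUE, FALSE)) {
      got <- compute_plif(cx$receptor, cx$ligand, cx$residues, nobb = nobb)
      want <- oracle_plif(cx$receptor, cx$ligand, cx$residues, nobb = nobb)
      expect_equal(got$bits, want)
    }
  }
})

test_that("fingerprint config files round-trip", {
  path <- withr::local_tempfile(fileext = ".config")
  prm <- geometry_params(apolar_cutoff = 4.0)
  write_plif_config(path, ache_consensus_residues(), nobb = TRUE,
                    params = prm)
  cfg <- read_plif_config(path)
  expect_equal(cfg$residues, ache_consensus_residues())
  expect_true(cfg$nobb)
  expect_equal(cfg$params$apolar_cutoff, 4.0)
  expect_equal(cfg$params$ionic_cutoff, 4.0)

  cx <- make_complex(list(list(type = "apolar", distance = 3.5)))
  b <- compute_plif(cx$receptor, cx$ligand, cx$residues)
  expect_equal(nchar(as_bitstring(b)), 7L)
  expect_equal(set_bits(b), which(b$bits))
})
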