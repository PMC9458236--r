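# Deterministic synthetic-fixture generators: planted-interaction complexes
# built from idealized residue geometries and small ligand probes, emulated
# docking outputs in the multi-model Vina format, and synthetic screening
# tables with a known planted decision rule. Everything is seeded; nothing
# here aims for physically realistic conformations or energies.

the <- new.env(parent = emptyenv())

#' Idealized residue geometry template
#'
#' Returns the idealized 3D geometry of one canonical amino-acid residue
#' (with hydrogens) from the packaged template file
#' `inst/extdata/residue_templates.pdb`. These are textbook idealized
#' geometries for fixture construction, not experimental coordinates.
#'
#' @param resname 3-letter residue code (e.g. `"ASP"`).
#' @return a [plif_mol()] of that single residue.
#' @export
residue_template <- function(resname) {
  resname <- toupper(resname)
  if (is.null(the$templates)) {
    path <- system.file("extdata", "residue_templates.pdb",
                        package = "ensplif")
    if (path == "") path <- file.path("inst", "extdata",
                                      "residue_templates.pdb")
    the$templates <- read_pdb(path)
  }
  a <- the$templates$atoms
  sel <- a$resname == resname
  if (!any(sel)) stop(sprintf("no template for residue '%s'", resname))
  atoms <- a[sel, , drop = FALSE]
  atoms$resno <- 1L
  atoms$chain <- "A"
  rownames(atoms) <- NULL
  plif_mol(atoms, name = resname)
}

# small ligand probes: name, element, xyz, charge, bonds
PROBES <- list(
  methane = list(
    atoms = data.frame(
      name = c("C1", "H1", "H2", "H3", "H4"),
      element = c("C", "H", "H", "H", "H"),
      x = c(0, 0.629, 0.629, -0.629, -0.629),
      y = c(0, 0.629, -0.629, 0.629, -0.629),
      z = c(0, 0.629, -0.629, -0.629, 0.629),
      charge = c(-0.06, 0.015, 0.015, 0.015, 0.015)),
    bonds = data.frame(i = 1L, j = 2:5, order = 1)),
  benzene = list(
    atoms = local({
      th <- seq(0, 300, by = 60) * pi / 180
      data.frame(
        name = c(paste0("C", 1:6), paste0("H", 1:6)),
        element = rep(c("C", "H"), each = 6L),
        x = c(1.39 * cos(th), 2.48 * cos(th)),
        y = c(1.39 * sin(th), 2.48 * sin(th)),
        z = 0,
        charge = rep(c(-0.06, 0.06), each = 6L))
    }),
    bonds = data.frame(i = c(1:6, 1:6), j = c(2:6, 1L, 7:12),
                       order = c(rep(1.5, 6), rep(1, 6)))),
  ammonium = list(
    atoms = data.frame(
      name = c("N1", "H1", "H2", "H3", "H4"),
      element = c("N", "H", "H", "H", "H"),
      x = c(0, 0.589, 0.589, -0.589, -0.589),
      y = c(0, 0.589, -0.589, 0.589, -0.589),
      z = c(0, 0.589, -0.589, -0.589, 0.589),
      charge = c(0.50, 0.125, 0.125, 0.125, 0.125)),
    bonds = data.frame(i = 1L, j = 2:5, order = 1)),
  acetate = list(
    atoms = data.frame(
      name = c("C1", "C2", "O1", "O2", "H1", "H2", "H3"),
      element = c("C", "C", "O", "O", "H", "H", "H"),
      x = c(-1.50, 0, 0.65, 0.65, -1.88, -1.88, -1.88),
      y = c(0, 0, 1.10, -1.10, 0.51, 0.51, -1.02),
      z = c(0, 0, 0, 0, 0.88, -0.88, 0),
      charge = c(-0.10, 0.40, -0.65, -0.65, 0.0, 0.0, 0.0)),
    bonds = data.frame(i = c(1L, 2L, 2L, 1L, 1L, 1L),
                       j = c(2L, 3L, 4L, 5L, 6L, 7L),
                       order = c(1, 1.5, 1.5, 1, 1, 1))),
  methanol = list(
    atoms = data.frame(
      name = c("C1", "O1", "HO", "H1", "H2", "H3"),
      element = c("C", "O", "H", "H", "H", "H"),
      x = c(0, 1.41, 1.75, -0.52, -0.36, -0.36),
      y = c(0, 0, 0.86, 0.90, -0.51, -0.51),
      z = c(0, 0, 0, 0, 0.89, -0.89),
      charge = c(0.12, -0.60, 0.40, 0.02, 0.02, 0.02)),
    bonds = data.frame(i = c(1L, 2L, 1L, 1L, 1L),
                       j = c(2L, 3L, 4L, 5L, 6L),
                       order = 1))
)

#' Build a small ligand probe
#'
#' Minimal ligand fragments with set partial charges and explicit bonds,
#' used to plant one interaction class at a time: `methane` (apolar),
#' `benzene` (aromatic + apolar), `ammonium` (cation + donor), `acetate`
#' (carboxylate anion + acceptors), `methanol` (donor + acceptor).
#'
#' @param which probe name.
#' @return a [plif_mol()].
#' @export
ligand_probe <- function(which = c("methane", "benzene", "ammonium",
                                   "acetate", "methanol")) {
  which <- match.arg(which)
  p <- PROBES[[which]]
  a <- p$atoms
  atoms <- data.frame(serial = seq_len(nrow(a)), name = a$name,
                      element = a$element, x = a$x, y = a$y, z = a$z,
                      charge = a$charge, resname = "LIG", resno = 1L,
                      icode = "", chain = "", is_backbone = FALSE,
                      type = "", stringsAsFactors = FALSE)
  plif_mol(atoms, p$bonds, name = which)
}

#' Apply a rigid motion to a molecule
#' @param mol a [plif_mol()].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (Angstrom).
#' @return the transformed molecule.
#' @export
transform_molecule <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(R)
  mol$atoms$x <- xyz[, 1L] + t[1L]
  mol$atoms$y <- xyz[, 2L] + t[2L]
  mol$atoms$z <- xyz[, 3L] + t[3L]
  mol
}

#' Random rotation matrix
#' @param seed RNG seed (optional; uses current RNG state when NULL).
#' @return orthonormal 3x3 matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  gen <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3L, 3L, byrow = TRUE)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- axis - sum(axis * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

probe_anchor <- function(probe, lf, type) {
  switch(type,
         apolar = lf$apolar[1L],
         aromatic_face_to_face = ,
         aromatic_edge_to_face = NA_integer_,   # anchored by ring centroid
         hbond_protein_donor = lf$acceptors[1L],
         hbond_protein_acceptor = lf$donors[[1L]]$heavy,
         ionic_protein_cation = lf$anions[[1L]][1L],
         ionic_protein_anion = lf$cations[[1L]][1L],
         stop(sprintf("unknown interaction type '%s'", type)))
}

default_probe <- function(type) {
  switch(type,
         apolar = "methane",
         aromatic_face_to_face = "benzene",
         aromatic_edge_to_face = "benzene",
         hbond_protein_donor = "methanol",
         hbond_protein_acceptor = "methanol",
         ionic_protein_cation = "acetate",
         ionic_protein_anion = "ammonium")
}

default_residue <- function(type) {
  switch(type,
         apolar = "LEU",
         aromatic_face_to_face = "PHE",
         aromatic_edge_to_face = "PHE",
         hbond_protein_donor = "SER",
         hbond_protein_acceptor = "SER",
         ionic_protein_cation = "LYS",
         ionic_protein_anion = "ASP")
}

# place one probe relative to one residue so the requested interaction
# geometry holds at the stated distance/angle
place_probe_for <- function(res_mol, type, probe_name, distance, angle) {
  probe <- ligand_probe(probe_name)
  feat <- perceive_residue(res_mol$atoms, include_backbone = FALSE)
  lf <- perceive_ligand(probe)
  rxyz <- as.matrix(res_mol$atoms[, c("x", "y", "z")])
  heavy_cen <- colMeans(rxyz[res_mol$atoms$element != "H", , drop = FALSE])

  if (type %in% c("aromatic_face_to_face", "aromatic_edge_to_face")) {
    if (length(feat$rings) == 0L)
      stop(sprintf("residue %s has no aromatic ring", res_mol$name))
    ring <- feat$rings[[1L]]
    lring <- lf$rings[[1L]]
    # align probe ring normal with residue ring normal, then tilt by `angle`
    R1 <- rotation_between(lring$normal, ring$normal)
    probe <- transform_molecule(probe, R1, -as.vector(R1 %*% lring$centroid))
    if (angle != 0) {
      ax <- ring$normal
      ortho <- if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      ortho <- ortho - sum(ortho * ax) * ax
      ortho <- ortho / sqrt(sum(ortho^2))
      th <- angle * pi / 180
      K <- matrix(c(0, -ortho[3], ortho[2], ortho[3], 0, -ortho[1],
                    -ortho[2], ortho[1], 0), 3L, 3L, byrow = TRUE)
      Rt <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      probe <- transform_molecule(probe, Rt)
    }
    target <- ring$centroid + ring$normal * distance
    probe <- transform_molecule(probe, diag(3), target)
    return(probe)
  }

  anchor_res <- switch(type,
    apolar = {
      if (length(feat$apolar) == 0L)
        stop(sprintf("residue %s has no apolar atoms", res_mol$name))
      feat$apolar[length(feat$apolar)]
    },
    hbond_protein_donor = feat$donors[[1L]]$heavy,
    hbond_protein_acceptor = feat$acceptors[1L],
    ionic_protein_cation = feat$cations[[1L]][1L],
    ionic_protein_anion = feat$anions[[1L]][1L])
  if (length(anchor_res) == 0L || is.na(anchor_res))
    stop(sprintf("residue %s lacks the features for '%s'",
                 res_mol$name, type))
  apos <- rxyz[anchor_res, ]
  dir <- apos - heavy_cen
  if (sqrt(sum(dir^2)) < 1e-6) dir <- c(1, 0, 0)
  dir <- dir / sqrt(sum(dir^2))
  target <- apos + dir * distance

  pidx <- probe_anchor(probe, lf, type)
  pxyz <- as.matrix(probe$atoms[, c("x", "y", "z")])
  if (type == "hbond_protein_acceptor") {
    # point the probe donor O-H bond at the residue acceptor
    d <- lf$donors[[1L]]
    hvec <- pxyz[d$h[1L], ] - pxyz[d$heavy, ]
    R <- rotation_between(hvec, -dir)
    probe <- transform_molecule(probe, R, -as.vector(R %*% pxyz[d$heavy, ]))
    probe <- transform_molecule(probe, diag(3), target)
  } else if (type == "hbond_protein_donor") {
    # keep the acceptor's lone-pair side toward the residue donor H
    probe <- transform_molecule(probe, diag(3),
                                target - pxyz[pidx, ])
    # residue donor H alignment: move target along D-H direction if H known
    dres <- feat$donors[[1L]]
    if (length(dres$h) > 0L) {
      hpos <- rxyz[dres$h[1L], ]
      dh <- hpos - apos
      dh <- dh / sqrt(sum(dh^2))
      shift <- (apos + dh * distance) -
        as.matrix(probe$atoms[pidx, c("x", "y", "z")])[1L, ]
      probe <- transform_molecule(probe, diag(3), as.numeric(shift))
    }
  } else {
    probe <- transform_molecule(probe, diag(3), target - pxyz[pidx, ])
  }
  probe
}

#' Generate a planted-interaction complex
#'
#' Builds a minimal receptor (single idealized residues spaced far apart)
#' and one ligand (possibly multi-fragment) in which each requested
#' (residue, interaction type) pair holds at the requested geometry. Specs
#' placed at `distance` beyond a detector cutoff act as negative controls.
#'
#' @param specs list of specs; each a list with `type` (one of
#'   [interaction_types()] labels), and optionally `residue` (3-letter
#'   code; a type-appropriate default otherwise), `probe` (see
#'   [ligand_probe()]), `distance` (Angstrom; measured anchor-to-anchor or
#'   centroid-to-centroid for aromatics), `angle` (degrees; aromatic plane
#'   tilt, default 0), and `jitter` (sd of Gaussian coordinate noise on the
#'   probe, default 0).
#' @param seed RNG seed (jitter and the optional global orientation).
#' @param rotate apply one random rigid rotation+translation to the whole
#'   complex (receptor and ligand together).
#' @param dir optional directory: when given, writes `receptor.pdbqt`,
#'   `ligand.pdbqt` and a `manifest.txt` there.
#' @return list with `receptor` and `ligand` ([plif_mol()]s), and
#'   `residues` (display names in receptor order).
#' @export
make_complex <- function(specs, seed = 1L, rotate = FALSE, dir = NULL) {
  if (length(specs) == 0L)   # all-zero-fingerprint complex: probe far away
    specs <- list(list(type = "apolar", distance = 50))
  with_seed(seed, {
    rec_atoms <- NULL
    lig_atoms <- NULL
    lig_bonds <- empty_bonds()
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      type <- sp$type
      resname <- toupper(sp$residue %||% default_residue(type))
      probe_name <- sp$probe %||% default_probe(type)
      distance <- sp$distance %||% 3.0
      angle <- sp$angle %||% 0
      jitter <- sp$jitter %||% 0

      res <- residue_template(resname)
      probe <- place_probe_for(res, type, probe_name, distance, angle)
      if (jitter > 0) {
        n <- nrow(probe$atoms)
        probe$atoms$x <- probe$atoms$x + stats::rnorm(n, 0, jitter)
        probe$atoms$y <- probe$atoms$y + stats::rnorm(n, 0, jitter)
        probe$atoms$z <- probe$atoms$z + stats::rnorm(n, 0, jitter)
      }
      off <- c(30 * (k - 1L), 0, 0)   # keep planted sites independent
      res <- transform_molecule(res, diag(3), off)
      probe <- transform_molecule(probe, diag(3), off)
      res$atoms$resno <- k
      probe$atoms$resno <- k
      nlig0 <- if (is.null(lig_atoms)) 0L else nrow(lig_atoms)
      pb <- probe$bonds
      if (nrow(pb) > 0L) {
        pb$i <- pb$i + nlig0
        pb$j <- pb$j + nlig0
      }
      rec_atoms <- rbind(rec_atoms, res$atoms)
      lig_atoms <- rbind(lig_atoms, probe$atoms)
      lig_bonds <- rbind(lig_bonds, pb)
    }
    rec_atoms$serial <- seq_len(nrow(rec_atoms))
    lig_atoms$serial <- seq_len(nrow(lig_atoms))
    receptor <- plif_mol(rec_atoms, name = "planted_receptor")
    ligand <- plif_mol(lig_atoms, lig_bonds, name = "planted_ligand")
    if (rotate) {
      R <- random_rotation()
      t <- stats::runif(3, -10, 10)
      receptor <- transform_molecule(receptor, R, t)
      ligand <- transform_molecule(ligand, R, t)
    }
    out <- list(receptor = receptor, ligand = ligand,
                residues = residue_table(receptor)$display)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_molecule(receptor, file.path(dir, "receptor.pdbqt"), "pdbqt")
      write_molecule(ligand, file.path(dir, "ligand.pdbqt"), "pdbqt",
                     hetatm = TRUE)
      writeLines(c(sprintf("seed %d", seed),
                   vapply(specs, function(sp)
                     sprintf("spec %s %s %s %.3f",
                             sp$residue %||% default_residue(sp$type),
                             sp$type, sp$probe %||% default_probe(sp$type),
                             sp$distance %||% 3.0), "")),
                 file.path(dir, "manifest.txt"))
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emulate multi-model Vina docking output files
#'
#' Writes `n_runs` multi-model PDBQT files, each with `n_modes` MODEL blocks
#' carrying `REMARK VINA RESULT` lines. Scores are drawn from
#' `N(score_mean, score_sd)` and sorted ascending within each run (docking
#' rank order). Poses are rigid jittered copies of a ligand probe.
#' Byte-identical under a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param n_runs number of independent runs (files).
#' @param n_modes binding modes per run.
#' @param score_mean,score_sd score model, kcal/mol.
#' @param probe probe name for the pose geometry.
#' @param seed RNG seed.
#' @param prefix file-name prefix.
#' @return character vector of file paths, plus a `manifest.txt`.
#' @export
make_vina_output <- function(dir, n_runs = 6L, n_modes = 5L,
                             score_mean = -8.5, score_sd = 0.8,
                             probe = "benzene", seed = 1L,
                             prefix = "run") {
  stopifnot(n_modes >= 1L, n_runs >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- ligand_probe(probe)
  paths <- character(n_runs)
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      scores <- sort(stats::rnorm(n_modes, score_mean, score_sd))
      lines <- character()
      for (m in seq_len(n_modes)) {
        pose <- transform_molecule(base, random_rotation(),
                                   stats::runif(3, -2, 2))
        lines <- c(lines,
                   sprintf("MODEL %d", m),
                   sprintf("REMARK VINA RESULT: %8.1f %10.3f %10.3f",
                           round(scores[m], 1), 0, 0),
                   format_atom_lines(pose, "pdbqt", hetatm = TRUE),
                   "ENDMDL")
      }
      paths[r] <- file.path(dir, sprintf("%s%d.pdbqt", prefix, r))
      writeLines(lines, paths[r])
    }
  })
  writeLines(c(sprintf("seed %d", seed),
               sprintf("runs %d modes %d score N(%.2f, %.2f)", n_runs,
                       n_modes, score_mean, score_sd),
               basename(paths)),
             file.path(dir, "manifest.txt"))
  paths
}

#' Generate a synthetic ensPLIF screening table
#'
#' Rows emulate the analysis-table structure: `y`, `name`, `dg`, `V1..Vn`
#' with every descriptor a fraction `k/denominator`. Active compounds
#' satisfy every condition of the planted rule (except with probability
#' `bit_noise` per condition); decoys and all unplanted descriptors follow
#' low background rates. Docking scores are drawn per class; the defaults
#' (actives N(-9.5, 0.5), decoys N(-7.5, 0.7) kcal/mol) make a cutoff near
#' -8.7 separate the classes imperfectly, as a realistic screen would. The
#' default class sizes emulate the DUD-E AChE benchmark balance
#' (453 actives, 26250 decoys, prevalence 0.017).
#'
#' @param n_active,n_decoy class sizes (`n_active + n_decoy >= 10`).
#' @param n_vars number of descriptor columns.
#' @param rule planted rule: list of conditions, each
#'   `list(var = "V5", threshold = 0.5, dir = ">=")` (dir `">="` or `"<"`),
#'   that active compounds satisfy.
#' @param bit_noise per-condition probability that an active ignores the
#'   rule.
#' @param active_score,decoy_score length-2 `(mean, sd)` kcal/mol.
#' @param denominator pose count behind the fractions (default 30 = 2
#'   receptors x 3 replicates x 5 modes).
#' @param seed RNG seed.
#' @return ensPLIF data.frame.
#' @export
make_table <- function(n_active = 453L, n_decoy = 26250L, n_vars = 30L,
                       rule = list(list(var = "V5", threshold = 0.5,
                                        dir = ">=")),
                       bit_noise = 0.05,
                       active_score = c(-9.5, 0.5),
                       decoy_score = c(-7.5, 0.7),
                       denominator = 30L, seed = 1L) {
  stopifnot(n_active + n_decoy >= 10L)
  with_seed(seed, {
    n <- n_active + n_decoy
    y <- c(rep(1L, n_active), rep(0L, n_decoy))
    base_p <- stats::runif(n_vars, 0.02, 0.20)
    V <- matrix(stats::rbinom(n * n_vars, denominator,
                              rep(base_p, each = n)) / denominator,
                nrow = n, ncol = n_vars)
    for (cond in rule) {
      v <- as.integer(sub("^V", "", cond$var))
      stopifnot(v >= 1L, v <= n_vars)
      kmin <- ceiling(cond$threshold * denominator)
      obey <- stats::runif(n_active) >= bit_noise
      hi <- sample(seq(kmin, denominator), n_active, replace = TRUE) /
        denominator
      lo <- sample(seq(0L, max(0L, kmin - 1L)), n_active, replace = TRUE) /
        denominator
      if (identical(cond$dir, ">=")) {
        V[seq_len(n_active), v] <- ifelse(obey, hi, V[seq_len(n_active), v])
      } else {
        V[seq_len(n_active), v] <- ifelse(obey, lo, V[seq_len(n_active), v])
      }
    }
    dg <- c(stats::rnorm(n_active, active_score[1L], active_score[2L]),
            stats::rnorm(n_decoy, decoy_score[1L], decoy_score[2L]))
    tab <- data.frame(y = y,
                      name = c(sprintf("act%04d", seq_len(n_active)),
                               sprintf("dec%05d", seq_len(n_decoy))),
                      dg = round(dg, 2), stringsAsFactors = FALSE)
    Vdf <- as.data.frame(V)
    names(Vdf) <- paste0("V", seq_len(n_vars))
    cbind(tab, Vdf)
  })
}
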