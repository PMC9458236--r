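# Chemical feature perception for interaction detection.
#
# Protein residues are perceived from per-residue atom-name templates (the 20
# canonical amino acids, PDB naming); ligands are perceived from geometry +
# partial charges because docking-output PDBQT carries no bond records (MOL2
# bonds are trusted when present).

# side-chain feature templates; apolar = side-chain C/S with no O/N neighbour
RESIDUE_TEMPLATES <- list(
  ALA = list(apolar = "CB"),
  ARG = list(apolar = c("CB", "CG"),
             cations = list(c("NE", "CZ", "NH1", "NH2")),
             donors = list(c("NE", "HE"), c("NH1", "HH11", "HH12"),
                           c("NH2", "HH21", "HH22"))),
  ASN = list(apolar = "CB", donors = list(c("ND2", "HD21", "HD22")),
             acceptors = "OD1"),
  ASP = list(apolar = "CB", anions = list(c("OD1", "OD2")),
             acceptors = c("OD1", "OD2")),
  CYS = list(apolar = c("CB", "SG")),
  GLN = list(apolar = c("CB", "CG"), donors = list(c("NE2", "HE21", "HE22")),
             acceptors = "OE1"),
  GLU = list(apolar = c("CB", "CG"), anions = list(c("OE1", "OE2")),
             acceptors = c("OE1", "OE2")),
  GLY = list(),
  HIS = list(apolar = "CB", rings = list(c("CG", "ND1", "CD2", "CE1", "NE2"))),
  ILE = list(apolar = c("CB", "CG1", "CG2", "CD1", "CD")),
  LEU = list(apolar = c("CB", "CG", "CD1", "CD2")),
  LYS = list(apolar = c("CB", "CG", "CD"), cations = list("NZ"),
             donors = list(c("NZ", "HZ1", "HZ2", "HZ3"))),
  MET = list(apolar = c("CB", "CG", "SD", "CE")),
  PHE = list(apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             rings = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))),
  PRO = list(apolar = c("CB", "CG")),
  SER = list(donors = list(c("OG", "HG")), acceptors = "OG"),
  THR = list(apolar = "CG2", donors = list(c("OG1", "HG1")),
             acceptors = "OG1"),
  TRP = list(apolar = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
             rings = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                          c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
             donors = list(c("NE1", "HE1"))),
  TYR = list(apolar = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
             rings = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
             donors = list(c("OH", "HH")), acceptors = "OH"),
  VAL = list(apolar = c("CB", "CG1", "CG2"))
)

HIS_ALIASES <- c(HID = "HIS", HIE = "HIS", HIP = "HIS", CYX = "CYS")

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, CL = 1.02, BR = 1.20, I = 1.39,
                    B = 0.84, SE = 1.20)
HALOGENS <- c("F", "CL", "BR", "I")

empty_features <- function() {
  list(apolar = integer(), rings = list(), donors = list(),
       acceptors = integer(), cations = list(), anions = list())
}

#' Fit a plane through ring atoms
#'
#' Least-squares plane through three or more non-collinear points.
#'
#' @param xyz numeric matrix (n x 3) of atom coordinates in Angstrom.
#' @return list with `centroid` (3-vector) and `normal` (unit 3-vector; the
#'   sign is arbitrary, consumers use absolute angles).
#' @export
ring_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3L) stop("ring plane needs at least 3 atoms")
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2L, centroid)
  sv <- svd(centered)
  if (sv$d[2L] < 1e-6 * max(sv$d[1L], 1e-12))
    stop("ring atoms are collinear; no unique plane")
  normal <- sv$v[, 3L]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

#' Perceive interaction features of one protein residue
#'
#' Template-driven perception for the 20 canonical amino acids (PDB atom
#' naming; HID/HIE/HIP/CYX aliases accepted). Histidine protonation follows
#' the atom records: neutral tautomers donate from the protonated ring
#' nitrogen and accept on the unprotonated one; only when both HD1 and HE2
#' are present is the imidazolium treated as cationic. Asp/Glu are always
#' anionic and Lys/Arg always cationic, matching a pH 7.4 preparation.
#' Backbone N (donor) and O/OXT (acceptor) features are included only when
#' `include_backbone` is TRUE; apolar sets never include backbone atoms.
#'
#' @param atoms atom table rows (as in a [plif_mol()]) for one residue.
#' @param include_backbone include backbone H-bond features.
#' @return feature list: `apolar` (indices into `atoms` rows), `rings`
#'   (each with `idx`, `centroid`, `normal`), `donors` (each with `heavy`,
#'   `h`), `acceptors`, `cations`, `anions` (lists of index vectors).
#' @export
perceive_residue <- function(atoms, include_backbone = TRUE) {
  resname <- toupper(atoms$resname[1L])
  if (resname %in% names(HIS_ALIASES)) resname <- HIS_ALIASES[[resname]]
  tpl <- RESIDUE_TEMPLATES[[resname]]
  if (is.null(tpl))
    stop(sprintf("unknown residue name '%s' (no perception template)",
                 atoms$resname[1L]))
  idx_of <- function(nms) which(atoms$name %in% nms)
  f <- empty_features()
  f$apolar <- idx_of(tpl$apolar)
  for (ring_names in tpl$rings) {
    ridx <- match(ring_names, atoms$name)
    if (anyNA(ridx)) next  # incomplete side chain: skip the ring
    pl <- ring_plane(as.matrix(atoms[ridx, c("x", "y", "z")]))
    f$rings[[length(f$rings) + 1L]] <-
      list(idx = ridx, centroid = pl$centroid, normal = pl$normal)
  }
  for (d in tpl$donors) {
    heavy <- match(d[1L], atoms$name)
    if (is.na(heavy)) next
    f$donors[[length(f$donors) + 1L]] <-
      list(heavy = heavy, h = idx_of(d[-1L]))
  }
  f$acceptors <- idx_of(tpl$acceptors)
  f$cations <- lapply(tpl$cations, idx_of)
  f$cations <- Filter(function(g) length(g) > 0L, f$cations)
  f$anions <- lapply(tpl$anions, idx_of)
  f$anions <- Filter(function(g) length(g) > 0L, f$anions)

  if (resname == "HIS") {
    nd1 <- match("ND1", atoms$name); ne2 <- match("NE2", atoms$name)
    hd1 <- match("HD1", atoms$name); he2 <- match("HE2", atoms$name)
    if (!is.na(nd1) && !is.na(ne2)) {
      if (!is.na(hd1) && !is.na(he2)) {              # imidazolium
        f$cations <- list(c(nd1, ne2))
        f$donors <- c(f$donors, list(list(heavy = nd1, h = hd1),
                                     list(heavy = ne2, h = he2)))
      } else if (!is.na(hd1)) {                      # ND1-protonated tautomer
        f$donors <- c(f$donors, list(list(heavy = nd1, h = hd1)))
        f$acceptors <- c(f$acceptors, ne2)
      } else {                                       # NE2 tautomer (default)
        f$donors <- c(f$donors,
                      list(list(heavy = ne2,
                                h = if (is.na(he2)) integer() else he2)))
        f$acceptors <- c(f$acceptors, nd1)
      }
    }
  }

  if (include_backbone) {
    n_idx <- which(atoms$name == "N" & atoms$is_backbone)
    if (length(n_idx) == 1L) {
      hs <- which(atoms$name %in% c("H", "HN", "H1", "H2", "H3") &
                    atoms$is_backbone)
      f$donors <- c(f$donors, list(list(heavy = n_idx, h = hs)))
    }
    f$acceptors <- c(f$acceptors,
                     which(atoms$name %in% c("O", "OXT") & atoms$is_backbone))
  }
  f
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is at most the sum of their
#' covalent radii plus 0.45 Angstrom (and above 0.4 Angstrom). Used for
#' PDBQT ligands, which carry no bond records.
#'
#' @param mol a [plif_mol()].
#' @return bond data.frame (`i`, `j`, `order` = 1).
#' @export
infer_bonds <- function(mol) {
  a <- mol$atoms
  n <- nrow(a)
  if (n < 2L) return(empty_bonds())
  r <- COVALENT_RADII[a$element]
  r[is.na(r)] <- 0.77
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+") + 0.45
  hit <- which(d <= thr & d > 0.4 & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty_bonds())
  data.frame(i = hit[, 1L], j = hit[, 2L], order = 1)
}

# smallest rings (size 3-8) through each edge, via shortest paths in the
# heavy-atom bond graph with the edge removed
find_rings <- function(n_atoms, bonds, heavy) {
  hb <- bonds[bonds$i %in% heavy & bonds$j %in% heavy, , drop = FALSE]
  if (nrow(hb) == 0L) return(list())
  g <- igraph::graph_from_edgelist(cbind(hb$i, hb$j), directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  rings <- list()
  seen <- character()
  for (e in seq_len(nrow(hb))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(hb$i[e], hb$j[e])))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = hb$i[e], to = hb$j[e])$vpath[[1L]])
    if (length(sp) >= 3L && length(sp) <= 8L) {
      ring <- sort(as.integer(sp))
      key <- paste(ring, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- as.integer(sp)
      }
    }
  }
  rings
}

#' Perceive interaction features of a ligand
#'
#' Rule-driven perception over the whole molecule. Bonds are taken from the
#' molecule when present, otherwise inferred with [infer_bonds()]. Rings come
#' from the smallest cycles of the heavy-atom bond graph; a ring is aromatic
#' when all members are C/N/O/S, every member has at most three heavy
#' neighbours, and the ring is planar within a 7.5 degree mean out-of-plane
#' deviation. Donors are N/O with at least one bound hydrogen; acceptors are
#' N/O that are not positively charged; cation centres are quaternary N or
#' atoms with partial charge >= +0.30 e; anion groups are
#' carboxylate/phosphate/sulfate terminal-oxygen pairs or single O with
#' charge <= -0.30 e; apolar atoms are C/S bonded only to C/S/H, plus
#' halogens.
#'
#' @param mol a [plif_mol()] ligand.
#' @return feature list in the same layout as [perceive_residue()].
#' @export
perceive_ligand <- function(mol) {
  a <- mol$atoms
  if (nrow(a) == 0L) stop("cannot perceive features of a zero-atom molecule")
  bonds <- if (nrow(mol$bonds) > 0L) mol$bonds else infer_bonds(mol)
  n <- nrow(a)
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    nbrs[[bonds$i[k]]] <- c(nbrs[[bonds$i[k]]], bonds$j[k])
    nbrs[[bonds$j[k]]] <- c(nbrs[[bonds$j[k]]], bonds$i[k])
  }
  el <- a$element
  heavy <- which(el != "H")
  heavy_deg <- vapply(seq_len(n), function(i)
    sum(el[nbrs[[i]]] != "H"), 0L)
  all_deg <- lengths(nbrs)

  f <- empty_features()

  # rings + aromaticity
  for (ring in find_rings(n, bonds, heavy)) {
    if (!all(el[ring] %in% c("C", "N", "O", "S"))) next
    if (any(heavy_deg[ring] > 3L)) next
    xyz <- as.matrix(a[ring, c("x", "y", "z")])
    pl <- tryCatch(ring_plane(xyz), error = function(e) NULL)
    if (is.null(pl)) next
    centered <- sweep(xyz, 2L, pl$centroid)
    vlen <- sqrt(rowSums(centered^2))
    oop <- asin(pmin(1, abs(centered %*% pl$normal) / pmax(vlen, 1e-9)))
    if (mean(oop) * 180 / pi > 7.5) next
    f$rings[[length(f$rings) + 1L]] <-
      list(idx = ring, centroid = pl$centroid, normal = pl$normal)
  }

  # charged groups
  cation_atoms <- integer()
  for (i in which(el == "N")) {
    if (all_deg[i] == 4L || a$charge[i] >= 0.30) {
      f$cations[[length(f$cations) + 1L]] <- i
      cation_atoms <- c(cation_atoms, i)
    }
  }
  grouped_o <- integer()
  for (c_at in which(el %in% c("C", "P", "S"))) {
    o_nb <- nbrs[[c_at]][el[nbrs[[c_at]]] == "O"]
    terminal_o <- o_nb[heavy_deg[o_nb] == 1L]
    if (length(terminal_o) >= 2L) {
      f$anions[[length(f$anions) + 1L]] <- sort(terminal_o)
      grouped_o <- c(grouped_o, terminal_o)
    }
  }
  for (i in which(el == "O")) {
    if (!(i %in% grouped_o) && a$charge[i] <= -0.30)
      f$anions[[length(f$anions) + 1L]] <- i
  }

  # donors / acceptors
  for (i in which(el %in% c("N", "O"))) {
    hs <- nbrs[[i]][el[nbrs[[i]]] == "H"]
    if (length(hs) > 0L)
      f$donors[[length(f$donors) + 1L]] <- list(heavy = i, h = hs)
  }
  f$acceptors <- which(el %in% c("N", "O") & a$charge < 0.30 &
                         !(seq_len(n) %in% cation_atoms) & all_deg < 4L)

  # apolar
  ap <- vapply(seq_len(n), function(i) {
    if (el[i] %in% HALOGENS) return(TRUE)
    if (!el[i] %in% c("C", "S")) return(FALSE)
    all(el[nbrs[[i]]] %in% c("C", "S", "H"))
  }, logical(1L))
  f$apolar <- which(ap)
  f
}
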