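# Structure-file readers: PDB, AutoDock PDBQT (single- and multi-model docking
# output), Tripos MOL2, and SMILES-with-name label lists. All readers normalise
# into one atom-table molecule model so interaction detection is format-blind.

#' @importFrom stats setNames
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "HID", "HIE", "HIP", "ILE", "LEU", "LYS", "MET",
                 "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL", "CYX")

# Backbone atom names for standard residues: N/CA/C/O/OXT plus amide and
# alpha hydrogens (Gly contributes HA2/HA3).
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT",
                    "H", "H1", "H2", "H3", "HN", "HA", "HA2", "HA3")

AD_TYPE_ELEMENT <- c(H = "H", HD = "H", HS = "H", C = "C", A = "C",
                     N = "N", NA. = "N", NS = "N", OA = "O", OS = "O",
                     F = "F", MG = "MG", P = "P", SA = "S", S = "S",
                     CL = "CL", CA = "CA", MN = "MN", FE = "FE",
                     ZN = "ZN", BR = "BR", I = "I")
names(AD_TYPE_ELEMENT)[names(AD_TYPE_ELEMENT) == "NA."] <- "NA"

#' Construct a molecule object
#'
#' The internal molecular model shared by all readers: an ordered atom table,
#' an optional bond list, and a name. Atom order always follows file order.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `x`, `y`,
#'   `z`, `charge`, `resname`, `resno`, `icode`, `chain`, `is_backbone`, and
#'   optionally `type` (AutoDock or SYBYL atom type annotation).
#' @param bonds data.frame with columns `i`, `j`, `order` (atom indices into
#'   `atoms`), or an empty data.frame when connectivity is unknown.
#' @param name molecule name.
#' @return An object of class `plif_mol`.
#' @export
plif_mol <- function(atoms, bonds = empty_bonds(), name = "") {
  stopifnot(is.data.frame(atoms))
  if (nrow(bonds) > 0L) {
    idx <- c(bonds$i, bonds$j)
    if (any(idx < 1L | idx > nrow(atoms)))
      stop("bond endpoints must be valid atom indices")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "plif_mol")
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), order = numeric())
}

#' @export
print.plif_mol <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "icode")]))
  cat(sprintf("<plif_mol '%s': %d atoms, %d bonds, %d residues>\n",
              x$name, nrow(x$atoms), nrow(x$bonds), nres))
  invisible(x)
}

#' Coordinates of a molecule as a matrix
#' @param mol a `plif_mol`.
#' @param heavy drop hydrogens first.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(mol, heavy = FALSE) {
  a <- mol$atoms
  if (heavy) a <- a[a$element != "H", , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

element_from_name <- function(name) {
  # strip digits and primes, keep leading alpha token
  core <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(core, 1L, 2L))
  ifelse(two %in% c("CL", "BR", "MG", "ZN", "FE", "MN", "SE"),
         two, toupper(substr(core, 1L, 1L)))
}

parse_num_field <- function(txt, what, lineno, path) {
  v <- suppressWarnings(as.numeric(trimws(txt)))
  bad <- which(!is.finite(v))
  if (length(bad) > 0L)
    stop(sprintf("malformed %s field in '%s' at line %d: '%s'",
                 what, path, lineno[bad[1L]], trimws(txt[bad[1L]])),
         call. = FALSE)
  v
}

# Shared fixed-column ATOM/HETATM parser for PDB and PDBQT dialects.
parse_atom_records <- function(lines, lineno, format, path) {
  if (length(lines) == 0L)
    stop(sprintf("no ATOM/HETATM records found in '%s'", path), call. = FALSE)
  rec    <- trimws(substr(lines, 1L, 6L))
  serial <- suppressWarnings(as.integer(trimws(substr(lines, 7L, 11L))))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  name   <- trimws(substr(lines, 13L, 16L))
  altloc <- substr(lines, 17L, 17L)
  resname <- trimws(substr(lines, 18L, 20L))
  chain  <- substr(lines, 22L, 22L)
  resno  <- suppressWarnings(as.integer(trimws(substr(lines, 23L, 26L))))
  resno[is.na(resno)] <- 1L
  icode  <- substr(lines, 27L, 27L)
  icode[icode == " "] <- ""
  x <- parse_num_field(substr(lines, 31L, 38L), "x-coordinate", lineno, path)
  y <- parse_num_field(substr(lines, 39L, 46L), "y-coordinate", lineno, path)
  z <- parse_num_field(substr(lines, 47L, 54L), "z-coordinate", lineno, path)

  if (format == "pdbqt") {
    qtxt <- substr(lines, 67L, 76L)
    if (any(trimws(qtxt) == ""))
      stop(sprintf("missing partial-charge column in '%s' at line %d",
                   path, lineno[which(trimws(qtxt) == "")[1L]]), call. = FALSE)
    charge <- parse_num_field(qtxt, "partial-charge", lineno, path)
    adtype <- trimws(substr(lines, 78L, 79L))
    element <- AD_TYPE_ELEMENT[toupper(adtype)]
    element[is.na(element)] <- element_from_name(name[is.na(element)])
    type <- adtype
  } else {
    charge <- rep(0, length(lines))
    eltxt <- trimws(substr(lines, 77L, 78L))
    element <- ifelse(eltxt == "", element_from_name(name), toupper(eltxt))
    type <- rep("", length(lines))
  }
  # single-letter elements stay as-is; normalise e.g. "Cl" handled above
  is_bb <- rec == "ATOM" & resname %in% STANDARD_AA & name %in% BACKBONE_NAMES

  atoms <- data.frame(serial = serial, name = name, element = element,
                      x = x, y = y, z = z, charge = charge,
                      resname = resname, resno = resno, icode = icode,
                      chain = chain, is_backbone = is_bb, type = type,
                      stringsAsFactors = FALSE)

  # altloc policy: keep the first alternate location, warn once
  alt <- altloc != " " & altloc != ""
  if (any(alt)) {
    key <- paste(chain, resno, icode, name)
    keep <- !duplicated(key)
    if (any(!keep))
      warning(sprintf("'%s': alternate locations present; keeping first altloc (%d atoms dropped)",
                      path, sum(!keep)), call. = FALSE)
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  atoms
}

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  readLines(path, warn = FALSE)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records into the internal molecule model. Backbone
#' flags are assigned from atom names for the standard amino-acid residues;
#' HETATM (non-polymer) atoms are never flagged as backbone. Insertion codes
#' are preserved as part of residue identity. Alternate locations keep the
#' first altloc with a warning.
#'
#' @param path path to a PDB file.
#' @return a [plif_mol()].
#' @export
read_pdb <- function(path) {
  lines <- read_lines_checked(path)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  atoms <- parse_atom_records(lines[sel], which(sel), "pdb", path)
  plif_mol(atoms, name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read an AutoDock PDBQT file
#'
#' Like [read_pdb()] but additionally reads the partial-charge column (e) and
#' the AutoDock atom type, which is kept in the `type` atom annotation.
#' Flexibility-tree records (ROOT/BRANCH/TORSDOF etc.) are tolerated and
#' skipped; both ATOM and HETATM records count as atoms.
#'
#' @param path path to a PDBQT file.
#' @return a [plif_mol()] with `charge` populated.
#' @export
read_pdbqt <- function(path) {
  lines <- read_lines_checked(path)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  atoms <- parse_atom_records(lines[sel], which(sel), "pdbqt", path)
  plif_mol(atoms, name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read multi-model AutoDock Vina docking output
#'
#' Parses a multi-model PDBQT as written by AutoDock Vina: MODEL/ENDMDL
#' blocks, each carrying a `REMARK VINA RESULT: <affinity> <rmsd_lb>
#' <rmsd_ub>` line. One pose and one score (the affinity, kcal/mol) are
#' produced per MODEL, in file order; the reader asserts nothing about score
#' ordering.
#'
#' @param path path to the docking output file.
#' @param source_tag free-form provenance tag (receptor id + replicate id).
#' @return a `pose_set`: list with `poses` (list of [plif_mol()]), `scores`
#'   (numeric, kcal/mol) and `source_tag`.
#' @export
read_vina_poses <- function(path, source_tag = basename(path)) {
  lines <- read_lines_checked(path)
  open_at <- NA_integer_
  blocks <- list()
  for (k in seq_along(lines)) {
    if (grepl("^MODEL", lines[k])) {
      if (!is.na(open_at))
        stop(sprintf("'%s': MODEL at line %d before ENDMDL of MODEL at line %d",
                     path, k, open_at), call. = FALSE)
      open_at <- k
    } else if (grepl("^ENDMDL", lines[k])) {
      if (is.na(open_at))
        stop(sprintf("'%s': ENDMDL at line %d without open MODEL", path, k),
             call. = FALSE)
      blocks[[length(blocks) + 1L]] <- c(open_at, k)
      open_at <- NA_integer_
    }
  }
  if (!is.na(open_at))
    stop(sprintf("'%s': MODEL at line %d is never closed", path, open_at),
         call. = FALSE)
  if (length(blocks) == 0L)
    stop(sprintf("'%s': no MODEL blocks found", path), call. = FALSE)

  poses <- vector("list", length(blocks))
  scores <- numeric(length(blocks))
  for (b in seq_along(blocks)) {
    rng <- blocks[[b]][1L]:blocks[[b]][2L]
    blk <- lines[rng]
    res <- grep("^REMARK VINA RESULT:", blk, value = TRUE)
    if (length(res) == 0L)
      stop(sprintf("'%s': MODEL starting at line %d has no 'REMARK VINA RESULT' line",
                   path, blocks[[b]][1L]), call. = FALSE)
    toks <- strsplit(trimws(sub("^REMARK VINA RESULT:", "", res[1L])),
                     "\\s+")[[1L]]
    scores[b] <- as.numeric(toks[1L])
    if (!is.finite(scores[b]))
      stop(sprintf("'%s': unparseable VINA RESULT affinity in MODEL at line %d",
                   path, blocks[[b]][1L]), call. = FALSE)
    sel <- grepl("^(ATOM  |HETATM)", blk)
    atoms <- parse_atom_records(blk[sel], rng[sel], "pdbqt", path)
    poses[[b]] <- plif_mol(atoms, name = sprintf("%s_mode%d", source_tag, b))
  }
  pose_set(poses, scores, source_tag)
}

#' Construct a pose set
#' @param poses list of [plif_mol()] in docking rank (file) order.
#' @param scores numeric docking scores (kcal/mol), one per pose.
#' @param source_tag provenance tag.
#' @return object of class `pose_set`.
#' @export
pose_set <- function(poses, scores, source_tag = "") {
  if (length(poses) != length(scores))
    stop("poses and scores must have equal length")
  structure(list(poses = poses, scores = as.numeric(scores),
                 source_tag = source_tag), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set '%s': %d poses, scores [%s] kcal/mol>\n",
              x$source_tag, length(x$poses),
              paste(format(x$scores, digits = 3), collapse = ", ")))
  invisible(x)
}

MOL2_ORDER <- c("1" = 1, "2" = 2, "3" = 3, ar = 1.5, am = 1, du = 0,
                un = 0, nc = 0)

#' Read a Tripos MOL2 file
#'
#' Reads the `@<TRIPOS>ATOM` section (required) and the `@<TRIPOS>BOND`
#' section (optional; bonds are empty when absent). SYBYL atom types are
#' kept in the `type` annotation; aromatic bonds get order 1.5.
#'
#' @param path path to a MOL2 file.
#' @return a [plif_mol()] with bonds when the file provides them.
#' @export
read_mol2 <- function(path) {
  lines <- read_lines_checked(path)
  tags <- grep("^@<TRIPOS>", lines)
  section <- function(nm) {
    at <- which(lines[tags] == paste0("@<TRIPOS>", nm))
    if (length(at) == 0L) return(NULL)
    from <- tags[at[1L]] + 1L
    to <- if (at[1L] < length(tags)) tags[at[1L] + 1L] - 1L else length(lines)
    if (to < from) return(integer(0))
    (from:to)[trimws(lines[from:to]) != ""]
  }
  mol_sec <- section("MOLECULE")
  name <- if (!is.null(mol_sec) && length(mol_sec) > 0L)
    trimws(lines[mol_sec[1L]]) else sub("\\.[^.]*$", "", basename(path))
  atom_sec <- section("ATOM")
  if (is.null(atom_sec) || length(atom_sec) == 0L)
    stop(sprintf("'%s': missing @<TRIPOS>ATOM section", path), call. = FALSE)

  n <- length(atom_sec)
  fields <- strsplit(trimws(lines[atom_sec]), "\\s+")
  short <- which(vapply(fields, length, 1L) < 6L)
  if (length(short) > 0L)
    stop(sprintf("'%s': truncated ATOM line %d", path, atom_sec[short[1L]]),
         call. = FALSE)
  get <- function(i) vapply(fields, function(f) f[i], "")
  getn <- function(i, what) parse_num_field(get(i), what, atom_sec, path)
  sybyl <- get(6L)
  nf <- vapply(fields, length, 1L)
  subst_name <- ifelse(nf >= 8L, vapply(fields, function(f)
    if (length(f) >= 8L) f[8L] else "LIG", ""), "LIG")
  charge <- vapply(seq_len(n), function(k)
    if (nf[k] >= 9L) suppressWarnings(as.numeric(fields[[k]][9L])) else 0,
    0)
  charge[!is.finite(charge)] <- 0
  resname <- toupper(gsub("[0-9]+$", "", subst_name))
  resname[resname == ""] <- "LIG"
  resno <- suppressWarnings(as.integer(vapply(seq_len(n), function(k)
    if (nf[k] >= 7L) fields[[k]][7L] else "1", "")))
  resno[is.na(resno)] <- 1L

  atoms <- data.frame(
    serial = as.integer(getn(1L, "atom id")),
    name = get(2L),
    element = toupper(sub("\\..*$", "", sybyl)),
    x = getn(3L, "x-coordinate"), y = getn(4L, "y-coordinate"),
    z = getn(5L, "z-coordinate"),
    charge = charge, resname = resname, resno = resno,
    icode = "", chain = "",
    is_backbone = FALSE, type = sybyl, stringsAsFactors = FALSE)
  # SYBYL residues may actually be protein (e.g. a MOL2 receptor); flag
  # backbone for standard residue names by atom-name convention
  bb <- atoms$resname %in% STANDARD_AA & atoms$name %in% BACKBONE_NAMES
  atoms$is_backbone <- bb

  bonds <- empty_bonds()
  bond_sec <- section("BOND")
  if (!is.null(bond_sec) && length(bond_sec) > 0L) {
    bf <- strsplit(trimws(lines[bond_sec]), "\\s+")
    short <- which(vapply(bf, length, 1L) < 4L)
    if (length(short) > 0L)
      stop(sprintf("'%s': truncated BOND line %d", path, bond_sec[short[1L]]),
           call. = FALSE)
    ord <- MOL2_ORDER[tolower(vapply(bf, function(f) f[4L], ""))]
    ord[is.na(ord)] <- 1
    id <- setNames(seq_len(n), as.character(atoms$serial))
    bonds <- data.frame(
      i = as.integer(id[vapply(bf, function(f) f[2L], "")]),
      j = as.integer(id[vapply(bf, function(f) f[3L], "")]),
      order = as.numeric(ord))
    if (any(is.na(bonds$i) | is.na(bonds$j)))
      stop(sprintf("'%s': bond references unknown atom id", path),
           call. = FALSE)
  }
  plif_mol(atoms, bonds, name = name)
}

#' Read a SMILES-with-name compound list
#'
#' Reads whitespace-separated text in the ".ism" style: SMILES in the first
#' column, compound name in the next token. SMILES strings are carried as
#' opaque text and never interpreted chemically; the caller supplies the
#' binary activity label the file represents.
#'
#' @param path path to the list file.
#' @param label binary label to assign to every compound in this file
#'   (1 = active, 0 = decoy).
#' @param auto_name when TRUE, lines lacking a name token are named
#'   `line<i>` by their line index instead of raising an error.
#' @return named integer vector mapping compound name to `label`.
#' @export
read_label_list <- function(path, label, auto_name = FALSE) {
  stopifnot(label %in% c(0L, 1L))
  lines <- read_lines_checked(path)
  lines <- lines[trimws(lines) != ""]
  toks <- strsplit(trimws(lines), "\\s+")
  nms <- vapply(seq_along(toks), function(k) {
    tk <- toks[[k]]
    if (length(tk) >= 2L) tk[2L]
    else if (auto_name) sprintf("line%d", k)
    else stop(sprintf("'%s': line %d has a SMILES but no name token",
                      path, k), call. = FALSE)
  }, "")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0L)
    stop(sprintf("'%s': duplicate compound names: %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  setNames(rep(as.integer(label), length(nms)), nms)
}

#' Write a molecule as PDB or PDBQT
#'
#' Fixed-column writer used by the synthetic-fixture generators; PDBQT output
#' carries the partial charge and the `type` annotation (falling back to the
#' element symbol).
#'
#' @param mol a [plif_mol()].
#' @param path output path.
#' @param format `"pdb"` or `"pdbqt"`.
#' @param hetatm write HETATM records instead of ATOM.
#' @return `path`, invisibly.
#' @export
write_molecule <- function(mol, path, format = c("pdb", "pdbqt"),
                           hetatm = FALSE) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_atom_lines(mol, format, hetatm), con)
  writeLines("END", con)
  invisible(path)
}

format_atom_lines <- function(mol, format, hetatm = FALSE) {
  a <- mol$atoms
  rec <- if (hetatm) "HETATM" else "ATOM  "
  nm <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1L, 4L),
               sprintf(" %-3s", a$name))
  base <- sprintf("%s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                  rec, a$serial, nm, substr(a$resname, 1L, 3L),
                  ifelse(a$chain == "", "A", a$chain), a$resno,
                  ifelse(a$icode == "", " ", a$icode),
                  a$x, a$y, a$z, 1, 0)
  if (format == "pdbqt") {
    type <- ifelse(a$type == "", a$element, a$type)
    paste0(base, sprintf("    %6.3f %-2s", a$charge, substr(type, 1L, 2L)))
  } else {
    paste0(base, sprintf("          %2s", substr(a$element, 1L, 2L)))
  }
}

#' Unique residues of a molecule
#'
#' Residue identity is (chain, residue number, insertion code); the display
#' name is the field-conventional `ResnameNumber` form (e.g. `Asp72`).
#'
#' @param mol a [plif_mol()].
#' @return data.frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `display`, one row per residue in file order.
#' @export
residue_table <- function(mol) {
  a <- mol$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  first <- !duplicated(key)
  res <- a[first, c("chain", "resno", "icode", "resname")]
  res$display <- residue_display(res$resname, res$resno, res$icode)
  rownames(res) <- NULL
  res
}

residue_display <- function(resname, resno, icode = "") {
  nm <- paste0(substr(toupper(resname), 1L, 1L),
               tolower(substr(resname, 2L, 3L)))
  paste0(nm, resno, ifelse(icode == "", "", icode))
}
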