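# Per-residue protein-ligand interaction fingerprints: 7 bits per binding-site
# residue over a fixed, ordered residue list. Bit numbering is 1-based so
# descriptor N of the aggregated table ("ensPLIF-N") is bit N here.

#' The seven interaction classes
#'
#' Fixed per-residue bit order: 1 apolar (hydrophobic), 2 aromatic
#' face-to-face, 3 aromatic edge-to-face, 4 H-bond with the residue as donor,
#' 5 H-bond with the residue as acceptor, 6 ionic with the residue as cation,
#' 7 ionic with the residue as anion. This order is load-bearing: descriptor
#' numbering of downstream tables depends on it.
#'
#' @return data.frame with columns `ordinal` and `label`.
#' @export
interaction_types <- function() {
  data.frame(
    ordinal = 1:7,
    label = c("apolar", "aromatic_face_to_face", "aromatic_edge_to_face",
              "hbond_protein_donor", "hbond_protein_acceptor",
              "ionic_protein_cation", "ionic_protein_anion"),
    stringsAsFactors = FALSE)
}

type_ordinal <- function(type) {
  tt <- interaction_types()
  if (is.numeric(type)) {
    ord <- as.integer(type)
  } else {
    ord <- tt$ordinal[match(type, tt$label)]
  }
  if (anyNA(ord) || any(ord < 1L) || any(ord > 7L))
    stop(sprintf("unknown interaction type: %s",
                 paste(type[is.na(ord) | ord < 1 | ord > 7], collapse = ", ")))
  ord
}

#' Geometry parameters for interaction detection
#'
#' Distance and angle thresholds of the seven detectors, all configurable.
#' Defaults follow the classical residue-based interaction-fingerprint
#' scheme: 4.5 A apolar contact, 4.0 A aromatic centroid distance with a
#' 30 degree face-to-face/edge-to-face plane-angle boundary, 3.5 A
#' donor-acceptor distance with a 135 degree D-H...A angle when the polar
#' hydrogen is present, 4.0 A ionic contact.
#'
#' @param apolar_cutoff,aromatic_centroid_cutoff,hbond_da_cutoff,ionic_cutoff
#'   distance thresholds in Angstrom.
#' @param f2f_max_plane_angle inter-plane angle (degrees) separating
#'   face-to-face from edge-to-face stacking; must be below 90.
#' @param hbond_min_dha_angle minimum donor-H-acceptor angle in degrees.
#' @return list of class `geometry_params`.
#' @export
geometry_params <- function(apolar_cutoff = 4.5,
                            aromatic_centroid_cutoff = 4.0,
                            f2f_max_plane_angle = 30,
                            hbond_da_cutoff = 3.5,
                            hbond_min_dha_angle = 135,
                            ionic_cutoff = 4.0) {
  p <- list(apolar_cutoff = apolar_cutoff,
            aromatic_centroid_cutoff = aromatic_centroid_cutoff,
            f2f_max_plane_angle = f2f_max_plane_angle,
            hbond_da_cutoff = hbond_da_cutoff,
            hbond_min_dha_angle = hbond_min_dha_angle,
            ionic_cutoff = ionic_cutoff)
  if (any(unlist(p) <= 0)) stop("all geometry parameters must be positive")
  if (p$f2f_max_plane_angle >= 90)
    stop("f2f_max_plane_angle must be below 90 degrees")
  structure(p, class = "geometry_params")
}

#' Bit index of a (residue position, interaction type) pair
#'
#' With 7 bits per residue block, the bit (and descriptor) index of residue
#' position `p` (1-based within the ordered residue list) and interaction
#' ordinal `o` is `(p - 1) * 7 + o`.
#'
#' @param residue_position 1-based position in the residue list.
#' @param type interaction type label or ordinal (see [interaction_types()]).
#' @param n_residues length of the residue list (for range checking;
#'   optional).
#' @return integer bit index (1-based).
#' @export
bit_index <- function(residue_position, type, n_residues = NULL) {
  residue_position <- as.integer(residue_position)
  if (any(residue_position < 1L))
    stop("residue_position must be >= 1")
  if (!is.null(n_residues) && any(residue_position > n_residues))
    stop(sprintf("residue_position out of range (list has %d residues)",
                 n_residues))
  (residue_position - 1L) * 7L + type_ordinal(type)
}

#' Describe a bit index as (residue, interaction type)
#'
#' Exact inverse of [bit_index()] over a given ordered residue list.
#'
#' @param index 1-based bit index.
#' @param residue_list character vector of residue display names in list
#'   order.
#' @return data.frame with columns `index`, `residue`, `type`.
#' @export
describe_bit <- function(index, residue_list) {
  index <- as.integer(index)
  n <- length(residue_list)
  if (any(index < 1L | index > 7L * n))
    stop(sprintf("bit index out of range 1..%d", 7L * n))
  pos <- (index - 1L) %/% 7L + 1L
  ord <- (index - 1L) %% 7L + 1L
  data.frame(index = index, residue = residue_list[pos],
             type = interaction_types()$label[ord],
             stringsAsFactors = FALSE)
}

resolve_residue_list <- function(residue_list) {
  if (is.data.frame(residue_list)) residue_list$display
  else as.character(residue_list)
}

angle_deg <- function(v1, v2) {
  c1 <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, c1))) * 180 / pi
}

plane_angle_deg <- function(n1, n2) {
  a <- angle_deg(n1, n2)
  if (a > 90) 180 - a else a
}

min_group_dist <- function(xyz1, xyz2) {
  d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") - 2 * xyz1 %*% t(xyz2)
  sqrt(max(0, min(d2)))
}

# D-H...A test for one donor (heavy atom index + H indices) against acceptor
# coordinates; when no polar H is recorded the angle test is skipped and the
# detection is distance-only.
hbond_hit <- function(d_xyz, h_xyz, a_xyz, params) {
  da <- sqrt(sum((d_xyz - a_xyz)^2))
  if (da > params$hbond_da_cutoff) return(FALSE)
  if (is.null(h_xyz) || nrow(h_xyz) == 0L) return(TRUE)
  for (k in seq_len(nrow(h_xyz))) {
    ang <- angle_deg(d_xyz - h_xyz[k, ], a_xyz - h_xyz[k, ])
    if (ang >= params$hbond_min_dha_angle) return(TRUE)
  }
  FALSE
}

#' Compute the interaction fingerprint of one receptor/pose pair
#'
#' Evaluates the seven geometric detectors for every residue of the ordered
#' binding-site list against a docked ligand pose and returns the
#' 7-bits-per-residue fingerprint. With `nobb = TRUE` ("no backbone") the
#' receptor atoms considered are restricted to side-chain atoms before any
#' perception or detection, so main-chain contacts never set a bit; a
#' glycine block can then only be all-zero.
#'
#' @param receptor receptor [plif_mol()] covering every residue in
#'   `residue_list`.
#' @param pose ligand pose [plif_mol()].
#' @param residue_list ordered residue list: character display names
#'   (`"Asp72"`) or a residue data.frame from [select_residues()] /
#'   [consensus_residues()].
#' @param nobb neglect backbone atoms (side-chain only detection).
#' @param params a [geometry_params()].
#' @return object of class `plif_bits`: list with `residues` (display
#'   names) and `bits` (logical, length `7 * length(residues)`, 1-based
#'   descriptor numbering).
#' @export
compute_plif <- function(receptor, pose, residue_list, nobb = FALSE,
                         params = geometry_params()) {
  rl <- resolve_residue_list(residue_list)
  rtab <- residue_table(receptor)
  at <- match(rl, rtab$display)
  if (anyNA(at))
    stop(sprintf("residue(s) absent from receptor: %s",
                 paste(rl[is.na(at)], collapse = ", ")))
  lig_feat <- perceive_ligand(pose)
  lig_xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])

  bits <- logical(7L * length(rl))
  ra <- receptor$atoms
  rkey <- paste(ra$chain, ra$resno, ra$icode, sep = "|")
  for (p in seq_along(rl)) {
    rrow <- rtab[at[p], ]
    sel <- rkey == paste(rrow$chain, rrow$resno, rrow$icode, sep = "|")
    res_atoms <- ra[sel, , drop = FALSE]
    if (nobb)
      res_atoms <- res_atoms[!res_atoms$is_backbone, , drop = FALSE]
    if (nrow(res_atoms) == 0L) next
    feat <- perceive_residue(res_atoms, include_backbone = !nobb)
    rxyz <- as.matrix(res_atoms[, c("x", "y", "z")])
    block <- detect_block(feat, rxyz, lig_feat, lig_xyz, params)
    bits[(p - 1L) * 7L + 1:7] <- block
  }
  structure(list(residues = rl, bits = bits), class = "plif_bits")
}

# seven detectors for one residue block; feat/rxyz are residue features and
# coordinates, lf/lxyz the ligand's
detect_block <- function(feat, rxyz, lf, lxyz, params) {
  block <- logical(7L)
  if (length(feat$apolar) > 0L && length(lf$apolar) > 0L)
    block[1L] <- min_group_dist(rxyz[feat$apolar, , drop = FALSE],
                                lxyz[lf$apolar, , drop = FALSE]) <=
      params$apolar_cutoff
  for (rr in feat$rings) for (lr in lf$rings) {
    if (sqrt(sum((rr$centroid - lr$centroid)^2)) >
          params$aromatic_centroid_cutoff) next
    if (plane_angle_deg(rr$normal, lr$normal) <= params$f2f_max_plane_angle)
      block[2L] <- TRUE
    else block[3L] <- TRUE
  }
  for (d in feat$donors) {
    if (block[4L]) break
    for (acc in lf$acceptors)
      if (hbond_hit(rxyz[d$heavy, ], rxyz[d$h, , drop = FALSE],
                    lxyz[acc, ], params)) {
        block[4L] <- TRUE
        break
      }
  }
  for (d in lf$donors) {
    if (block[5L]) break
    for (acc in feat$acceptors)
      if (hbond_hit(lxyz[d$heavy, ], lxyz[d$h, , drop = FALSE],
                    rxyz[acc, ], params)) {
        block[5L] <- TRUE
        break
      }
  }
  for (cg in feat$cations) for (ag in lf$anions) {
    if (min_group_dist(rxyz[cg, , drop = FALSE],
                       lxyz[ag, , drop = FALSE]) <= params$ionic_cutoff)
      block[6L] <- TRUE
  }
  for (ag in feat$anions) for (cg in lf$cations) {
    if (min_group_dist(rxyz[ag, , drop = FALSE],
                       lxyz[cg, , drop = FALSE]) <= params$ionic_cutoff)
      block[7L] <- TRUE
  }
  block
}

#' @export
print.plif_bits <- function(x, ...) {
  on <- which(x$bits)
  cat(sprintf("<plif_bits: %d residues, %d bits, %d set%s>\n",
              length(x$residues), length(x$bits), length(on),
              if (length(on) > 0L && length(on) <= 20L)
                paste0(" (", paste(on, collapse = ","), ")") else ""))
  invisible(x)
}

#' Export a fingerprint as a 0/1 string or index list
#' @param bits a `plif_bits`.
#' @return `as_bitstring`: single string of 0/1 characters;
#'   `set_bits`: integer vector of 1-based set-bit indices.
#' @export
as_bitstring <- function(bits) paste(as.integer(bits$bits), collapse = "")

#' @rdname as_bitstring
#' @export
set_bits <- function(bits) which(bits$bits)

#' Write / read a fingerprint configuration file
#'
#' Plain key-value text: the ordered residue display names, the `nobb` flag
#' and any geometry overrides. The residue list is written in the order the
#' fingerprint uses.
#'
#' @param path file path.
#' @param residues character vector of residue display names in order.
#' @param nobb logical.
#' @param params a [geometry_params()].
#' @return `write_plif_config`: `path` invisibly. `read_plif_config`: list
#'   with `residues`, `nobb`, `params`.
#' @export
write_plif_config <- function(path, residues, nobb = TRUE,
                              params = geometry_params()) {
  lines <- c(paste("residues", paste(residues, collapse = " ")),
             paste("nobb", if (nobb) "true" else "false"),
             vapply(names(params), function(k)
               sprintf("%s %.6g", k, params[[k]]), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_plif_config
#' @export
read_plif_config <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[trimws(lines) != "" & !grepl("^#", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  keys <- vapply(toks, `[`, "", 1L)
  get <- function(k) toks[[match(k, keys)]][-1L]
  if (!"residues" %in% keys) stop("config lacks a 'residues' line")
  prm <- geometry_params()
  for (k in names(prm))
    if (k %in% keys) prm[[k]] <- as.numeric(get(k)[1L])
  list(residues = get("residues"),
       nobb = isTRUE(tolower(get("nobb")[1L]) %in% c("true", "1", "yes")),
       params = do.call(geometry_params, unclass(prm)))
}
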