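# Binding-pocket residue selection around a reference ligand, consensus lists
# over a receptor ensemble, and docking-box geometry (the PLANTS "bind"
# equivalent for an AutoDock Vina configuration).

#' Binding-site residues of the AChE receptor ensemble
#'
#' The 57-residue consensus binding-pocket list for Torpedo californica
#' acetylcholinesterase used throughout the worked examples: the sorted union
#' of pocket residues selected at 5 Angstrom around the AEYTR reference
#' ligand over the two receptor-ensemble clusters. With 7 interaction bits
#' per residue it implies a 399-bit fingerprint.
#'
#' @return character vector of 57 residue display names (`Gln69` ... `Glu445`).
#' @export
ache_consensus_residues <- function() {
  c("Gln69", "Tyr70", "Val71", "Asp72", "Gln74", "Phe75", "Phe78", "Ser79",
    "Gly80", "Ser81", "Glu82", "Met83", "Trp84", "Asn85", "Pro86", "Trp114",
    "Tyr116", "Gly117", "Gly118", "Gly119", "Phe120", "Tyr121", "Ser122",
    "Gly123", "Ser124", "Leu127", "Val129", "Tyr130", "Glu199", "Ser200",
    "Ala201", "Gly202", "Ser226", "Trp233", "Trp279", "Phe288", "Phe290",
    "Asn324", "Asp326", "Glu327", "Gly328", "Ser329", "Phe330", "Phe331",
    "Leu332", "Leu333", "Tyr334", "Val400", "Trp432", "Met436", "Ile439",
    "His440", "Gly441", "Tyr442", "Glu443", "Ile444", "Glu445")
}

#' Select binding-pocket residues around a reference ligand
#'
#' A residue is selected when any of its heavy atoms lies within `cutoff` of
#' any heavy atom of the reference ligand (heavy-atom/heavy-atom distance; no
#' surface computation). Selection is monotone in `cutoff`.
#'
#' @param receptor receptor [plif_mol()].
#' @param reference_ligand reference ligand [plif_mol()].
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @return data.frame of selected residues (columns as [residue_table()]),
#'   sorted by (chain, residue number, insertion code).
#' @export
select_residues <- function(receptor, reference_ligand, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  ra <- receptor$atoms[receptor$atoms$element != "H", , drop = FALSE]
  lxyz <- coords(reference_ligand, heavy = TRUE)
  if (nrow(ra) == 0L || nrow(lxyz) == 0L)
    stop("receptor and reference ligand must contain heavy atoms")
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  d2 <- outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") -
    2 * rxyz %*% t(lxyz)
  close_atom <- apply(d2, 1L, min) <= cutoff^2 + 1e-12
  key <- paste(ra$chain, ra$resno, ra$icode, sep = "|")
  hit <- unique(key[close_atom])
  if (length(hit) == 0L)
    stop(sprintf("no residue within %.2f Angstrom of the reference ligand",
                 cutoff))
  res <- residue_table(plif_mol(ra))
  res <- res[paste(res$chain, res$resno, res$icode, sep = "|") %in% hit, ,
             drop = FALSE]
  res <- res[order(res$chain, res$resno, res$icode), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge per-receptor residue selections into a consensus list
#'
#' Sorted union of the per-receptor binding-site selections; duplicates are
#' collapsed. The operation is order-insensitive in its inputs and
#' idempotent. Residues sharing a (chain, number, insertion code) key but
#' disagreeing on the residue name indicate inconsistent receptor numbering
#' and raise an error.
#'
#' @param per_receptor_lists list of residue data.frames from
#'   [select_residues()].
#' @return one residue data.frame, sorted by (chain, residue number,
#'   insertion code).
#' @export
consensus_residues <- function(per_receptor_lists) {
  stopifnot(length(per_receptor_lists) >= 1L)
  all_res <- do.call(rbind, per_receptor_lists)
  key <- paste(all_res$chain, all_res$resno, all_res$icode, sep = "|")
  nm_by_key <- tapply(toupper(all_res$resname), key,
                      function(v) length(unique(v)))
  if (any(nm_by_key > 1L)) {
    bad <- names(nm_by_key)[nm_by_key > 1L]
    stop(sprintf("conflicting residue names for position(s): %s",
                 paste(bad, collapse = ", ")))
  }
  res <- all_res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$chain, res$resno, res$icode), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compute the docking box for a binding site
#'
#' Box centre = heavy-atom centroid of the reference ligand; box size =
#' axis-aligned extent of the selected residues' heavy atoms, padded by
#' `2 * padding` per dimension and never smaller than the ligand extent.
#' The box only feeds external docking configuration; it never enters the
#' fingerprint math.
#'
#' @param reference_ligand reference ligand [plif_mol()].
#' @param receptor receptor [plif_mol()].
#' @param selected_residues residue data.frame from [select_residues()].
#' @param padding padding in Angstrom per side (default 5.0).
#' @return list with `residues`, `box_center`, `box_size` (class
#'   `binding_site_spec`).
#' @export
compute_box <- function(reference_ligand, receptor, selected_residues,
                        padding = 5.0) {
  stopifnot(padding >= 0)
  if (is.null(selected_residues) || nrow(selected_residues) == 0L)
    stop("empty residue list")
  lig <- coords(reference_ligand, heavy = TRUE)
  ra <- receptor$atoms[receptor$atoms$element != "H", , drop = FALSE]
  key <- paste(ra$chain, ra$resno, ra$icode, sep = "|")
  sel_key <- paste(selected_residues$chain, selected_residues$resno,
                   selected_residues$icode, sep = "|")
  rxyz <- as.matrix(ra[key %in% sel_key, c("x", "y", "z")])
  if (nrow(rxyz) == 0L) stop("selected residues absent from receptor")
  center <- colMeans(lig)
  ext_res <- apply(rxyz, 2L, max) - apply(rxyz, 2L, min) + 2 * padding
  ext_lig <- apply(lig, 2L, max) - apply(lig, 2L, min)
  size <- pmax(ext_res, ext_lig)
  if (any(size <= 0)) size <- pmax(size, 1e-3)
  structure(list(residues = selected_residues,
                 box_center = unname(center), box_size = unname(size)),
            class = "binding_site_spec")
}

#' @export
print.binding_site_spec <- function(x, ...) {
  cat(sprintf("<binding_site_spec: %d residues; center (%.2f, %.2f, %.2f); size (%.2f, %.2f, %.2f) A>\n",
              nrow(x$residues), x$box_center[1L], x$box_center[2L],
              x$box_center[3L], x$box_size[1L], x$box_size[2L],
              x$box_size[3L]))
  invisible(x)
}

#' Render a binding-site spec as AutoDock Vina config text
#' @param spec a `binding_site_spec`.
#' @return character vector of config lines
#'   (`center_x/center_y/center_z`, `size_x/size_y/size_z`).
#' @export
vina_config <- function(spec) {
  c(sprintf("center_x = %.3f", spec$box_center[1L]),
    sprintf("center_y = %.3f", spec$box_center[2L]),
    sprintf("center_z = %.3f", spec$box_center[3L]),
    sprintf("size_x = %.3f", spec$box_size[1L]),
    sprintf("size_y = %.3f", spec$box_size[2L]),
    sprintf("size_z = %.3f", spec$box_size[3L]))
}
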