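# Aggregation of per-pose fingerprints across the receptor ensemble
# (receptors x replicates x binding modes) into ensPLIF fraction descriptors,
# and the analysis table built from them.

#' Bundle the docking runs of one compound
#'
#' One screened compound owns `n_receptors * n_replicates` independent
#' docking runs (the reference protocol uses 2 receptor clusters x 3
#' replicates = 6 runs of 5 binding modes each, i.e. 30 poses). A deviating
#' run count is accepted but reported via a message.
#'
#' @param name compound name.
#' @param runs list of runs, each a list with `receptor_id`, `replicate`,
#'   and `poses` (a [pose_set()]).
#' @param label optional 0/1 activity label.
#' @param expected_runs expected run count (default 6); deviations are
#'   messaged, not errors.
#' @return object of class `compound_docking_result`.
#' @export
compound_docking_result <- function(name, runs, label = NA_integer_,
                                    expected_runs = 6L) {
  stopifnot(is.list(runs))
  if (length(runs) != expected_runs)
    message(sprintf("compound '%s': %d runs (expected %d)", name,
                    length(runs), expected_runs))
  structure(list(name = name, runs = runs, label = label),
            class = "compound_docking_result")
}

#' Aggregate per-pose fingerprints into ensPLIF fractions
#'
#' For each bit, the fraction of aggregated poses in which the bit is set:
#' `V[i] = k_i / m` with `k_i` the number of poses showing bit `i` and `m`
#' the number of poses. Permutation-invariant; merging two pose sets merges
#' the fractions by pose-count weighting.
#'
#' @param bitstrings list of `plif_bits` over the same residue list.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
aggregate_plif <- function(bitstrings) {
  if (length(bitstrings) == 0L) stop("no bitstrings to aggregate")
  lens <- vapply(bitstrings, function(b) length(b$bits), 0L)
  if (length(unique(lens)) != 1L)
    stop("bitstrings have mixed lengths; cannot aggregate")
  res0 <- bitstrings[[1L]]$residues
  for (b in bitstrings)
    if (!identical(b$residues, res0))
      stop("bitstrings cover different residue lists")
  counts <- Reduce(`+`, lapply(bitstrings, function(b) as.integer(b$bits)))
  counts / length(bitstrings)
}

#' Average docking score of a compound
#'
#' The `dg` column of the analysis table: the mean over runs of each run's
#' best (lowest, kcal/mol) score. Invariant to mode order within a run.
#'
#' @param result a [compound_docking_result()].
#' @return numeric scalar, kcal/mol.
#' @export
compound_dg <- function(result) {
  best <- vapply(result$runs, function(r) {
    if (length(r$poses$scores) == 0L)
      stop(sprintf("compound '%s': run without poses", result$name))
    min(r$poses$scores)
  }, 0)
  mean(best)
}

#' Filter docked poses by score cutoff
#'
#' Retains poses with score at or below `cutoff` (kcal/mol; lower is
#' better). A compound may be left with zero poses; downstream its
#' descriptor row becomes all-zero and is flagged.
#'
#' @param result a [compound_docking_result()].
#' @param cutoff maximum (i.e. least negative) score to retain.
#' @return a new `compound_docking_result` with filtered pose sets.
#' @export
filter_poses_by_score <- function(result, cutoff) {
  runs <- lapply(result$runs, function(r) {
    keep <- r$poses$scores <= cutoff
    r$poses <- pose_set(r$poses$poses[keep], r$poses$scores[keep],
                        r$poses$source_tag)
    r
  })
  out <- result
  out$runs <- runs
  out
}

#' Build the ensPLIF analysis table
#'
#' One row per compound in input order: `y` (1 active / 0 decoy), `name`,
#' `dg` (average docking score, kcal/mol), then `V1..Vn` fraction
#' descriptors (`n = 7 * length(residue_list)`). When `score_cutoff` is
#' given, poses are filtered first and the fraction denominator is the
#' number of retained poses; compounds retaining zero poses get an all-zero
#' descriptor row with `dg` equal to their best pre-filter score, and are
#' listed in the `zero_pose_compounds` attribute.
#'
#' @param results list of [compound_docking_result()]; every element needs a
#'   0/1 `label`.
#' @param receptors named list of receptor [plif_mol()], keyed by the
#'   `receptor_id` used in the runs.
#' @param residue_list ordered residue list (display names or data.frame).
#' @param nobb side-chain-only detection flag, passed to [compute_plif()].
#' @param params a [geometry_params()].
#' @param score_cutoff optional kcal/mol pose filter.
#' @return data.frame with columns `y`, `name`, `dg`, `V1..Vn`.
#' @export
build_ensplif_table <- function(results, receptors, residue_list,
                                nobb = TRUE, params = geometry_params(),
                                score_cutoff = NULL) {
  rl <- resolve_residue_list(residue_list)
  nv <- 7L * length(rl)
  nms <- vapply(results, function(r) r$name, "")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0L)
    stop(sprintf("duplicate compound names: %s", paste(dup, collapse = ", ")))
  labels <- vapply(results, function(r) as.integer(r$label), 0L)
  if (anyNA(labels)) stop("every compound needs a 0/1 activity label")

  V <- matrix(0, nrow = length(results), ncol = nv)
  dg <- numeric(length(results))
  zero_pose <- character()
  for (k in seq_along(results)) {
    res <- results[[k]]
    dg[k] <- compound_dg(res)
    use <- if (is.null(score_cutoff)) res
           else filter_poses_by_score(res, score_cutoff)
    bs <- list()
    for (r in use$runs) {
      rec <- receptors[[r$receptor_id]]
      if (is.null(rec))
        stop(sprintf("unknown receptor id '%s'", r$receptor_id))
      for (pose in r$poses$poses)
        bs[[length(bs) + 1L]] <- compute_plif(rec, pose, rl, nobb = nobb,
                                              params = params)
    }
    if (length(bs) == 0L) {
      zero_pose <- c(zero_pose, res$name)      # all-zero row, flagged
    } else {
      V[k, ] <- aggregate_plif(bs)
    }
  }
  if (length(zero_pose) > 0L)
    message(sprintf("%d compound(s) retained zero poses after the cutoff: %s",
                    length(zero_pose), paste(zero_pose, collapse = ", ")))
  tab <- data.frame(y = labels, name = nms, dg = dg,
                    stringsAsFactors = FALSE)
  Vdf <- as.data.frame(V)
  names(Vdf) <- paste0("V", seq_len(nv))
  tab <- cbind(tab, Vdf)
  attr(tab, "zero_pose_compounds") <- zero_pose
  tab
}

#' Write / read an ensPLIF table as CSV
#'
#' Comma-separated with header exactly `y,name,dg,V1,...,Vn`; decimal
#' points, fractions at full precision.
#'
#' @param table ensPLIF data.frame.
#' @param path file path.
#' @return `write_ensplif`: `path` invisibly; `read_ensplif`: the
#'   data.frame.
#' @export
write_ensplif <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ensplif
#' @export
read_ensplif <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("y", "name", "dg")
  if (!all(need %in% names(tab)[1:3]))
    stop(sprintf("'%s' is not an ensPLIF table (header must start y,name,dg)",
                 path))
  tab
}

#' Descriptor (V) columns of an ensPLIF table
#' @param table ensPLIF data.frame.
#' @return character vector of `V*` column names in numeric order.
#' @export
v_columns <- function(table) {
  v <- grep("^V[0-9]+$", names(table), value = TRUE)
  v[order(as.integer(sub("^V", "", v)))]
}
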