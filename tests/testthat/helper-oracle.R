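# Independent oracles used to cross-check the package implementations.
# Deliberately written as plain scalar double loops applying the geometric
# definitions directly, sharing no detection code with the package.

o_dist <- function(p, q) sqrt(sum((p - q)^2))

o_angle_deg <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# brute-force fingerprint: double loop over every atom/feature pair
oracle_plif <- function(receptor, pose, residues, nobb = FALSE,
                        params = geometry_params()) {
  lf <- perceive_ligand(pose)
  lx <- as.matrix(pose$atoms[, c("x", "y", "z")])
  rtab <- residue_table(receptor)
  bits <- logical(7L * length(residues))
  for (p in seq_along(residues)) {
    row <- rtab[match(residues[p], rtab$display), ]
    sel <- receptor$atoms$chain == row$chain &
      receptor$atoms$resno == row$resno & receptor$atoms$icode == row$icode
    at <- receptor$atoms[sel, , drop = FALSE]
    if (nobb) at <- at[!at$is_backbone, , drop = FALSE]
    if (nrow(at) == 0L) next
    rf <- perceive_residue(at, include_backbone = !nobb)
    rx <- as.matrix(at[, c("x", "y", "z")])
    b <- logical(7L)
    for (i in rf$apolar) for (j in lf$apolar)
      if (o_dist(rx[i, ], lx[j, ]) <= params$apolar_cutoff) b[1L] <- TRUE
    for (rr in rf$rings) for (lr in lf$rings) {
      if (o_dist(rr$centroid, lr$centroid) <=
            params$aromatic_centroid_cutoff) {
        a <- o_angle_deg(rr$normal, lr$normal)
        if (a > 90) a <- 180 - a
        if (a <= params$f2f_max_plane_angle) b[2L] <- TRUE else b[3L] <- TRUE
      }
    }
    hb <- function(dpos, hpos_list, apos) {
      if (o_dist(dpos, apos) > params$hbond_da_cutoff) return(FALSE)
      if (length(hpos_list) == 0L) return(TRUE)
      for (h in hpos_list)
        if (o_angle_deg(dpos - h, apos - h) >= params$hbond_min_dha_angle)
          return(TRUE)
      FALSE
    }
    for (d in rf$donors) for (acc in lf$acceptors)
      if (hb(rx[d$heavy, ], lapply(d$h, function(i) rx[i, ]), lx[acc, ]))
        b[4L] <- TRUE
    for (d in lf$donors) for (acc in rf$acceptors)
      if (hb(lx[d$heavy, ], lapply(d$h, function(i) lx[i, ]), rx[acc, ]))
        b[5L] <- TRUE
    for (cg in rf$cations) for (ag in lf$anions)
      for (i in cg) for (j in ag)
        if (o_dist(rx[i, ], lx[j, ]) <= params$ionic_cutoff) b[6L] <- TRUE
    for (ag in rf$anions) for (cg in lf$cations)
      for (i in ag) for (j in cg)
        if (o_dist(rx[i, ], lx[j, ]) <= params$ionic_cutoff) b[7L] <- TRUE
    bits[(p - 1L) * 7L + 1:7] <- b
  }
  bits
}

# exhaustive best-split search with plain (frequency-weighted) Gini; used as
# the unweighted-CART oracle at frequency priors
oracle_best_split <- function(x, y, min_leaf = 1L) {
  n <- length(y)
  gini <- function(idx) {
    if (length(idx) == 0L) return(0)
    p1 <- mean(y[idx] == 1L)
    (length(idx) / n) * 2 * p1 * (1 - p1)
  }
  root <- gini(seq_len(n))
  best <- list(gain = 0, var = NA_integer_, threshold = NA_real_)
  for (v in seq_len(ncol(x))) {
    vals <- sort(unique(x[, v]))
    if (length(vals) < 2L) next
    for (k in seq_len(length(vals) - 1L)) {
      thr <- (vals[k] + vals[k + 1L]) / 2
      l <- which(x[, v] < thr)
      if (length(l) < min_leaf || n - length(l) < min_leaf) next
      gain <- root - gini(l) - gini(setdiff(seq_len(n), l))
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, var = v, threshold = thr)
      }
    }
  }
  best
}

# brute-force cutoff scan: max F1 over all distinct cutoffs
oracle_scan <- function(dg, labels) {
  best_f1 <- -1; best_cut <- NA_real_
  for (ct in sort(unique(dg))) {
    tp <- sum(labels == 1 & dg <= ct)
    fp <- sum(labels == 0 & dg <= ct)
    fn <- sum(labels == 1 & dg > ct)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best_f1 + 1e-12) {
      best_f1 <- f1; best_cut <- ct
    }
  }
  list(best_cutoff = best_cut, best_F1 = best_f1)
}

# Table 1 descriptor assignments: residue, interaction class, printed index
table1_descriptors <- function() {
  data.frame(
    residue = c("Asp72", "Asp72", "Asn85", "Pro86", "Ser122", "Trp279",
                "Trp279", "Phe330", "Tyr334", "His440", "Tyr442"),
    type = c("apolar", "ionic_protein_anion", "apolar", "apolar",
             "hbond_protein_donor", "apolar", "aromatic_face_to_face",
             "apolar", "aromatic_edge_to_face", "apolar",
             "aromatic_edge_to_face"),
    index = c(22L, 28L, 92L, 99L, 158L, 239L, 240L, 295L, 325L, 358L, 374L),
    stringsAsFactors = FALSE)
}
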