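# Retrospective-screening statistics: confusion matrices, enrichment factor,
# F1, balanced accuracy, docking-score cutoff scanning, and the
# replication-count selection rule.

#' Construct a confusion matrix
#' @param TP,FN,TN,FP non-negative integer counts; TP+FN is the number of
#'   actives and TN+FP the number of decoys.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FN, TN, FP) {
  v <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(v < 0) || any(v != round(v)))
    stop("confusion-matrix counts must be non-negative integers")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix TP=%d FN=%d TN=%d FP=%d>\n",
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Count a confusion matrix from labels and predictions
#'
#' Compounds that failed structure preparation (and so could never be
#' docked) are conventionally forced to a negative prediction: pass them via
#' `forced_negative` and they are routed to FN or TN by their label.
#'
#' @param labels 0/1 activity labels.
#' @param predictions 0/1 predictions, same length.
#' @param forced_negative optional logical vector; TRUE forces the
#'   prediction to 0.
#' @return a [confusion_matrix()].
#' @export
confusion <- function(labels, predictions, forced_negative = NULL) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1))
    stop("labels and predictions must be binary (0/1)")
  if (!is.null(forced_negative)) predictions[forced_negative] <- 0L
  confusion_matrix(TP = sum(labels == 1L & predictions == 1L),
                   FN = sum(labels == 1L & predictions == 0L),
                   TN = sum(labels == 0L & predictions == 0L),
                   FP = sum(labels == 0L & predictions == 1L))
}

#' Screening statistics from a confusion matrix
#'
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP); precision =
#' TP/(TP+FP) (0 when TP+FP = 0); F1 = 2TP/(2TP+FP+FN); BA =
#' (sensitivity+specificity)/2; EF = sensitivity / (FP/(FP+TN)), i.e. the
#' positive likelihood ratio (+Inf when FP = 0 with TP > 0; 0 when TP = 0).
#' This EF definition — not precision over prevalence — is the one
#' consistent with the protocol-comparison statistics this package mirrors.
#'
#' @param cm a [confusion_matrix()].
#' @return list of class `screen_metrics` with `sensitivity`,
#'   `specificity`, `precision`, `F1`, `BA`, `EF`.
#' @export
metrics <- function(cm) {
  P <- cm$TP + cm$FN
  N <- cm$TN + cm$FP
  if (P == 0L || N == 0L)
    stop("metrics need at least one active and one decoy")
  sens <- cm$TP / P
  spec <- cm$TN / N
  prec <- if (cm$TP + cm$FP == 0L) 0 else cm$TP / (cm$TP + cm$FP)
  f1 <- if (cm$TP == 0L) 0 else 2 * cm$TP / (2 * cm$TP + cm$FP + cm$FN)
  fpr <- cm$FP / N
  ef <- if (cm$TP == 0L) 0 else if (fpr == 0) Inf else sens / fpr
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 F1 = f1, BA = (sens + spec) / 2, EF = ef),
            class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat(sprintf(
    "<screen_metrics EF=%.3f F1=%.3f BA=%.3f sens=%.3f spec=%.3f prec=%.3f>\n",
    x$EF, x$F1, x$BA, x$sensitivity, x$specificity, x$precision))
  invisible(x)
}

#' Classify compounds by docking-score cutoff
#'
#' Predicted active iff `dg <= cutoff` (kcal/mol, lower is better; the
#' boundary itself counts as active).
#'
#' @param dg numeric docking scores.
#' @param cutoff kcal/mol cutoff.
#' @return integer 0/1 predictions.
#' @export
classify_by_score <- function(dg, cutoff) as.integer(dg <= cutoff)

#' Scan the docking-score cutoff for maximum F1
#'
#' Evaluates F1 with every distinct score as the cutoff and returns the
#' maximiser; ties break toward the more negative (stricter) cutoff.
#'
#' @param dg numeric docking scores (kcal/mol).
#' @param labels 0/1 activity labels.
#' @return list with `best_cutoff`, `best_F1`, and `curve` (data.frame of
#'   `cutoff`, `F1`, `BA`, `EF` over all distinct cutoffs, ascending).
#' @export
scan_cutoff <- function(dg, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("cutoff scan needs at least one active and one decoy")
  cuts <- sort(unique(dg))
  rows <- lapply(cuts, function(ct) {
    m <- metrics(confusion(labels, classify_by_score(dg, ct)))
    data.frame(cutoff = ct, F1 = m$F1, BA = m$BA, EF = m$EF)
  })
  curve <- do.call(rbind, rows)
  best <- which(curve$F1 == max(curve$F1))[1L]  # ascending order: first = strictest
  list(best_cutoff = curve$cutoff[best], best_F1 = curve$F1[best],
       curve = curve)
}

#' Select the docking replication count
#'
#' Given the F1 obtained with k = 1, 2, ... replicated docking runs, picks
#' the smallest k whose F1 is within `tolerance` of the maximum — the
#' cheapest protocol that is as good as the best.
#'
#' @param f1_by_k named numeric vector or list mapping the replicate count
#'   k to its F1.
#' @param tolerance non-negative slack from the maximum (default 0).
#' @return integer k.
#' @export
select_replication <- function(f1_by_k, tolerance = 0) {
  stopifnot(length(f1_by_k) >= 1L, tolerance >= 0)
  f1 <- unlist(f1_by_k)
  k <- as.integer(names(f1))
  if (anyNA(k)) stop("f1_by_k must be named by replicate count")
  ord <- order(k)
  k <- k[ord]; f1 <- f1[ord]
  k[which(f1 >= max(f1) - tolerance)[1L]]
}

#' Write a metrics report
#'
#' Human-readable text report of a confusion matrix, its statistics and
#' (optionally) a full cutoff-scan curve; the curve also goes to a CSV
#' alongside when `path` is given.
#'
#' @param cm a [confusion_matrix()].
#' @param path optional output path for the text report (`<path>.curve.csv`
#'   is written next to it when `scan` is supplied).
#' @param scan optional result of [scan_cutoff()].
#' @return the report lines, invisibly.
#' @export
metrics_report <- function(cm, path = NULL, scan = NULL) {
  m <- metrics(cm)
  lines <- c("screening metrics report",
             sprintf("confusion: TP=%d FN=%d TN=%d FP=%d",
                     cm$TP, cm$FN, cm$TN, cm$FP),
             sprintf("sensitivity  %.4f", m$sensitivity),
             sprintf("specificity  %.4f", m$specificity),
             sprintf("precision    %.4f", m$precision),
             sprintf("F1           %.4f", m$F1),
             sprintf("BA           %.4f", m$BA),
             sprintf("EF           %.4f", m$EF))
  if (!is.null(scan))
    lines <- c(lines, sprintf("best cutoff  %.3f kcal/mol (F1 %.4f)",
                              scan$best_cutoff, scan$best_F1))
  if (!is.null(path)) {
    writeLines(lines, path)
    if (!is.null(scan))
      utils::write.csv(scan$curve, paste0(path, ".curve.csv"),
                       row.names = FALSE)
  }
  invisible(lines)
}
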