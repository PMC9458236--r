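# Prior-weighted binary CART for ensPLIF tables.
#
# Greedy recursive partitioning with Gini impurity computed on prior-adjusted
# class proportions
#     p(j|t) = pi_j * n_j(t)/N_j / sum_k pi_k * n_k(t)/N_k ,
# node class = argmax_j pi_j * n_j(t)/N_j, followed by weakest-link
# cost-complexity pruning with alpha = cp * R(root). Altered class priors are
# how a rare-active screening table (prevalence ~1.7%) is kept from collapsing
# into an all-inactive tree. No surrogate splits and no missing-value
# handling: descriptor tables are complete by construction.

#' Configuration for fitting the decision tree
#'
#' @param priors length-2 prior probabilities `(inactive, active)`, summing
#'   to 1, or `NULL` (default) for the empirical class frequencies — the
#'   classical CART default, under which the fit reduces to plain
#'   frequency-weighted Gini partitioning. The convention follows the R
#'   tradition of listing the classes in sorted label order (0 then 1), so
#'   `c(0.9, 0.1)` puts prior mass 0.1 on the active class — which still
#'   up-weights actives about six-fold relative to a 1.7% prevalence.
#' @param min_split minimum node size to attempt a split.
#' @param min_leaf minimum child size.
#' @param cp complexity parameter; a subtree survives pruning only while its
#'   per-split risk reduction exceeds `cp * R(root)`.
#' @param max_depth maximum tree depth (root = 0).
#' @param seed seed for any tie randomisation; the fit itself is
#'   deterministic (ties break toward the lowest column index, then the
#'   lowest threshold), the seed is recorded for provenance.
#' @return list of class `tree_config`.
#' @export
tree_config <- function(priors = NULL, min_split = 20L,
                        min_leaf = 7L, cp = 0.01, max_depth = 30L,
                        seed = 1L) {
  if (!is.null(priors)) {
    priors <- as.numeric(priors)
    if (length(priors) != 2L || any(priors <= 0))
      stop("priors must be two positive numbers (inactive, active)")
    priors <- priors / sum(priors)
  }
  structure(list(priors = priors, min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf), cp = cp,
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "tree_config")
}

table_xy <- function(table) {
  vc <- v_columns(table)
  if (length(vc) == 0L) stop("table has no V descriptor columns")
  list(x = as.matrix(table[, vc, drop = FALSE]), y = as.integer(table$y),
       vars = vc)
}

#' Fit the prior-weighted decision tree
#'
#' @param table ensPLIF data.frame (`y`, `name`, `dg`, `V1..Vn`); both
#'   classes must be present.
#' @param config a [tree_config()].
#' @return object of class `plif_tree`: recursive node list plus the fit
#'   configuration and descriptor names.
#' @export
fit_plif_tree <- function(table, config = tree_config()) {
  d <- table_xy(table)
  y <- d$y
  if (length(unique(y)) < 2L)
    stop("cannot fit a tree on a single-class table")
  N <- c(sum(y == 0L), sum(y == 1L))
  pri <- config$priors %||% (N / sum(N))   # empirical frequencies by default
  w <- ifelse(y == 1L, pri[2L] / N[2L], pri[1L] / N[1L])  # case weights

  gini_risk <- function(idx) {
    # returns c(p(t), impurity contribution p(t)*i(t), risk R(t), class, p0, p1)
    p0 <- sum(w[idx][y[idx] == 0L]); p1 <- sum(w[idx][y[idx] == 1L])
    pt <- p0 + p1
    cls <- if (p1 > p0) 1L else 0L
    list(pt = pt, gini = if (pt > 0) pt * (1 - (p0 / pt)^2 - (p1 / pt)^2)
                         else 0,
         risk = min(p0, p1), class = cls,
         prob = if (pt > 0) c(p0, p1) / pt else c(0.5, 0.5))
  }

  best_split <- function(idx) {
    x <- d$x[idx, , drop = FALSE]
    yy <- y[idx]; ww <- w[idx]
    node <- gini_risk(idx)
    best <- NULL
    for (v in seq_len(ncol(x))) {
      ord <- order(x[, v])
      xv <- x[ord, v]; yv <- yy[ord]; wv <- ww[ord]
      cw1 <- cumsum(wv * (yv == 1L)); cw0 <- cumsum(wv * (yv == 0L))
      n <- length(xv)
      # candidate cuts between consecutive distinct values
      cut_at <- which(diff(xv) > 0)
      if (length(cut_at) == 0L) next
      keep <- cut_at >= config$min_leaf & (n - cut_at) >= config$min_leaf
      cut_at <- cut_at[keep]
      if (length(cut_at) == 0L) next
      p0L <- cw0[cut_at]; p1L <- cw1[cut_at]
      p0R <- cw0[n] - p0L; p1R <- cw1[n] - p1L
      ptL <- p0L + p1L; ptR <- p0R + p1R
      gL <- ifelse(ptL > 0, ptL * (1 - (p0L / ptL)^2 - (p1L / ptL)^2), 0)
      gR <- ifelse(ptR > 0, ptR * (1 - (p0R / ptR)^2 - (p1R / ptR)^2), 0)
      gain <- node$gini - gL - gR
      b <- which.max(gain)
      if (gain[b] > 1e-12 &&
          (is.null(best) || gain[b] > best$gain + 1e-12)) {
        best <- list(var = v, gain = gain[b],
                     threshold = (xv[cut_at[b]] + xv[cut_at[b] + 1L]) / 2)
      }
    }
    best
  }

  grow <- function(idx, depth) {
    info <- gini_risk(idx)
    node <- list(n = length(idx), n_by_class = c(sum(y[idx] == 0L),
                                                 sum(y[idx] == 1L)),
                 prob = info$prob, class = info$class, risk = info$risk,
                 leaf = TRUE)
    if (length(idx) < config$min_split || depth >= config$max_depth ||
        info$risk <= 0)
      return(node)
    sp <- best_split(idx)
    if (is.null(sp)) return(node)
    go_left <- d$x[idx, sp$var] < sp$threshold
    node$leaf <- FALSE
    node$var <- d$vars[sp$var]
    node$var_idx <- sp$var
    node$threshold <- sp$threshold
    node$left <- grow(idx[go_left], depth + 1L)    # condition TRUE -> left
    node$right <- grow(idx[!go_left], depth + 1L)
    node
  }

  root <- grow(seq_along(y), 0L)
  root <- prune_tree(root, alpha = config$cp * root$risk)
  structure(list(root = root, config = config, vars = d$vars,
                 n = length(y), class_counts = N),
            class = "plif_tree")
}

subtree_stats <- function(node) {
  if (node$leaf) return(c(risk = node$risk, leaves = 1))
  l <- subtree_stats(node$left); r <- subtree_stats(node$right)
  c(risk = unname(l["risk"] + r["risk"]),
    leaves = unname(l["leaves"] + r["leaves"]))
}

# weakest-link cost-complexity pruning at fixed alpha
prune_tree <- function(root, alpha) {
  repeat {
    weakest <- function(node) {
      if (node$leaf) return(NULL)
      st <- subtree_stats(node)
      g <- (node$risk - st["risk"]) / (st["leaves"] - 1)
      cand <- list(g = unname(g), node = node)
      for (child in list(node$left, node$right)) {
        c2 <- weakest(child)
        if (!is.null(c2) && c2$g < cand$g) cand <- c2
      }
      cand
    }
    wk <- weakest(root)
    if (is.null(wk) || wk$g > alpha + 1e-15) break
    root <- collapse_at(root, wk$node)
  }
  root
}

collapse_at <- function(node, target) {
  if (node$leaf) return(node)
  if (identical(node, target)) {
    node$leaf <- TRUE
    node[c("var", "var_idx", "threshold", "left", "right")] <- NULL
    return(node)
  }
  node$left <- collapse_at(node$left, target)
  node$right <- collapse_at(node$right, target)
  node
}

#' Predict activity with a fitted tree
#'
#' Deterministic root-to-leaf descent; at each split the left branch is
#' taken when the condition `V < threshold` is true. A missing split
#' variable is an error (no surrogate splits).
#'
#' @param object a `plif_tree`.
#' @param newdata ensPLIF data.frame or a matrix/data.frame containing the
#'   split variables as columns.
#' @param ... unused.
#' @return integer 0/1 predictions, one per row.
#' @export
predict.plif_tree <- function(object, newdata, ...) {
  used <- tree_variables(object)
  miss <- setdiff(used, colnames(newdata))
  if (length(miss) > 0L)
    stop(sprintf("newdata lacks split variable(s): %s",
                 paste(miss, collapse = ", ")))
  x <- as.matrix(as.data.frame(newdata)[, used, drop = FALSE])
  vapply(seq_len(nrow(x)), function(i) {
    node <- object$root
    while (!node$leaf)
      node <- if (x[i, node$var] < node$threshold) node$left else node$right
    node$class
  }, 0L)
}

#' Split variables used by a tree
#' @param tree a `plif_tree`.
#' @return character vector of V-column names, in first-use (pre-order)
#'   order.
#' @export
tree_variables <- function(tree) {
  walk <- function(node) {
    if (node$leaf) return(character())
    c(node$var, walk(node$left), walk(node$right))
  }
  unique(walk(tree$root))
}

#' @export
print.plif_tree <- function(x, ...) {
  pri <- x$config$priors %||% (x$class_counts / sum(x$class_counts))
  cat(sprintf("<plif_tree: n=%d, priors (%.2f, %.2f), %d split variable(s)>\n",
              x$n, pri[1L], pri[2L], length(tree_variables(x))))
  lines <- character()
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      lines <<- c(lines, sprintf("%sleaf: class %d (n=%d, p=%.3f/%.3f)",
                                 pad, node$class, node$n, node$prob[1L],
                                 node$prob[2L]))
    } else {
      lines <<- c(lines, sprintf("%s%s < %.4g ?", pad, node$var,
                                 node$threshold))
      walk(node$left, indent + 1L)
      walk(node$right, indent + 1L)
    }
  }
  walk(x$root, 0L)
  cat(lines, sep = "\n")
  cat("\n")
  invisible(x)
}

#' Active-class decision rules ("keys") of a tree
#'
#' Enumerates every root-to-leaf path ending in an active leaf as a
#' conjunction of split conditions — the "keys that open the lock".
#'
#' @param tree a `plif_tree`.
#' @return character vector, one rule per active leaf.
#' @export
tree_rules <- function(tree) {
  rules <- character()
  walk <- function(node, conds) {
    if (node$leaf) {
      if (node$class == 1L)
        rules <<- c(rules, sprintf("Key #%d: %s", length(rules) + 1L,
                                   paste(conds, collapse = " & ")))
      return(invisible())
    }
    walk(node$left, c(conds, sprintf("%s < %.4g", node$var, node$threshold)))
    walk(node$right, c(conds, sprintf("%s >= %.4g", node$var,
                                      node$threshold)))
  }
  walk(tree$root, character())
  rules
}

#' Serialise a tree as nested JSON-like text
#' @param tree a `plif_tree`.
#' @param path optional output path.
#' @return character scalar of the serialised tree.
#' @export
tree_text <- function(tree, path = NULL) {
  walk <- function(node, ind) {
    pad <- strrep(" ", ind)
    if (node$leaf)
      return(sprintf('%s{"leaf": true, "class": %d, "n": %d, "p_active": %.6f}',
                     pad, node$class, node$n, node$prob[2L]))
    sprintf('%s{"var": "%s", "threshold": %.6f,\n%s "left":\n%s,\n%s "right":\n%s\n%s}',
            pad, node$var, node$threshold, pad,
            walk(node$left, ind + 2L), pad, walk(node$right, ind + 2L), pad)
  }
  txt <- walk(tree$root, 0L)
  if (!is.null(path)) writeLines(txt, path)
  txt
}

train_metrics <- function(tree, table) {
  metrics(confusion(table$y, predict(tree, table)))
}

#' Grid search over class priors
#'
#' Fits one tree per prior setting and selects the one with the highest
#' training balanced accuracy among those whose training F1 exceeds
#' `f1_floor`. Ties break toward the less extreme prior (active prior
#' closest to 0.5). The full grid trace is returned either way; when no
#' setting clears the floor, the error carries the trace in its
#' `trace` attribute.
#'
#' @param table ensPLIF data.frame.
#' @param prior_grid numeric vector of active-class priors in (0, 1).
#' @param f1_floor minimum training F1 (strict inequality).
#' @param config base [tree_config()]; its priors are overridden by the
#'   grid.
#' @return list with `priors` (length-2, inactive first), `tree`,
#'   `metrics`, `trace` (data.frame over the grid).
#' @export
grid_search_priors <- function(table, prior_grid = seq(0.05, 0.95, by = 0.05),
                               f1_floor = 0, config = tree_config()) {
  stopifnot(length(prior_grid) >= 1L)
  rows <- list(); fits <- list()
  for (k in seq_along(prior_grid)) {
    pa <- prior_grid[k]
    cfg <- config
    cfg$priors <- c(1 - pa, pa)
    fit <- fit_plif_tree(table, cfg)
    m <- train_metrics(fit, table)
    fits[[k]] <- fit
    rows[[k]] <- data.frame(prior_active = pa, F1 = m$F1, BA = m$BA,
                            EF = m$EF, sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            n_vars = length(tree_variables(fit)))
  }
  trace <- do.call(rbind, rows)
  ok <- trace$F1 > f1_floor
  if (!any(ok)) {
    e <- simpleError(sprintf(
      "no prior setting reaches F1 > %.3f (best F1 %.3f)", f1_floor,
      max(trace$F1)))
    attr(e, "trace") <- trace
    stop(e)
  }
  cand <- which(ok)
  cand <- cand[trace$BA[cand] >= max(trace$BA[cand]) - 1e-12]
  best <- cand[order(abs(prior_grid[cand] - 0.5))][1L]
  list(priors = c(1 - prior_grid[best], prior_grid[best]),
       tree = fits[[best]], metrics = train_metrics(fits[[best]], table),
       trace = trace)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' y-scrambling (chance-correlation) check
#'
#' Permutes the activity labels, refits with the same configuration and
#' records the training balanced accuracy, `n_iterations` times. On a table
#' with real signal the unscrambled BA should sit far above this null
#' distribution; a mean scrambled BA near 0.5 indicates no chance
#' correlation. Reproducible given `seed`.
#'
#' @param table ensPLIF data.frame.
#' @param config a [tree_config()].
#' @param n_iterations number of label permutations.
#' @param seed RNG seed.
#' @return numeric vector of scrambled training BA values.
#' @export
y_scramble <- function(table, config = tree_config(), n_iterations = 20L,
                       seed = 1L) {
  stopifnot(n_iterations >= 1L)
  with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      tab <- table
      tab$y <- sample(tab$y)
      fit <- tryCatch(fit_plif_tree(tab, config), error = function(e) NULL)
      if (is.null(fit)) return(0.5)
      m <- train_metrics(fit, tab)
      m$BA
    }, 0)
  })
}

#' Cross-correlation between descriptors
#'
#' Pearson correlation matrix over the given descriptor columns; the
#' maximum absolute off-diagonal value is flagged when it exceeds
#' `threshold`. Zero-variance columns contribute correlation 0 with a
#' warning.
#'
#' @param table ensPLIF data.frame.
#' @param variables character vector of V-column names (>= 2), typically
#'   [tree_variables()].
#' @param threshold flag threshold on |r| (default 0.8).
#' @return list with `correlation` (matrix), `max_abs_r`, `flag`.
#' @export
descriptor_cross_correlation <- function(table, variables,
                                         threshold = 0.8) {
  stopifnot(length(variables) >= 2L)
  x <- as.matrix(table[, variables, drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    warning(sprintf("zero-variance descriptor(s): %s (correlation set to 0)",
                    paste(variables[sds == 0], collapse = ", ")))
  cc <- suppressWarnings(stats::cor(x))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  off <- abs(cc[upper.tri(cc)])
  list(correlation = cc, max_abs_r = max(off), flag = max(off) > threshold)
}

#' Overfitting check by stratified cross-validation
#'
#' Stratified k-fold cross-validation with pooled held-out predictions;
#' flags overfitting when training BA exceeds cross-validated BA by more
#' than `margin`.
#'
#' @param table ensPLIF data.frame.
#' @param config a [tree_config()].
#' @param k_folds number of folds (>= 2).
#' @param seed RNG seed for fold assignment.
#' @param margin flag margin on `train_BA - cv_BA` (default 0.1).
#' @return list with `train_BA`, `cv_BA`, `flag`.
#' @export
overfit_check <- function(table, config = tree_config(), k_folds = 5L,
                          seed = 1L, margin = 0.1) {
  stopifnot(k_folds >= 2L)
  y <- as.integer(table$y)
  if (min(sum(y == 1L), sum(y == 0L)) < k_folds)
    stop(sprintf("a class has fewer than %d members; use fewer folds",
                 k_folds))
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in 0:1) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  pred <- integer(length(y))
  for (f in seq_len(k_folds)) {
    fit <- fit_plif_tree(table[folds != f, , drop = FALSE], config)
    pred[folds == f] <- predict(fit, table[folds == f, , drop = FALSE])
  }
  cv_ba <- metrics(confusion(y, pred))$BA
  train_ba <- train_metrics(fit_plif_tree(table, config), table)$BA
  list(train_BA = train_ba, cv_BA = cv_ba,
       flag = (train_ba - cv_ba) > margin)
}

#' Full validity report for a fitted tree
#'
#' Bundles the three standard checks — overfitting (stratified CV),
#' descriptor cross-correlation among the tree's split variables, and
#' chance correlation (y-scrambling) — into one report.
#'
#' @param table ensPLIF data.frame.
#' @param config a [tree_config()].
#' @param k_folds folds for the overfitting check.
#' @param n_scramble y-scrambling iterations.
#' @param seed RNG seed (fold assignment and permutations).
#' @param cor_threshold cross-correlation flag threshold.
#' @param margin overfitting flag margin.
#' @return list of class `validation_report`.
#' @export
validate_tree <- function(table, config = tree_config(), k_folds = 5L,
                          n_scramble = 20L, seed = 1L, cor_threshold = 0.8,
                          margin = 0.1) {
  fit <- fit_plif_tree(table, config)
  ov <- overfit_check(table, config, k_folds, seed, margin)
  vars <- tree_variables(fit)
  cc <- if (length(vars) >= 2L)
    descriptor_cross_correlation(table, vars, cor_threshold)
  else list(correlation = NULL, max_abs_r = 0, flag = FALSE)
  sc <- y_scramble(table, config, n_scramble, seed + 1L)
  structure(list(tree = fit, train_BA = ov$train_BA, cv_BA = ov$cv_BA,
                 scrambled_BA = sc,
                 max_abs_descriptor_correlation = cc$max_abs_r,
                 flags = c(overfitting = ov$flag,
                           cross_correlation = cc$flag,
                           # chance correlation: the model is suspect when
                           # its training BA is not clearly above the
                           # label-permutation null
                           chance_correlation = unname(
                             ov$train_BA <= stats::quantile(sc, 0.95))),
                 seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<validation_report: train BA %.3f | CV BA %.3f | scrambled BA %.3f ",
    "(mean of %d) | max |r| %.3f>\n"),
    x$train_BA, x$cv_BA, mean(x$scrambled_BA), length(x$scrambled_BA),
    x$max_abs_descriptor_correlation))
  for (f in names(x$flags))
    cat(sprintf("  %-18s %s\n", f, if (x$flags[[f]]) "FLAGGED" else "ok"))
  invisible(x)
}
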