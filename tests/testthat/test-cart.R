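# Prior-weighted CART: fitting, prediction, prior search, validity checks.

planted_two_split <- function(n = 300L, seed = 9L) {
  # noise-free table generated by a planted depth-2 tree:
  # active iff V1 >= 0.5 & V3 < 0.3
  set.seed(seed)
  V1 <- sample(seq(0, 30) / 30, n, replace = TRUE)
  V3 <- sample(seq(0, 30) / 30, n, replace = TRUE)
  V2 <- runif(n)
  y <- as.integer(V1 >= 0.5 & V3 < 0.3)
  data.frame(y = y, name = sprintf("c%03d", seq_len(n)), dg = -8,
             V1 = V1, V2 = V2, V3 = V3)
}

test_that("a planted noise-free partition is recovered with training BA 1", {
  tab <- planted_two_split()
  fit <- fit_plif_tree(tab, tree_config(priors = c(0.5, 0.5),
                                        min_split = 4L, min_leaf = 2L,
                                        cp = 0.001))
  m <- metrics(confusion(tab$y, predict(fit, tab)))
  expect_equal(m$BA, 1)
  expect_setequal(tree_variables(fit), c("V1", "V3"))
})

test_that("at frequency priors the fit reduces to plain Gini CART", {
  tab <- make_table(n_active = 80L, n_decoy = 220L, n_vars = 6L,
                    rule = list(list(var = "V2", threshold = 0.4,
                                     dir = ">=")),
                    bit_noise = 0.1, seed = 31L)
  freq <- c(mean(tab$y == 0L), mean(tab$y == 1L))
  cfg <- tree_config(priors = freq, min_split = 20L, min_leaf = 7L,
                     cp = 0.01)
  fit <- fit_plif_tree(tab, cfg)

  # exhaustive-search oracle agrees on the root split
  d <- as.matrix(tab[, paste0("V", 1:6)])
  ob <- oracle_best_split(d, tab$y, min_leaf = 7L)
  expect_equal(fit$root$var, paste0("V", ob$var))
  expect_equal(fit$root$threshold, ob$threshold)

  # rpart (independent CART implementation) predicts identically
  rp <- rpart::rpart(y ~ ., data = tab[, c("y", paste0("V", 1:6))],
                     method = "class",
                     control = rpart::rpart.control(minsplit = 20L,
                                                    minbucket = 7L,
                                                    cp = 0.01,
                                                    maxsurrogate = 0,
                                                    xval = 0))
  rp_pred <- as.integer(as.character(predict(rp, tab, type = "class")))
  expect_equal(predict(fit, tab), rp_pred)
})

test_that("up-weighting the active class raises sensitivity on rare actives", {
  # overlapping classes at ~1.7% prevalence: under proportional priors no
  # leaf can reach an active majority, so the tree stays conservative
  set.seed(77)
  n_act <- 40L; n_dec <- 2310L
  tab <- data.frame(
    y = c(rep(1L, n_act), rep(0L, n_dec)),
    name = sprintf("c%04d", seq_len(n_act + n_dec)), dg = -8,
    V1 = c(rbinom(n_act, 30L, 0.55), rbinom(n_dec, 30L, 0.30)) / 30,
    V2 = runif(n_act + n_dec))
  m_prop <- metrics(confusion(tab$y, predict(
    fit_plif_tree(tab, tree_config(priors = NULL)), tab)))
  m_alt <- metrics(confusion(tab$y, predict(
    fit_plif_tree(tab, tree_config(priors = c(0.9, 0.1))), tab)))
  expect_gt(m_alt$sensitivity, m_prop$sensitivity)
})

test_that("prediction descends the tree deterministically", {
  leaf <- function(cls) list(leaf = TRUE, class = cls, n = 1L,
                             prob = c(1 - cls, cls), risk = 0,
                             n_by_class = c(1L, 1L))
  tree <- structure(list(
    root = list(leaf = FALSE, var = "V295", var_idx = 1L, threshold = 0.5,
                left = leaf(0L), right = leaf(1L), class = 0L,
                prob = c(0.5, 0.5), risk = 0.5, n = 2L,
                n_by_class = c(1L, 1L)),
    config = tree_config(), vars = "V295", n = 2L,
    class_counts = c(1L, 1L)), class = "plif_tree")
  expect_equal(predict(tree, data.frame(V295 = 0.933)), 1L)
  expect_equal(predict(tree, data.frame(V295 = 0.0)), 0L)
  expect_error(predict(tree, data.frame(V1 = 1)), "V295")

  # brute-force region enumeration on a fitted 2-variable tree
  tab <- planted_two_split(200L, seed = 12L)
  fit <- fit_plif_tree(tab, tree_config(min_split = 4L, min_leaf = 2L,
                                        cp = 0.001))
  grid <- expand.grid(V1 = seq(0, 1, 0.1), V2 = 0.5, V3 = seq(0, 1, 0.1))
  expect_equal(predict(fit, grid),
               as.integer(grid$V1 >= 0.5 & grid$V3 < 0.3))
})

test_that("prior grid search maximises BA above the F1 floor", {
  tab <- make_table(n_active = 50L, n_decoy = 700L, n_vars = 8L,
                    rule = list(list(var = "V4", threshold = 0.45,
                                     dir = ">=")),
                    bit_noise = 0.25, seed = 5L)
  gs <- grid_search_priors(tab, prior_grid = seq(0.05, 0.5, by = 0.05),
                           f1_floor = 0.2)
  # trace self-consistency
  ok <- gs$trace$F1 > 0.2
  expect_true(any(ok))
  expect_equal(gs$metrics$BA, max(gs$trace$BA[ok]))
  expect_true(gs$metrics$F1 > 0.2)

  one <- grid_search_priors(tab, prior_grid = 0.3)
  expect_equal(one$priors, c(0.7, 0.3))

  err <- tryCatch(grid_search_priors(tab, prior_grid = c(0.2, 0.4),
                                     f1_floor = 1.1),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_s3_class(attr(err, "trace"), "data.frame")
  expect_equal(nrow(attr(err, "trace")), 2L)
})

test_that("y-scrambling behaves as a null and is reproducible", {
  null_tab <- make_table(n_active = 40L, n_decoy = 160L, n_vars = 6L,
                         rule = list(), bit_noise = 0, seed = 19L)
  sc <- y_scramble(null_tab, tree_config(), n_iterations = 15L, seed = 4L)
  expect_length(sc, 15L)
  se <- sd(sc) / sqrt(length(sc))
  expect_lt(abs(mean(sc) - 0.5), 3 * max(se, 0.02))

  expect_equal(y_scramble(null_tab, n_iterations = 1L, seed = 8L),
               y_scramble(null_tab, n_iterations = 1L, seed = 8L))

  planted <- make_table(n_active = 40L, n_decoy = 160L, n_vars = 6L,
                        rule = list(list(var = "V1", threshold = 0.5,
                                         dir = ">=")),
                        bit_noise = 0.05, seed = 20L)
  cfg <- tree_config(min_split = 10L, min_leaf = 4L)
  real_ba <- metrics(confusion(planted$y, predict(
    fit_plif_tree(planted, cfg), planted)))$BA
  null_ba <- y_scramble(planted, cfg, n_iterations = 19L, seed = 6L)
  expect_gt(real_ba, quantile(null_ba, 0.95))
})

test_that("descriptor cross-correlation flags redundant variables", {
  set.seed(33)
  tab <- data.frame(y = rbinom(200, 1, 0.3), name = as.character(1:200),
                    dg = -8, V1 = runif(200))
  tab$V2 <- tab$V1                      # exact copy
  tab$V3 <- -tab$V1 + 1                 # anticorrelated
  tab$V4 <- runif(200)
  cc <- descriptor_cross_correlation(tab, c("V1", "V2"))
  expect_equal(cc$max_abs_r, 1)
  expect_true(cc$flag)
  cc2 <- descriptor_cross_correlation(tab, c("V1", "V3"))
  expect_true(cc2$flag)
  expect_equal(cc2$correlation[1L, 2L], -1)

  # independent columns stay uncorrelated
  set.seed(44)
  big <- as.data.frame(matrix(runif(1000 * 5), ncol = 5L))
  names(big) <- paste0("V", 1:5)
  big <- cbind(data.frame(y = 0L, name = as.character(1:1000), dg = -8), big)
  cc3 <- descriptor_cross_correlation(big, paste0("V", 1:5))
  expect_lt(cc3$max_abs_r, 0.15)
  expect_false(cc3$flag)

  tab$V5 <- 0.25
  expect_warning(descriptor_cross_correlation(tab, c("V1", "V5")),
                 "zero-variance")
})

test_that("the overfitting check flags noise-chasing deep trees only", {
  planted <- make_table(n_active = 80L, n_decoy = 400L, n_vars = 6L,
                        rule = list(list(var = "V2", threshold = 0.45,
                                         dir = ">=")),
                        bit_noise = 0.1, seed = 3L)
  ok <- overfit_check(planted, tree_config(), k_folds = 5L, seed = 2L)
  expect_false(ok$flag)

  noise <- make_table(n_active = 50L, n_decoy = 150L, n_vars = 25L,
                      rule = list(), seed = 13L)
  deep <- tree_config(min_split = 2L, min_leaf = 1L, cp = 0, max_depth = 30L)
  bad <- overfit_check(noise, deep, k_folds = 4L, seed = 2L)
  expect_equal(bad$train_BA, 1)
  expect_true(bad$flag)

  again <- overfit_check(noise, deep, k_folds = 4L, seed = 2L)
  expect_equal(bad$cv_BA, again$cv_BA)

  expect_error(overfit_check(planted, tree_config(), k_folds = 100L),
               "fewer folds")
})

test_that("validation reports bundle all three checks", {
  planted <- make_table(n_active = 60L, n_decoy = 300L, n_vars = 6L,
                        rule = list(list(var = "V1", threshold = 0.5,
                                         dir = ">=")),
                        bit_noise = 0.1, seed = 8L)
  rep <- validate_tree(planted, tree_config(), k_folds = 4L,
                       n_scramble = 8L, seed = 3L)
  expect_named(rep$flags, c("overfitting", "cross_correlation",
                            "chance_correlation"))
  expect_length(rep$scrambled_BA, 8L)
  expect_gt(rep$train_BA, 0.8)
  rules <- tree_rules(rep$tree)
  expect_true(length(rules) >= 1L)
  expect_match(rules[1L], "^Key #1: ")
  txt <- tree_text(rep$tree)
  expect_match(txt, "\"var\"")
})
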