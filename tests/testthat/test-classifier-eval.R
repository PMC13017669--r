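# The Monte-Carlo RF evaluation framework: splits, SMOTE, metrics, tuning,
# feature selection and group comparisons.

test_that("stratified splits hit per-class rounded counts", {
  y <- rep(c("a", "b"), each = 10)
  sp <- stratified_mc_split(y, 0.7, seed = 1)
  expect_identical(sum(y[sp$train] == "a"), 7L)
  expect_identical(sum(y[sp$train] == "b"), 7L)
  expect_identical(length(sp$test), 6L)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_identical(stratified_mc_split(y, 0.7, seed = 9),
                   stratified_mc_split(y, 0.7, seed = 9))
  # the clinical task sizes: 90 vs 41 -> train 63 + 29, test 27 + 12
  y2 <- c(rep("NT2", 90), rep("CC", 41))
  sp2 <- stratified_mc_split(y2, 0.7, seed = 2)
  expect_identical(sum(y2[sp2$train] == "NT2"), 63L)
  expect_identical(sum(y2[sp2$train] == "CC"), 29L)
  expect_identical(sum(y2[sp2$test] == "NT2"), 27L)
  expect_identical(sum(y2[sp2$test] == "CC"), 12L)
  expect_error(stratified_mc_split(c("a", rep("b", 10)), 0.7, seed = 1),
               "at least 4")
})

test_that("SMOTE interpolates along minority segments", {
  xm <- rbind(c(0, 0), c(1, 1))
  syn <- smote_oversample(xm, 50, k = 1, seed = 3)
  expect_identical(nrow(syn), 50L)
  expect_equal(syn[, 1], syn[, 2])
  expect_true(all(syn >= 0 & syn <= 1))
  # degenerate minority: synthetics coincide with it
  same <- matrix(2, 4, 3)
  expect_true(all(smote_oversample(same, 10, k = 2, seed = 4) == 2))
  # nothing requested: empty result
  expect_identical(nrow(smote_oversample(xm, 0, k = 1, seed = 5)), 0L)
  expect_error(smote_oversample(matrix(1, 1, 2), 3, k = 1, seed = 6),
               "at least 2")
  # balancing to equality, with synthetic rows flagged
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("maj", "min"), c(15, 5))
  bal <- somnphen:::smote_balance(x, y, k = 3, seed = 7)
  expect_identical(sum(bal$y == "min"), sum(bal$y == "maj"))
  expect_identical(bal$synthetic, c(rep(FALSE, 20), rep(TRUE, 10)))
})

test_that("roc_auc equals brute-force pair counting and pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(roc_auc(c(0.8, 0.4, 0.6, 0.3),
                       c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(8)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(sc, lab), auc_brute(sc, lab), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(9)
  lab <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  sc <- rnorm(40)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lab), ref, tolerance = 1e-12)
})

test_that("f1 follows the precision/recall harmonic mean", {
  expect_equal(f1_score(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(f1_score(c(0.1, 0.2, 0.3), c(TRUE, FALSE, TRUE)), 0)
  # TP = 2, FP = 1, FN = 1 -> 2*2/(2*2+1+1)
  sc <- c(0.9, 0.8, 0.7, 0.1)
  lab <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(f1_score(sc, lab), 2 / 3, tolerance = 1e-12)
})

test_that("tuning prefers deep trees on an interaction task", {
  set.seed(10)
  n <- 160
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(xor(x[, 1] > 0, x[, 2] > 0), "pos", "neg")
  cfg <- eval_config(runs = 1, cv_folds = 5, n_trees = 150, seed = 1,
                     grid = data.frame(max_depth = c(1L, 0L),
                                       mtry_frac = c(0.5, 0.5)))
  tuned <- tune_hyperparameters(x, y, cfg, seed = 2)
  expect_identical(tuned$best$max_depth, 0L)
  expect_gt(tuned$mean_auc[2], tuned$mean_auc[1])
  # a singleton grid is returned without search
  cfg1 <- eval_config(runs = 1, grid = data.frame(max_depth = 5L,
                                                  mtry_frac = NA_real_))
  t1 <- tune_hyperparameters(x, y, cfg1, seed = 3)
  expect_identical(t1$best$max_depth, 5L)
})

test_that("evaluation is perfect on a separable feature and never uses
           SMOTE in the final fit", {
  set.seed(11)
  n <- 40
  y <- rep(c("a", "b"), c(24, 16))
  x <- cbind(sep = ifelse(y == "b", 5, 0) + rnorm(n, sd = 0.1),
             noise = rnorm(n))
  cfg <- eval_config(runs = 5, n_trees = 100, seed = 2,
                     grid = data.frame(max_depth = 0L,
                                       mtry_frac = NA_real_))
  ev <- evaluate_task(x, y, config = cfg)
  expect_equal(ev$mean_auc, 1)
  expect_equal(ev$mean_f1, 1)
  expect_identical(ev$positive, "b")     # smaller class is positive
  # final fits train on the un-augmented training split only
  expect_true(all(ev$n_train_per_run ==
                    round(0.7 * 24) + round(0.7 * 16)))
  # determinism given the master seed
  ev2 <- evaluate_task(x, y, config = cfg)
  expect_identical(ev$auc, ev2$auc)
  expect_identical(ev$importance, ev2$importance)
  expect_error(evaluate_task(x, y, features = character(0), config = cfg),
               "empty feature subset")
})

test_that("a lone informative feature earns the best mean rank", {
  set.seed(12)
  n <- 60
  y <- rep(c("a", "b"), each = 30)
  x <- matrix(rnorm(n * 51), n, 51,
              dimnames = list(NULL, c("signal", paste0("noise", 1:50))))
  x[, "signal"] <- ifelse(y == "b", 1.5, 0) + rnorm(n, sd = 0.5)
  cfg <- eval_config(runs = 10, n_trees = 200, seed = 3,
                     grid = data.frame(max_depth = 0L,
                                       mtry_frac = NA_real_))
  ev <- evaluate_task(x, y, config = cfg)
  expect_identical(names(which.min(ev$mean_rank)), "signal")
})

test_that("top-feature selection and balanced exclusion yield fixed sizes", {
  rk <- fx_rankings()
  sel <- select_top_features(rk, k = 8)
  expect_identical(length(sel), 48L)
  expect_identical(length(unique(sel)), 48L)
  # per-set membership is 8 each
  cat_ <- feature_catalog()
  tab <- table(cat_$set[match(sel, cat_$name)])
  expect_true(all(tab == 8))
  sel1 <- select_top_features(rk, k = 1)
  expect_identical(length(sel1), 6L)
  expect_identical(select_top_features(rk, k = 8), sel)   # deterministic

  # exclusion variants keep the 48-feature budget
  expect_identical(balanced_exclusion_model(rk, character(0)), sel)
  ex_q <- balanced_exclusion_model(rk, "qeeg")
  expect_identical(length(ex_q), 48L)
  expect_false(any(ex_q %in% cat_$name[cat_$set == "qeeg"]))
  ex2 <- balanced_exclusion_model(rk, c("qeeg", "spindle"))
  expect_identical(length(ex2), 48L)
  tab2 <- table(cat_$set[match(ex2, cat_$name)])
  # even refill where possible: the 8-feature whole-night set is exhausted
  # and the remaining budget rotates over the other three retained sets
  expect_identical(tab2[["hypnogram"]], 8L)
  expect_identical(tab2[["quarter_hypnogram"]], 14L)
  expect_identical(tab2[["transition"]], 13L)
  expect_identical(tab2[["hypnodensity"]], 13L)
  expect_error(balanced_exclusion_model(rk, names(rk)), "retained")
})

test_that("group comparisons report percent differences with pooled BH", {
  set.seed(13)
  g1 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("u", "v", "w")))
  x <- rbind(g1, g1)      # identical groups
  groups <- rep(c("A", "B"), each = 20)
  cmp <- group_mean_comparison(x, groups, list(c("A", "B")))
  expect_true(all(cmp$p == 1))
  expect_true(all(abs(cmp$pct_diff) < 1e-9))

  x2 <- rbind(matrix(12 + rnorm(40, sd = 1e-9), 20, 2),
              matrix(10 + rnorm(40, sd = 1e-9), 20, 2))
  cmp2 <- group_mean_comparison(x2, groups, list(c("A", "B")))
  expect_equal(cmp2$pct_diff, rep(20, 2), tolerance = 1e-6)

  # BH agrees with the step-up oracle (worked example + random vectors)
  p <- c(0.005, 0.011, 0.02, 0.04)
  expect_equal(bh_adjust(p), c(0.02, 0.022, 0.02 * 4 / 3, 0.04),
               tolerance = 1e-12)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  set.seed(14)
  for (n in c(10, 100, 1000)) {
    pv <- runif(n)^2
    expect_equal(bh_adjust(pv), bh_oracle(pv), tolerance = 1e-12)
  }
})
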