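# Monte-Carlo random-forest evaluation framework: stratified 70/30 splits
# across R outer runs, 10-fold cross-validated hyperparameter tuning with
# SMOTE applied only inside training folds, a final un-balanced fit,
# AUC/F1 aggregation, impurity-importance ranking, per-set top-feature
# selection and balanced feature-exclusion variants.

#' Evaluation configuration
#'
#' @param runs Number of outer Monte-Carlo runs (the full protocol uses 200
#'   for single feature sets and 500 for combined-model experiments).
#' @param train_fraction Training fraction of each stratified split (0.7).
#' @param cv_folds Folds for hyperparameter tuning (10).
#' @param grid data.frame of hyperparameter candidates with columns
#'   \code{max_depth} (0 = unbounded) and \code{mtry_frac} (NA = sqrt(p)/p);
#'   default grid crosses depth {5, 10, unbounded} with feature fractions
#'   {sqrt(p)/p, 0.25, 0.5}.
#' @param n_trees Trees per forest (500).
#' @param smote_k SMOTE nearest-neighbour count (5).
#' @param seed Master seed; per-run seeds are derived as seed + run index.
#' @return List of class \code{"eval_config"}.
#' @export
eval_config <- function(runs = 200L, train_fraction = 0.7, cv_folds = 10L,
                        grid = default_rf_grid(), n_trees = 500L,
                        smote_k = 5L, seed = 1L) {
  stopifnot(runs >= 1L, train_fraction > 0, train_fraction < 1,
            nrow(grid) >= 1L)
  structure(list(runs = as.integer(runs), train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), grid = grid,
                 n_trees = as.integer(n_trees), smote_k = as.integer(smote_k),
                 seed = as.integer(seed)),
            class = "eval_config")
}

#' @rdname eval_config
#' @export
default_rf_grid <- function() {
  expand.grid(max_depth = c(5L, 10L, 0L),
              mtry_frac = c(NA_real_, 0.25, 0.5))
}

#' Stratified Monte-Carlo train/test split
#'
#' Draws round(train_fraction x n_class) members of each class into the
#' training set; the remainder form the test set.
#'
#' @param labels Vector of class labels (two or more classes).
#' @param train_fraction Training fraction (default 0.7).
#' @param seed Integer seed (NULL: use the current RNG stream).
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
stratified_mc_split <- function(labels, train_fraction = 0.7, seed = NULL) {
  tab <- table(labels)
  if (any(tab < 4L)) {
    stop("each class needs at least 4 members for a stratified split")
  }
  with_seed(seed, {
    train <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_tr <- round(train_fraction * length(idx))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' SMOTE synthetic oversampling
#'
#' Generates synthetic minority-class points by linear interpolation: each
#' synthetic point is \code{x + u (x_nn - x)} with \code{u ~ U[0,1]},
#' \code{x} a random minority point and \code{x_nn} one of its \code{k}
#' nearest minority neighbours under Euclidean distance.
#'
#' @param x Numeric matrix of minority-class points (rows).
#' @param n_synthetic Number of synthetic points to create.
#' @param k Nearest-neighbour count (default 5; capped at n-1).
#' @param seed Integer seed (NULL: current stream).
#' @return Matrix of \code{n_synthetic} synthetic rows.
#' @export
smote_oversample <- function(x, n_synthetic, k = 5L, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("SMOTE needs at least 2 minority points")
  if (n_synthetic == 0L) return(x[0, , drop = FALSE])
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1L, function(r) order(r)[seq_len(k)]),
               ncol = k, byrow = TRUE)
  with_seed(seed, {
    base <- sample.int(n, n_synthetic, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_synthetic, replace = TRUE))]
    u <- stats::runif(n_synthetic)
    x[base, , drop = FALSE] +
      u * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
  })
}

# balance a training set to class equality; synthetic rows are flagged
smote_balance <- function(x, y, k = 5L, seed = NULL) {
  tab <- table(y)
  if (length(tab) != 2L) stop("binary task required")
  minority <- names(tab)[which.min(tab)]
  n_syn <- max(tab) - min(tab)
  if (n_syn == 0L) {
    return(list(x = x, y = y, synthetic = rep(FALSE, length(y))))
  }
  xm <- x[y == minority, , drop = FALSE]
  syn <- smote_oversample(xm, n_syn, k, seed)
  list(x = rbind(x, syn),
       y = c(as.character(y), rep(minority, n_syn)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_syn)))
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability of the scores: the fraction of
#' (positive, negative) pairs where the positive scores higher, ties
#' counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical or two-level vector; TRUE / second level =
#'   positive.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  if (length(lv) != 2L) stop("binary labels required")
  labels == lv[2L]
}

#' F1 score at a probability threshold
#'
#' Harmonic mean of precision and recall for the positive class at the
#' given score threshold; 0 when nothing is predicted positive.
#'
#' @inheritParams roc_auc
#' @param threshold Score cut (default 0.5).
#' @return F1 in [0, 1].
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  pos <- as_positive(labels)
  pred <- scores >= threshold
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# ROC curve as step function evaluated on an FPR grid (vertical averaging)
roc_on_grid <- function(scores, labels, fpr_grid = seq(0, 1, length.out = 101)) {
  pos <- as_positive(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  tpr <- c(0, tp / sum(pos)); fpr <- c(0, fp / sum(!pos))
  vapply(fpr_grid, function(g) max(tpr[fpr <= g + 1e-12]), numeric(1))
}

# fit one random forest (ranger behind the module surface)
fit_rf <- function(x, y, max_depth, mtry_frac, n_trees, seed) {
  p <- ncol(x)
  mtry <- if (is.na(mtry_frac)) max(1L, floor(sqrt(p))) else
    max(1L, round(mtry_frac * p))
  df <- as.data.frame(x)
  df$.y <- factor(y)
  ranger::ranger(.y ~ ., data = df, num.trees = n_trees, mtry = mtry,
                 max.depth = if (max_depth == 0L) NULL else max_depth,
                 probability = TRUE, importance = "impurity",
                 seed = seed, num.threads = 1L)
}

# probability of the positive (second factor level) class
rf_scores <- function(fit, x, positive) {
  pr <- stats::predict(fit, data = as.data.frame(x),
                       num.threads = 1L)$predictions
  pr[, positive]
}

# stratified fold assignment; refolds (with sub-seeds) until every fold
# holds both classes
stratified_folds <- function(y, n_folds, seed) {
  for (attempt in 0:20) {
    f <- with_seed(seed + attempt, {
      fold <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      fold
    })
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(y[f == k])) == 2L && length(unique(y[f != k])) == 2L
    }, logical(1)))
    if (ok) {
      if (attempt > 0L) message("refolded CV partition (attempt ", attempt, ")")
      return(f)
    }
  }
  stop("could not build stratified folds with both classes per fold")
}

#' Cross-validated hyperparameter tuning with SMOTE inside folds
#'
#' Stratified k-fold partition of the training set; for every grid
#' candidate and fold, the k-1 training folds are SMOTE-balanced to class
#' equality, a forest is fitted on the balanced data and validated (AUC)
#' on the untouched fold. The candidate with the highest mean validation
#' AUC wins; ties go to the earliest grid row. Validation folds never
#' contain synthetic points.
#'
#' @param x Numeric feature matrix (training set, imputed).
#' @param y Two-level label vector.
#' @param config An \code{\link{eval_config}}.
#' @param seed Integer seed for folds and SMOTE.
#' @return List: \code{best} (row of the grid), \code{mean_auc} per
#'   candidate.
#' @export
tune_hyperparameters <- function(x, y, config, seed) {
  grid <- config$grid
  if (nrow(grid) == 1L) {
    return(list(best = grid[1L, , drop = FALSE], mean_auc = NA_real_))
  }
  y <- as.character(y)
  positive <- positive_class(y)
  folds <- stratified_folds(y, config$cv_folds, seed)
  aucs <- matrix(NA_real_, nrow(grid), config$cv_folds)
  for (k in seq_len(config$cv_folds)) {
    tr <- folds != k
    bal <- smote_balance(x[tr, , drop = FALSE], y[tr], config$smote_k,
                         seed = derive_seed(seed, k))
    for (g in seq_len(nrow(grid))) {
      fit <- fit_rf(bal$x, bal$y, grid$max_depth[g], grid$mtry_frac[g],
                    config$n_trees, seed = derive_seed(seed, g * 100L + k))
      sc <- rf_scores(fit, x[!tr, , drop = FALSE], positive)
      aucs[g, k] <- roc_auc(sc, y[!tr] == positive)
    }
  }
  mean_auc <- rowMeans(aucs)
  best <- which.max(mean_auc)   # ties: first in grid order
  list(best = grid[best, , drop = FALSE], mean_auc = mean_auc)
}

# positive class = smaller class (ties: second sorted level)
positive_class <- function(y) {
  tab <- sort(table(y))
  if (tab[1] < tab[2]) names(tab)[1] else sort(names(tab))[2]
}

#' Monte-Carlo evaluation of one binary classification task
#'
#' For each of \code{config$runs} outer runs: stratified 70/30 split;
#' missing cells imputed with the training-set feature mean; 10-fold
#' SMOTE-balanced tuning over the grid; a final forest trained on the full
#' training set \emph{without} SMOTE; AUC and F1 on the held-out test set;
#' impurity importances from the final fit. Metrics and importances are
#' averaged across runs, with the mean ROC obtained by vertical averaging
#' on a fixed 101-point false-positive-rate grid.
#'
#' @param x Numeric feature matrix (participants x features, NAs allowed).
#' @param y Two-level label vector.
#' @param features Character vector of column names to use (default: all).
#' @param config An \code{\link{eval_config}}.
#' @return Object of class \code{"rf_eval"}: list with \code{auc},
#'   \code{f1} (per-run vectors), \code{mean_auc}, \code{sd_auc},
#'   \code{mean_f1}, \code{sd_f1}, \code{importance} (per-feature mean
#'   impurity importance), \code{mean_rank} (per-feature mean importance
#'   rank, 1 = most important), \code{roc} (data.frame fpr/tpr),
#'   \code{positive}, \code{n_train_per_run}.
#' @export
evaluate_task <- function(x, y, features = colnames(x), config = eval_config()) {
  if (length(features) == 0L) stop("empty feature subset")
  x <- as.matrix(x[, features, drop = FALSE])
  y <- as.character(y)
  if (length(unique(y)) != 2L) stop("binary task required")
  positive <- positive_class(y)
  R <- config$runs
  auc <- f1 <- numeric(R)
  n_train <- integer(R)
  imp <- matrix(0, R, ncol(x), dimnames = list(NULL, colnames(x)))
  rnk <- matrix(0, R, ncol(x), dimnames = list(NULL, colnames(x)))
  fpr_grid <- seq(0, 1, length.out = 101)
  tpr_acc <- matrix(0, R, length(fpr_grid))
  for (r in seq_len(R)) {
    seed_r <- config$seed + r
    sp <- stratified_mc_split(y, config$train_fraction, seed = seed_r)
    xtr <- x[sp$train, , drop = FALSE]
    xte <- x[sp$test, , drop = FALSE]
    # impute with training means only (no test leakage)
    mu <- colMeans(xtr, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in seq_len(ncol(xtr))) {
      xtr[is.na(xtr[, j]), j] <- mu[j]
      xte[is.na(xte[, j]), j] <- mu[j]
    }
    tuned <- tune_hyperparameters(xtr, y[sp$train], config,
                                  seed = derive_seed(seed_r, 1L))
    # final fit on the whole training set, no SMOTE
    fit <- fit_rf(xtr, y[sp$train], tuned$best$max_depth,
                  tuned$best$mtry_frac, config$n_trees, seed = seed_r)
    n_train[r] <- fit$num.samples
    sc <- rf_scores(fit, xte, positive)
    lab <- y[sp$test] == positive
    auc[r] <- roc_auc(sc, lab)
    f1[r] <- f1_score(sc, lab)
    imp[r, names(fit$variable.importance)] <- fit$variable.importance
    rnk[r, ] <- rank(-imp[r, ], ties.method = "average")
    tpr_acc[r, ] <- roc_on_grid(sc, lab, fpr_grid)
  }
  structure(list(
    auc = auc, f1 = f1,
    mean_auc = mean(auc), sd_auc = stats::sd(auc),
    mean_f1 = mean(f1), sd_f1 = stats::sd(f1),
    importance = colMeans(imp),
    mean_rank = colMeans(rnk),
    roc = data.frame(fpr = fpr_grid, tpr = colMeans(tpr_acc)),
    positive = positive,
    n_train_per_run = n_train,
    config = config
  ), class = "rf_eval")
}

#' @export
print.rf_eval <- function(x, ...) {
  cat(sprintf("<rf_eval: %d runs, positive = '%s'>\n",
              length(x$auc), x$positive))
  cat(sprintf("  AUC %.3f (SD %.3f), F1 %.3f (SD %.3f)\n",
              x$mean_auc, x$sd_auc, x$mean_f1, x$sd_f1))
  top <- names(sort(x$mean_rank))[seq_len(min(5L, length(x$mean_rank)))]
  cat("  top features:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Select top features per set and combine
#'
#' Given per-set mean-rank vectors (from \code{\link{evaluate_task}} on
#' each feature set), takes the \code{k} best-ranked features of each set
#' and returns their union in canonical set order (6 sets x 8 = 48 for the
#' full design).
#'
#' @param rankings Named list: one numeric mean-rank vector per feature
#'   set (names = feature names; smaller rank = more important).
#' @param k Features per set (default 8).
#' @return Character vector of selected feature names.
#' @export
select_top_features <- function(rankings, k = 8L) {
  out <- character(0)
  for (set in names(rankings)) {
    r <- rankings[[set]]
    take <- min(k, length(r))
    if (take < k) {
      message("feature set '", set, "' has fewer than ", k,
              " features; taking all ", take)
    }
    out <- c(out, names(sort(r))[seq_len(take)])
  }
  out
}

#' Balanced feature-exclusion variant
#'
#' Drops the excluded sets' top features and refills round-robin from the
#' retained sets' next-ranked features (canonical set order, rank order
#' within set) until the target size (6 x k) is reached again.
#'
#' @param rankings Named list of per-set mean-rank vectors (all features).
#' @param exclude Character vector of set names to drop.
#' @param k Features per set in the base selection (default 8).
#' @return Character vector of feature names of the same total size as the
#'   unexcluded selection (shortfall logged if retained sets run dry).
#' @export
balanced_exclusion_model <- function(rankings, exclude = character(0), k = 8L) {
  target <- length(rankings) * k
  retained <- setdiff(names(rankings), exclude)
  if (length(retained) == 0L) stop("at least one retained set is required")
  ordered <- lapply(rankings[retained], function(r) names(sort(r)))
  selected <- unlist(lapply(ordered, function(nm) nm[seq_len(min(k, length(nm)))]),
                     use.names = FALSE)
  depth <- k
  while (length(selected) < target) {
    depth <- depth + 1L
    added <- FALSE
    for (set in retained) {
      if (length(selected) >= target) break
      nm <- ordered[[set]]
      if (length(nm) >= depth) {
        selected <- c(selected, nm[depth])
        added <- TRUE
      }
    }
    if (!added) {
      message("retained sets exhausted; returning ", length(selected),
              " of ", target, " features")
      break
    }
  }
  selected
}

#' Pairwise group mean comparison of features
#'
#' Per feature: percent difference of group means (relative to the second
#' group), Welch t-test p-value, and Benjamini-Hochberg adjusted p-value
#' pooled across the whole requested comparison family.
#'
#' @param x Numeric feature matrix (participants x features).
#' @param groups Group label vector.
#' @param pairs List of length-2 character vectors (group1, group2); BH
#'   pooling spans all pairs together.
#' @return data.frame: \code{pair}, \code{feature}, \code{mean1},
#'   \code{mean2}, \code{pct_diff}, \code{p}, \code{p_adj}.
#' @export
group_mean_comparison <- function(x, groups, pairs) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  rows <- list()
  for (pr in pairs) {
    g1 <- x[groups == pr[1], , drop = FALSE]
    g2 <- x[groups == pr[2], , drop = FALSE]
    if (nrow(g1) == 0L || nrow(g2) == 0L) stop("empty group in pair")
    for (j in seq_len(ncol(x))) {
      a <- g1[, j][!is.na(g1[, j])]
      b <- g2[, j][!is.na(g2[, j])]
      m1 <- mean(a); m2 <- mean(b)
      pct <- if (isTRUE(m2 == 0)) NA_real_ else 100 * (m1 - m2) / m2
      p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      if (length(a) > 1L && length(b) > 1L &&
          stats::sd(a) == 0 && stats::sd(b) == 0 && m1 == m2) {
        p <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(pr, collapse = "-"), feature = colnames(x)[j],
        mean1 = m1, mean2 = m2, pct_diff = pct, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}
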