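# Within-group clustering: preprocessing, PCA feature space, k-means with
# Calinski-Harabasz model selection, small-cluster exclusion and formal
# between-cluster comparison.

#' Preprocess a feature table for clustering
#'
#' Mean-imputes missing cells (per feature, computed over all participants;
#' warning above 2% missing, error above 5%), drops near-zero-variance
#' features (variance below \code{var_tol} or fewer than 2 distinct
#' values), and z-standardizes every retained column to mean 0, variance 1.
#'
#' @param x Numeric participants x features matrix (NAs allowed).
#' @param var_tol Near-zero-variance cut (default 1e-8).
#' @return Object of class \code{"preproc_matrix"}: list with \code{z}
#'   (standardized matrix), \code{impute_means}, \code{dropped},
#'   \code{center}, \code{scale}.
#' @export
preprocess_features <- function(x, var_tol = 1e-8) {
  x <- as.matrix(x)
  miss <- colMeans(is.na(x))
  if (any(miss > 0.05)) {
    stop("feature(s) with more than 5% missing: ",
         paste(colnames(x)[miss > 0.05], collapse = ", "))
  }
  if (any(miss > 0.02)) {
    warning("feature(s) exceed 2% missing; imputing anyway: ",
            paste(colnames(x)[miss > 0.02], collapse = ", "))
  }
  all_missing <- miss == 1
  if (any(all_missing)) {
    warning("dropping all-missing feature(s): ",
            paste(colnames(x)[all_missing], collapse = ", "))
  }
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  v <- apply(x, 2L, stats::var)
  distinct <- apply(x, 2L, function(c) length(unique(c)))
  drop <- all_missing | is.na(v) | v < var_tol | distinct < 2L
  kept <- x[, !drop, drop = FALSE]
  ctr <- colMeans(kept)
  scl <- apply(kept, 2L, stats::sd)
  z <- scale(kept, center = ctr, scale = scl)
  structure(list(z = z, impute_means = mu,
                 dropped = colnames(x)[drop],
                 center = ctr, scale = scl),
            class = "preproc_matrix")
}

#' @export
print.preproc_matrix <- function(x, ...) {
  cat(sprintf("<preproc_matrix: %d x %d standardized (%d dropped)>\n",
              nrow(x$z), ncol(x$z), length(x$dropped)))
  invisible(x)
}

#' PCA feature space at a cumulative-variance threshold
#'
#' Principal components of the (already standardized) all-participants
#' matrix; retains the smallest number of leading components whose
#' cumulative explained variance reaches \code{variance_threshold}, and
#' projects every participant onto them.
#'
#' @param pre A \code{\link{preprocess_features}} result (or a numeric
#'   matrix already centered/scaled).
#' @param variance_threshold Cumulative share to reach (default 0.90).
#' @return List: \code{scores} (participants x m), \code{m},
#'   \code{explained} (per-component variance shares), \code{rotation}.
#' @export
pca_space <- function(pre, variance_threshold = 0.90) {
  z <- if (inherits(pre, "preproc_matrix")) pre$z else as.matrix(pre)
  if (nrow(z) < 2L) stop("need at least 2 participants")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 0) stop("degenerate (rank 0) matrix")
  share <- ev / tot
  m <- which(cumsum(share) >= variance_threshold - 1e-12)[1]
  list(scores = pc$x[, seq_len(m), drop = FALSE], m = m,
       explained = share, rotation = pc$rotation[, seq_len(m), drop = FALSE])
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' \code{(B/(k-1)) / (W/(n-k))}; larger values indicate better-separated,
#' more compact clusters. Returns \code{Inf} when the within-cluster sum
#' of squares is exactly zero.
#'
#' @param points Numeric matrix (n x d).
#' @param assignments Cluster label vector of length n (k >= 2 distinct
#'   values, each nonempty, n > k).
#' @return Scalar CH value.
#' @export
calinski_harabasz <- function(points, assignments) {
  points <- as.matrix(points)
  n <- nrow(points)
  cl <- as.character(assignments)
  ks <- unique(cl)
  k <- length(ks)
  if (k < 2L) stop("need at least 2 clusters")
  if (n <= k) stop("need more points than clusters")
  grand <- colMeans(points)
  B <- 0; W <- 0
  for (g in ks) {
    pts <- points[cl == g, , drop = FALSE]
    if (nrow(pts) == 0L) stop("empty cluster")
    ctr <- colMeans(pts)
    B <- B + nrow(pts) * sum((ctr - grand)^2)
    W <- W + sum(sweep(pts, 2L, ctr)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

# k-means++ seeding: returns initial center matrix
kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  i <- sample.int(n, 1L)
  centers[1L, ] <- points[i, ]
  d2 <- rowSums(sweep(points, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- points[i, ]
    d2 <- pmin(d2, rowSums(sweep(points, 2L, centers[j, ])^2))
  }
  centers
}

# best-of-restarts k-means with k-means++ seeding
kmeans_restarts <- function(points, k, restarts = 50L, seed = NULL,
                            iter_max = 100L) {
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      ctr <- kmeanspp_centers(points, k)
      ctr <- ctr[!duplicated(ctr), , drop = FALSE]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(points, centers = ctr,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed for k = ", k)
    best
  })
}

#' Cluster one diagnosis group with CH model selection
#'
#' Runs k-means (k-means++ seeding, \code{restarts} restarts, best
#' inertia) for every k in \code{k_range} on the group's PCA coordinates,
#' scores each candidate with the Calinski-Harabasz index and keeps the k
#' optimizing the criterion (\code{direction = "maximize"} by default).
#' Clusters with fewer than \code{min_cluster_size} members are flagged as
#' excluded from comparison.
#'
#' @param points Numeric matrix of one group's PCA coordinates.
#' @param k_range Candidate cluster counts (default 2:10; shrunk with a
#'   warning when the group is too small).
#' @param seed Integer seed.
#' @param restarts Restarts per k (default 50).
#' @param direction \code{"maximize"} (standard CH semantics, default) or
#'   \code{"minimize"}.
#' @param min_cluster_size Exclusion cut for small clusters (default 10).
#' @return Object of class \code{"cluster_result"}: list with \code{k},
#'   \code{assignments}, \code{ch} (named per-candidate values),
#'   \code{excluded_clusters}, \code{centers}, \code{direction}.
#' @export
cluster_group <- function(points, k_range = 2:10, seed = 1L, restarts = 50L,
                          direction = c("maximize", "minimize"),
                          min_cluster_size = 10L) {
  direction <- match.arg(direction)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n <= min_cluster_size) stop("group size must exceed ", min_cluster_size)
  if (n <= max(k_range)) {
    k_range <- k_range[k_range < n]
    warning("k range shrunk to ", paste(range(k_range), collapse = ":"),
            " for group of size ", n)
  }
  ch <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- kmeans_restarts(points, k, restarts, seed = derive_seed(seed, k))
    fits[[i]] <- fit
    ch[i] <- calinski_harabasz(points, fit$cluster)
  }
  pick <- if (direction == "maximize") which.max(ch) else which.min(ch)
  fit <- fits[[pick]]
  sizes <- table(fit$cluster)
  excluded <- as.integer(names(sizes)[sizes < min_cluster_size])
  structure(list(k = k_range[pick], assignments = fit$cluster, ch = ch,
                 excluded_clusters = excluded, centers = fit$centers,
                 direction = direction),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k = %d (%s CH), sizes %s>\n", x$k,
              x$direction, paste(table(x$assignments), collapse = "/")))
  if (length(x$excluded_clusters) > 0L) {
    cat("  excluded (<10 members):",
        paste(x$excluded_clusters, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare clusters on original-scale features
#'
#' Welch t-tests per original-scale feature (and optional demographic
#' columns, which are never part of the clustering itself) between the two
#' retained clusters of a group, with Benjamini-Hochberg adjustment within
#' that group's family of tests. With more than two non-excluded clusters
#' the two largest are compared with a warning.
#'
#' @param x Numeric participants x features matrix on the original scale.
#' @param result A \code{\link{cluster_group}} result for the same rows.
#' @param extra Optional numeric matrix/data.frame of extra columns
#'   (demographics, biomarkers) to compare alongside the features.
#' @return data.frame: \code{feature}, \code{cluster1}, \code{cluster2},
#'   \code{mean1}, \code{mean2}, \code{pct_diff}, \code{p}, \code{p_adj},
#'   \code{sig}, \code{sig_adj}.
#' @export
compare_clusters <- function(x, result, extra = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  cl <- result$assignments
  keep <- setdiff(sort(unique(cl)), result$excluded_clusters)
  if (length(keep) < 2L) {
    stop("fewer than 2 non-excluded clusters; nothing to compare")
  }
  if (length(keep) > 2L) {
    sizes <- table(cl)[as.character(keep)]
    keep <- as.integer(names(sort(sizes, decreasing = TRUE))[1:2])
    warning("more than 2 retained clusters; comparing the two largest (",
            paste(keep, collapse = ", "), ")")
  }
  keep <- sort(keep)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    x <- cbind(x, extra)
  }
  rows <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[cl == keep[1], j]; a <- a[!is.na(a)]
    b <- x[cl == keep[2], j]; b <- b[!is.na(b)]
    m1 <- mean(a); m2 <- mean(b)
    p <- if (length(a) > 1L && length(b) > 1L &&
             (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      stats::t.test(a, b)$p.value
    } else NA_real_
    data.frame(feature = colnames(x)[j], cluster1 = keep[1],
               cluster2 = keep[2], mean1 = m1, mean2 = m2,
               pct_diff = if (isTRUE(m2 == 0)) NA_real_ else
                 100 * (m1 - m2) / m2,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$sig <- !is.na(out$p) & out$p < 0.05
  out$sig_adj <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}
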