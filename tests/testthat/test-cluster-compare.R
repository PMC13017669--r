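# Preprocessing, PCA space, CH index, k-means model selection and cluster
# comparison.

test_that("preprocessing imputes, drops degenerate columns, standardizes", {
  set.seed(20)
  x <- cbind(a = c(NA, rnorm(99, 4)), b = rep(7, 100), c = rnorm(100))
  pre <- preprocess_features(x)
  expect_identical(pre$dropped, "b")
  expect_equal(unname(pre$impute_means["a"]), mean(x[-1, "a"]))
  expect_equal(unname(colMeans(pre$z)), rep(0, 2), tolerance = 1e-9)
  expect_equal(unname(apply(pre$z, 2, var)), rep(1, 2), tolerance = 1e-6)
  # a column with >5% missing is an error; >2% only warns
  bad <- cbind(matrix(rnorm(300), 100, 3), miss = c(rep(NA, 10), rnorm(90)))
  expect_error(preprocess_features(bad), "5%")
  warnish <- cbind(matrix(rnorm(300), 100, 3),
                   m = c(rep(NA, 3), rnorm(97)))
  expect_warning(preprocess_features(warnish), "2%")
})

test_that("PCA retains the smallest space reaching 90% variance", {
  set.seed(21)
  base <- rnorm(40)
  two <- scale(cbind(base, 2 * base + 1e-8 * rnorm(40)))
  expect_identical(pca_space(two)$m, 1L)

  # exactly isotropic 10-feature cloud (whitened): 9 of 10 components
  x <- matrix(rnorm(500), 50, 10)
  white <- scale(x %*% solve(chol(stats::cov(x))))
  expect_identical(pca_space(white)$m, 9L)

  # one dominant direction carrying ~95% of 2-D variance
  dom <- cbind(rnorm(200, sd = sqrt(0.95)), rnorm(200, sd = sqrt(0.05)))
  dom <- scale(dom, scale = FALSE)
  expect_identical(pca_space(dom)$m, 1L)
  expect_error(pca_space(matrix(0, 5, 3)), "degenerate")
})

test_that("Calinski-Harabasz matches hand computation and the brute force", {
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  cl <- c(1, 1, 2, 2)
  expect_equal(calinski_harabasz(pts, cl), 200)
  # zero within-cluster scatter: reported as maximal
  expect_identical(calinski_harabasz(matrix(c(0, 0, 5, 5), 4, 1), cl), Inf)
  expect_error(calinski_harabasz(pts, rep(1, 4)), "2 clusters")
  expect_error(calinski_harabasz(pts, c(1, 2, 3, 4)), "more points")
  # random labels on isotropic noise sit near 1
  set.seed(22)
  noise <- matrix(rnorm(400), 200, 2)
  ch_null <- calinski_harabasz(noise, sample(1:2, 200, replace = TRUE))
  expect_gt(ch_null, 0.05)
  expect_lt(ch_null, 5)
  # exhaustive small-instance equivalence with the two-loop oracle
  for (i in 1:40) {
    n <- sample(6:20, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    cl <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
    expect_equal(calinski_harabasz(pts, cl), ch_brute(pts, cl),
                 tolerance = 1e-12)
  }
})

test_that("restarted k-means never loses to a single restart", {
  set.seed(23)
  pts <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2),
               matrix(rnorm(60, 8), 30, 2))
  best <- somnphen:::kmeans_restarts(pts, 3, restarts = 25, seed = 1)
  for (s in 2:6) {
    single <- somnphen:::kmeans_restarts(pts, 3, restarts = 1, seed = s)
    expect_lte(best$tot.withinss, single$tot.withinss + 1e-9)
  }
})

test_that("CH model selection recovers well-separated blob counts", {
  set.seed(24)
  blob <- function(center, n) {
    sweep(matrix(rnorm(n * 2, sd = 0.5), n, 2), 2, center, "+")
  }
  two <- rbind(blob(c(0, 0), 40), blob(c(10, 0), 40))
  res2 <- cluster_group(two, k_range = 2:6, seed = 31, restarts = 15)
  expect_identical(res2$k, 2L)
  truth2 <- rep(1:2, each = 40)
  expect_equal(adjusted_rand_index(res2$assignments, truth2), 1)

  three <- rbind(blob(c(0, 0), 40), blob(c(10, 0), 40), blob(c(5, 9), 40))
  res3 <- cluster_group(three, k_range = 2:6, seed = 32, restarts = 15)
  expect_identical(res3$k, 3L)

  # a 5-point outlying blob is flagged as excluded (< 10 members)
  outl <- rbind(blob(c(0, 0), 40), blob(c(10, 0), 40), blob(c(30, 30), 5))
  reso <- cluster_group(outl, k_range = 2:6, seed = 33, restarts = 15)
  sizes <- table(reso$assignments)
  expect_true(any(sizes < 10))
  expect_identical(sort(reso$excluded_clusters),
                   as.integer(names(sizes)[sizes < 10]))

  expect_error(cluster_group(two[1:8, ], seed = 1), "exceed")
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(25)
  for (i in 1:10) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("cluster comparison flags induced effects and ignores extras", {
  set.seed(26)
  n <- 60
  x <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  cl_truth <- rep(1:2, each = 30)
  x[cl_truth == 1, 1] <- x[cl_truth == 1, 1] + 2   # +2 SD shift on f1
  pre <- preprocess_features(x)
  ps <- pca_space(pre)
  res <- cluster_group(ps$scores, k_range = 2:4, seed = 41, restarts = 15)
  cmp <- compare_clusters(x, res, extra = cbind(age = rnorm(n, 33, 10)))
  expect_true("age" %in% cmp$feature)
  f1row <- cmp[cmp$feature == "f1", ]
  expect_true(f1row$sig_adj)
  # the extra column was never part of the clustered matrix
  expect_identical(ncol(ps$scores) <= 20, TRUE)
  expect_identical(nrow(cmp), 21L)
})
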