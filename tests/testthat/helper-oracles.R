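# Independent oracles used against the package implementations. These stay
# deliberately naive (double loops, literal formulas) and share no code
# with the functions they check.

# AUC by brute-force pair enumeration, ties counting one half
auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the literal step-up construction: sort ascending,
# multiply p_(i) by n/i, enforce monotonicity from the top, cap at 1
bh_oracle <- function(p) {
  n <- length(p)
  if (n <= 1L) return(pmin(p, 1))
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Calinski-Harabasz by the literal two-loop formula
ch_brute <- function(points, assignments) {
  points <- as.matrix(points)
  n <- nrow(points)
  ks <- unique(assignments)
  k <- length(ks)
  grand <- colMeans(points)
  B <- 0
  W <- 0
  for (g in ks) {
    pts <- points[assignments == g, , drop = FALSE]
    ctr <- colMeans(pts)
    B <- B + nrow(pts) * sum((ctr - grand)^2)
    for (i in seq_len(nrow(pts))) W <- W + sum((pts[i, ] - ctr)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# event-level recall/precision of detections against truth intervals
# (any temporal overlap counts as a match)
event_recall <- function(truth, detected) {
  if (nrow(truth) == 0L) return(NA_real_)
  if (nrow(detected) == 0L) return(0)
  mean(vapply(seq_len(nrow(truth)), function(i) {
    any(detected$start < truth$end[i] & detected$end > truth$start[i])
  }, logical(1)))
}

event_precision <- function(truth, detected) {
  if (nrow(detected) == 0L) return(NA_real_)
  mean(vapply(seq_len(nrow(detected)), function(i) {
    any(truth$start < detected$end[i] & truth$end > detected$start[i])
  }, logical(1)))
}

# interval intersection-over-union
interval_iou <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  inter / (max(a1, b1) - min(a0, b0))
}
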