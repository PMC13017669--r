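# Hypnodensity feature block: per quarter, the 5 mean single-stage
# probabilities, 10 pairwise mixture probabilities and the mean Shannon
# entropy (16 x 4 = 64 features).

#' Validate a hypnodensity matrix
#'
#' Checks a per-epoch stage-probability matrix: 5 columns, nonnegative
#' entries, rows summing to 1 within \code{tol}; rows within tolerance are
#' renormalized to sum exactly to 1.
#'
#' @param matrix Numeric epochs x 5 matrix (columns in canonical stage
#'   order W, N1, N2, N3, R).
#' @param tol Row-sum tolerance (default 1e-3).
#' @return The validated, renormalized matrix with stage colnames.
#' @export
validate_hypnodensity <- function(matrix, tol = 1e-3) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 5L) stop("hypnodensity must have 5 columns")
  if (any(matrix < 0)) stop("hypnodensity entries must be nonnegative")
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > tol)) {
    stop("hypnodensity row sums deviate from 1 by more than ", tol)
  }
  matrix <- matrix / rs
  colnames(matrix) <- stage_levels()
  matrix
}

#' Quarter-night hypnodensity features
#'
#' For each quarter of the night window: the mean probability of each
#' stage (5), the mean pairwise mixture probability
#' \code{min(p_a, p_b)} for each of the 10 unordered stage pairs, and the
#' mean per-epoch Shannon entropy \code{-sum(p log p)} (natural log).
#'
#' @param h Validated hypnodensity matrix
#'   (\code{\link{validate_hypnodensity}}).
#' @param window A \code{\link{detect_night_window}} result; the matrix
#'   must cover the window's epochs.
#' @return Named numeric vector of length 64: \code{hd.p.<stage>.Q<i>},
#'   \code{hd.mix.<a>_<b>.Q<i>}, \code{hd.entropy.Q<i>}.
#' @export
hypnodensity_feature_block <- function(h, window) {
  h <- validate_hypnodensity(h)
  if (nrow(h) < window$final) {
    stop("night window extends beyond the hypnodensity matrix")
  }
  pairs <- stage_pairs()
  out <- numeric(0)
  for (q in 1:4) {
    b <- window$quarter_bounds[q, ]
    sub <- h[b[1]:(b[2] - 1L), , drop = FALSE]
    p_mean <- colMeans(sub)
    names(p_mean) <- paste0("hd.p.", stage_levels(), ".Q", q)
    mix <- vapply(seq_len(nrow(pairs)), function(i) {
      mean(pmin(sub[, pairs[i, 1]], sub[, pairs[i, 2]]))
    }, numeric(1))
    names(mix) <- paste0("hd.mix.", pairs[, 1], "_", pairs[, 2], ".Q", q)
    ent <- mean(apply(sub, 1L, shannon_entropy))
    out <- c(out, p_mean, mix, stats::setNames(ent, paste0("hd.entropy.Q", q)))
  }
  out
}

# natural-log Shannon entropy of one probability row; 0 log 0 = 0
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
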