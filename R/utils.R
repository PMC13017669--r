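# RNG hygiene: run code under a given seed without disturbing the caller's
# RNG stream. All generator-facing functions funnel through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# derive a reproducible 31-bit child seed from a master seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values by the Benjamini-Hochberg step-up
#' procedure, applied across one family of tests. Thin, NA-tolerant wrapper
#' over \code{stats::p.adjust(method = "BH")} so the family semantics are
#' explicit at call sites (pooled across diagnosis pairs; within a diagnosis
#' group for cluster comparisons).
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items, used
#' to score cluster recovery against generator ground truth.
#'
#' @param a,b Two label vectors of equal length.
#' @return Scalar in (-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# largest run-length encoding helper: first index starting a run of >= k
# TRUEs in logical vector x, or NA if none
first_run_at_least <- function(x, k) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1L]]
}
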