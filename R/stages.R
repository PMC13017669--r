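#' Canonical sleep-stage alphabet
#'
#' The five AASM sleep stages in the fixed canonical order used throughout
#' the package: wake, N1, N2, N3 and REM (coded \code{"R"}). All hypnograms,
#' transition matrices, spectral profiles and hypnodensity matrices are
#' indexed in this order.
#'
#' @return Character vector \code{c("W","N1","N2","N3","R")}.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "R")

#' Standard EEG frequency bands
#'
#' Six contiguous bands covering the 0.5--47 Hz analysis range: delta
#' (0.5--4 Hz), theta (4--8), alpha (8--12), sigma (12--16), beta (16--30)
#' and gamma (30--47 Hz).
#'
#' @return A data.frame with columns \code{band}, \code{low}, \code{high}.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "sigma", "beta", "gamma"),
    low  = c(0.5, 4, 8, 12, 16, 30),
    high = c(4, 8, 12, 16, 30, 47),
    stringsAsFactors = FALSE
  )
}

#' Unordered stage pairs in canonical order
#'
#' The 10 unordered pairs of distinct sleep stages, used for hypnodensity
#' mixture features.
#'
#' @return A two-column character matrix, one row per pair.
#' @keywords internal
stage_pairs <- function() {
  s <- stage_levels()
  idx <- utils::combn(5L, 2L)
  cbind(s[idx[1L, ]], s[idx[2L, ]])
}

# validate a stage vector; returns it as character or stops
check_stages <- function(stages) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), stage_levels())
  if (length(bad) > 0L) {
    stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  }
  stages
}

#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of 30-second scored sleep epochs over
#' the canonical stage alphabet.
#'
#' @param stages Character vector of stage codes in \code{stage_levels()}.
#' @param epoch_seconds Epoch duration in seconds (default 30).
#' @return An object of class \code{"hypnogram"}: a character vector with an
#'   \code{epoch_seconds} attribute.
#' @export
hypnogram <- function(stages, epoch_seconds = 30) {
  stages <- check_stages(stages)
  if (length(stages) == 0L) stop("hypnogram must be nonempty")
  structure(stages, epoch_seconds = epoch_seconds, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = stage_levels()))
  cat(sprintf("<hypnogram: %d epochs of %gs>\n", length(x),
              attr(x, "epoch_seconds")))
  print(tab)
  invisible(x)
}

epoch_seconds <- function(h) {
  es <- attr(h, "epoch_seconds")
  if (is.null(es)) 30 else es
}
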