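# Hypnogram feature sets: 8 whole-night features, 7-per-quarter
# quarter-night features, and 25-per-quarter stage-transition probabilities.

#' Locate the analyzed night window
#'
#' The analysis window runs from persistent sleep onset (first epoch opening
#' a run of at least 20 consecutive non-wake epochs, i.e. 10 minutes) to the
#' final non-wake epoch, and is partitioned into four contiguous quarters
#' Q1--Q4 with boundary i placed at \code{onset + floor(i*N/4)} (half-open
#' intervals; remainder epochs accrue to later quarters).
#'
#' @param hypnogram A \code{\link{hypnogram}}.
#' @param persistent_epochs Run length defining persistent sleep onset
#'   (default 20 epochs = 10 min).
#' @return An object of class \code{"night_window"}: list with
#'   \code{onset} and \code{final} (1-based epoch indices, inclusive),
#'   \code{n} (window length in epochs) and \code{quarter_bounds} (4x2
#'   matrix of half-open [start, end) epoch indices).
#' @export
detect_night_window <- function(hypnogram, persistent_epochs = 20L) {
  stages <- check_stages(unclass(hypnogram))
  onset <- first_run_at_least(stages != "W", persistent_epochs)
  if (is.na(onset)) {
    stop("no sleep onset: hypnogram has no run of ",
         persistent_epochs, " consecutive non-wake epochs")
  }
  final <- max(which(stages != "W"))
  n <- final - onset + 1L
  cuts <- onset + floor((0:4) * n / 4)
  qb <- cbind(start = cuts[1:4], end = cuts[2:5])   # half-open [start, end)
  structure(list(onset = onset, final = final, n = n,
                 quarter_bounds = qb,
                 epoch_seconds = epoch_seconds(hypnogram)),
            class = "night_window")
}

#' @export
print.night_window <- function(x, ...) {
  cat(sprintf("<night_window: epochs %d..%d (N = %d), quarters of %s epochs>\n",
              x$onset, x$final, x$n,
              paste(x$quarter_bounds[, 2] - x$quarter_bounds[, 1],
                    collapse = "/")))
  invisible(x)
}

# features of one stage subsequence: TST (min), SSI (per hour), proportions
window_metrics <- function(stages, es) {
  n <- length(stages)
  tst <- sum(stages != "W") * es / 60
  shifts <- if (n > 1L) sum(stages[-1] != stages[-n]) else 0L
  hours <- n * es / 3600
  ssi <- shifts / hours
  props <- as.numeric(table(factor(stages, levels = stage_levels()))) / n
  names(props) <- stage_levels()
  list(tst = tst, ssi = ssi, props = props)
}

#' Whole-night hypnogram features
#'
#' The eight whole-night features over the analysis window: total sleep time
#' (minutes of non-wake epochs), REM sleep onset (minutes from persistent
#' sleep onset to the first REM epoch; missing if no REM), the stage shift
#' index (transitions between differing adjacent epochs per hour of window
#' duration) and the proportion of window time in each of the five stages.
#'
#' @param hypnogram A \code{\link{hypnogram}}.
#' @param window A \code{\link{detect_night_window}} result.
#' @return Named numeric vector of length 8: \code{hyp.tst},
#'   \code{hyp.rem_onset}, \code{hyp.ssi}, \code{hyp.prop.W},
#'   \code{hyp.prop.N1}, \code{hyp.prop.N2}, \code{hyp.prop.N3},
#'   \code{hyp.prop.R}.
#' @export
whole_night_features <- function(hypnogram, window) {
  stages <- check_stages(unclass(hypnogram))
  es <- window$epoch_seconds
  w <- stages[window$onset:window$final]
  m <- window_metrics(w, es)
  first_rem <- which(w == "R")[1]
  rem_onset <- if (is.na(first_rem)) NA_real_ else (first_rem - 1) * es / 60
  c(hyp.tst = m$tst, hyp.rem_onset = rem_onset, hyp.ssi = m$ssi,
    stats::setNames(m$props, paste0("hyp.prop.", names(m$props))))
}

#' Quarter-night hypnogram features
#'
#' Per quarter of the night window: total sleep time, stage shift index and
#' the five stage proportions (7 features x 4 quarters = 28). Identical in
#' construction to the whole-night set but without REM sleep onset.
#'
#' @inheritParams whole_night_features
#' @return Named numeric vector of length 28, names
#'   \code{qhyp.<metric>.Q<i>}.
#' @export
quarter_hypnogram_features <- function(hypnogram, window) {
  stages <- check_stages(unclass(hypnogram))
  es <- window$epoch_seconds
  out <- numeric(0)
  for (q in 1:4) {
    b <- window$quarter_bounds[q, ]
    sub <- stages[b[1]:(b[2] - 1L)]
    m <- window_metrics(sub, es)
    v <- c(tst = m$tst, ssi = m$ssi,
           stats::setNames(m$props, paste0("prop.", names(m$props))))
    names(v) <- paste0("qhyp.", names(v), ".Q", q)
    out <- c(out, v)
  }
  out
}

#' Quarter-night stage-transition probabilities
#'
#' For each quarter, counts of consecutive epoch pairs (both epochs inside
#' the quarter; pairs straddling a quarter boundary are not counted) by
#' (from, to) stage, row-normalized into P(next | current). Rows with no
#' observed departures are wholly missing. 25 features per quarter, 100 in
#' total.
#'
#' @inheritParams whole_night_features
#' @return Named numeric vector of length 100, names
#'   \code{tp.<from>_to_<to>.Q<i>} in canonical stage order.
#' @export
quarter_transition_matrices <- function(hypnogram, window) {
  stages <- check_stages(unclass(hypnogram))
  s <- stage_levels()
  out <- numeric(0)
  for (q in 1:4) {
    b <- window$quarter_bounds[q, ]
    sub <- stages[b[1]:(b[2] - 1L)]
    P <- transition_probs(sub)
    v <- as.vector(t(P))   # row-major: from W row first
    names(v) <- paste0("tp.", rep(s, each = 5L), "_to_", rep(s, 5L), ".Q", q)
    out <- c(out, v)
  }
  out
}

# row-normalized 5x5 transition probability matrix from a stage sequence;
# unobserved from-rows are NA
transition_probs <- function(stages) {
  s <- stage_levels()
  counts <- matrix(0, 5L, 5L, dimnames = list(s, s))
  if (length(stages) >= 2L) {
    from <- stages[-length(stages)]
    to <- stages[-1]
    tab <- table(factor(from, levels = s), factor(to, levels = s))
    counts <- counts + unclass(tab)
  }
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, NA_real_, rs)
  P[rs == 0, ] <- NA_real_
  P
}
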