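# The feature catalog: the single source of truth for the 330 feature
# names, their order and their partition into the six feature sets.

#' The 330-feature catalog
#'
#' Ordered list of every feature the pipeline derives, tagged by feature
#' set: whole-night hypnogram (8), whole-night spindle (10), quarter-night
#' hypnogram (28), quarter-night stage-transition probability (100),
#' quarter-night qEEG (120) and quarter-night hypnodensity (64);
#' 8 + 10 + 28 + 100 + 120 + 64 = 330. Classifier set partitions and
#' cluster inputs are derived from this catalog; no feature exists outside
#' it.
#'
#' @return data.frame with columns \code{name} and \code{set} (330 rows).
#' @export
feature_catalog <- function() {
  s <- stage_levels()
  hyp <- c("hyp.tst", "hyp.rem_onset", "hyp.ssi", paste0("hyp.prop.", s))
  spindle <- c("spindle.count", "spindle.density", "spindle.frequency",
               "spindle.amplitude", "spindle.duration",
               "spindle.so_coupling_prop", "spindle.so_coupling_angle",
               "spindle.so_phase_locking", "spindle.dispersion",
               "spindle.sigma_isolation")
  qhyp <- as.vector(vapply(1:4, function(q) {
    paste0("qhyp.", c("tst", "ssi", paste0("prop.", s)), ".Q", q)
  }, character(7)))
  tp <- as.vector(vapply(1:4, function(q) {
    paste0("tp.", rep(s, each = 5L), "_to_", rep(s, 5L), ".Q", q)
  }, character(25)))
  bands <- eeg_bands()$band
  qeeg <- character(0)
  for (b in bands) for (st in s) for (q in 1:4) {
    qeeg <- c(qeeg, paste0("qeeg.", b, ".", st, ".Q", q))
  }
  pairs <- stage_pairs()
  hd <- as.vector(vapply(1:4, function(q) {
    c(paste0("hd.p.", s, ".Q", q),
      paste0("hd.mix.", pairs[, 1], "_", pairs[, 2], ".Q", q),
      paste0("hd.entropy.Q", q))
  }, character(16)))
  data.frame(
    name = c(hyp, spindle, qhyp, tp, qeeg, hd),
    set = rep(c("hypnogram", "spindle", "quarter_hypnogram",
                "transition", "qeeg", "hypnodensity"),
              times = c(8L, 10L, 28L, 100L, 120L, 64L)),
    stringsAsFactors = FALSE
  )
}

#' Feature names of one set
#'
#' @param set One of \code{"hypnogram"}, \code{"spindle"},
#'   \code{"quarter_hypnogram"}, \code{"transition"}, \code{"qeeg"},
#'   \code{"hypnodensity"}.
#' @return Character vector of feature names in catalog order.
#' @export
feature_set_names <- function(set) {
  cat_ <- feature_catalog()
  if (!set %in% cat_$set) stop("unknown feature set: ", set)
  cat_$name[cat_$set == set]
}
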