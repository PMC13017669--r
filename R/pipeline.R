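# End-to-end feature assembly: one 330-value row per participant, cohort
# tables, and a demo pipeline runner.

#' Extract the full 330-feature row for one recording
#'
#' Runs all four feature modules on one participant's bundle (hypnogram,
#' EEG, optional hypnodensity) and assembles the values in catalog order.
#' Features whose substrate is absent stay missing (e.g. all 64
#' hypnodensity features without a hypnodensity matrix; REM-conditional
#' features in a night without REM), but the row schema is always the full
#' 330-name catalog.
#'
#' @param hypnogram A \code{\link{hypnogram}}.
#' @param eeg Numeric microvolt vector aligned to the hypnogram from
#'   recording start.
#' @param fs Sampling rate in Hz.
#' @param hypnodensity Optional epochs x 5 probability matrix.
#' @param so_stages Stages searched for slow oscillations (default: all
#'   non-wake sleep).
#' @return Named numeric vector of length 330 in catalog order.
#' @export
extract_all_features <- function(hypnogram, eeg, fs, hypnodensity = NULL,
                                 so_stages = c("N1", "N2", "N3", "R")) {
  spe <- round(epoch_seconds(hypnogram) * fs)
  if (length(eeg) < length(unclass(hypnogram)) * spe) {
    stop("EEG is shorter than the hypnogram span")
  }
  window <- detect_night_window(hypnogram)
  out <- stats::setNames(rep(NA_real_, 330L), feature_catalog()$name)

  out[names(whole_night_features(hypnogram, window))] <-
    whole_night_features(hypnogram, window)
  q <- quarter_hypnogram_features(hypnogram, window)
  out[names(q)] <- q
  tp <- quarter_transition_matrices(hypnogram, window)
  out[names(tp)] <- tp

  filtered <- fir_bandpass(eeg, fs, 0.5, 47)
  qe <- qeeg_feature_block(filtered, fs, hypnogram, window,
                           prefiltered = TRUE)
  out[names(qe)] <- qe

  n2 <- stage_intervals(hypnogram, "N2", window)
  sleep <- stage_intervals(hypnogram, so_stages, window)
  spindles <- detect_spindles(filtered, fs, n2)
  sos <- detect_slow_oscillations(filtered, fs, sleep)
  sp <- spindle_summary(spindles, sos, filtered, fs, n2)
  out[names(sp)] <- sp

  if (!is.null(hypnodensity)) {
    hd <- hypnodensity_feature_block(hypnodensity, window)
    out[names(hd)] <- hd
  }
  out
}

#' Extract features for a whole synthetic cohort
#'
#' Applies \code{\link{extract_all_features}} to every participant of a
#' \code{\link{generate_cohort}} result and, afterwards, blanks feature
#' cells at each group's \code{missing_rate} (reproducing the up-to-2%
#' missingness of real feature tables; seeds derived from the cohort's
#' master seed).
#'
#' @param cohort A \code{\link{generate_cohort}} result.
#' @param inject_missing Apply the group missing rates (default TRUE).
#' @return data.frame: \code{participant_id}, \code{group}, then the 330
#'   catalog columns.
#' @export
extract_cohort_features <- function(cohort, inject_missing = TRUE) {
  specs <- cohort$truth$specs
  rate_of <- stats::setNames(
    vapply(specs, function(s) s$missing_rate, numeric(1)),
    vapply(specs, function(s) s$label, character(1)))
  rows <- lapply(cohort$participants, function(p) {
    tryCatch(
      extract_all_features(p$hypnogram, p$eeg, p$fs, p$hypnodensity),
      error = function(e) {
        warning("participant ", p$id, " unusable (", conditionMessage(e),
                "); emitting an all-missing feature row", call. = FALSE)
        stats::setNames(rep(NA_real_, 330L), feature_catalog()$name)
      })
  })
  feat <- do.call(rbind, rows)
  if (inject_missing) {
    feat <- with_seed(derive_seed(cohort$truth$seed, 999983L), {
      for (i in seq_len(nrow(feat))) {
        rate <- rate_of[[cohort$participants[[i]]$group]]
        if (rate > 0) {
          hit <- stats::runif(ncol(feat)) < rate
          feat[i, hit] <- NA_real_
        }
      }
      feat
    })
  }
  cbind(cohort$cohort[, c("participant_id", "group")],
        as.data.frame(feat))
}

#' Write / read a feature table
#'
#' CSV with \code{participant_id}, \code{group}, then the 330 catalog
#' columns in order; missing values as empty cells; values printed at
#' full precision so the round-trip is lossless at 10+ significant
#' digits.
#'
#' @param x data.frame as from \code{\link{extract_cohort_features}}.
#' @param path File path.
#' @return \code{write_feature_table}: the path, invisibly;
#'   \code{read_feature_table}: the data.frame with catalog-ordered
#'   columns.
#' @export
write_feature_table <- function(x, path) {
  if (anyDuplicated(x$participant_id)) stop("duplicate participant ids")
  wanted <- c("participant_id", "group", feature_catalog()$name)
  missing_cols <- setdiff(wanted, colnames(x))
  if (length(missing_cols) > 0L) {
    stop("feature table lacks columns: ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  }
  utils::write.csv(x[, wanted], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       check.names = FALSE, na.strings = "")
  wanted <- c("participant_id", "group", feature_catalog()$name)
  missing_cols <- setdiff(wanted, colnames(x))
  if (length(missing_cols) > 0L) {
    stop("feature table lacks columns: ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  }
  x[, wanted]
}

#' Run the demonstration pipeline end to end
#'
#' Simulates a cohort, extracts the 330-feature table, evaluates the
#' binary classification task on all features and clusters the first
#' group, returning every intermediate product along with a manifest of
#' the seeds used. Intended for smoke testing and the worked example; the
#' individual stages are the real interface.
#'
#' @param specs List of two or more \code{\link{group_spec}}s.
#' @param seed Master seed.
#' @param runs Outer Monte-Carlo runs for the classifier (default 20).
#' @param grid Hyperparameter grid (default: a single unbounded-depth,
#'   sqrt-mtry candidate to keep the demo fast).
#' @return List: \code{features} (table), \code{eval} (rf_eval),
#'   \code{clusters} (cluster_result), \code{manifest}.
#' @export
run_pipeline <- function(specs, seed = 1L, runs = 20L,
                         grid = data.frame(max_depth = 0L,
                                           mtry_frac = NA_real_)) {
  if (length(specs) < 2L) stop("need at least two groups")
  cohort <- generate_cohort(specs, seed)
  tab <- extract_cohort_features(cohort)
  fx <- as.matrix(tab[, feature_catalog()$name])
  cfg <- eval_config(runs = runs, grid = grid,
                     seed = derive_seed(seed, 101L))
  ev <- evaluate_task(fx, tab$group, config = cfg)
  g1 <- vapply(specs, function(s) s$label, character(1))[1]
  # features too sparsely observed at this cohort size cannot be imputed
  # sensibly; drop them from the clustering input
  usable <- colMeans(is.na(fx)) <= 0.05
  if (any(!usable)) {
    message(sum(!usable), " feature(s) with >5% missing dropped before ",
            "clustering preprocessing")
  }
  pre <- preprocess_features(fx[, usable, drop = FALSE])
  pca <- pca_space(pre)
  pts <- pca$scores[tab$group == g1, , drop = FALSE]
  cl <- tryCatch(
    cluster_group(pts, k_range = 2:min(10L, nrow(pts) - 1L),
                  seed = derive_seed(seed, 202L)),
    error = function(e) NULL)
  list(features = tab, eval = ev, clusters = cl,
       manifest = list(master_seed = seed,
                       classifier_seed = derive_seed(seed, 101L),
                       cluster_seed = derive_seed(seed, 202L),
                       n_participants = nrow(tab),
                       runs = runs))
}
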