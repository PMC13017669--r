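# Synthetic nPSG cohort generator with known ground truth.
#
# Every downstream stage (feature extraction, classification, clustering) is
# validated against recordings produced here: a per-epoch Markov hypnogram, a
# single-channel EEG built from stage-shaped band-limited noise with injected
# sigma-band spindles (N2) and slow oscillations (N3), and a Dirichlet
# hypnodensity sharpened around the true stage.

#' Default per-epoch stage-transition kernel
#'
#' A sticky 5x5 row-stochastic matrix over (W, N1, N2, N3, R) representing a
#' plausible clinical night at 30-s epoch resolution.
#'
#' @return 5x5 numeric matrix, rows summing to 1, dimnames in canonical
#'   stage order.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    0.60, 0.30, 0.08, 0.01, 0.01,   # from W
    0.10, 0.50, 0.35, 0.02, 0.03,   # from N1
    0.03, 0.05, 0.80, 0.08, 0.04,   # from N2
    0.01, 0.02, 0.12, 0.84, 0.01,   # from N3
    0.04, 0.04, 0.05, 0.01, 0.86    # from R
  ), nrow = 5, byrow = TRUE, dimnames = list(stage_levels(), stage_levels()))
  m
}

#' Default stage-conditioned spectral profiles
#'
#' Relative band-power targets (rows: stages, columns: the six bands; each
#' row sums to 1). Delta dominance deepens from N1 to N3; wake and REM carry
#' more alpha/beta/gamma.
#'
#' @return 5x6 numeric matrix with stage and band dimnames.
#' @export
default_spectral_profiles <- function() {
  m <- matrix(c(
    # delta theta alpha sigma beta  gamma
    0.15, 0.15, 0.30, 0.10, 0.20, 0.10,   # W
    0.30, 0.30, 0.15, 0.08, 0.12, 0.05,   # N1
    0.48, 0.21, 0.11, 0.05, 0.10, 0.05,   # N2
    0.70, 0.12, 0.06, 0.05, 0.04, 0.03,   # N3
    0.35, 0.25, 0.12, 0.06, 0.14, 0.08    # R
  ), nrow = 5, byrow = TRUE,
  dimnames = list(stage_levels(), eeg_bands()$band))
  m
}

#' Specify one synthetic participant group
#'
#' Bundles every generator parameter for one diagnosis-like group. Group
#' differences are induced through the same levers the feature modules
#' measure: stage-transition structure, stage-conditioned spectra, spindle
#' parameters and hypnodensity sharpness.
#'
#' @param label Group name.
#' @param n_participants Number of participants to simulate.
#' @param transition_matrix 5x5 row-stochastic per-epoch Markov kernel.
#' @param initial_distribution Length-5 probability vector over stages at
#'   the first epoch (default: start awake).
#' @param spectral_profiles 5x6 matrix of relative band powers per stage,
#'   rows summing to 1.
#' @param eeg_scale_uv Total background EEG standard deviation in microvolts.
#' @param spindle_density Spindle events per minute of N2.
#' @param spindle_frequency_hz Injected spindle oscillation frequency.
#' @param spindle_amplitude_uv Injected spindle peak-to-peak amplitude.
#' @param spindle_duration_s Injected spindle duration (Hann envelope).
#' @param so_rate Slow-oscillation events per minute of N3.
#' @param so_frequency_hz Slow-oscillation frequency (single cycle).
#' @param so_amplitude_uv Slow-oscillation peak-to-peak amplitude.
#' @param hypnodensity_concentration Dirichlet weight on the true stage
#'   (larger = sharper, more one-hot hypnodensity rows).
#' @param missing_rate Fraction of feature cells to blank after extraction,
#'   in [0, 0.02] (the cohort the pipeline emulates had up to 2% missing).
#' @param n_epochs_range Inclusive range of per-participant night lengths in
#'   30-s epochs (default 700--1100, a typical clinical night).
#' @return An object of class \code{"group_spec"}.
#' @export
group_spec <- function(label,
                       n_participants = 20L,
                       transition_matrix = default_transition_matrix(),
                       initial_distribution = c(1, 0, 0, 0, 0),
                       spectral_profiles = default_spectral_profiles(),
                       eeg_scale_uv = 12,
                       spindle_density = 2,
                       spindle_frequency_hz = 13,
                       spindle_amplitude_uv = 30,
                       spindle_duration_s = 1.0,
                       so_rate = 5,
                       so_frequency_hz = 0.8,
                       so_amplitude_uv = 120,
                       hypnodensity_concentration = 50,
                       missing_rate = 0.01,
                       n_epochs_range = c(700L, 1100L)) {
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == c(5L, 5L))) {
    stop("transition_matrix must be 5x5")
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("transition_matrix rows must be nonnegative and sum to 1")
  }
  if (abs(sum(initial_distribution) - 1) > 1e-9 ||
      any(initial_distribution < 0)) {
    stop("initial_distribution must be a probability vector")
  }
  spectral_profiles <- as.matrix(spectral_profiles)
  if (!all(dim(spectral_profiles) == c(5L, 6L)) ||
      any(spectral_profiles < 0) ||
      any(abs(rowSums(spectral_profiles) - 1) > 1e-6)) {
    stop("spectral_profiles must be 5x6 with rows summing to 1")
  }
  if (missing_rate < 0 || missing_rate > 0.02) {
    stop("missing_rate must lie in [0, 0.02]")
  }
  if (spindle_density < 0 || so_rate < 0) stop("event rates must be >= 0")
  if (hypnodensity_concentration <= 0) {
    stop("hypnodensity_concentration must be positive")
  }
  structure(list(
    label = label,
    n_participants = as.integer(n_participants),
    transition_matrix = transition_matrix,
    initial_distribution = initial_distribution,
    spectral_profiles = spectral_profiles,
    eeg_scale_uv = eeg_scale_uv,
    spindle_density = spindle_density,
    spindle_frequency_hz = spindle_frequency_hz,
    spindle_amplitude_uv = spindle_amplitude_uv,
    spindle_duration_s = spindle_duration_s,
    so_rate = so_rate,
    so_frequency_hz = so_frequency_hz,
    so_amplitude_uv = so_amplitude_uv,
    hypnodensity_concentration = hypnodensity_concentration,
    missing_rate = missing_rate,
    n_epochs_range = as.integer(n_epochs_range)
  ), class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec '%s': %d participants, spindles %.1f/min N2, SO %.1f/min N3>\n",
              x$label, x$n_participants, x$spindle_density, x$so_rate))
  invisible(x)
}

#' Simulate a hypnogram from a Markov stage kernel
#'
#' Draws a stage sequence of \code{n_epochs} 30-s epochs from the group's
#' per-epoch transition kernel, starting from its initial distribution.
#'
#' @param spec A \code{\link{group_spec}}.
#' @param n_epochs Number of epochs (>= 40).
#' @param seed Integer seed; the draw is deterministic given (spec, seed).
#' @return A \code{\link{hypnogram}}.
#' @export
generate_hypnogram <- function(spec, n_epochs, seed) {
  stopifnot(inherits(spec, "group_spec"))
  if (n_epochs < 40L) stop("n_epochs must be >= 40")
  with_seed(seed, {
    s <- stage_levels()
    out <- integer(n_epochs)
    out[1L] <- sample.int(5L, 1L, prob = spec$initial_distribution)
    P <- spec$transition_matrix
    for (i in 2:n_epochs) {
      out[i] <- sample.int(5L, 1L, prob = P[out[i - 1L], ])
    }
    hypnogram(s[out])
  })
}

# single Hann-windowed spindle waveform (samples), amplitude = peak amp in uV
spindle_waveform <- function(fs, freq, amp_pp, dur) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  (amp_pp / 2) * sin(2 * pi * freq * t) * (0.5 - 0.5 * cos(2 * pi * t / dur))
}

# single-cycle slow oscillation: negative half-wave first
so_waveform <- function(fs, freq, amp_pp) {
  dur <- 1 / freq
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  -(amp_pp / 2) * sin(2 * pi * freq * t)
}

# place k non-overlapping event starts of length dur_s inside one epoch
place_events <- function(k, epoch_start_s, epoch_len_s, dur_s) {
  starts <- numeric(0)
  tries <- 0L
  while (length(starts) < k && tries < 50L) {
    cand <- epoch_start_s + stats::runif(1, 0, epoch_len_s - dur_s)
    if (all(abs(cand - starts) >= dur_s)) starts <- c(starts, cand)
    tries <- tries + 1L
  }
  sort(starts)
}

#' Synthesize a stage-shaped EEG signal with known events
#'
#' Builds the background as a sum of six band-limited Gaussian noise
#' components whose per-epoch variances realize the stage's relative
#' band-power profile, then injects Hann-windowed sigma bursts (spindles)
#' into N2 epochs at \code{spindle_density} per minute and single-cycle slow
#' oscillations into N3 epochs at \code{so_rate} per minute. All injected
#' events are recorded in the returned truth.
#'
#' @param hypnogram A \code{\link{hypnogram}}.
#' @param spec A \code{\link{group_spec}}.
#' @param fs Sampling rate in Hz (>= 100; default 128).
#' @param seed Integer seed.
#' @return A list with \code{samples} (microvolt numeric vector),
#'   \code{fs}, and \code{truth}: a list with data.frames \code{spindles}
#'   and \code{sos} (columns start, end, peak, seconds from recording
#'   start) plus the generating parameters.
#' @export
generate_eeg <- function(hypnogram, spec, fs = 128, seed = 1L) {
  stopifnot(inherits(spec, "group_spec"))
  if (fs < 100) stop("fs must be >= 100 Hz")
  stages <- check_stages(unclass(hypnogram))
  es <- epoch_seconds(hypnogram)
  n_ep <- length(stages)
  spe <- round(es * fs)                    # samples per epoch
  n <- n_ep * spe
  bands <- eeg_bands()
  with_seed(seed, {
    # Per-epoch spectral synthesis: real white noise per epoch is shaped in
    # the frequency domain by a stage-specific amplitude mask whose band
    # plateaus realize the stage's relative band powers exactly in
    # expectation. Batched over epochs with mvfft.
    f <- (0:(spe - 1)) * fs / spe
    f <- pmin(f, fs - f)
    masks <- matrix(0, spe, 5L)
    for (s_i in 1:5) {
      for (b in 1:6) {
        sel <- f >= bands$low[b] & f < bands$high[b]
        share <- spec$spectral_profiles[s_i, b]
        masks[sel, s_i] <- spec$eeg_scale_uv *
          sqrt(share * spe / max(1L, sum(sel)))
      }
    }
    stage_idx <- match(stages, stage_levels())
    E <- matrix(stats::rnorm(n), spe, n_ep)
    Fm <- stats::mvfft(E) * masks[, stage_idx, drop = FALSE]
    x <- as.vector(Re(stats::mvfft(Fm, inverse = TRUE))) / spe

    # spindles in N2
    sp_list <- list()
    if (spec$spindle_density > 0) {
      n2_epochs <- which(stages == "N2")
      lambda <- spec$spindle_density * es / 60
      counts <- stats::rpois(length(n2_epochs), lambda)
      wf <- spindle_waveform(fs, spec$spindle_frequency_hz,
                             spec$spindle_amplitude_uv, spec$spindle_duration_s)
      for (j in seq_along(n2_epochs)) {
        if (counts[j] == 0L) next
        ep <- n2_epochs[j]
        starts <- place_events(counts[j], (ep - 1) * es, es,
                               spec$spindle_duration_s)
        for (st in starts) {
          i0 <- round(st * fs) + 1L
          idx <- i0:(i0 + length(wf) - 1L)
          keep <- idx <= length(x)
          x[idx[keep]] <- x[idx[keep]] + wf[keep]
          sp_list[[length(sp_list) + 1L]] <- c(
            start = st, end = st + spec$spindle_duration_s,
            peak = st + spec$spindle_duration_s / 2)
        }
      }
    }
    # slow oscillations in N3
    so_list <- list()
    if (spec$so_rate > 0) {
      n3_epochs <- which(stages == "N3")
      so_dur <- 1 / spec$so_frequency_hz
      lambda <- spec$so_rate * es / 60
      counts <- stats::rpois(length(n3_epochs), lambda)
      wf <- so_waveform(fs, spec$so_frequency_hz, spec$so_amplitude_uv)
      for (j in seq_along(n3_epochs)) {
        if (counts[j] == 0L) next
        ep <- n3_epochs[j]
        starts <- place_events(counts[j], (ep - 1) * es, es, so_dur)
        for (st in starts) {
          i0 <- round(st * fs) + 1L
          idx <- i0:(i0 + length(wf) - 1L)
          keep <- idx <= length(x)
          x[idx[keep]] <- x[idx[keep]] + wf[keep]
          so_list[[length(so_list) + 1L]] <- c(
            start = st, end = st + so_dur, peak = st + so_dur / 4)
        }
      }
    }
    as_event_df <- function(lst) {
      if (length(lst) == 0L) {
        data.frame(start = numeric(0), end = numeric(0), peak = numeric(0))
      } else {
        as.data.frame(do.call(rbind, lst))
      }
    }
    list(samples = x, fs = fs,
         truth = list(seed = seed,
                      spindles = as_event_df(sp_list),
                      sos = as_event_df(so_list),
                      spec_label = spec$label))
  })
}

#' Simulate a hypnodensity matrix around a true hypnogram
#'
#' Each epoch's stage-probability row is drawn from a Dirichlet distribution
#' whose base weights put \code{concentration} on the true stage and 1 on
#' each other stage; large concentrations approach one-hot staging.
#'
#' @param hypnogram A \code{\link{hypnogram}}.
#' @param concentration Positive sharpness scalar.
#' @param seed Integer seed.
#' @return An epochs x 5 matrix with rows summing to 1, columns in canonical
#'   stage order.
#' @export
generate_hypnodensity <- function(hypnogram, concentration, seed) {
  if (concentration <= 0) stop("concentration must be positive")
  stages <- check_stages(unclass(hypnogram))
  idx <- match(stages, stage_levels())
  n <- length(idx)
  with_seed(seed, {
    alpha <- matrix(1, n, 5L)
    alpha[cbind(seq_len(n), idx)] <- concentration
    g <- matrix(stats::rgamma(n * 5L, shape = as.vector(alpha)), n, 5L)
    h <- g / rowSums(g)
    colnames(h) <- stage_levels()
    h
  })
}

#' Simulate a full multi-group cohort
#'
#' Generates hypnogram, EEG and hypnodensity for every participant of every
#' group, with per-participant seeds derived deterministically from the
#' master seed. Feature-level missingness (each group's \code{missing_rate})
#' is applied later, after feature extraction, by
#' \code{\link{extract_cohort_features}}.
#'
#' @param specs List of \code{\link{group_spec}} objects (>= 1; >= 2 for
#'   classification scenarios).
#' @param seed Master integer seed.
#' @param fs EEG sampling rate (default 128 Hz).
#' @param with_hypnodensity Generate hypnodensity matrices (default TRUE).
#' @return A list with \code{participants} (list of per-participant bundles:
#'   id, group, hypnogram, eeg, fs, hypnodensity, truth), \code{cohort}
#'   (data.frame: participant_id, group, age, sex), and \code{truth}
#'   (master seed and the specs).
#' @export
generate_cohort <- function(specs, seed, fs = 128, with_hypnodensity = TRUE) {
  if (length(specs) == 0L) stop("at least one group_spec is required")
  if (!all(vapply(specs, inherits, logical(1), "group_spec"))) {
    stop("specs must be group_spec objects")
  }
  participants <- list()
  rows <- list()
  pid <- 0L
  for (g in seq_along(specs)) {
    spec <- specs[[g]]
    for (p in seq_len(spec$n_participants)) {
      pid <- pid + 1L
      s_hyp <- derive_seed(seed, pid * 4L)
      s_eeg <- derive_seed(seed, pid * 4L + 1L)
      s_hd  <- derive_seed(seed, pid * 4L + 2L)
      s_dem <- derive_seed(seed, pid * 4L + 3L)
      n_epochs <- with_seed(s_dem, {
        sample(spec$n_epochs_range[1]:spec$n_epochs_range[2], 1L)
      })
      hyp <- generate_hypnogram(spec, n_epochs, s_hyp)
      eeg <- generate_eeg(hyp, spec, fs = fs, seed = s_eeg)
      hd <- if (with_hypnodensity) {
        generate_hypnodensity(hyp, spec$hypnodensity_concentration, s_hd)
      } else NULL
      demo <- with_seed(s_dem + 1L, {
        list(age = round(min(79, max(18, stats::rnorm(1, 33, 12)))),
             sex = sample(c("F", "M"), 1L))
      })
      id <- sprintf("%s_%03d", spec$label, p)
      participants[[pid]] <- list(
        id = id, group = spec$label, hypnogram = hyp,
        eeg = eeg$samples, fs = fs, hypnodensity = hd, truth = eeg$truth)
      rows[[pid]] <- data.frame(participant_id = id, group = spec$label,
                                age = demo$age, sex = demo$sex,
                                stringsAsFactors = FALSE)
    }
  }
  list(participants = participants,
       cohort = do.call(rbind, rows),
       truth = list(seed = seed, specs = specs))
}

#' Two-group example scenarios
#'
#' Ready-made pairs of \code{\link{group_spec}}s for validation studies.
#' \code{"null"} returns two identical groups (statistically exchangeable;
#' any classifier should land at chance). \code{"separated"} returns two
#' groups differing on the levers the feature modules measure: a more
#' fragmented transition kernel (more wake/N1, less stable N2/N3/REM),
#' roughly doubled gamma band power in N1/N2/REM, higher spindle density
#' with slower spindles, and a flatter (lower-concentration) hypnodensity.
#'
#' @param kind \code{"null"} or \code{"separated"}.
#' @param n_participants Participants per group (default 25).
#' @param n_epochs_range Night length range in epochs; the default
#'   240--320 keeps validation studies desk-sized (the clinical-scale
#'   default of \code{\link{group_spec}} is 700--1100).
#' @return List of two \code{\link{group_spec}}s labelled "A" and "B".
#' @export
example_group_specs <- function(kind = c("null", "separated"),
                                n_participants = 25L,
                                n_epochs_range = c(240L, 320L)) {
  kind <- match.arg(kind)
  a <- group_spec("A", n_participants = n_participants,
                  n_epochs_range = n_epochs_range)
  if (kind == "null") {
    b <- group_spec("B", n_participants = n_participants,
                    n_epochs_range = n_epochs_range)
    return(list(a, b))
  }
  tm <- matrix(c(
    0.60, 0.25, 0.12, 0.01, 0.02,
    0.12, 0.55, 0.25, 0.03, 0.05,
    0.05, 0.13, 0.70, 0.07, 0.05,
    0.02, 0.05, 0.18, 0.73, 0.02,
    0.04, 0.09, 0.06, 0.01, 0.80
  ), nrow = 5, byrow = TRUE,
  dimnames = list(stage_levels(), stage_levels()))
  prof <- default_spectral_profiles()
  prof["N1", ] <- c(0.25, 0.30, 0.15, 0.08, 0.12, 0.10)
  prof["N2", ] <- c(0.44, 0.20, 0.11, 0.05, 0.10, 0.10)
  prof["R", ]  <- c(0.30, 0.25, 0.12, 0.06, 0.14, 0.13)
  b <- group_spec("B", n_participants = n_participants,
                  n_epochs_range = n_epochs_range,
                  transition_matrix = tm,
                  spectral_profiles = prof,
                  spindle_density = 4,
                  spindle_frequency_hz = 12,
                  hypnodensity_concentration = 8)
  list(a, b)
}
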