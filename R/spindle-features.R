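# Sleep-spindle and slow-oscillation detection and the 10 whole-night
# spindle features, including spindle-SO coupling.

#' Detect sleep spindles in N2
#'
#' Wavelet detector: complex Morlet magnitude-squared power centered at
#' \code{center_hz} (bandwidth spanning roughly 11--16 Hz), smoothed with a
#' 0.1-s moving average. Thresholds are multiples of the N2 sigma-power
#' noise floor, estimated robustly as the median smoothed N2 power divided
#' by ln 2 (the median-to-mean factor of exponentially distributed
#' narrow-band noise power; unlike the raw mean it is not inflated by the
#' spindles themselves). Candidate samples exceed \code{core_mult} x the
#' floor, are extended to a flanking threshold of \code{flank_mult} x the
#' floor, merged when gaps are shorter than \code{merge_gap_s}, and kept
#' when 0.5--3.0 s long.
#' Events are confined to N2 intervals. Event amplitude (largest
#' peak-to-peak), frequency (zero-crossings / (2 x duration)) and peak time
#' (sigma-envelope maximum) come from the 11--16 Hz filtered trace;
#' per-event sigma-band isolation compares the event's sigma-power
#' enrichment over a local baseline against the mean enrichment of the
#' other five bands.
#'
#' @param eeg Numeric microvolt vector (recording-aligned).
#' @param fs Sampling rate in Hz.
#' @param n2_intervals Two-column matrix of [start, end) times in seconds
#'   of N2 stretches (e.g. from \code{\link{stage_intervals}}).
#' @param center_hz Wavelet center frequency (default 13.5).
#' @param cycles Morlet cycles (default 7; sets the sigma bandwidth).
#' @param core_mult,flank_mult Detection thresholds as multiples of the
#'   N2 noise-floor power estimate (defaults 4.5 and 2).
#' @param smooth_s Power-smoothing window in seconds (default 0.1).
#' @param merge_gap_s Merge events separated by less than this (default 0.5).
#' @param min_dur,max_dur Duration bounds in seconds (0.5, 3.0).
#' @return data.frame of events: \code{start}, \code{end}, \code{peak}
#'   (seconds), \code{duration}, \code{amplitude} (microvolts p-p),
#'   \code{frequency} (Hz), \code{sigma_isolation}.
#' @export
detect_spindles <- function(eeg, fs, n2_intervals, center_hz = 13.5,
                            cycles = 7, core_mult = 4.5, flank_mult = 2,
                            smooth_s = 0.1, merge_gap_s = 0.5,
                            min_dur = 0.5, max_dur = 3.0) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      peak = numeric(0), duration = numeric(0),
                      amplitude = numeric(0), frequency = numeric(0),
                      sigma_isolation = numeric(0))
  if (is.null(n2_intervals) || nrow(n2_intervals) == 0L) return(empty)
  n2_minutes <- sum(n2_intervals[, 2] - n2_intervals[, 1]) / 60
  if (n2_minutes < 5) return(empty)

  power <- morlet_power(eeg, fs, center_hz, cycles)
  power <- moving_average(power, round(smooth_s * fs))
  n2_mask <- intervals_to_mask(n2_intervals, fs, length(eeg))
  floor_est <- stats::median(power[n2_mask]) / log(2)
  if (!is.finite(floor_est) || floor_est <= 0) return(empty)

  sigma_an <- band_analytic(eeg, fs, 11, 16)
  sigma_trace <- Re(sigma_an)
  env <- Mod(sigma_an)

  events <- list()
  segs <- mask_to_runs(n2_mask)
  for (r in seq_len(nrow(segs))) {
    i0 <- segs[r, 1]; i1 <- segs[r, 2]
    p <- power[i0:i1]
    core <- p > core_mult * floor_est
    if (!any(core)) next
    flank <- p > flank_mult * floor_est
    cand <- extend_cores(core, flank)
    runs <- mask_to_runs(cand)
    if (nrow(runs) == 0L) next
    # merge runs separated by < merge_gap_s
    runs <- merge_runs(runs, round(merge_gap_s * fs))
    for (k in seq_len(nrow(runs))) {
      a <- i0 + runs[k, 1] - 1L
      b <- i0 + runs[k, 2] - 1L
      dur <- (b - a + 1L) / fs
      if (dur < min_dur || dur > max_dur) next
      seg <- sigma_trace[a:b]
      zc <- sum(diff(sign(seg)) != 0)
      peak_i <- a + which.max(env[a:b]) - 1L
      events[[length(events) + 1L]] <- data.frame(
        start = (a - 1L) / fs, end = b / fs,
        peak = (peak_i - 1L) / fs, duration = dur,
        amplitude = diff(range(seg)),
        frequency = zc / (2 * dur),
        sigma_isolation = NA_real_)
    }
  }
  if (length(events) == 0L) return(empty)
  out <- do.call(rbind, events)
  out$sigma_isolation <- vapply(seq_len(nrow(out)), function(i) {
    sigma_isolation(eeg, fs, out$start[i], out$end[i])
  }, numeric(1))
  out
}

# |Morlet CWT|^2 at one center frequency; the complex wavelet's Gaussian
# frequency response is applied directly in the Fourier domain (relative
# scale only -- thresholds are multiples of the in-stage noise floor)
morlet_power <- function(x, fs, f0, cycles) {
  sigma_t <- cycles / (2 * pi * f0)
  n <- length(x)
  nf <- smooth_length(n)
  X <- stats::fft(c(x, numeric(nf - n)))
  f <- (0:(nf - 1)) * fs / nf
  W <- exp(-2 * pi^2 * sigma_t^2 * (f - f0)^2)
  W[f > fs / 2] <- 0
  y <- stats::fft(X * W, inverse = TRUE)[seq_len(n)] / nf
  Mod(y)^2
}

# logical mask of length n from [start, end) second intervals
intervals_to_mask <- function(intervals, fs, n) {
  mask <- logical(n)
  for (r in seq_len(nrow(intervals))) {
    a <- max(1L, floor(intervals[r, 1] * fs) + 1L)
    b <- min(n, ceiling(intervals[r, 2] * fs))
    if (b >= a) mask[a:b] <- TRUE
  }
  mask
}

# runs of TRUE as a 2-column [start, end] (inclusive, 1-based) matrix
mask_to_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# keep flank runs that contain at least one core sample
extend_cores <- function(core, flank) {
  runs <- mask_to_runs(flank)
  out <- logical(length(flank))
  for (k in seq_len(nrow(runs))) {
    if (any(core[runs[k, 1]:runs[k, 2]])) out[runs[k, 1]:runs[k, 2]] <- TRUE
  }
  out
}

# merge [start, end] runs whose gap (samples) is < gap
merge_runs <- function(runs, gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1L, , drop = FALSE]
  for (k in 2:nrow(runs)) {
    if (runs[k, 1] - out[nrow(out), 2] - 1L < gap) {
      out[nrow(out), 2] <- runs[k, 2]
    } else {
      out <- rbind(out, runs[k, , drop = FALSE])
    }
  }
  out
}

# sigma-band enrichment of [start, end] over a local baseline, relative to
# the mean enrichment of the other five bands (periodogram-based)
sigma_isolation <- function(eeg, fs, start_s, end_s, pad_s = 3) {
  n <- length(eeg)
  a <- floor(start_s * fs) + 1L
  b <- min(n, ceiling(end_s * fs))
  base_idx <- c(max(1L, a - round(pad_s * fs)):(a - 1L),
                (b + 1L):min(n, b + round(pad_s * fs)))
  base_idx <- base_idx[base_idx >= 1L & base_idx <= n & !(base_idx %in% a:b)]
  if (length(base_idx) < fs) return(NA_real_)
  bp_ev <- segment_band_powers(eeg[a:b], fs)
  bp_ba <- segment_band_powers(eeg[base_idx], fs)
  ratio <- bp_ev / bp_ba
  sigma_i <- which(eeg_bands()$band == "sigma")
  as.numeric(ratio[sigma_i] / mean(ratio[-sigma_i]))
}

# raw periodogram band powers (density per band, not normalized)
segment_band_powers <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n
  freqs <- (0:(n - 1)) * fs / n
  bands <- eeg_bands()
  vapply(seq_len(nrow(bands)), function(b) {
    sel <- freqs >= bands$low[b] & freqs < bands$high[b]
    if (!any(sel)) return(NA_real_)
    mean(p[sel])
  }, numeric(1))
}

#' Stage occupancy intervals of a hypnogram
#'
#' Consecutive epochs of the given stage merged into [start, end) second
#' intervals, optionally restricted to the night window.
#'
#' @param hypnogram A \code{\link{hypnogram}}.
#' @param stage Stage code, or a vector of codes (e.g. all non-wake).
#' @param window Optional \code{\link{detect_night_window}} result.
#' @return Two-column matrix of [start, end) times in seconds.
#' @export
stage_intervals <- function(hypnogram, stage, window = NULL) {
  stages <- check_stages(unclass(hypnogram))
  es <- epoch_seconds(hypnogram)
  mask <- stages %in% stage
  if (!is.null(window)) {
    inwin <- logical(length(stages))
    inwin[window$onset:window$final] <- TRUE
    mask <- mask & inwin
  }
  runs <- mask_to_runs(mask)
  if (nrow(runs) == 0L) return(matrix(numeric(0), 0L, 2L))
  cbind((runs[, 1] - 1L) * es, runs[, 2] * es)
}

#' Detect slow oscillations
#'
#' Band-passes the signal to 0.3--1.5 Hz; candidate events are consecutive
#' negative-going zero-crossing pairs whose negative phase lasts 0.3--1.5 s;
#' events are kept when the negative peak is at or below \code{neg_peak_uv}
#' and the peak-to-peak amplitude (negative peak to the following positive
#' peak before the next down-crossing) is at least \code{p2p_uv}.
#'
#' @param eeg Numeric microvolt vector.
#' @param fs Sampling rate in Hz.
#' @param sleep_intervals Two-column [start, end) second matrix of the
#'   sleep stretches to search (default: whole signal).
#' @param neg_peak_uv Negative-peak criterion (default -40).
#' @param p2p_uv Peak-to-peak criterion (default 75).
#' @return data.frame of events: \code{start}, \code{end},
#'   \code{neg_peak_time}, \code{amplitude} (p-p microvolts).
#' @export
detect_slow_oscillations <- function(eeg, fs, sleep_intervals = NULL,
                                     neg_peak_uv = -40, p2p_uv = 75) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      neg_peak_time = numeric(0), amplitude = numeric(0))
  lf <- fft_bandpass(eeg, fs, 0.3, 1.5)
  if (is.null(sleep_intervals)) {
    sleep_intervals <- matrix(c(0, length(eeg) / fs), 1L)
  }
  if (nrow(sleep_intervals) == 0L) return(empty)
  events <- list()
  for (r in seq_len(nrow(sleep_intervals))) {
    a <- max(1L, floor(sleep_intervals[r, 1] * fs) + 1L)
    b <- min(length(eeg), ceiling(sleep_intervals[r, 2] * fs))
    seg <- lf[a:b]
    if (length(seg) < fs) next
    sgn <- sign(seg)
    down <- which(diff(sgn < 0) == 1)        # entering negative phase
    up <- which(diff(sgn < 0) == -1)         # leaving negative phase
    for (d in down) {
      u <- up[up > d][1]
      if (is.na(u)) next
      nd <- down[down > d][1]
      neg_dur <- (u - d) / fs
      if (neg_dur < 0.3 || neg_dur > 1.5) next
      neg_seg <- seg[(d + 1L):u]
      neg_peak <- min(neg_seg)
      if (neg_peak > neg_peak_uv) next
      pos_end <- if (is.na(nd)) length(seg) else nd
      pos_peak <- max(seg[u:pos_end])
      if (pos_peak - neg_peak < p2p_uv) next
      t0 <- (a - 1L) / fs
      events[[length(events) + 1L]] <- data.frame(
        start = t0 + d / fs,
        end = t0 + pos_end / fs,
        neg_peak_time = t0 + (d + which.min(neg_seg)) / fs,
        amplitude = pos_peak - neg_peak)
    }
  }
  if (length(events) == 0L) return(empty)
  do.call(rbind, events)
}

#' Whole-night spindle feature summary
#'
#' The 10 spindle features: count, density (per minute of N2), mean
#' frequency, mean amplitude, mean duration, spindle-SO coupling proportion
#' (fraction of spindles whose interval intersects any SO), coupling angle
#' (circular mean of the 0.3--1.5 Hz analytic-signal phase at the spindle
#' peak, over coupled spindles), coupling phase locking (resultant length
#' of those phases), dispersion (Fano factor, variance/mean of per-30-s-N2
#' epoch spindle counts) and mean sigma-band isolation.
#'
#' @param spindles data.frame from \code{\link{detect_spindles}}.
#' @param sos data.frame from \code{\link{detect_slow_oscillations}}.
#' @param eeg Numeric microvolt vector (for the SO-band phase).
#' @param fs Sampling rate in Hz.
#' @param n2_intervals Two-column [start, end) second matrix of N2 time.
#' @param epoch_s Epoch length for the dispersion counts (default 30).
#' @return Named numeric vector of length 10, names \code{spindle.*}.
#' @export
spindle_summary <- function(spindles, sos, eeg, fs, n2_intervals,
                            epoch_s = 30) {
  n2_minutes <- if (is.null(n2_intervals) || nrow(n2_intervals) == 0L) 0 else
    sum(n2_intervals[, 2] - n2_intervals[, 1]) / 60
  nm <- c("spindle.count", "spindle.density", "spindle.frequency",
          "spindle.amplitude", "spindle.duration",
          "spindle.so_coupling_prop", "spindle.so_coupling_angle",
          "spindle.so_phase_locking", "spindle.dispersion",
          "spindle.sigma_isolation")
  out <- stats::setNames(rep(NA_real_, 10L), nm)
  if (n2_minutes <= 0) return(out)
  n_sp <- nrow(spindles)
  out["spindle.count"] <- n_sp
  out["spindle.density"] <- n_sp / n2_minutes
  if (n_sp == 0L) {
    out["spindle.dispersion"] <- 0
    return(out)
  }
  out["spindle.frequency"] <- mean(spindles$frequency)
  out["spindle.amplitude"] <- mean(spindles$amplitude)
  out["spindle.duration"] <- mean(spindles$duration)
  out["spindle.sigma_isolation"] <- mean(spindles$sigma_isolation,
                                         na.rm = TRUE)

  # coupling: any temporal intersection with an SO
  coupled <- rep(FALSE, n_sp)
  if (nrow(sos) > 0L) {
    for (i in seq_len(n_sp)) {
      coupled[i] <- any(spindles$start[i] < sos$end &
                          spindles$end[i] > sos$start)
    }
  }
  out["spindle.so_coupling_prop"] <- mean(coupled)
  if (any(coupled)) {
    phase <- Arg(band_analytic(eeg, fs, 0.3, 1.5))
    idx <- pmin(length(phase),
                pmax(1L, round(spindles$peak[coupled] * fs) + 1L))
    theta <- phase[idx]
    out["spindle.so_coupling_angle"] <- circular_mean(theta)
    out["spindle.so_phase_locking"] <- resultant_length(theta)
  }

  # dispersion: Fano factor of per-epoch N2 spindle counts
  counts <- integer(0)
  for (r in seq_len(nrow(n2_intervals))) {
    edges <- seq(n2_intervals[r, 1], n2_intervals[r, 2], by = epoch_s)
    if (edges[length(edges)] < n2_intervals[r, 2]) {
      edges <- c(edges, n2_intervals[r, 2])
    }
    for (e in seq_len(length(edges) - 1L)) {
      counts <- c(counts, sum(spindles$peak >= edges[e] &
                                spindles$peak < edges[e + 1L]))
    }
  }
  out["spindle.dispersion"] <- if (length(counts) > 0L && mean(counts) > 0) {
    stats::var(counts) / mean(counts)
  } else 0
  out
}

#' Circular-statistics helpers for spindle-SO coupling
#'
#' \code{coupling_stats} returns the circular mean angle and the phase
#' locking value (resultant length) of a set of phase angles.
#'
#' @param theta Numeric vector of phases in radians.
#' @return List with \code{angle} (radians in (-pi, pi]) and \code{plv}
#'   in [0, 1].
#' @export
coupling_stats <- function(theta) {
  list(angle = circular_mean(theta), plv = resultant_length(theta))
}
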