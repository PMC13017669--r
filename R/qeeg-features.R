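# Artifact-screened multitaper band-power features: normalized average
# power in 6 bands x 5 stages x 4 quarters (120 features).

#' Artifact screening of one 2-s EEG window
#'
#' Classifies a window as \code{flat} (peak-to-peak below
#' \code{flat_uv}), \code{saturated} (any absolute sample at or above
#' \code{saturation_uv}), \code{high_slew} (any consecutive-sample jump
#' above \code{slew_uv}) or \code{clean}, with the checks applied in that
#' order. Thresholds are implementation defaults, exposed here.
#'
#' @param samples Numeric microvolt vector, exactly 2 s of samples.
#' @param fs Sampling rate in Hz.
#' @param flat_uv,saturation_uv,slew_uv Thresholds in microvolts.
#' @return One of \code{"flat"}, \code{"saturated"}, \code{"high_slew"},
#'   \code{"clean"}.
#' @export
screen_window <- function(samples, fs, flat_uv = 1, saturation_uv = 500,
                          slew_uv = 100) {
  if (length(samples) != round(2 * fs)) {
    stop("window must contain exactly 2 s of samples")
  }
  if (diff(range(samples)) < flat_uv) return("flat")
  if (any(abs(samples) >= saturation_uv)) return("saturated")
  if (any(abs(diff(samples)) > slew_uv)) return("high_slew")
  "clean"
}

# vectorized screening over a windows-in-rows matrix -> verdict per row
screen_windows_matrix <- function(W, flat_uv = 1, saturation_uv = 500,
                                  slew_uv = 100) {
  ptp <- apply(W, 1L, function(r) diff(range(r)))
  maxabs <- apply(abs(W), 1L, max)
  maxslew <- apply(abs(t(diff(t(W)))), 1L, max)
  verdict <- rep("clean", nrow(W))
  verdict[maxslew > slew_uv] <- "high_slew"
  verdict[maxabs >= saturation_uv] <- "saturated"
  verdict[ptp < flat_uv] <- "flat"
  verdict
}

#' Normalized multitaper band powers of one clean 2-s window
#'
#' Multitaper power spectral density (DPSS tapers, time-bandwidth
#' \code{nw}, \code{k} tapers, averaged across tapers); band power is the
#' PSD summed over the band's frequency bins (low edge inclusive, high edge
#' exclusive except the topmost band), normalized by total power over
#' 0.5--47 Hz so the six shares sum to 1.
#'
#' @param samples 2-s microvolt window.
#' @param fs Sampling rate in Hz.
#' @param scheme Band scheme data.frame as from \code{\link{eeg_bands}}.
#' @param nw Time-bandwidth product (default 2).
#' @param k Number of tapers (default 3).
#' @return Named numeric 6-vector of band-power shares summing to 1.
#' @export
multitaper_band_powers <- function(samples, fs, scheme = eeg_bands(),
                                   nw = 2, k = 3L) {
  if (stats::sd(samples) == 0) {
    stop("constant window has undefined normalized band power ",
         "(should have been screened as flat)")
  }
  psd <- multitaper_psd_matrix(matrix(samples, nrow = 1L), fs, nw, k)
  band_shares(psd, fs, length(samples), scheme)[1L, ]
}

# multitaper PSD for many windows at once: W is windows x n matrix;
# returns windows x n matrix of |fft|^2 averaged over tapers
multitaper_psd_matrix <- function(W, fs, nw = 2, k = 3L) {
  n <- ncol(W)
  tap <- dpss_tapers(n, nw, k)
  W <- W - rowMeans(W)
  acc <- matrix(0, nrow(W), n)
  for (j in seq_len(k)) {
    ft <- stats::mvfft(t(W) * tap[, j])
    acc <- acc + t(Mod(ft)^2)
  }
  acc / k
}

# integrate PSD rows over the band scheme and normalize to shares
band_shares <- function(psd, fs, n, scheme = eeg_bands()) {
  freqs <- (0:(n - 1)) * fs / n
  total_lo <- min(scheme$low)
  total_hi <- max(scheme$high)
  shares <- matrix(NA_real_, nrow(psd), nrow(scheme),
                   dimnames = list(NULL, scheme$band))
  bandpow <- sapply(seq_len(nrow(scheme)), function(b) {
    hi_inc <- b == nrow(scheme)   # topmost band includes its upper edge
    sel <- freqs >= scheme$low[b] &
      (if (hi_inc) freqs <= scheme$high[b] else freqs < scheme$high[b])
    rowSums(psd[, sel, drop = FALSE])
  })
  bandpow <- matrix(bandpow, nrow = nrow(psd))
  tot <- rowSums(bandpow)
  shares[] <- bandpow / tot
  shares
}

#' Quarter-night qEEG feature block
#'
#' Band-pass filters the recording to 0.5--47 Hz (zero-phase FIR), tiles
#' the night window into non-overlapping 2-s windows aligned to epoch
#' starts (15 per 30-s epoch), screens each window for artifacts, computes
#' normalized multitaper band powers for the clean ones, and averages them
#' per (band, stage, quarter). Cells with no clean window are missing.
#'
#' @param eeg Numeric microvolt vector, time-aligned to the hypnogram from
#'   recording start.
#' @param fs Sampling rate in Hz.
#' @param hypnogram A \code{\link{hypnogram}}.
#' @param window A \code{\link{detect_night_window}} result.
#' @param nw,k Multitaper parameters (see
#'   \code{\link{multitaper_band_powers}}).
#' @param prefiltered Set TRUE if \code{eeg} is already band-limited to
#'   0.5--47 Hz (skips the FIR stage).
#' @return Named numeric vector of length 120, names
#'   \code{qeeg.<band>.<stage>.Q<i>}.
#' @export
qeeg_feature_block <- function(eeg, fs, hypnogram, window, nw = 2, k = 3L,
                               prefiltered = FALSE) {
  stages <- check_stages(unclass(hypnogram))
  es <- window$epoch_seconds
  spe <- round(es * fs)
  if (length(eeg) < length(stages) * spe) {
    stop("EEG is shorter than the hypnogram span")
  }
  if (!prefiltered) eeg <- fir_bandpass(eeg, fs, 0.5, 47)
  wlen <- round(2 * fs)
  wins_per_epoch <- floor(spe / wlen)

  # enumerate 2-s windows inside the night window
  ep_idx <- window$onset:window$final
  quarter_of <- integer(length(stages))
  for (q in 1:4) {
    b <- window$quarter_bounds[q, ]
    quarter_of[b[1]:(b[2] - 1L)] <- q
  }
  ep_rep <- rep(ep_idx, each = wins_per_epoch)
  off_rep <- rep(seq_len(wins_per_epoch) - 1L, times = length(ep_idx))
  starts <- (ep_rep - 1L) * spe + off_rep * wlen + 1L
  W <- matrix(eeg[rep(starts, each = wlen) + rep(0:(wlen - 1L),
                                                 times = length(starts))],
              nrow = length(starts), byrow = TRUE)
  verdict <- screen_windows_matrix(W)
  clean <- verdict == "clean"
  stage_w <- stages[ep_rep]
  quarter_w <- quarter_of[ep_rep]

  shares <- matrix(NA_real_, length(starts), 6L)
  if (any(clean)) {
    psd <- multitaper_psd_matrix(W[clean, , drop = FALSE], fs, nw, k)
    shares[clean, ] <- band_shares(psd, fs, wlen)
  }

  bands <- eeg_bands()$band
  s <- stage_levels()
  out <- rep(NA_real_, 120L)
  nm <- character(120L)
  i <- 0L
  for (b in 1:6) for (st in s) for (q in 1:4) {
    i <- i + 1L
    nm[i] <- paste0("qeeg.", bands[b], ".", st, ".Q", q)
    sel <- clean & stage_w == st & quarter_w == q
    if (any(sel)) out[i] <- mean(shares[sel, b])
  }
  stats::setNames(out, nm)
}
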