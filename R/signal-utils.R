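# Signal-processing primitives shared by the qEEG and spindle modules.

# smallest 5-smooth (factors 2/3/5) length >= n: keeps the mixed-radix FFT
# fast without the near-doubling cost of power-of-two padding
smooth_length <- function(n) {
  min(stats::nextn(n, 2), stats::nextn(n, c(2, 3)), stats::nextn(n, c(2, 3, 5)))
}

# Zero-phase band-pass via linear-phase FIR (signal::fir1) applied by FFT
# convolution (power-of-two padded) with exact group-delay compensation.
# Used for the documented 0.5-47 Hz preconditioning of the raw EEG.
fir_bandpass <- function(x, fs, low, high, order = 512L) {
  ny <- fs / 2
  h <- signal::fir1(order, c(low, high) / ny, type = "pass")
  delay <- order / 2L
  n <- length(x)
  nf <- smooth_length(n + order)
  X <- stats::fft(c(x, numeric(nf - n)))
  H <- stats::fft(c(h, numeric(nf - length(h))))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nf
  y[(delay + 1L):(delay + n)]
}

# Ideal (brick-wall) zero-phase band filter in the frequency domain
# (power-of-two padded; the trailing pad is discarded). Used for internal
# narrow-band traces where exact band edges are wanted.
fft_bandpass <- function(x, fs, low, high) {
  Re(band_analytic(x, fs, low, high))
}

# Band-limited analytic signal in one pass: positive-frequency brick-wall
# mask times 2, inverse FFT. Re() is the zero-phase band-filtered trace,
# Mod() its envelope, Arg() its instantaneous phase.
band_analytic <- function(x, fs, low, high) {
  n <- length(x)
  nf <- smooth_length(n)
  X <- stats::fft(c(x, numeric(nf - n)))
  f <- (0:(nf - 1)) * fs / nf                # positive-frequency axis
  keep <- f >= low & f <= high & f <= fs / 2
  (stats::fft(X * (2 * keep), inverse = TRUE) / nf)[seq_len(n)]
}

# Analytic signal via the frequency-domain Hilbert construction; returns a
# complex vector whose Arg is the instantaneous phase.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# centered moving average with window w samples (odd enforced); edges fall
# back to the raw value
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  v <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  na <- is.na(v)
  v[na] <- x[na]
  v
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric tridiagonal
# eigenproblem. Returns an n x k matrix of unit-energy tapers, cached per
# (n, nw, k). Small n only (2-s analysis windows), so a dense eigen call is
# adequate.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3L) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- 0:(n - 1)
  diagonal <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diagonal
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix sign so symmetric tapers have positive mean
  for (j in seq_len(k)) {
    tapers[, j] <- tapers[, j] / sqrt(sum(tapers[, j]^2))
    if (sum(tapers[, j]) < 0 ||
        (abs(sum(tapers[, j])) < 1e-8 && tapers[2, j] < 0)) {
      tapers[, j] <- -tapers[, j]
    }
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

# simple wrap of circular mean / resultant length over phase angles
circular_mean <- function(theta) Arg(mean(exp(1i * theta)))
resultant_length <- function(theta) Mod(mean(exp(1i * theta)))
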