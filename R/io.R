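# File formats: hypnogram CSV, hypnodensity CSV, and a minimal
# single-channel EDF writer/reader (no EDF package exists in the R
# dependency stack, so the 16-bit EDF record layout is implemented here
# directly and round-trip tested).

#' Write / read a hypnogram CSV
#'
#' Two-column dialect: header \code{epoch,stage}, 0-based epoch index,
#' stage codes W/N1/N2/N3/R.
#'
#' @param h A \code{\link{hypnogram}}.
#' @param path File path.
#' @return \code{write_hypnogram_csv}: the path invisibly;
#'   \code{read_hypnogram_csv}: a \code{\link{hypnogram}}.
#' @export
write_hypnogram_csv <- function(h, path) {
  utils::write.csv(
    data.frame(epoch = seq_along(h) - 1L, stage = unclass(h)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch", "stage") %in% colnames(x))) {
    stop("hypnogram CSV must have columns epoch,stage: ", path)
  }
  hypnogram(x$stage[order(x$epoch)])
}

#' Write / read a hypnodensity CSV
#'
#' Five probability columns headed \code{W,N1,N2,N3,R}, one row per 30-s
#' epoch aligned to the hypnogram's epoch index.
#'
#' @param h Epochs x 5 probability matrix.
#' @param path File path.
#' @return \code{write_hypnodensity_csv}: the path invisibly;
#'   \code{read_hypnodensity_csv}: the validated matrix.
#' @export
write_hypnodensity_csv <- function(h, path) {
  h <- validate_hypnodensity(h)
  utils::write.csv(as.data.frame(h), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnodensity_csv
#' @export
read_hypnodensity_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(stage_levels() %in% colnames(x))) {
    stop("hypnodensity CSV must have columns W,N1,N2,N3,R: ", path)
  }
  validate_hypnodensity(as.matrix(x[, stage_levels()]))
}

# fixed-width ascii field for EDF headers
edf_field <- function(x, width) {
  s <- format(x, width = width)
  s <- substr(paste0(as.character(x), strrep(" ", width)), 1L, width)
  s
}

#' Write a single-channel EDF file
#'
#' Minimal EDF: one signal, 1-s data records, 16-bit little-endian
#' samples, physical range set from the data. The final partial record is
#' zero-padded; \code{\link{read_edf}} trims it back using the stored
#' sample count.
#'
#' @param samples Numeric microvolt vector.
#' @param fs Sampling rate in Hz (integer samples per 1-s record).
#' @param path File path.
#' @param label Channel label (default \code{"EEG C3"}).
#' @return The path, invisibly.
#' @export
write_edf <- function(samples, fs, path, label = "EEG C3") {
  fs <- as.integer(round(fs))
  n <- length(samples)
  n_rec <- ceiling(n / fs)
  phys_min <- floor(min(samples, -1))
  phys_max <- ceiling(max(samples, 1))
  dig_min <- -32768L
  dig_max <- 32767L
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  digital <- as.integer(round((samples - phys_min) * gain) + dig_min)
  digital <- pmin(dig_max, pmax(dig_min, digital))
  pad <- n_rec * fs - n
  if (pad > 0L) {
    zero_dig <- as.integer(round((0 - phys_min) * gain) + dig_min)
    digital <- c(digital, rep(zero_dig, pad))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) writeChar(edf_field(x, w), con, nchars = w,
                                  eos = NULL)
  put("0", 8)                                   # version
  put(sprintf("nsamples=%d", n), 80)            # patient id (carries n)
  put("somnphen synthetic", 80)                 # recording id
  put("01.01.26", 8); put("00.00.00", 8)        # start date/time
  put(as.character(256L + 256L), 8)             # header bytes
  put("", 44)                                   # reserved
  put(as.character(n_rec), 8)                   # number of records
  put("1", 8)                                   # record duration (s)
  put("1", 4)                                   # number of signals
  put(label, 16)
  put("synthetic EEG", 80)                      # transducer
  put("uV", 8)
  put(as.character(phys_min), 8)
  put(as.character(phys_max), 8)
  put(as.character(dig_min), 8)
  put(as.character(dig_max), 8)
  put("", 80)                                   # prefiltering
  put(as.character(fs), 8)                      # samples per record
  put("", 32)                                   # reserved
  writeBin(digital, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' Counterpart of \code{\link{write_edf}}; understands the general
#' single-signal EDF layout (any record duration whose sample count is
#' integral).
#'
#' @param path File path.
#' @return List: \code{samples} (microvolts), \code{fs}, \code{label}.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- get(8)
  patient <- get(80)
  get(80); get(8); get(8)
  header_bytes <- as.integer(get(8))
  get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  n_sig <- as.integer(get(4))
  if (n_sig != 1L) stop("only single-signal EDF supported: ", path)
  label <- get(16)
  get(80); get(8)
  phys_min <- as.numeric(get(8))
  phys_max <- as.numeric(get(8))
  dig_min <- as.numeric(get(8))
  dig_max <- as.numeric(get(8))
  get(80)
  spr <- as.integer(get(8))
  get(32)
  digital <- readBin(con, integer(), n = n_rec * spr, size = 2L,
                     signed = TRUE, endian = "little")
  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  samples <- (digital - dig_min) / gain + phys_min
  n_declared <- suppressWarnings(
    as.integer(sub("^nsamples=", "", patient)))
  if (!is.na(n_declared) && n_declared <= length(samples)) {
    samples <- samples[seq_len(n_declared)]
  }
  list(samples = samples, fs = spr / rec_dur, label = label)
}
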