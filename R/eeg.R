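# Sedation depth from frontal EEG: 2-s epoching, amplitude-based artifact
# rejection, Hann-tapered normalized power spectral density, and the 95%
# spectral edge frequency (SEF95).

#' Construct a multichannel frontal EEG record
#'
#' @param channels Numeric matrix, samples x channels, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param mer_window Optional `[start, end]` window (s) covering the MER
#'   period; defaults to the full record.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(channels, fs, mer_window = NULL) {
  channels <- as.matrix(channels)
  if (!is.numeric(fs) || fs <= 0) stop_config("'fs' must be positive")
  duration <- nrow(channels) / fs
  if (is.null(mer_window)) mer_window <- c(0, duration)
  if (length(mer_window) != 2L || mer_window[1] < 0 ||
      mer_window[2] > duration + 1e-9 || mer_window[1] >= mer_window[2]) {
    stop_config("mer_window must be [start, end] within the record duration")
  }
  structure(list(channels = channels, fs = fs, duration = duration,
                 mer_window = mer_window), class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record: %d channels, %.1f s @ %g Hz, MER window [%.1f, %.1f] s>\n",
              ncol(x$channels), x$duration, x$fs, x$mer_window[1], x$mer_window[2]))
  invisible(x)
}

#' Cut an EEG record into non-overlapping 2-s epochs
#'
#' A trailing partial window is dropped. Channels are stacked: the result has
#' one column per (epoch, channel) pair.
#'
#' @param record An `eeg_record`.
#' @param epoch_length Epoch length in seconds (default 2).
#' @param window Optional `[start, end]` restriction in seconds.
#' @return Numeric matrix, samples x (epochs * channels), with attributes
#'   `fs`, `n_epochs`, `n_channels`.
#' @export
epoch_eeg <- function(record, epoch_length = 2, window = NULL) {
  if (is.null(window)) window <- c(0, record$duration)
  if (window[1] < 0 || window[2] > record$duration + 1e-9) {
    stop_config("window outside the record")
  }
  i0 <- floor(window[1] * record$fs) + 1L
  i1 <- min(floor(window[2] * record$fs), nrow(record$channels))
  nsamp <- round(epoch_length * record$fs)
  n_epochs <- (i1 - i0 + 1L) %/% nsamp
  if (n_epochs < 1L) stop_insufficient("window shorter than one epoch")
  cols <- vector("list", n_epochs * ncol(record$channels))
  k <- 1L
  for (ch in seq_len(ncol(record$channels))) {
    for (e in seq_len(n_epochs)) {
      a <- i0 + (e - 1L) * nsamp
      cols[[k]] <- record$channels[a:(a + nsamp - 1L), ch]
      k <- k + 1L
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "fs") <- record$fs
  attr(out, "n_epochs") <- n_epochs
  attr(out, "n_channels") <- ncol(record$channels)
  out
}

#' Reject artifact-contaminated epochs
#'
#' An epoch column is rejected when any sample exceeds `amp_max` microvolts in
#' absolute value or its peak-to-peak range exceeds `ptp_max`.
#'
#' @param epochs Epoch matrix from [epoch_eeg()].
#' @param amp_max Absolute amplitude threshold in microvolts (default 100).
#' @param ptp_max Peak-to-peak threshold in microvolts (default 200).
#' @return List with `retained` (epoch matrix) and `rejected_count`.
#' @export
reject_artifacts <- function(epochs, amp_max = 100, ptp_max = 200) {
  if (is.null(dim(epochs)) || ncol(epochs) == 0L) {
    return(list(retained = epochs, rejected_count = 0L))
  }
  bad <- apply(epochs, 2L, function(x) {
    max(abs(x)) > amp_max || (max(x) - min(x)) > ptp_max
  })
  ret <- epochs[, !bad, drop = FALSE]
  attr(ret, "fs") <- attr(epochs, "fs")
  list(retained = ret, rejected_count = sum(bad))
}

#' Normalized power spectral density over the analysis band
#'
#' Per-epoch Hann-tapered periodogram, averaged across epochs and channels,
#' restricted to `(band[1], band[2]]` Hz, and scaled to unit total band power.
#'
#' @param epochs Epoch matrix from [epoch_eeg()] (carries `fs`), or a plain
#'   matrix plus `fs`.
#' @param fs Sampling rate; taken from the matrix attribute when absent.
#' @param band Analysis band in Hz (default `c(0.5, 30)`).
#' @param min_epochs Minimum epoch columns required (default 15).
#' @return Object of class `mer_psd`: list with `freq`, `power` (sums to 1),
#'   `band`, `n_epochs`.
#' @export
normalized_psd <- function(epochs, fs = NULL, band = c(0.5, 30),
                           min_epochs = 15L) {
  fs <- fs %||% attr(epochs, "fs")
  if (is.null(fs)) stop_config("sampling rate unknown")
  if (is.null(dim(epochs)) || ncol(epochs) < min_epochs) {
    stop_insufficient(sprintf("need at least %d retained epochs", min_epochs))
  }
  n <- nrow(epochs)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)  # Hann taper
  tapered <- epochs * w
  spec <- abs(stats::mvfft(tapered))^2
  keep <- seq_len(n %/% 2 + 1L)
  freq <- (keep - 1L) * fs / n
  pow <- rowMeans(spec[keep, , drop = FALSE])
  sel <- freq > band[1] & freq <= band[2]
  if (!any(sel)) stop_config("no frequency bins inside the analysis band")
  p <- pow[sel] / sum(pow[sel])
  structure(list(freq = freq[sel], power = p, band = band,
                 n_epochs = ncol(epochs)), class = "mer_psd")
}

#' @export
print.mer_psd <- function(x, ...) {
  cat(sprintf("<mer_psd: %d bins on (%.1f, %.1f] Hz, %d epochs>\n",
              length(x$freq), x$band[1], x$band[2], x$n_epochs))
  invisible(x)
}

#' Construct a PSD object directly from frequencies and powers
#'
#' Mostly useful for closed-form checks; powers are renormalized to sum to 1.
#'
#' @param freq Increasing frequency vector (Hz).
#' @param power Non-negative power per bin.
#' @param band Analysis band; defaults to `c(min(freq) - step, max(freq))`.
#' @return An object of class `mer_psd`.
#' @export
psd_from_values <- function(freq, power, band = NULL) {
  if (length(freq) != length(power)) stop_config("freq/power length mismatch")
  if (is.null(band)) {
    step <- if (length(freq) > 1L) freq[2] - freq[1] else 0
    band <- c(freq[1] - step, freq[length(freq)])
  }
  structure(list(freq = freq, power = power / sum(power), band = band,
                 n_epochs = NA_integer_), class = "mer_psd")
}

#' 95% spectral edge frequency
#'
#' The smallest frequency below which 95% of the band power is contained,
#' with linear interpolation of the cumulative power between bins; each bin's
#' power is treated as spread over the interval down to the previous bin
#' (anchored at the lower band edge). A single-bin PSD returns that bin's
#' frequency.
#'
#' @param psd An `mer_psd` object.
#' @param edge Cumulative-power fraction (default 0.95).
#' @return Frequency in Hz.
#' @export
sef95 <- function(psd, edge = 0.95) {
  stopifnot(inherits(psd, "mer_psd"))
  f <- psd$freq
  cum <- cumsum(psd$power) / sum(psd$power)
  if (length(f) == 1L) return(f)
  if (f[1] > psd$band[1]) {
    f <- c(psd$band[1], f)
    cum <- c(0, cum)
  }
  k <- which(cum >= edge)[1]
  if (k == 1L) return(f[1])
  f[k - 1L] + (edge - cum[k - 1L]) / (cum[k] - cum[k - 1L]) * (f[k] - f[k - 1L])
}

#' Sedation index for the MER window of an EEG record
#'
#' Runs the epoch -> artifact rejection -> normalized PSD -> SEF95 chain on
#' the record restricted to its MER window.
#'
#' @param record An `eeg_record`.
#' @param window Optional window override (`[start, end]` in seconds).
#' @param band Analysis band in Hz.
#' @param amp_max,ptp_max Artifact thresholds (microvolts).
#' @param min_epochs Minimum retained epochs for a stable SEF95 (default 15).
#' @param propofol_rate Carried through into the result.
#' @return Object of class `sedation_index`: `sef95`, `n_epochs_used`,
#'   `n_epochs_rejected`, `propofol_rate`.
#' @export
sedation_for_mer <- function(record, window = NULL, band = c(0.5, 30),
                             amp_max = 100, ptp_max = 200, min_epochs = 15L,
                             propofol_rate = NA_real_) {
  window <- window %||% record$mer_window
  ep <- epoch_eeg(record, window = window)
  rej <- reject_artifacts(ep, amp_max = amp_max, ptp_max = ptp_max)
  psd <- normalized_psd(rej$retained, band = band, min_epochs = min_epochs)
  structure(list(sef95 = sef95(psd),
                 n_epochs_used = ncol(rej$retained),
                 n_epochs_rejected = rej$rejected_count,
                 propofol_rate = propofol_rate),
            class = "sedation_index")
}

#' @export
print.sedation_index <- function(x, ...) {
  cat(sprintf("<sedation_index: SEF95 %.2f Hz (%d epochs used, %d rejected)>\n",
              x$sef95, x$n_epochs_used, x$n_epochs_rejected))
  invisible(x)
}

#' Read an EEG record from delimited text
#'
#' One column per channel; the header's first line carries the sampling rate
#' as written by [write_cohort()] (`# fs=<Hz>`).
#'
#' @param path CSV path.
#' @return An `eeg_record`.
#' @export
read_eeg <- function(path) {
  first <- readLines(path, n = 1L)
  fs <- as.numeric(sub("^#\\s*fs=", "", first))
  if (is.na(fs)) stop_config("missing '# fs=<Hz>' header line")
  dat <- utils::read.csv(path, comment.char = "#")
  eeg_record(as.matrix(dat), fs = fs)
}
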