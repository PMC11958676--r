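#' Welch spectral estimation settings
#'
#' Settings shared by all spectral estimators in the pipeline. Defaults:
#' 1-s Hann windows with 50% overlap inside each 2-s epoch (three averaging
#' segments), zero-padded to twice the window length so the frequency grid
#' has 0.5 Hz spacing and the 0.5 Hz delta band edge falls on a bin edge.
#'
#' @param window_sec segment length in seconds.
#' @param overlap fractional overlap between consecutive segments in [0, 1).
#' @param nfft_factor zero-padding factor; FFT length = `nfft_factor` times
#'   the window length in samples. 2 halves the bin spacing.
#' @param window taper: `"hann"` or `"rect"` (rectangular; with
#'   `window_sec` equal to the epoch length this gives the raw periodogram,
#'   exact for spectrally-shaped test signals).
#' @return list of class `psd_settings`.
#' @export
psd_settings <- function(window_sec = 1, overlap = 0.5, nfft_factor = 2,
                         window = c("hann", "rect")) {
  window <- match.arg(window)
  stopifnot(window_sec > 0, overlap >= 0, overlap < 1, nfft_factor >= 1)
  structure(list(window_sec = window_sec, overlap = overlap,
                 nfft_factor = as.integer(nfft_factor), window = window),
            class = "psd_settings")
}

# start indices of Welch segments covering n samples
welch_starts <- function(n, win_len, overlap) {
  step <- max(1L, as.integer(round(win_len * (1 - overlap))))
  starts <- seq.int(1L, n - win_len + 1L, by = step)
  starts
}

taper_vector <- function(win_len, window) {
  if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(win_len) / (win_len + 1))
  else rep(1, win_len)
}

# Segment-wise FFTs of many signals at once.
#
# x: samples x n_signals matrix. Returns list with:
#   fft: complex array [n_freq, n_signals, n_segments] (one-sided bins)
#   freqs, df, scale (density normalization 1/(fs*sum(w^2))), n_segments
# Shared backbone of PSD and coherence estimation.
welch_fft <- function(x, sampling_rate, settings = psd_settings()) {
  x <- as.matrix(x)
  n <- nrow(x)
  win_len <- as.integer(round(settings$window_sec * sampling_rate))
  if (n < win_len) {
    stop("signal (", n, " samples) is shorter than one Welch window (",
         win_len, " samples)")
  }
  starts <- welch_starts(n, win_len, settings$overlap)
  w <- taper_vector(win_len, settings$window)
  nfft <- win_len * settings$nfft_factor
  n_freq <- nfft %/% 2L + 1L
  n_sig <- ncol(x)
  out <- array(0i, dim = c(n_freq, n_sig, length(starts)))
  # demean per segment, taper, zero-pad, FFT all signals in one mvfft call
  pad <- matrix(0, nfft - win_len, n_sig)
  for (s in seq_along(starts)) {
    seg <- x[starts[s] + seq_len(win_len) - 1L, , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg), "-") * w
    X <- stats::mvfft(rbind(seg, pad))
    out[, , s] <- X[seq_len(n_freq), , drop = FALSE]
  }
  freqs <- (seq_len(n_freq) - 1L) * sampling_rate / nfft
  list(fft = out, freqs = freqs, df = sampling_rate / nfft,
       scale = 1 / (sampling_rate * sum(w^2)),
       n_segments = length(starts), nfft = nfft)
}

# Welch power spectral density of many signals at once.
# x: samples x n_signals. Returns list(freqs, power [n_signals x n_freq]).
welch_psd <- function(x, sampling_rate, settings = psd_settings()) {
  wf <- welch_fft(x, sampling_rate, settings)
  p <- rowMeans(Mod(wf$fft)^2, dims = 2) * wf$scale
  # one-sided doubling, except DC and (if nfft even) Nyquist
  dbl <- rep(2, length(wf$freqs))
  dbl[1] <- 1
  if (wf$nfft %% 2L == 0L) dbl[length(dbl)] <- 1
  p <- p * dbl
  list(freqs = wf$freqs, power = t(p))
}

#' Welch power spectral density of one epoch
#'
#' Averaged-periodogram PSD per channel with Hann taper and overlapping
#' segments, normalized as a one-sided density (µV²/Hz) so that the PSD
#' integrated over frequency approximates the signal variance.
#'
#' @param epoch_data numeric matrix, channels x samples, one epoch.
#' @param sampling_rate sampling rate in Hz.
#' @param settings a [psd_settings()] object.
#' @return object of class `psd`: list with `freqs` (Hz, length F) and
#'   `power` (channels x F matrix, non-negative).
#' @examples
#' x <- matrix(rnorm(2 * 500), nrow = 2) # 2 channels, 2 s at 250 Hz
#' p <- compute_psd(x, 250)
#' sum(p$power[1, ]) * diff(p$freqs[1:2]) # ~ var of channel 1
#' @export
compute_psd <- function(epoch_data, sampling_rate,
                        settings = psd_settings()) {
  epoch_data <- as.matrix(epoch_data)
  res <- welch_psd(t(epoch_data), sampling_rate, settings)
  structure(list(freqs = res$freqs, power = res$power,
                 sampling_rate = sampling_rate),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat("Welch PSD: ", nrow(x$power), " channels, ",
      length(x$freqs), " bins (", min(x$freqs), "-", max(x$freqs),
      " Hz, df = ", signif(diff(x$freqs[1:2]), 3), " Hz)\n", sep = "")
  invisible(x)
}

# PSD for a whole epochs x channels x samples array, vectorized:
# returns array [epochs, channels, n_freq] plus freqs.
epochs_psd <- function(data, sampling_rate, settings = psd_settings()) {
  d <- dim(data)
  stopifnot(length(d) == 3)
  n_ep <- d[1]; n_ch <- d[2]; n_s <- d[3]
  # samples x (epochs*channels): signals vary fastest by epoch then channel
  flat <- matrix(aperm(data, c(3, 1, 2)), nrow = n_s)
  res <- welch_psd(flat, sampling_rate, settings)
  pw <- array(res$power, dim = c(n_ep, n_ch, length(res$freqs)))
  list(freqs = res$freqs, power = pw)
}
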