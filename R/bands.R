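#' Canonical EEG frequency band scheme
#'
#' A band scheme is an ordered table of named frequency bands with lower and
#' upper edges in Hz. The default is the canonical five-band M/EEG scheme
#' used throughout the pipeline: delta 0.5-4.5, theta 4.5-8.5, alpha
#' 8.5-13.5, beta 15-30 and gamma 30-80 Hz. Note the deliberate 13.5-15 Hz
#' gap between alpha and beta; band membership of a frequency bin is
#' half-open, `f_lo <= f < f_hi`, so adjacent band edges partition cleanly.
#'
#' @param bands named list of numeric length-2 vectors `c(f_lo, f_hi)` in Hz.
#' @return object of class `band_scheme`: a data.frame with columns `band`,
#'   `f_lo`, `f_hi`.
#' @examples
#' band_scheme()
#' band_scheme(list(slow = c(1, 8), fast = c(8, 40)))
#' @export
band_scheme <- function(bands = list(
                          delta = c(0.5, 4.5),
                          theta = c(4.5, 8.5),
                          alpha = c(8.5, 13.5),
                          beta  = c(15, 30),
                          gamma = c(30, 80))) {
  stopifnot(length(bands) >= 1, !is.null(names(bands)))
  lo <- vapply(bands, `[`, numeric(1), 1L)
  hi <- vapply(bands, `[`, numeric(1), 2L)
  if (any(lo >= hi)) {
    stop("each band must have f_lo < f_hi")
  }
  scheme <- data.frame(band = names(bands), f_lo = unname(lo),
                       f_hi = unname(hi), stringsAsFactors = FALSE)
  class(scheme) <- c("band_scheme", "data.frame")
  scheme
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("EEG band scheme (", nrow(x), " bands, half-open bins [f_lo, f_hi)):\n",
      sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# highest band edge, used to validate sampling rates
max_band_edge <- function(scheme) max(scheme$f_hi)

# logical index of PSD bins belonging to a band (half-open)
band_bins <- function(freqs, f_lo, f_hi) freqs >= f_lo & freqs < f_hi
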