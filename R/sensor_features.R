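#' Band-averaged spectral power
#'
#' Mean PSD over the bins of each band, with half-open bin membership
#' `f_lo <= f < f_hi`.
#'
#' @param psd a [compute_psd()] result.
#' @param scheme a [band_scheme()].
#' @return channels x bands numeric matrix (columns named by band).
#' @export
band_power <- function(psd, scheme = band_scheme()) {
  stopifnot(inherits(psd, "psd"))
  out <- matrix(NA_real_, nrow(psd$power), nrow(scheme),
                dimnames = list(NULL, scheme$band))
  for (i in seq_len(nrow(scheme))) {
    bb <- band_bins(psd$freqs, scheme$f_lo[i], scheme$f_hi[i])
    if (!any(bb)) {
      stop("band ", scheme$band[i], " [", scheme$f_lo[i], ", ",
           scheme$f_hi[i], ") contains no PSD bins")
    }
    out[, i] <- rowMeans(psd$power[, bb, drop = FALSE])
  }
  out
}

# entropy (bits) of each row of a non-negative matrix, rows normalized to 1;
# all-zero rows give 0
entropy_bits <- function(p) {
  s <- rowSums(p)
  ok <- s > 0
  h <- numeric(nrow(p))
  if (any(ok)) {
    q <- p[ok, , drop = FALSE] / s[ok]
    ql <- q * log2(q)
    ql[q == 0] <- 0
    h[ok] <- -rowSums(ql)
  }
  h
}

#' Band-limited spectral Shannon entropy
#'
#' Shannon entropy (base 2) of the PSD bins within each band, after
#' normalizing the band's bins to sum to one. Low entropy means the band's
#' power is concentrated in few bins (peaked, oscillatory); high entropy
#' means a flat, noise-like band spectrum. With `normalize = TRUE` the
#' entropy is divided by `log2(n_bins)` so values lie in `[0, 1]`.
#'
#' A band with all-zero power is degenerate; its entropy is defined as 0
#' and a warning is raised.
#'
#' @inheritParams band_power
#' @param normalize divide by the per-band maximum entropy `log2(n_bins)`.
#' @return channels x bands numeric matrix.
#' @export
spectral_entropy <- function(psd, scheme = band_scheme(), normalize = TRUE) {
  stopifnot(inherits(psd, "psd"))
  out <- matrix(NA_real_, nrow(psd$power), nrow(scheme),
                dimnames = list(NULL, scheme$band))
  for (i in seq_len(nrow(scheme))) {
    bb <- band_bins(psd$freqs, scheme$f_lo[i], scheme$f_hi[i])
    if (sum(bb) < 2) {
      stop("band ", scheme$band[i], " has fewer than 2 PSD bins; ",
           "entropy is undefined")
    }
    p <- psd$power[, bb, drop = FALSE]
    if (any(rowSums(p) == 0)) {
      warning("all-zero ", scheme$band[i], " band in ",
              sum(rowSums(p) == 0), " channel(s); entropy set to 0")
    }
    h <- entropy_bits(p)
    if (normalize) h <- h / log2(sum(bb))
    out[, i] <- h
  }
  out
}

#' Aperiodic (1/f) fit settings
#'
#' @param fit_range frequency range (Hz) used for the log-log fit.
#' @param exclude_range frequency range excluded from the fit (line-noise
#'   guard); `NULL` for none.
#' @param k positive-residual threshold, in residual standard deviations,
#'   above which bins are treated as oscillatory peaks and excluded.
#' @param max_iter maximum peak-exclusion refit iterations.
#' @param min_bins minimum bins that must remain in the fit.
#' @return list of class `aperiodic_settings`.
#' @export
aperiodic_settings <- function(fit_range = c(0.5, 80),
                               exclude_range = c(45, 55),
                               k = 2.5, max_iter = 5L, min_bins = 10L) {
  stopifnot(fit_range[1] < fit_range[2], k > 0, max_iter >= 0)
  structure(list(fit_range = fit_range, exclude_range = exclude_range,
                 k = k, max_iter = as.integer(max_iter),
                 min_bins = as.integer(min_bins)),
            class = "aperiodic_settings")
}

# Vectorized iterative log-log power-law fit over many spectra.
# power: n_spectra x n_freq; returns data.frame(offset, slope, r_squared,
# n_excluded, converged). Model: log10 P = offset - slope * log10 f,
# ordinary least squares with iterative exclusion of positive outlier bins.
aperiodic_fit_matrix <- function(power, freqs,
                                 settings = aperiodic_settings(),
                                 on_nonpositive = c("error", "na")) {
  on_nonpositive <- match.arg(on_nonpositive)
  sel <- freqs >= settings$fit_range[1] & freqs <= settings$fit_range[2] &
    freqs > 0
  if (!is.null(settings$exclude_range)) {
    sel <- sel & !(freqs >= settings$exclude_range[1] &
                   freqs <= settings$exclude_range[2])
  }
  if (sum(sel) < settings$min_bins) {
    stop("fewer than ", settings$min_bins, " PSD bins in the aperiodic ",
         "fit range")
  }
  P <- power[, sel, drop = FALSE]
  bad_rows <- apply(P <= 0, 1L, any)
  if (any(bad_rows)) {
    if (on_nonpositive == "error") {
      stop("non-positive power inside the aperiodic fit range; cannot ",
           "take logarithms")
    }
    out <- data.frame(offset = rep(NA_real_, nrow(P)), slope = NA_real_,
                      r_squared = NA_real_, n_excluded = NA_integer_,
                      converged = FALSE)
    if (any(!bad_rows)) {
      out[!bad_rows, ] <- aperiodic_fit_matrix(
        power[!bad_rows, , drop = FALSE], freqs, settings)
    }
    return(out)
  }
  x <- log10(freqs[sel])
  Y <- log10(P)
  n_spec <- nrow(Y)
  nb <- length(x)

  fit_once <- function(W) {
    sw <- rowSums(W)
    sx <- as.vector(W %*% x)
    sx2 <- as.vector(W %*% x^2)
    sy <- rowSums(W * Y)
    sxy <- as.vector((W * Y) %*% x)
    den <- sw * sx2 - sx^2
    b <- (sw * sxy - sx * sy) / den
    a <- (sy - b * sx) / sw
    list(a = a, b = b)
  }

  W <- matrix(1, n_spec, nb)
  f0 <- fit_once(W)
  a <- f0$a; b <- f0$b
  converged <- rep(TRUE, n_spec)
  for (it in seq_len(settings$max_iter)) {
    R <- Y - (a + outer(b, x))
    sig <- sqrt(rowSums(W * R^2) / pmax(rowSums(W), 1))
    newW <- W * (R <= settings$k * pmax(sig, .Machine$double.eps)) * 1
    # never drop below min_bins: rows that would, keep their previous mask
    # and are flagged as not converged (plain fit retained)
    short <- rowSums(newW) < settings$min_bins
    if (any(short)) {
      newW[short, ] <- 1
      converged[short] <- FALSE
    }
    if (identical(newW, W)) break
    W <- newW
    f <- fit_once(W)
    a <- f$a; b <- f$b
  }
  R <- Y - (a + outer(b, x))
  ssr <- rowSums(W * R^2)
  ym <- rowSums(W * Y) / rowSums(W)
  sst <- rowSums(W * (Y - ym)^2)
  r2 <- ifelse(sst > 0, 1 - ssr / sst, 1)
  data.frame(offset = a, slope = -b,
             r_squared = pmin(pmax(r2, 0), 1),
             n_excluded = nb - rowSums(W),
             converged = converged)
}

#' Fit the aperiodic (1/f) background of a power spectrum
#'
#' Fits `log10 P(f) = offset - slope * log10 f` by least squares over the
#' configured fit range, iteratively excluding bins whose positive residual
#' exceeds `k` residual standard deviations (oscillatory peaks ride on top
#' of the background, so only positive outliers are removed), up to
#' `max_iter` refits. If exclusion would leave fewer than `min_bins` bins
#' the plain no-exclusion fit is returned with `converged = FALSE`.
#'
#' @inheritParams band_power
#' @param settings an [aperiodic_settings()] object.
#' @return data.frame with one row per channel: `offset` (log10 µV²/Hz
#'   intercept), `slope` (power-law exponent; positive = decaying),
#'   `r_squared`, `n_excluded`, `converged`.
#' @examples
#' f <- seq(0.5, 100, by = 0.5)
#' psd <- structure(list(freqs = f, power = rbind(10^2 * f^-1.5)),
#'                  class = "psd")
#' fit_aperiodic(psd) # offset 2, slope 1.5
#' @export
fit_aperiodic <- function(psd, settings = aperiodic_settings()) {
  stopifnot(inherits(psd, "psd"))
  aperiodic_fit_matrix(psd$power, psd$freqs, settings)
}

#' Assemble the sensor-space feature matrix
#'
#' Computes, per epoch and channel, the three sensor feature families:
#' band power (one column per band and channel), band spectral Shannon
#' entropy (same layout) and the aperiodic offset and slope (one column
#' each per channel). For a 62-channel montage and five bands this yields
#' the canonical 310 + 310 + 124 = 744 columns. Column order is
#' deterministic: the band-power block (bands outer, channels inner), the
#' entropy block, then all offsets, then all slopes.
#'
#' Epochs whose features contain non-finite values are excluded and logged
#' (their row metadata is kept in the `"dropped_rows"` attribute).
#'
#' @param epochs an `epoch_set` (see [project_to_sensors()]).
#' @param scheme a [band_scheme()].
#' @param psd a [psd_settings()] object.
#' @param aperiodic an [aperiodic_settings()] object.
#' @param entropy_normalize normalize entropies to `[0, 1]`.
#' @return a [feature_matrix()] with families `band_power`, `entropy`,
#'   `aperiodic_offset`, `aperiodic_slope`.
#' @export
assemble_sensor_features <- function(epochs, scheme = band_scheme(),
                                     psd = psd_settings(),
                                     aperiodic = aperiodic_settings(),
                                     entropy_normalize = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]
  ch <- epochs$channel_names
  ep <- epochs_psd(epochs$data, epochs$sampling_rate, psd)
  n_bands <- nrow(scheme)

  pow <- matrix(NA_real_, n_ep, n_ch * n_bands)
  ent <- matrix(NA_real_, n_ep, n_ch * n_bands)
  for (i in seq_len(n_bands)) {
    bb <- band_bins(ep$freqs, scheme$f_lo[i], scheme$f_hi[i])
    if (!any(bb)) stop("band ", scheme$band[i], " contains no PSD bins")
    block <- (i - 1) * n_ch + seq_len(n_ch)
    pslice <- ep$power[, , bb, drop = FALSE]
    pow[, block] <- rowMeans(pslice, dims = 2)
    flat <- matrix(pslice, n_ep * n_ch, sum(bb))
    h <- entropy_bits(flat)
    if (entropy_normalize) h <- h / log2(sum(bb))
    ent[, block] <- matrix(h, n_ep, n_ch)
  }

  spec_flat <- matrix(ep$power, n_ep * n_ch, length(ep$freqs))
  ap <- aperiodic_fit_matrix(spec_flat, ep$freqs, aperiodic,
                             on_nonpositive = "na")
  off <- matrix(ap$offset, n_ep, n_ch)
  slo <- matrix(ap$slope, n_ep, n_ch)

  band_rep <- rep(scheme$band, each = n_ch)
  ch_rep <- rep(ch, times = n_bands)
  meta <- rbind(
    data.frame(feature = paste0("pow_", band_rep, "_", ch_rep),
               family = "band_power", band = band_rep, unit = ch_rep,
               hemisphere = channel_hemisphere(ch_rep)),
    data.frame(feature = paste0("ent_", band_rep, "_", ch_rep),
               family = "entropy", band = band_rep, unit = ch_rep,
               hemisphere = channel_hemisphere(ch_rep)),
    data.frame(feature = paste0("apoff_", ch),
               family = "aperiodic_offset", band = NA_character_, unit = ch,
               hemisphere = channel_hemisphere(ch)),
    data.frame(feature = paste0("apslope_", ch),
               family = "aperiodic_slope", band = NA_character_, unit = ch,
               hemisphere = channel_hemisphere(ch)))
  rows <- data.frame(subject_id = epochs$subject_id,
                     epoch = seq_len(n_ep),
                     group = if (!is.null(epochs$group)) epochs$group
                             else NA_character_,
                     stringsAsFactors = FALSE)
  fm <- feature_matrix(cbind(pow, ent, off, slo), meta, rows)
  drop_bad_rows(fm)
}
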