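#' Magnitude coherence spectrum of two signals
#'
#' Welch-averaged magnitude coherence
#' `Coh(f) = |<Sxy(f)>| / sqrt(<Sxx(f)> <Syy(f)>)`, with `<.>` the average
#' over overlapping tapered segments within the epoch. At least three
#' averaging segments are required: with a single segment the estimator is
#' degenerate at 1 for any pair of signals.
#'
#' @param x,y equal-length numeric signals.
#' @param sampling_rate sampling rate in Hz.
#' @param settings a [psd_settings()] object (windowing shared with the PSD
#'   estimator).
#' @param pair optional pair label stored in the result.
#' @return object of class `coherence_spectrum`: list with `freqs`, `coh`
#'   (values in `[0, 1]`) and `pair`. Symmetric in the order of `x` and `y`.
#' @export
coherence <- function(x, y, sampling_rate, settings = psd_settings(),
                      pair = c("x", "y")) {
  if (length(x) != length(y)) stop("signals must have equal length")
  wf <- welch_fft(cbind(x, y), sampling_rate, settings)
  if (wf$n_segments < 3) {
    stop("coherence needs at least 3 averaging segments, got ",
         wf$n_segments, "; use shorter windows or longer signals")
  }
  X <- wf$fft[, 1, ]
  Y <- wf$fft[, 2, ]
  sxx <- rowMeans(Mod(X)^2)
  syy <- rowMeans(Mod(Y)^2)
  sxy <- rowMeans(X * Conj(Y))
  coh <- Mod(sxy) / sqrt(pmax(sxx * syy, .Machine$double.xmin))
  coh[sxx == 0 | syy == 0] <- 0
  structure(list(freqs = wf$freqs, coh = pmin(coh, 1), pair = pair),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat("Coherence spectrum ", x$pair[1], " ~ ", x$pair[2], ": ",
      length(x$freqs), " bins, mean ", signif(mean(x$coh), 3), "\n", sep = "")
  invisible(x)
}

#' Default within-auditory-network label pairs
#'
#' Named label pairs whose band coherence is extracted as individual
#' features: the interhemispheric primary auditory (transverse temporal),
#' secondary auditory (superior temporal) and superior parietal homologue
#' pairs, plus the crossed left superior parietal / right superior temporal
#' pair.
#'
#' @return list of length-2 character vectors.
#' @export
default_aun_pairs <- function() {
  list(c("lh_transversetemporal", "rh_transversetemporal"),
       c("lh_superiortemporal", "rh_superiortemporal"),
       c("lh_superiorparietal", "rh_superiorparietal"),
       c("lh_superiorparietal", "rh_superiortemporal"))
}

# member label indices per network: primary assignments plus the AUN overlay
network_members <- function(map, labels) {
  nets <- sort(unique(map$network))
  members <- lapply(nets, function(n) which(map$network == n))
  names(members) <- nets
  if (any(map$aun) && !"AUN" %in% nets) {
    members$AUN <- which(map$aun)
  }
  empty <- names(members)[vapply(members, length, 1L) == 0]
  if (length(empty)) {
    stop("network(s) with no member labels: ", paste(empty, collapse = ", "))
  }
  members
}

#' Network-aggregated band coherence features
#'
#' Per epoch: (i) for every unordered pair of networks (within-network
#' pairs included) and every requested band, the mean band coherence over
#' all label pairs spanning the two networks; (ii) the band coherence of
#' each named label pair in `pair_spec`. Band coherence is the mean of the
#' per-bin magnitude coherence over the band's bins, estimated per epoch by
#' Welch segment averaging (a deliberately high-variance per-epoch
#' estimator, matching the epoch-level classification design; see
#' `average = "subject"` for the pooled alternative).
#'
#' Within-network aggregates for single-label networks have no label pairs
#' and are omitted. Column order is deterministic: network pairs in
#' alphabetical order, then named pairs, bands outer.
#'
#' @param lts a `label_time_series`.
#' @param map a `network_map` covering all labels in `lts` (see
#'   [read_network_map()]).
#' @param bands band names to use (default alpha and gamma).
#' @param pair_spec list of length-2 character vectors of label names;
#'   `NULL` selects [default_aun_pairs()] when the labels cover them,
#'   otherwise no named pairs.
#' @param scheme a [band_scheme()].
#' @param settings a [psd_settings()] object.
#' @param average `"epoch"` (one feature row per epoch) or `"subject"`
#'   (cross-spectra pooled over all epochs' segments; one row).
#' @return a [feature_matrix()] with family `coherence`.
#' @export
network_coherence <- function(lts, map, bands = c("alpha", "gamma"),
                              pair_spec = NULL, scheme = band_scheme(),
                              settings = psd_settings(),
                              average = c("epoch", "subject")) {
  average <- match.arg(average)
  labs <- lts$label_names
  missing <- setdiff(labs, map$label)
  if (length(missing)) {
    stop("network map does not cover labels: ",
         paste(missing, collapse = ", "))
  }
  map <- map[match(labs, map$label), ]
  stopifnot(all(bands %in% scheme$band))
  if (is.null(pair_spec)) {
    pair_spec <- Filter(function(p) all(p %in% labs), default_aun_pairs())
  }
  for (p in pair_spec) {
    if (!all(p %in% labs)) stop("pair_spec references unknown labels: ",
                                paste(setdiff(p, labs), collapse = ", "))
  }
  members <- network_members(map, labs)
  nets <- names(members)
  # unordered network pairs incl. within, alphabetical, within first
  net_pairs <- list()
  for (i in seq_along(nets)) {
    for (j in i:length(nets)) {
      a <- members[[i]]; b <- members[[j]]
      if (i == j && length(a) < 2) next # no label pairs within
      net_pairs[[length(net_pairs) + 1]] <-
        list(name = paste0(nets[i], "-", nets[j]), a = a, b = b,
             within = i == j)
    }
  }
  d <- dim(lts$data)
  n_ep <- d[1]; L <- d[2]
  band_idx <- lapply(bands, function(b) {
    i <- match(b, scheme$band)
    c(scheme$f_lo[i], scheme$f_hi[i])
  })

  # per-epoch (or pooled) band coherence matrices
  epoch_band_coh <- function(fft_arr, freqs, bins_list) {
    lapply(bins_list, function(bb) {
      idx <- which(bb)
      acc <- matrix(0, L, L)
      for (f in idx) {
        M <- fft_arr[f, , , drop = TRUE]
        if (is.null(dim(M))) M <- matrix(M, nrow = L)
        S <- M %*% Conj(t(M))
        dg <- Re(diag(S))
        acc <- acc + Mod(S) / sqrt(pmax(outer(dg, dg), .Machine$double.xmin))
      }
      acc / length(idx)
    })
  }

  first <- welch_fft(t(lts$data[1, , , drop = TRUE]), lts$sampling_rate,
                     settings)
  if (first$n_segments < 3) {
    stop("coherence needs at least 3 averaging segments per epoch")
  }
  bins_list <- lapply(band_idx, function(e) band_bins(first$freqs, e[1], e[2]))
  for (bb in bins_list) {
    if (!any(bb)) stop("a requested band contains no frequency bins")
  }

  extract_row <- function(cohs) {
    vals <- numeric(0)
    for (k in seq_along(bands)) {
      C <- cohs[[k]]
      for (np in net_pairs) {
        if (np$within) {
          pairs_idx <- utils::combn(np$a, 2)
          v <- mean(C[t(pairs_idx)])
        } else {
          grid <- expand.grid(a = np$a, b = np$b)
          grid <- grid[grid$a != grid$b, ]
          v <- mean(C[as.matrix(grid)])
        }
        vals <- c(vals, v)
      }
      for (p in pair_spec) {
        vals <- c(vals, C[match(p[1], labs), match(p[2], labs)])
      }
    }
    vals
  }

  n_net_cols <- length(net_pairs)
  n_pair_cols <- length(pair_spec)
  n_cols <- length(bands) * (n_net_cols + n_pair_cols)

  if (average == "subject") {
    # pool cross-spectra across all epochs' segments before normalizing
    accS <- vector("list", length(bands))
    idx_list <- lapply(bins_list, which)
    for (k in seq_along(bands)) {
      accS[[k]] <- array(0i, dim = c(L, L, length(idx_list[[k]])))
    }
    for (e in seq_len(n_ep)) {
      wf <- if (e == 1) first else
        welch_fft(t(lts$data[e, , , drop = TRUE]), lts$sampling_rate,
                  settings)
      for (k in seq_along(bands)) {
        for (fi in seq_along(idx_list[[k]])) {
          M <- wf$fft[idx_list[[k]][fi], , , drop = TRUE]
          if (is.null(dim(M))) M <- matrix(M, nrow = L)
          accS[[k]][, , fi] <- accS[[k]][, , fi] + M %*% Conj(t(M))
        }
      }
    }
    cohs <- lapply(accS, function(Sarr) {
      acc <- matrix(0, L, L)
      for (fi in seq_len(dim(Sarr)[3])) {
        S <- Sarr[, , fi]
        dg <- Re(diag(S))
        acc <- acc + Mod(S) / sqrt(pmax(outer(dg, dg), .Machine$double.xmin))
      }
      acc / dim(Sarr)[3]
    })
    values <- matrix(extract_row(cohs), nrow = 1)
    rows <- data.frame(subject_id = lts$subject_id, epoch = NA_integer_,
                       group = if (!is.null(lts$group)) lts$group
                               else NA_character_)
  } else {
    values <- matrix(NA_real_, n_ep, n_cols)
    for (e in seq_len(n_ep)) {
      wf <- if (e == 1) first else
        welch_fft(t(lts$data[e, , , drop = TRUE]), lts$sampling_rate,
                  settings)
      values[e, ] <- extract_row(epoch_band_coh(wf$fft, wf$freqs, bins_list))
    }
    rows <- data.frame(subject_id = lts$subject_id, epoch = seq_len(n_ep),
                       group = if (!is.null(lts$group)) lts$group
                               else NA_character_)
  }

  unit <- character(0)
  band_col <- character(0)
  for (b in bands) {
    unit <- c(unit, vapply(net_pairs, `[[`, character(1), "name"),
              vapply(pair_spec, paste, character(1), collapse = "~"))
    band_col <- c(band_col, rep(b, n_net_cols + n_pair_cols))
  }
  meta <- data.frame(feature = paste0("coh_", band_col, "_", unit),
                     family = "coherence", band = band_col, unit = unit,
                     hemisphere = "mid", stringsAsFactors = FALSE)
  drop_bad_rows(feature_matrix(values, meta, rows))
}
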