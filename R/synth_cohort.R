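#' Configuration of a synthetic resting-state EEG cohort
#'
#' Defines the generative model for a two-group (+BATS / -BATS) cohort of
#' epoched resting-state EEG, at source-label and sensor level. Each label's
#' signal is an aperiodic 1/f background (power-law PSD
#' `P(f) = 10^offset * f^-slope`, realized by spectrally shaping Gaussian
#' noise) plus narrowband-filtered Gaussian oscillations in each canonical
#' band. Group differences are planted as standardized shifts of
#' log oscillation power in configurable label sets, shifts of the
#' aperiodic offset/slope, and shared band-limited sources raising the
#' coherence of configured label pairs.
#'
#' Defaults emulate the study conditions the pipeline targets: 35 +BATS and
#' 38 -BATS subjects (47.9% +BATS), ~140 two-second epochs per subject,
#' a 62-channel montage, the 68-parcel Desikan-Killiany atlas at 250 Hz,
#' higher alpha oscillatory power in right temporal/auditory labels and
#' higher gamma power in the left homologues for +BATS, a lower aperiodic
#' offset and steeper slope in +BATS, and stronger interhemispheric
#' auditory alpha coupling in +BATS.
#'
#' @param n_subjects_per_group length-2 named vector `c(pos = , neg = )`:
#'   subjects in the +BATS and -BATS groups.
#' @param n_epochs_per_subject epochs per subject (2-s epochs).
#' @param epoch_duration epoch length in seconds.
#' @param sampling_rate sampling rate in Hz; must be at least twice the
#'   highest band edge of `scheme`.
#' @param n_channels sensor montage size (62 gives the canonical 744-column
#'   sensor feature matrix).
#' @param n_labels number of source labels (68 = full Desikan-Killiany).
#' @param scheme a [band_scheme()].
#' @param band_effects named list, one entry per band, each
#'   `list(labels = <label names>, d = <standardized group difference in
#'   log oscillation power, +BATS minus -BATS>)`. `labels = NULL` applies
#'   the shift to every label.
#' @param aperiodic_effect named numeric `c(offset = , slope = )`: +BATS
#'   minus -BATS difference in aperiodic offset (log10 µV²/Hz) and slope.
#' @param coherence_effects list of
#'   `list(pair = c(label_a, label_b), band = <band name>,
#'   mixing = c(pos = , neg = ))`; `mixing` is the shared-source fraction of
#'   the pair's band oscillation (1 = identical band components). The
#'   mapping from mixing fraction to realized coherence is calibrated
#'   numerically by [calibrate_coherence_mixing()].
#' @param osc_power named numeric: baseline total oscillation power (µV²)
#'   per band.
#' @param subject_sd between-subject s.d. of log oscillation power; planted
#'   standardized differences are expressed in units of this s.d.
#' @param aperiodic_offset,aperiodic_slope baseline aperiodic parameters.
#' @param aperiodic_subject_sd named numeric `c(offset=, slope=)`:
#'   between-subject s.d. of the aperiodic parameters.
#' @param osc_bandwidth_frac oscillation bandwidth as a fraction of the
#'   band width (oscillations are narrower than their band so band spectra
#'   are peaked, keeping spectral entropy informative).
#' @param sensor_noise_sd s.d. of additive white sensor noise (µV).
#' @param shaping `"stochastic"` (Gaussian spectral amplitudes) or
#'   `"deterministic"` (fixed amplitudes, random phases; epoch periodograms
#'   then match the configured spectrum exactly).
#' @param outcome_scale `"regensburg_0_100"` (post-stimulation loudness,
#'   0-100%) or `"zurich_0_neg5"` (0 none ... -5 full suppression).
#' @param outcome_threshold binarization threshold on the suppression side:
#'   +BATS iff score <= threshold (default 90 on the Regensburg scale,
#'   -1 on the Zurich scale).
#' @param seed master seed; every subject draws from an independent stream
#'   derived from `(seed, subject index)`.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects_per_group = c(pos = 35, neg = 38),
                          n_epochs_per_subject = 140,
                          epoch_duration = 2,
                          sampling_rate = 250,
                          n_channels = 62,
                          n_labels = 68,
                          scheme = band_scheme(),
                          band_effects = NULL,
                          aperiodic_effect = c(offset = -0.3, slope = 0.3),
                          coherence_effects = NULL,
                          osc_power = c(delta = 1, theta = 1, alpha = 3,
                                        beta = 0.8, gamma = 3),
                          subject_sd = 0.4,
                          aperiodic_offset = 0,
                          aperiodic_slope = 1,
                          aperiodic_subject_sd = c(offset = 0.1, slope = 0.1),
                          osc_bandwidth_frac = 0.4,
                          sensor_noise_sd = 0.5,
                          shaping = c("stochastic", "deterministic"),
                          outcome_scale = c("regensburg_0_100",
                                            "zurich_0_neg5"),
                          outcome_threshold = NULL,
                          seed = 1L) {
  shaping <- match.arg(shaping)
  outcome_scale <- match.arg(outcome_scale)
  stopifnot(length(n_subjects_per_group) == 2,
            all(n_subjects_per_group >= 1),
            n_epochs_per_subject >= 1, epoch_duration > 0,
            n_channels >= 1, n_labels >= 1, subject_sd >= 0)
  if (is.null(names(n_subjects_per_group))) {
    names(n_subjects_per_group) <- c("pos", "neg")
  }
  if (sampling_rate < 2 * max_band_edge(scheme)) {
    stop("sampling_rate (", sampling_rate, " Hz) must be at least twice ",
         "the highest band edge (", max_band_edge(scheme),
         " Hz); gamma up to 80 Hz needs >= 160 Hz")
  }
  label_names <- if (n_labels == 68) dk_labels() else generic_labels(n_labels)
  if (is.null(band_effects) && n_labels == 68) {
    auditory <- c("transversetemporal", "superiortemporal", "middletemporal",
                  "supramarginal", "superiorparietal", "insula")
    band_effects <- list(
      alpha = list(labels = paste0("rh_", auditory), d = 1.0),
      gamma = list(labels = paste0("lh_", auditory), d = 1.0))
  }
  if (is.null(coherence_effects) && n_labels == 68) {
    coherence_effects <- list(
      list(pair = c("lh_transversetemporal", "rh_transversetemporal"),
           band = "alpha", mixing = c(pos = 0.6, neg = 0.2)))
  }
  for (eff in band_effects) {
    bad <- setdiff(eff$labels, label_names)
    if (length(bad)) stop("band_effects references unknown labels: ",
                          paste(bad, collapse = ", "))
  }
  for (ce in coherence_effects) {
    bad <- setdiff(ce$pair, label_names)
    if (length(bad)) stop("coherence_effects references unknown labels: ",
                          paste(bad, collapse = ", "))
    if (!ce$band %in% scheme$band) stop("unknown band in coherence_effects: ",
                                        ce$band)
  }
  missing_bands <- setdiff(names(band_effects), scheme$band)
  if (length(missing_bands)) stop("band_effects for unknown bands: ",
                                  paste(missing_bands, collapse = ", "))
  if (is.null(outcome_threshold)) {
    outcome_threshold <- if (outcome_scale == "regensburg_0_100") 90 else -1
  }
  op <- osc_power[scheme$band]
  op[is.na(op)] <- 0
  names(op) <- scheme$band
  structure(list(
    n_subjects_per_group = n_subjects_per_group,
    n_epochs_per_subject = as.integer(n_epochs_per_subject),
    epoch_duration = epoch_duration,
    sampling_rate = sampling_rate,
    n_channels = as.integer(n_channels),
    n_labels = as.integer(n_labels),
    label_names = label_names,
    channel_names = montage_channel_names(n_channels),
    scheme = scheme,
    band_effects = band_effects,
    aperiodic_effect = aperiodic_effect,
    coherence_effects = coherence_effects,
    osc_power = op,
    subject_sd = subject_sd,
    aperiodic_offset = aperiodic_offset,
    aperiodic_slope = aperiodic_slope,
    aperiodic_subject_sd = aperiodic_subject_sd,
    osc_bandwidth_frac = osc_bandwidth_frac,
    sensor_noise_sd = sensor_noise_sd,
    shaping = shaping,
    outcome_scale = outcome_scale,
    outcome_threshold = outcome_threshold,
    seed = as.integer(seed)), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic EEG cohort config: ",
      x$n_subjects_per_group[["pos"]], " +BATS / ",
      x$n_subjects_per_group[["neg"]], " -BATS subjects, ",
      x$n_epochs_per_subject, " x ", x$epoch_duration, "-s epochs @ ",
      x$sampling_rate, " Hz\n  ", x$n_channels, " channels, ",
      x$n_labels, " labels; outcome scale ", x$outcome_scale,
      " (threshold ", x$outcome_threshold, "); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# generic paired label names for reduced atlases
generic_labels <- function(n) {
  hemi <- rep(c("lh", "rh"), length.out = n)
  idx <- ceiling(seq_len(n) / 2)
  sprintf("%s_label%02d", hemi, idx)
}

# standard 62-channel 10-10 montage; reduced montages take the first n
montage_channel_names <- function(n) {
  full <- c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
            "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
            "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
            "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
            "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
            "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
            "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
  if (n <= length(full)) full[seq_len(n)]
  else c(full, sprintf("EX%02d", seq_len(n - length(full))))
}

# hemisphere of a 10-10 channel name: odd final digit = left, even = right
channel_hemisphere <- function(ch) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", ch)))
  ifelse(is.na(num), "mid", ifelse(num %% 2 == 1, "left", "right"))
}

label_hemisphere <- function(lab) {
  ifelse(startsWith(lab, "lh_"), "left",
         ifelse(startsWith(lab, "rh_"), "right", "mid"))
}

# independent per-subject stream derived from (master seed, subject index)
subject_seed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %% 2147483629)
}

# ---- spectral shaping primitives -------------------------------------------
#
# Signals are synthesized in the frequency domain: each label's one-sided
# complex spectrum is assembled (aperiodic amplitudes on every bin, band
# components only on their in-band bins) and inverted with a single FFT
# per label. With stochastic shaping the coefficients are complex Gaussian
# (E|F_k|^2 matches the target density); with deterministic shaping the
# amplitudes are fixed and only phases are random, so each epoch's raw
# periodogram equals the target density exactly.

# complex unit-variance coefficients (rows x epochs)
cnorm_mat <- function(nr, nc, deterministic = FALSE) {
  if (nr == 0) return(matrix(0i, 0, nc))
  if (deterministic) {
    exp(2i * pi * matrix(runif(nr * nc), nr))
  } else {
    (matrix(rnorm(nr * nc), nr) + 1i * matrix(rnorm(nr * nc), nr)) / sqrt(2)
  }
}

# invert a one-sided spectrum (half x epochs, bins 1..n/2) to real signals
hermitian_ifft <- function(Z, n) {
  half <- n %/% 2
  stopifnot(nrow(Z) == half)
  if (n %% 2 == 0) Z[half, ] <- sqrt(2) * Re(Z[half, ]) # Nyquist bin real
  spec <- matrix(0i, n, ncol(Z))
  spec[2:(half + 1), ] <- Z
  n_conj <- if (n %% 2 == 0) half - 1L else half
  if (n_conj > 0) {
    spec[n:(n - n_conj + 1L), ] <- Conj(Z[seq_len(n_conj), , drop = FALSE])
  }
  Re(stats::mvfft(spec, inverse = TRUE)) / n
}

# spectral amplitude such that the raw periodogram equals `density` (µV²/Hz)
density_amp <- function(density, sampling_rate, n) {
  sqrt(pmax(density, 0) * sampling_rate * n / 2)
}

# oscillation sub-band inside a canonical band
osc_band_edges <- function(f_lo, f_hi, frac) {
  c0 <- (f_lo + f_hi) / 2
  hw <- frac * (f_hi - f_lo) / 2
  c(c0 - hw, c0 + hw)
}

# ---- label-level simulation -------------------------------------------------

#' Simulate source-label time courses for one subject
#'
#' Draws the subject's parameters (log oscillation power per label and band,
#' aperiodic offset/slope) from the group-level generative model in
#' `config`, then synthesizes all epochs: spectrally shaped 1/f background
#' plus narrowband oscillations, with shared band-limited sources injected
#' into configured coherent label pairs.
#'
#' @param config a [cohort_config()].
#' @param subject_group `"pos"` (+BATS) or `"neg"` (-BATS).
#' @param subject_id identifier stored with the result.
#' @param seed stream seed for this subject; by default derived from the
#'   config's master seed and `subject_index`.
#' @param subject_index 1-based index used to derive the default stream.
#' @return object of class `label_time_series`: list with `subject_id`,
#'   `data` (epochs x labels x samples array), `label_names`,
#'   `sampling_rate`, `group` and the drawn `subject_params`.
#' @export
simulate_label_signals <- function(config, subject_group = c("pos", "neg"),
                                   subject_id = "S01", subject_index = 1L,
                                   seed = subject_seed(config$seed,
                                                       subject_index)) {
  stopifnot(inherits(config, "cohort_config"))
  subject_group <- match.arg(subject_group)
  set.seed(seed)
  n <- as.integer(round(config$epoch_duration * config$sampling_rate))
  E <- config$n_epochs_per_subject
  L <- config$n_labels
  labs <- config$label_names
  scheme <- config$scheme
  det <- config$shaping == "deterministic"
  gsign <- if (subject_group == "pos") +0.5 else -0.5

  # subject-level parameters
  ap_off <- config$aperiodic_offset +
    gsign * config$aperiodic_effect[["offset"]] +
    rnorm(1, 0, config$aperiodic_subject_sd[["offset"]])
  ap_slo <- config$aperiodic_slope +
    gsign * config$aperiodic_effect[["slope"]] +
    rnorm(1, 0, config$aperiodic_subject_sd[["slope"]])
  # log oscillation power per (label, band): baseline + planted shift +
  # subject random effect (the subject's oscillatory "fingerprint")
  logv <- matrix(rep(log(pmax(config$osc_power, 1e-12)), each = L), L,
                 dimnames = list(labs, scheme$band))
  for (b in names(config$band_effects)) {
    eff <- config$band_effects[[b]]
    tgt <- if (is.null(eff$labels)) labs else eff$labels
    logv[tgt, b] <- logv[tgt, b] + gsign * eff$d * config$subject_sd
  }
  logv <- logv + matrix(rnorm(L * nrow(scheme), 0, config$subject_sd), L)
  v <- exp(logv)
  v[, config$osc_power[scheme$band] <= 0] <- 0

  # frequency grid and per-band spectral layout
  half <- n %/% 2
  f <- (1:half) * config$sampling_rate / n
  amp_ap <- density_amp(10^ap_off * f^(-ap_slo), config$sampling_rate, n)
  band_layout <- lapply(seq_len(nrow(scheme)), function(bi) {
    edges <- osc_band_edges(scheme$f_lo[bi], scheme$f_hi[bi],
                            config$osc_bandwidth_frac)
    idx <- which(f >= edges[1] & f <= edges[2])
    # unit-variance scaling: total power of the component is ~1
    list(idx = idx, amp = if (length(idx)) n / sqrt(2 * length(idx)) else NA)
  })
  for (bi in seq_len(nrow(scheme))) {
    if (any(v[, scheme$band[bi]] > 0) && !length(band_layout[[bi]]$idx)) {
      stop("band ", scheme$band[bi], " has no spectral bins at sampling ",
           "rate ", config$sampling_rate, " Hz / epoch length ",
           config$epoch_duration, " s")
    }
  }
  # shared band-limited sources for the configured coherent pairs
  shared <- lapply(config$coherence_effects, function(ce) {
    bi <- match(ce$band, scheme$band)
    cnorm_mat(length(band_layout[[bi]]$idx), E, det)
  })

  # samples x epochs x labels accumulator (flipped to output order at end)
  sig <- array(0, dim = c(n, E, L))
  for (l in seq_len(L)) {
    Z <- amp_ap * cnorm_mat(half, E, det)
    for (bi in seq_len(nrow(scheme))) {
      b <- scheme$band[bi]
      if (v[l, b] == 0) next
      lay <- band_layout[[bi]]
      comp <- cnorm_mat(length(lay$idx), E, det)
      for (ci in seq_along(config$coherence_effects)) {
        ce <- config$coherence_effects[[ci]]
        if (ce$band == b && labs[l] %in% ce$pair) {
          m <- ce$mixing[[subject_group]]
          comp <- sqrt(1 - m) * comp + sqrt(m) * shared[[ci]]
        }
      }
      Z[lay$idx, ] <- Z[lay$idx, ] + sqrt(v[l, b]) * lay$amp * comp
    }
    sig[, , l] <- hermitian_ifft(Z, n)
  }
  structure(list(subject_id = subject_id,
                 data = aperm(sig, c(2, 3, 1)), # epochs x labels x samples
                 label_names = labs,
                 sampling_rate = config$sampling_rate,
                 group = subject_group,
                 subject_params = list(aperiodic_offset = ap_off,
                                       aperiodic_slope = ap_slo,
                                       log_osc_power = logv),
                 seed = seed),
            class = "label_time_series")
}

#' @export
print.label_time_series <- function(x, ...) {
  d <- dim(x$data)
  cat("Label time series [", x$subject_id, ", group ", x$group, "]: ",
      d[1], " epochs x ", d[2], " labels x ", d[3], " samples @ ",
      x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Project label time courses to sensors
#'
#' Applies an abstract channels x labels mixing matrix (a stand-in for
#' volume conduction; no forward head model is implied), optionally adding
#' white sensor noise. With `sensor_noise_sd = 0` the result is a
#' deterministic function of its inputs.
#'
#' @param lts a `label_time_series`.
#' @param mixing channels x labels numeric matrix; every row must contain a
#'   non-zero entry.
#' @param channel_names names for the sensor rows.
#' @param sensor_noise_sd s.d. of additive white noise (0 = none).
#' @return object of class `epoch_set`: list with `subject_id`, `data`
#'   (epochs x channels x samples), `channel_names`, `sampling_rate`,
#'   `group`.
#' @export
project_to_sensors <- function(lts, mixing,
                               channel_names = montage_channel_names(nrow(mixing)),
                               sensor_noise_sd = 0) {
  stopifnot(inherits(lts, "label_time_series"))
  mixing <- as.matrix(mixing)
  d <- dim(lts$data)
  if (ncol(mixing) != d[2]) {
    stop("mixing has ", ncol(mixing), " columns but data has ", d[2],
         " labels")
  }
  if (any(rowSums(abs(mixing)) == 0)) {
    stop("mixing matrix has all-zero rows (dead channels)")
  }
  E <- d[1]; L <- d[2]; n <- d[3]; C <- nrow(mixing)
  # labels x (epochs*samples) -> channels x (epochs*samples)
  flat <- matrix(aperm(lts$data, c(2, 1, 3)), nrow = L)
  sens <- mixing %*% flat
  if (sensor_noise_sd > 0) {
    sens <- sens + rnorm(length(sens), 0, sensor_noise_sd)
  }
  data <- aperm(array(sens, dim = c(C, E, n)), c(2, 1, 3))
  structure(list(subject_id = lts$subject_id, data = data,
                 channel_names = channel_names,
                 sampling_rate = lts$sampling_rate,
                 group = lts$group),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoch set [", x$subject_id, "]: ", d[1], " epochs x ", d[2],
      " channels x ", d[3], " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Default sensor mixing matrix
#'
#' Smooth pseudo-random channels x labels mixing, deterministic in the seed:
#' channels and labels are placed on an abstract 1-D scalp coordinate and
#' weights decay with distance, plus a small diffuse component, rows
#' normalized to unit norm. Not a physical leadfield.
#'
#' @param n_channels,n_labels dimensions.
#' @param seed seed for the deterministic construction.
#' @param spread spatial decay constant of the distance kernel.
#' @return channels x labels matrix with unit-norm rows.
#' @export
default_mixing <- function(n_channels, n_labels, seed = 1L, spread = 0.15) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  pc <- sort(runif(n_channels))
  pl <- sort(runif(n_labels))
  m <- exp(-outer(pc, pl, function(a, b) ((a - b) / spread)^2)) +
    0.05 * matrix(abs(rnorm(n_channels * n_labels)), n_channels)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  m / sqrt(rowSums(m^2))
}

#' Assign BATS outcome scores to subjects
#'
#' Gives every +BATS subject a score on the suppression side of the
#' configured threshold and every -BATS subject a score on the other side,
#' with jitter confined to the correct side. On the Regensburg scale
#' (post-stimulation loudness, 0-100%) +BATS scores fall in
#' `[threshold - 50, threshold]` and -BATS in `(threshold, 100]`; on the
#' Zurich scale (0 none ... -5 full suppression) +BATS scores are integers
#' in `[-5, threshold]` and -BATS subjects score 0.
#'
#' @param config a [cohort_config()].
#' @param groups character vector of `"pos"` / `"neg"` per subject.
#' @param subject_ids identifiers; defaults to `S001`, `S002`, ...
#' @return data.frame of class `subject_outcomes`: `subject_id`, `scale`,
#'   `score`, `true_group`.
#' @export
assign_outcomes <- function(config, groups,
                            subject_ids = sprintf("S%03d", seq_along(groups))) {
  stopifnot(all(groups %in% c("pos", "neg")))
  thr <- config$outcome_threshold
  n <- length(groups)
  if (config$outcome_scale == "regensburg_0_100") {
    lo_pos <- max(0, thr - 50)
    score <- ifelse(groups == "pos",
                    runif(n, lo_pos, thr),
                    runif(n, thr + 1e-9, 100))
    score <- round(score, 1)
    score[groups == "pos"] <- pmin(score[groups == "pos"], thr)
    score[groups == "neg"] <- pmax(score[groups == "neg"],
                                   min(thr + 0.1, 100))
  } else {
    score <- ifelse(groups == "pos",
                    sample(seq(-5, thr), n, replace = TRUE),
                    0)
  }
  out <- data.frame(subject_id = subject_ids,
                    scale = config$outcome_scale,
                    score = score,
                    true_group = groups,
                    stringsAsFactors = FALSE)
  class(out) <- c("subject_outcomes", "data.frame")
  out
}

#' Simulate a full synthetic cohort
#'
#' Runs [simulate_label_signals()] for every subject (independent per-subject
#' random streams derived from the master seed), projects to sensors through
#' a shared [default_mixing()] matrix, and assigns outcome scores. Identical
#' configs (including seed) give byte-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param keep which signal levels to retain: subset of
#'   `c("label", "sensor")`. Dropping a level saves memory for large cohorts.
#' @param mixing optional custom mixing matrix (channels x labels).
#' @return object of class `eeg_cohort`: list with `config`, `outcomes`,
#'   `mixing`, and per-subject lists `label_ts` and `sensor` (those kept).
#' @export
simulate_cohort <- function(config, keep = c("label", "sensor"),
                            mixing = default_mixing(config$n_channels,
                                                    config$n_labels,
                                                    seed = config$seed)) {
  stopifnot(inherits(config, "cohort_config"))
  keep <- match.arg(keep, several.ok = TRUE)
  groups <- rep(c("pos", "neg"), times = config$n_subjects_per_group)
  ids <- sprintf("S%03d", seq_along(groups))
  set.seed(subject_seed(config$seed, 0L))
  outcomes <- assign_outcomes(config, groups, ids)
  label_ts <- list()
  sensor <- list()
  for (i in seq_along(groups)) {
    lts <- simulate_label_signals(config, groups[i], ids[i],
                                  subject_index = i)
    if ("sensor" %in% keep) {
      sensor[[ids[i]]] <- project_to_sensors(
        lts, mixing, channel_names = config$channel_names,
        sensor_noise_sd = config$sensor_noise_sd)
    }
    if ("label" %in% keep) label_ts[[ids[i]]] <- lts
  }
  structure(list(config = config, outcomes = outcomes, mixing = mixing,
                 label_ts = if ("label" %in% keep) label_ts,
                 sensor = if ("sensor" %in% keep) sensor),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("Synthetic EEG cohort: ", nrow(x$outcomes), " subjects (",
      sum(x$outcomes$true_group == "pos"), " +BATS / ",
      sum(x$outcomes$true_group == "neg"), " -BATS), ",
      x$config$n_epochs_per_subject, " epochs each\n", sep = "")
  invisible(x)
}

#' Calibrate shared-source mixing fraction against realized coherence
#'
#' The generator plants coherence by giving a label pair a common
#' band-limited component with mixing fraction `m`; the realized magnitude
#' coherence is lower than `m` because the aperiodic background dilutes the
#' band. This helper measures the mapping numerically: it simulates a
#' two-label pair under the config's signal parameters for a grid of mixing
#' fractions and returns the realized band coherence at each, so a target
#' coherence can be inverted by interpolation.
#'
#' @param config a [cohort_config()] supplying the signal parameters.
#' @param band band name to calibrate in.
#' @param mixing_grid mixing fractions to probe.
#' @param n_epochs epochs simulated per grid point.
#' @param seed simulation seed.
#' @return data.frame with columns `mixing` and `coherence`.
#' @export
calibrate_coherence_mixing <- function(config, band = "alpha",
                                       mixing_grid = seq(0, 1, by = 0.1),
                                       n_epochs = 200, seed = 1L) {
  stopifnot(band %in% config$scheme$band)
  cfg <- config
  cfg$n_labels <- 2L
  cfg$label_names <- c("lh_cal", "rh_cal")
  cfg$n_epochs_per_subject <- as.integer(n_epochs)
  cfg$band_effects <- NULL
  bi <- match(band, cfg$scheme$band)
  out <- vapply(mixing_grid, function(m) {
    cfg$coherence_effects <- list(list(pair = c("lh_cal", "rh_cal"),
                                       band = band,
                                       mixing = c(pos = m, neg = m)))
    lts <- simulate_label_signals(cfg, "pos", "CAL", seed = seed)
    co <- numeric(n_epochs)
    for (e in seq_len(n_epochs)) {
      cs <- coherence(lts$data[e, 1, ], lts$data[e, 2, ], cfg$sampling_rate)
      bb <- band_bins(cs$freqs, cfg$scheme$f_lo[bi], cfg$scheme$f_hi[bi])
      co[e] <- mean(cs$coh[bb])
    }
    mean(co)
  }, numeric(1))
  data.frame(mixing = mixing_grid, coherence = out)
}
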