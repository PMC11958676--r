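# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs quickly on one CPU.

# compact cohort config: paired generic labels lh_labelXX / rh_labelXX
toy_config <- function(n_pos = 6, n_neg = 6, n_epochs = 10, n_channels = 6,
                       n_labels = 6, alpha_d = 0, gamma_d = 0,
                       alpha_labels = "rh_label01",
                       gamma_labels = "lh_label01",
                       aperiodic_effect = c(offset = 0, slope = 0),
                       coherence_effects = list(), seed = 1, ...) {
  be <- list()
  if (alpha_d != 0) be$alpha <- list(labels = alpha_labels, d = alpha_d)
  if (gamma_d != 0) be$gamma <- list(labels = gamma_labels, d = gamma_d)
  cohort_config(n_subjects_per_group = c(pos = n_pos, neg = n_neg),
                n_epochs_per_subject = n_epochs,
                n_channels = n_channels, n_labels = n_labels,
                band_effects = be, aperiodic_effect = aperiodic_effect,
                coherence_effects = coherence_effects, seed = seed, ...)
}

# a psd object from an explicit power matrix (channels x freqs)
psd_from <- function(freqs, power) {
  structure(list(freqs = freqs, power = rbind(power)), class = "psd")
}

# independent naive coherence oracle: direct cross-spectra with explicit
# loops over segments and bins (no shared code with the implementation)
oracle_coherence <- function(x, y, fs, win_sec = 1, overlap = 0.5,
                             nfft_factor = 2) {
  win <- round(win_sec * fs)
  step <- round(win * (1 - overlap))
  starts <- seq(1, length(x) - win + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  nfft <- win * nfft_factor
  nf <- nfft %/% 2 + 1
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + win - 1)]; ys <- y[s:(s + win - 1)]
    xs <- (xs - mean(xs)) * w; ys <- (ys - mean(ys)) * w
    X <- stats::fft(c(xs, rep(0, nfft - win)))[1:nf]
    Y <- stats::fft(c(ys, rep(0, nfft - win)))[1:nf]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  list(freqs = (seq_len(nf) - 1) * fs / nfft,
       coh = Mod(sxy / length(starts)) /
         sqrt((sxx / length(starts)) * (syy / length(starts))))
}

# feature matrix with given columns of iid noise (for merge tests etc.)
noise_fm <- function(n_rows, n_cols, seed = 1) {
  set.seed(seed)
  feature_matrix(matrix(rnorm(n_rows * n_cols), n_rows),
                 data.frame(feature = sprintf("f%03d", seq_len(n_cols)),
                            family = "band_power", band = "alpha",
                            unit = "Cz", hemisphere = "mid"))
}

# tiny deterministic two-feature separable problem
separable_fm <- function(n = 120, seed = 1) {
  set.seed(seed)
  lab <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  X <- cbind(f1 = ifelse(lab == "pos", 3, -3) + rnorm(n, 0, 0.3),
             f2 = rnorm(n))
  fm <- feature_matrix(X, data.frame(feature = c("f1", "f2"),
                                     family = "band_power", band = "alpha",
                                     unit = c("C3", "C4"),
                                     hemisphere = c("left", "right")))
  list(fm = fm, labels = lab)
}

# small fitted probability forest + matching tree ensemble
toy_forest <- function(n = 200, p = 5, num.trees = 10, max.depth = 4,
                       seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("x", seq_len(p))
  y <- factor(ifelse(X[, 1] + 0.6 * X[, 2] + rnorm(n, 0, 0.4) > 0,
                     "pos", "neg"), levels = c("neg", "pos"))
  rf <- ranger::ranger(x = X, y = y, num.trees = num.trees,
                       probability = TRUE, max.depth = max.depth,
                       seed = seed, num.threads = 1)
  list(rf = rf, X = X, y = y, ens = as_tree_ensemble(rf, X))
}
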