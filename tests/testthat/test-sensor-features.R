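test_that("band power reduces flat and band-limited spectra correctly", {
  f <- seq(0.5, 100, by = 0.5)
  flat <- psd_from(f, rep(2.5, length(f)))
  bp <- band_power(flat)
  expect_equal(unname(bp[1, ]), rep(2.5, 5))
  # power only inside 9-13 Hz: all non-alpha bands zero
  p <- ifelse(f >= 9 & f <= 13, 1, 0)
  bp2 <- band_power(psd_from(f, p))
  expect_gt(bp2[1, "alpha"], 0)
  expect_equal(unname(bp2[1, c("delta", "theta", "beta", "gamma")]),
               rep(0, 4))
  # a band with no bins on the grid is rejected
  coarse <- psd_from(c(10, 20, 50), c(1, 1, 1))
  expect_error(band_power(coarse, band_scheme(list(delta = c(0.5, 4.5)))),
               "no PSD bins")
})

test_that("spectral entropy matches hand values and the brute-force oracle", {
  f <- c(1, 2, 3)
  scheme <- band_scheme(list(all = c(0.5, 3.5)))
  # flat band of n bins -> log2 n bits (normalized 1)
  expect_equal(unname(spectral_entropy(psd_from(f, c(1, 1, 1)), scheme,
                                       normalize = FALSE)[1, 1]), log2(3))
  expect_equal(unname(spectral_entropy(psd_from(f, c(1, 1, 1)),
                                       scheme)[1, 1]), 1)
  # point mass -> 0
  expect_equal(unname(spectral_entropy(psd_from(f, c(0, 5, 0)),
                                       scheme)[1, 1]), 0)
  # p = (0.5, 0.25, 0.25) -> 1.5 bits
  expect_equal(unname(spectral_entropy(psd_from(f, c(0.5, 0.25, 0.25)), scheme,
                                       normalize = FALSE)[1, 1]), 1.5)
  # oracle: -sum p log2 p on random positive vectors, 1e-12
  set.seed(7)
  for (i in 1:25) {
    nb <- sample(3:30, 1)
    p <- runif(nb)
    got <- unname(spectral_entropy(psd_from(seq_len(nb), p),
                                   band_scheme(list(b = c(0.5, nb + 0.5))),
                                   normalize = FALSE)[1, 1])
    q <- p / sum(p)
    expect_equal(got, -sum(q * log2(q)), tolerance = 1e-12)
  }
  # degenerate all-zero band: defined as 0 with a warning
  expect_warning(h0 <- spectral_entropy(psd_from(f, c(0, 0, 0)), scheme),
                 "all-zero")
  expect_equal(unname(h0[1, 1]), 0)
})

test_that("aperiodic fit is exact on noiseless power laws", {
  f <- seq(0.5, 100, by = 0.5)
  fit <- fit_aperiodic(psd_from(f, 10^2 * f^-1.5))
  expect_equal(fit$offset, 2, tolerance = 1e-6)
  expect_equal(fit$slope, 1.5, tolerance = 1e-6)
  # flat spectrum: slope 0, offset log10(level)
  fit0 <- fit_aperiodic(psd_from(f, rep(0.02, length(f))))
  expect_equal(fit0$slope, 0, tolerance = 1e-9)
  expect_equal(fit0$offset, log10(0.02), tolerance = 1e-9)
  expect_error(fit_aperiodic(psd_from(f, rep(0, length(f)))),
               "non-positive")
})

test_that("peak exclusion removes an alpha peak the plain fit absorbs", {
  f <- seq(0.5, 100, by = 0.5)
  base <- 10^1 * f^-1.5
  peak <- 30 * exp(-(f - 10)^2 / 2) # narrow alpha peak
  fit <- fit_aperiodic(psd_from(f, base + peak))
  plain <- fit_aperiodic(psd_from(f, base + peak),
                         aperiodic_settings(max_iter = 0))
  expect_lt(abs(fit$slope - 1.5), 0.1)
  expect_gt(abs(plain$slope - 1.5), 0.2) # unremoved peak biases the fit
  expect_gt(fit$n_excluded, 0)
  expect_lt(plain$r_squared, fit$r_squared)
})

test_that("sensor feature matrix has the canonical layout and cardinality", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 3, n_channels = 62,
                    n_labels = 6, seed = 13)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  es <- project_to_sensors(lts, default_mixing(62, 6, 1),
                           channel_names = cfg$channel_names)
  fm <- assemble_sensor_features(es)
  expect_identical(ncol(fm$values), 744L)
  expect_identical(as.vector(table(fm$meta$family)[
    c("band_power", "entropy", "aperiodic_offset", "aperiodic_slope")]),
    c(310L, 310L, 62L, 62L))
  # 4-channel toy: 10*C + 2*C = 48
  es4 <- project_to_sensors(lts, default_mixing(4, 6, 1),
                            channel_names = paste0("ch", 1:4))
  fm4 <- assemble_sensor_features(es4)
  expect_identical(ncol(fm4$values), 48L)
  # invariants: band powers non-negative, normalized entropies in [0, 1]
  expect_true(all(fm$values[, fm$meta$family == "band_power"] >= 0))
  ent <- fm$values[, fm$meta$family == "entropy"]
  expect_true(all(ent >= 0 & ent <= 1))
})

test_that("identical epochs give identical feature rows", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 2, n_channels = 4,
                    n_labels = 4, seed = 14)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  lts$data[2, , ] <- lts$data[1, , ] # duplicate the epoch
  es <- project_to_sensors(lts, default_mixing(4, 4, 1),
                           channel_names = paste0("ch", 1:4))
  fm <- assemble_sensor_features(es)
  expect_equal(fm$values[1, ], fm$values[2, ])
})
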