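rect_full_epoch <- psd_settings(window_sec = 2, overlap = 0,
                                nfft_factor = 1, window = "rect")

test_that("config validation rejects impossible sampling rates and labels", {
  expect_error(toy_config(sampling_rate = 100), "twice")
  expect_error(toy_config(alpha_d = 1, alpha_labels = "nosuchlabel"),
               "unknown labels")
  expect_error(toy_config(coherence_effects = list(
    list(pair = c("lh_label01", "rh_label01"), band = "sigma",
         mixing = c(pos = 0.5, neg = 0.5)))), "unknown band")
})

test_that("deterministic shaping realizes the configured power law exactly", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 4, n_labels = 2,
                    shaping = "deterministic",
                    osc_power = c(delta = 0, theta = 0, alpha = 0,
                                  beta = 0, gamma = 0),
                    aperiodic_subject_sd = c(offset = 0, slope = 0),
                    aperiodic_offset = 0.5, aperiodic_slope = 1.2, seed = 4)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  psd <- compute_psd(lts$data[1, , ], 250, rect_full_epoch)
  fit <- fit_aperiodic(psd)
  expect_equal(fit$offset, rep(0.5, 2), tolerance = 1e-6)
  expect_equal(fit$slope, rep(1.2, 2), tolerance = 1e-6)
  expect_equal(fit$r_squared, rep(1, 2), tolerance = 1e-9)
})

test_that("epoch-averaged Welch PSD of shaped noise recovers the power law", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 60, n_labels = 2,
                    osc_power = c(delta = 0, theta = 0, alpha = 0,
                                  beta = 0, gamma = 0),
                    aperiodic_subject_sd = c(offset = 0, slope = 0),
                    seed = 5)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  ps <- batseeg:::epochs_psd(lts$data, 250, rect_full_epoch)
  avg <- apply(ps$power, c(2, 3), mean)
  fit <- batseeg:::aperiodic_fit_matrix(avg, ps$freqs)
  expect_equal(fit$slope, rep(1, 2), tolerance = 0.05)
  expect_equal(fit$offset, rep(0, 2), tolerance = 0.05)
})

test_that("a fully shared band source gives near-unit alpha coherence", {
  # no aperiodic background, alpha oscillation only: mixing 1 means the
  # two labels' band content is identical
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 10, n_labels = 2,
                    osc_power = c(delta = 0, theta = 0, alpha = 3,
                                  beta = 0, gamma = 0),
                    aperiodic_offset = -12, # negligible background
                    coherence_effects = list(
                      list(pair = c("lh_label01", "rh_label01"),
                           band = "alpha", mixing = c(pos = 1, neg = 1))),
                    seed = 6)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  co <- vapply(1:10, function(e) {
    cs <- coherence(lts$data[e, 1, ], lts$data[e, 2, ], 250)
    mean(cs$coh[cs$freqs >= 8.5 & cs$freqs < 13.5])
  }, numeric(1))
  expect_gt(mean(co), 0.95)
})

test_that("planted log alpha-power difference of 1 s.d. is recovered", {
  # Monte-Carlo against the configured generative means: aperiodic group
  # effects off, alpha shift d = 1 in one label, n = 20/group
  ds <- vapply(1:20, function(s) {
    cfg <- toy_config(n_pos = 20, n_neg = 20, n_epochs = 10, n_labels = 2,
                      n_channels = 2, alpha_d = 1, seed = s)
    m <- vapply(seq_len(40), function(i) {
      g <- if (i <= 20) "pos" else "neg"
      lts <- simulate_label_signals(cfg, g, paste0("S", i),
                                    subject_index = i)
      fm <- label_band_power(lts)
      mean(log(fm$values[, fm$meta$feature == "src_alpha_rh_label01"]))
    }, numeric(1))
    g <- rep(c("pos", "neg"), each = 20)
    (mean(m[g == "pos"]) - mean(m[g == "neg"])) /
      sqrt((var(m[g == "pos"]) + var(m[g == "neg"])) / 2)
  }, numeric(1))
  expect_lt(abs(mean(ds) - 1), 0.3)
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- toy_config(n_pos = 2, n_neg = 2, n_epochs = 3, seed = 11)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$label_ts$S001$data, c2$label_ts$S001$data)
  expect_identical(c1$sensor$S003$data, c2$sensor$S003$data)
  expect_identical(c1$outcomes, c2$outcomes)
})

test_that("sensor projection handles identity, rank-1 and mismatched mixing", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 2, n_labels = 4,
                    seed = 8)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  es <- project_to_sensors(lts, diag(4))
  expect_equal(es$data, lts$data, tolerance = 1e-12)
  # single non-zero column: every channel a scaled copy of label 2
  m <- matrix(0, 3, 4); m[, 2] <- c(1, -2, 0.5)
  es2 <- project_to_sensors(lts, m)
  cors <- cor(t(es2$data[1, , ]))
  expect_equal(abs(cors), matrix(1, 3, 3), tolerance = 1e-10)
  expect_error(project_to_sensors(lts, matrix(1, 3, 5)), "labels")
  expect_error(project_to_sensors(lts, rbind(rep(0, 4), rep(1, 4))),
               "zero rows")
})

test_that("noise-free sensor variance is the mixing quadratic form", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 1, n_labels = 4,
                    seed = 9)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  mix <- default_mixing(3, 4, seed = 2)
  es <- project_to_sensors(lts, mix, sensor_noise_sd = 0)
  lab <- t(lts$data[1, , ]) # samples x labels
  cov_lab <- crossprod(sweep(lab, 2, colMeans(lab))) / (nrow(lab) - 1)
  expected <- diag(mix %*% cov_lab %*% t(mix))
  got <- apply(es$data[1, , ], 1, var)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("outcome scores respect scale, side of threshold, and round trip", {
  cfg <- toy_config(n_pos = 24, n_neg = 26, seed = 10)
  set.seed(1)
  groups <- rep(c("pos", "neg"), c(24, 26))
  out <- assign_outcomes(cfg, groups)
  expect_true(all(out$score[out$true_group == "pos"] <= 90))
  expect_true(all(out$score[out$true_group == "neg"] > 90))
  expect_true(all(out$score >= 0 & out$score <= 100))
  lab <- binarize_outcome(out, 90)
  expect_identical(as.vector(table(lab)), c(26L, 24L))
  # zurich scale: +BATS in [-5, -1], -BATS at 0
  cfgz <- toy_config(outcome_scale = "zurich_0_neg5", seed = 10)
  outz <- assign_outcomes(cfgz, groups)
  expect_true(all(outz$score[outz$true_group == "pos"] %in% -5:-1))
  expect_true(all(outz$score[outz$true_group == "neg"] == 0))
})

test_that("coherence mixing calibration is monotone in the mixing fraction", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, seed = 12)
  cal <- calibrate_coherence_mixing(cfg, "alpha",
                                    mixing_grid = c(0, 0.5, 1),
                                    n_epochs = 40)
  expect_true(all(diff(cal$coherence) > 0))
  # the 3-segment per-epoch estimator has a large positive floor for
  # independent signals (~1/sqrt(K)); the curve starts near it, not at 0
  expect_lt(cal$coherence[1], 0.7)
  expect_gt(cal$coherence[3], cal$coherence[1] + 0.15)
})
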