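test_that("coherence is 1 for identical and time-shifted signals", {
  set.seed(20)
  x <- rnorm(1000)
  cs <- coherence(x, x, 250)
  expect_true(all(abs(cs$coh - 1) < 1e-10))
  # constant lag, noise-free: magnitude coherence ignores the phase ramp
  lag <- 5
  cs2 <- coherence(x[1:(1000 - lag)], x[(1 + lag):1000], 250)
  expect_gt(mean(cs2$coh[cs2$freqs > 1 & cs2$freqs < 40]), 0.97)
})

test_that("coherence is symmetric and matches the direct cross-spectrum oracle", {
  set.seed(21)
  x <- rnorm(2250) # 9 s at 250 Hz -> 17 segments
  y <- rnorm(2250)
  cs <- coherence(x, y, 250)
  sc <- coherence(y, x, 250)
  expect_equal(cs$coh, sc$coh, tolerance = 1e-14)
  orc <- oracle_coherence(x, y, 250)
  expect_equal(cs$freqs, orc$freqs)
  expect_equal(cs$coh, orc$coh, tolerance = 1e-10)
  expect_true(all(cs$coh >= 0 & cs$coh <= 1))
  # band coherence of independent noise is small and shrinks with more
  # averaging segments
  short <- coherence(x[1:1000], y[1:1000], 250)
  expect_lt(mean(cs$coh), mean(short$coh))
  expect_lt(mean(cs$coh), 0.4)
})

test_that("coherence equals 1 when y is a noiseless linear filter of x", {
  set.seed(22)
  x <- rnorm(2000)
  y <- stats::filter(x, c(0.5, 0.3, 0.2), sides = 1)
  keep <- !is.na(y)
  cs <- coherence(x[keep], as.numeric(y[keep]), 250)
  expect_gt(mean(cs$coh[cs$freqs > 1 & cs$freqs < 100]), 0.95)
})

test_that("fewer than three averaging segments are rejected", {
  expect_error(coherence(rnorm(300), rnorm(300), 250), "3 averaging segments")
})

test_that("network coherence has the combinatorial column count", {
  # 2 networks x 2 labels each, 2 bands -> 2 x 3 network pairs + named pairs
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 3, n_labels = 4,
                    n_channels = 2, seed = 23)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  map <- batseeg:::toy_network_map(cfg$label_names,
                                   networks = c("AUN", "DMN"))
  pair <- list(c("lh_label01", "rh_label01"))
  fm <- network_coherence(lts, map, bands = c("alpha", "gamma"),
                          pair_spec = pair)
  expect_identical(ncol(fm$values), 2L * (3L + 1L))
  expect_true(all(fm$values >= 0 & fm$values <= 1))
  expect_identical(nrow(fm$values), 3L)
  # empty networks are rejected
  map_bad <- map; map_bad$network <- "AUN"; map_bad$aun <- TRUE
  expect_error(
    network_coherence(lts, map_bad[map_bad$label != "zzz", ][0, ],
                      bands = "alpha"),
    "does not cover")
})

test_that("a planted shared alpha source is the top connectivity separator", {
  cfg <- toy_config(
    n_pos = 8, n_neg = 8, n_epochs = 8, n_labels = 6, n_channels = 2,
    coherence_effects = list(
      list(pair = c("lh_label01", "rh_label01"), band = "alpha",
           mixing = c(pos = 0.8, neg = 0.05))),
    seed = 24)
  map <- batseeg:::toy_network_map(cfg$label_names,
                                   networks = c("AUN", "DMN", "VSN"))
  pair <- list(c("lh_label01", "rh_label01"), c("lh_label02", "rh_label02"))
  fms <- list()
  for (i in seq_len(16)) {
    g <- if (i <= 8) "pos" else "neg"
    lts <- simulate_label_signals(cfg, g, sprintf("S%02d", i),
                                  subject_index = i)
    fms[[i]] <- network_coherence(lts, map, bands = c("alpha", "gamma"),
                                  pair_spec = pair)
  }
  fm <- stack_features(fms)
  grp <- fm$rows$group
  tvals <- apply(fm$values, 2, function(v) {
    abs(t.test(v[grp == "pos"], v[grp == "neg"])$statistic)
  })
  planted <- fm$meta$feature == "coh_alpha_lh_label01~rh_label01"
  expect_identical(unname(which.max(tvals)), unname(which(planted)))
})

test_that("all-independent labels show no group structure in coherence", {
  cfg <- toy_config(n_pos = 6, n_neg = 6, n_epochs = 6, n_labels = 4,
                    n_channels = 2, seed = 25)
  map <- batseeg:::toy_network_map(cfg$label_names,
                                   networks = c("AUN", "DMN"))
  fms <- list()
  for (i in seq_len(12)) {
    g <- if (i <= 6) "pos" else "neg"
    lts <- simulate_label_signals(cfg, g, sprintf("S%02d", i),
                                  subject_index = i)
    fms[[i]] <- network_coherence(lts, map, bands = "alpha",
                                  pair_spec = list())
  }
  fm <- stack_features(fms)
  grp <- fm$rows$group
  pvals <- apply(fm$values, 2, function(v) {
    t.test(v[grp == "pos"], v[grp == "neg"])$p.value
  })
  expect_gt(min(pvals), 0.001) # nothing wildly significant
})
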