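test_that("source band power has labels-times-bands columns", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 2, n_labels = 68,
                    n_channels = 2, seed = 15)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  fm <- label_band_power(lts)
  expect_identical(ncol(fm$values), 340L)
  expect_true(all(fm$meta$family == "source_power"))
  expect_identical(sort(unique(fm$meta$unit)), sort(dk_labels()))
  # 10-label toy atlas -> 50 columns
  cfg10 <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 2, n_labels = 10,
                      n_channels = 2, seed = 15)
  fm10 <- label_band_power(simulate_label_signals(cfg10, "pos", "S1"))
  expect_identical(ncol(fm10$values), 50L)
})

test_that("unknown label names are rejected with the offenders listed", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 2, n_labels = 4,
                    n_channels = 2, seed = 16)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  lts$label_names[2] <- "lh_mystery"
  expect_error(label_band_power(lts, known_labels = dk_labels()),
               "lh_mystery")
})

test_that("identical label signals give identical feature columns", {
  cfg <- toy_config(n_pos = 1, n_neg = 1, n_epochs = 4, n_labels = 4,
                    n_channels = 2, seed = 17)
  lts <- simulate_label_signals(cfg, "pos", "S1")
  lts$data[, 2, ] <- lts$data[, 1, ]
  fm <- label_band_power(lts)
  a <- fm$values[, fm$meta$unit == "lh_label01"]
  b <- fm$values[, fm$meta$unit == "rh_label01"]
  expect_equal(unname(a), unname(b))
})

test_that("a planted alpha difference is detectable in that label's column", {
  cfg <- toy_config(n_pos = 12, n_neg = 12, n_epochs = 10, n_labels = 4,
                    n_channels = 2, alpha_d = 1.2, seed = 18)
  m <- vapply(seq_len(24), function(i) {
    g <- if (i <= 12) "pos" else "neg"
    lts <- simulate_label_signals(cfg, g, paste0("S", i), subject_index = i)
    fm <- label_band_power(lts)
    mean(log(fm$values[, fm$meta$feature == "src_alpha_rh_label01"]))
  }, numeric(1))
  g <- rep(c("pos", "neg"), each = 12)
  d <- (mean(m[g == "pos"]) - mean(m[g == "neg"])) /
    sqrt((var(m[g == "pos"]) + var(m[g == "neg"])) / 2)
  expect_gt(d, 0.5)
})

test_that("the default network map covers the full atlas", {
  map <- default_network_map()
  expect_identical(sort(map$label), sort(dk_labels()))
  expect_true(all(map$network %in%
                  c("VSN", "SMN", "DAN", "VAN", "LBN", "FPN", "DMN", "DGN")))
  expect_true(any(map$aun))
  expect_true(all(c("lh_transversetemporal", "rh_superiortemporal") %in%
                  map$label[map$aun]))
})
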