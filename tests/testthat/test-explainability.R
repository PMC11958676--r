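test_that("gini importance is normalized and finds a planted separator", {
  set.seed(50)
  n <- 300
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  X <- cbind(sep = ifelse(y == "pos", 2, -2) + rnorm(n, 0, 0.4),
             matrix(rnorm(n * 9), n))
  colnames(X) <- c("sep", paste0("noise", 1:9))
  rf <- ranger::ranger(x = X, y = y, num.trees = 50, probability = TRUE,
                       seed = 1, num.threads = 1)
  gi <- gini_importance(rf, X, y)
  expect_equal(sum(gi$gini_mean), 1, tolerance = 1e-9)
  expect_true(all(gi$gini_mean >= 0))
  expect_gt(gi$gini_mean[gi$feature == "sep"], 0.5)
  expect_true(all(gi$gini_std >= 0))
  expect_error(gini_importance(lm(rnorm(10) ~ 1), X, y), "tree ensembles")
})

test_that("label-independent features get roughly uniform importance", {
  ratios <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(300 * 6), 300)
    colnames(X) <- paste0("f", 1:6)
    y <- factor(sample(rep(c("neg", "pos"), 150)), levels = c("neg", "pos"))
    rf <- ranger::ranger(x = X, y = y, num.trees = 50, probability = TRUE,
                         seed = s, num.threads = 1)
    gi <- gini_importance(rf, X, y)
    max(gi$gini_mean) / min(gi$gini_mean)
  }, numeric(1))
  expect_lt(max(ratios), 3)
})

test_that("signed contributions satisfy local accuracy", {
  tf <- toy_forest(n = 300, p = 6, num.trees = 40, max.depth = 8, seed = 2)
  sc <- signed_contributions(tf$ens, tf$X[1:50, ])
  recon <- sc$base_value + rowSums(sc$contributions)
  expect_lt(max(abs(recon - sc$prediction)), 1e-6)
  # and the engine's predictions equal the forest's
  theirs <- predict(tf$rf, tf$X[1:50, ], num.threads = 1)$predictions[, "pos"]
  expect_equal(unname(sc$prediction), unname(theirs), tolerance = 1e-12)
})

test_that("path attribution equals exhaustive Shapley enumeration", {
  for (s in 1:3) {
    tf <- toy_forest(n = 150, p = 5, num.trees = 8, max.depth = 4, seed = s)
    sc <- signed_contributions(tf$ens, tf$X[1:6, ])
    for (i in 1:6) {
      ex <- exhaustive_shapley(tf$ens, tf$X[i, ])
      expect_lt(max(abs(ex$phi - sc$contributions[i, ])), 1e-8)
      expect_lt(abs(ex$base - sc$base_value), 1e-10)
    }
  }
})

test_that("a constant model attributes nothing", {
  # one-node trees: a single leaf, no splits
  leaf <- matrix(c(0, 0, 0, 0, 0.37, 100), 1,
                 dimnames = list(NULL, batseeg:::tree_cols))
  ens <- tree_ensemble(list(leaf, leaf), feature_names = c("a", "b"))
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  sc <- signed_contributions(ens, X)
  expect_true(all(sc$contributions == 0))
  expect_equal(sc$base_value, 0.37)
  expect_equal(unname(sc$prediction), rep(0.37, 5))
})

test_that("class aggregation sums per class and validates metadata", {
  tf <- toy_forest(n = 200, p = 4, num.trees = 10, seed = 3)
  sc <- signed_contributions(tf$ens, tf$X[1:30, ])
  meta <- data.frame(feature = paste0("x", 1:4),
                     family = c("band_power", "band_power", "entropy",
                                "aperiodic_offset"),
                     band = c("alpha", "gamma", "alpha", NA),
                     unit = "Cz", hemisphere = "mid")
  agg <- class_aggregate(sc, meta)
  expect_setequal(agg$class, c("alpha band_power", "gamma band_power",
                               "alpha entropy", "aperiodic_offset"))
  expect_equal(sum(agg$importance), sum(colMeans(abs(sc$contributions))),
               tolerance = 1e-12)
  # single class covering everything equals the total
  meta1 <- meta; meta1$family <- "band_power"; meta1$band <- "alpha"
  agg1 <- class_aggregate(sc, meta1)
  expect_identical(nrow(agg1), 1L)
  # unmapped features are rejected
  expect_error(class_aggregate(sc, meta[1:3, ]), "missing from metadata")
})

test_that("partial dependence is flat for ignored features and handles 1-point grids", {
  tf <- toy_forest(n = 200, p = 4, num.trees = 20, seed = 4)
  # x3 and x4 are noise; the forest may split on them a little, so compare
  # against the surface range for the informative pair
  pd_noise <- partial_dependence_2d(tf$ens, tf$X, "x3", "x4",
                                    grid_x = c(-1, 0, 1),
                                    grid_y = c(-1, 0, 1))
  pd_info <- partial_dependence_2d(tf$ens, tf$X, "x1", "x2",
                                   grid_x = c(-2, 0, 2),
                                   grid_y = c(-2, 0, 2))
  expect_lt(diff(range(pd_noise$surface)),
            0.2 * diff(range(pd_info$surface)))
  # informative surface increases along its feature's axis
  expect_gt(pd_info$surface[3, 2], pd_info$surface[1, 2])
  pd1 <- partial_dependence_2d(tf$ens, tf$X, "x1", "x2",
                               grid_x = 0, grid_y = 0)
  work <- tf$X; work[, 1] <- 0; work[, 2] <- 0
  expect_equal(pd1$surface[1, 1], mean(predict(tf$ens, work)))
  expect_error(partial_dependence_2d(tf$ens, tf$X, "x1", "x2",
                                     grid_x = numeric(0), grid_y = 1),
               "empty")
})
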