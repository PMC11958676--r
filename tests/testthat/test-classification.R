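cc_of <- function(tp, fn, fp, tn) {
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn),
            class = "confusion_counts")
}

test_that("threat-score accuracy matches hand-computed values", {
  expect_equal(eq1_accuracy(cc_of(3, 1, 1, 0)), 0.6)
  expect_equal(eq1_accuracy(cc_of(10, 0, 0, 5)), 1.0)
  counts <- cc_of(50, 25, 25, 100)
  expect_equal(eq1_accuracy(counts), 0.5)
  expect_equal(standard_accuracy(counts), 0.75)
  expect_warning(v <- eq1_accuracy(cc_of(0, 0, 0, 9)), "undefined")
  expect_true(is.na(v))
  # eq1 <= standard accuracy whenever tn > 0; equality when tn = 0
  set.seed(40)
  for (i in 1:50) {
    cts <- cc_of(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1),
                 sample(0:20, 1))
    if (cts$tp + cts$fn + cts$fp == 0) next
    e1 <- eq1_accuracy(cts)
    expect_equal(e1, cts$tp / (cts$tp + cts$fn + cts$fp))
    if (cts$tn > 0) expect_lte(e1, standard_accuracy(cts))
    if (cts$tn == 0) expect_equal(e1, standard_accuracy(cts))
  }
})

test_that("outcome binarization respects scale, boundary and inheritance", {
  outz <- data.frame(subject_id = c("A", "B", "C"),
                     scale = "zurich_0_neg5", score = c(-3, 0, -1))
  lab <- binarize_outcome(outz)
  expect_identical(as.character(lab), c("pos", "neg", "pos"))
  outr <- data.frame(subject_id = c("A", "B"),
                     scale = "regensburg_0_100", score = c(90, 90.1))
  labr <- binarize_outcome(outr, 90)
  expect_identical(as.character(labr), c("pos", "neg")) # boundary is +BATS
  rows <- data.frame(subject_id = c("A", "A", "B"))
  expect_identical(as.character(binarize_outcome(outr, 90, rows)),
                   c("pos", "pos", "neg"))
  mixed <- rbind(outz, data.frame(subject_id = "D",
                                  scale = "regensburg_0_100", score = 50))
  expect_error(binarize_outcome(mixed), "mix scales")
})

test_that("every suite member solves a linearly separable problem", {
  sep <- separable_fm(n = 160)
  res <- run_suite(sep$fm, sep$labels, split_spec(seed = 2, cv_folds = 3))
  for (r in res$results) {
    expect_true(is.na(r$error), info = r$classifier)
    expect_equal(r$eq1_accuracy, 1.0, info = r$classifier)
  }
})

test_that("label-independent features score near chance", {
  accs <- vapply(1:8, function(s) {
    fm <- noise_fm(400, 5, seed = s)
    set.seed(s + 100)
    labels <- factor(sample(rep(c("neg", "pos"), 200)),
                     levels = c("neg", "pos"))
    rs <- run_suite(fm, labels, split_spec(seed = s), suite = "rf",
                    cv = FALSE)
    rs$results$rf$standard_accuracy
  }, numeric(1))
  expect_lt(max(abs(accs - 0.5)), 0.12)
  expect_lt(abs(mean(accs) - 0.5), 0.07)
})

test_that("runs are reproducible under a fixed seed", {
  sep <- separable_fm(n = 100, seed = 3)
  r1 <- run_suite(sep$fm, sep$labels, split_spec(seed = 9, cv_folds = 3),
                  suite = c("rf", "dtree"))
  r2 <- run_suite(sep$fm, sep$labels, split_spec(seed = 9, cv_folds = 3),
                  suite = c("rf", "dtree"))
  expect_identical(r1$train_idx, r2$train_idx)
  expect_identical(summary(r1), summary(r2))
})

test_that("the shuffled-label control behaves like a permutation null", {
  cfg <- toy_config(n_pos = 8, n_neg = 8, n_epochs = 12, n_channels = 4,
                    n_labels = 4, alpha_d = 1.5, gamma_d = 1.5,
                    aperiodic_effect = c(offset = -0.3, slope = 0.3),
                    seed = 41)
  feats <- cohort_features(cfg, families = "sensor")
  labels <- binarize_outcome(feats$outcomes, rows = feats$sensor$rows)
  sp <- split_spec(seed = 4)
  base <- run_suite(feats$sensor, labels, sp, suite = "rf", cv = FALSE)
  shuf <- shuffled_label_control(feats$sensor, labels, sp, cv = FALSE)
  expect_gt(base$results$rf$standard_accuracy,
            shuf$results$rf$standard_accuracy)
  # identity permutation reproduces the unshuffled run exactly
  ident <- shuffled_label_control(feats$sensor, labels, sp,
                                  permutation = seq_along(labels),
                                  cv = FALSE)
  expect_identical(summary(ident), summary(base))
})

test_that("threshold sweep covers the grid and flags degenerate cells", {
  sep <- separable_fm(n = 100, seed = 5)
  # outcomes: +BATS subjects score 60, -BATS 95
  outcomes <- data.frame(
    subject_id = sprintf("S%03d", seq_len(100)),
    scale = "regensburg_0_100",
    score = ifelse(sep$labels == "pos", 60, 95))
  class(outcomes) <- c("subject_outcomes", "data.frame")
  fm <- sep$fm
  fm$rows$subject_id <- outcomes$subject_id
  tab <- threshold_sweep(fm, outcomes, thresholds = c(90, 70, 50),
                         split = split_spec(seed = 6, cv_folds = 3),
                         suite = c("rf", "nbayes"))
  expect_identical(nrow(tab), 6L) # 3 thresholds x 2 classifiers
  expect_true(all(tab$degenerate[tab$threshold == 50])) # below all scores
  ok <- tab$threshold %in% c(90, 70)
  expect_true(all(!tab$degenerate[ok]))
  expect_true(all(tab$eq1_accuracy[ok] == 1))
})

test_that("top-k retraining keeps informative features and the k = p case", {
  set.seed(42)
  n <- 300
  labels <- factor(rep(c("neg", "pos"), each = n / 2),
                   levels = c("neg", "pos"))
  signal <- ifelse(labels == "pos", 1.5, -1.5)
  X <- cbind(matrix(rnorm(n * 30), n), s1 = signal + rnorm(n, 0, 0.5))
  fm <- feature_matrix(X, data.frame(
    feature = c(sprintf("n%02d", 1:30), "s1"),
    family = "band_power", band = "alpha", unit = "Cz", hemisphere = "mid"))
  tk <- top_k_retrain(fm, labels, split_spec(seed = 7, cv_folds = 3), k = 5)
  expect_true("s1" %in% tk$selected)
  # k = 1 on a one-informative-feature problem is almost as good as all
  tk1 <- top_k_retrain(fm, labels, split_spec(seed = 7, cv_folds = 3), k = 1)
  base <- run_suite(fm, labels, split_spec(seed = 7, cv_folds = 3),
                    suite = "rf")
  expect_lt(abs(tk1$suite$results$rf$standard_accuracy -
                base$results$rf$standard_accuracy), 0.05)
  # k larger than p clamps with a warning and equals the baseline split
  expect_warning(tk_all <- top_k_retrain(fm, labels,
                                         split_spec(seed = 7, cv_folds = 3),
                                         k = 500), "clamp")
  expect_identical(length(tk_all$selected), ncol(fm$values))
})

test_that("epoch-level splits leak subject identity relative to subject-level", {
  # strong subject fingerprints, weak group effect: epoch-level accuracy
  # should beat subject-level accuracy
  cfg <- toy_config(n_pos = 6, n_neg = 6, n_epochs = 20, n_channels = 4,
                    n_labels = 4, alpha_d = 0.4, subject_sd = 0.8,
                    seed = 43)
  feats <- cohort_features(cfg, families = "sensor")
  labels <- binarize_outcome(feats$outcomes, rows = feats$sensor$rows)
  acc_ep <- run_suite(feats$sensor, labels,
                      split_spec(seed = 8, mode = "epoch_level"),
                      suite = "rf", cv = FALSE)$results$rf$standard_accuracy
  acc_su <- run_suite(feats$sensor, labels,
                      split_spec(seed = 8, mode = "subject_level"),
                      suite = "rf", cv = FALSE)$results$rf$standard_accuracy
  expect_gte(acc_ep, acc_su)
})
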