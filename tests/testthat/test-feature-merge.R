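test_that("exact duplicates are dropped in favour of the first column", {
  fm <- noise_fm(100, 3)
  fm$values[, 3] <- fm$values[, 1]
  mg <- merge_correlated(fm)
  expect_identical(mg$report$kept, c("f001", "f002"))
  expect_identical(unname(mg$report$dropped), "f001")
  expect_identical(names(mg$report$dropped), "f003")
  # anti-correlated duplicate is caught too (|r| is used)
  fm2 <- noise_fm(100, 2)
  fm2$values[, 2] <- -fm2$values[, 1]
  expect_identical(names(merge_correlated(fm2)$report$dropped), "f002")
})

test_that("correlation chains merge transitively into one component", {
  # a-b and b-c above threshold, a-c below: still one component of 3
  set.seed(30)
  n <- 4000
  z1 <- rnorm(n); z2 <- rnorm(n)
  a <- z1
  b <- 0.95 * z1 + sqrt(1 - 0.95^2) * z2
  cc <- 0.95 * b + sqrt(1 - 0.95^2) * rnorm(n)
  fm <- feature_matrix(cbind(a, b, cc),
                       data.frame(feature = c("a", "b", "c"),
                                  family = "band_power", band = "alpha",
                                  unit = "Cz", hemisphere = "mid"))
  C <- abs(cor(fm$values))
  expect_gt(C["a", "b"], 0.9); expect_gt(C["b", "c"], 0.9)
  expect_lt(C["a", "c"], 0.95)
  mg <- merge_correlated(fm)
  expect_identical(length(mg$report$groups), 1L)
  expect_identical(sort(mg$report$groups[[1]]), c("a", "b", "c"))
  expect_identical(mg$report$kept, "a")
})

test_that("independent columns survive merging across seeds", {
  for (s in 1:5) {
    fm <- noise_fm(500, 10, seed = s)
    mg <- merge_correlated(fm)
    expect_identical(length(mg$report$dropped), 0L)
    expect_identical(ncol(mg$fm$values), 10L)
  }
})

test_that("merging is idempotent and kept pairs stay below the threshold", {
  set.seed(31)
  base <- matrix(rnorm(200 * 4), 200)
  X <- cbind(base,
             base[, 1] + rnorm(200, 0, 0.1),
             base[, 2] + rnorm(200, 0, 0.1))
  fm <- feature_matrix(X, data.frame(feature = sprintf("f%d", 1:6),
                                     family = "band_power", band = "alpha",
                                     unit = "Cz", hemisphere = "mid"))
  mg <- merge_correlated(fm)
  kept_cor <- abs(cor(mg$fm$values))
  diag(kept_cor) <- 0
  expect_lte(max(kept_cor), 0.9)
  again <- merge_correlated(mg$fm)
  expect_identical(length(again$report$dropped), 0L)
  # report round-trip: kept + dropped = original columns
  expect_identical(length(mg$report$kept) + length(mg$report$dropped), 6L)
})

test_that("constant columns and single-row input are handled explicitly", {
  fm <- noise_fm(50, 3)
  fm$values[, 2] <- 7
  expect_warning(mg <- merge_correlated(fm), "constant")
  expect_identical(mg$report$constant, "f002")
  one_row <- feature_matrix(matrix(1:3, 1),
                            data.frame(feature = c("a", "b", "c"),
                                       family = "band_power", band = "alpha",
                                       unit = "Cz", hemisphere = "mid"))
  expect_error(merge_correlated(one_row), "fewer than 2 rows")
})
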