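test_that("the outlier fence is single-pass and strict-outside", {
  expect_equal(filter_outliers(rep(25, 5)), rep(25, 5))  # IQR 0, all equal kept

  # hand-computed fences: 100 tight values plus one far outlier
  withr::local_seed(2)
  x <- c(25 + runif(100, -0.1, 0.1), 80)
  kept <- filter_outliers(x)
  expect_equal(length(kept), 100L)
  expect_false(80 %in% kept)

  expect_error(filter_outliers(c(1, 2, 3)),
               class = "thermoleaf_insufficient_data_error")
})

test_that("under normality the fence removes about 0.7% of values", {
  withr::local_seed(31)
  x <- rnorm(1e5)
  frac <- 1 - length(filter_outliers(x)) / length(x)
  # asymptotic two-sided 1.5 IQR exceedance for a normal is ~0.70%
  expect_gt(frac, 0.004)
  expect_lt(frac, 0.011)
})

test_that("indicators follow the type-7 quantile oracle", {
  m <- matrix(1, 101, 101)
  m[, 1] <- 1:101
  fr <- thermal_frame(m, range_check = NULL)
  mask <- matrix(FALSE, 101, 101); mask[, 1] <- TRUE
  f <- extract_features(fr, leaf_mask(mask), multiplier = 1e9)  # fence disabled
  expect_equal(f$median, 51)
  expect_equal(f$p25, 26)
  expect_equal(f$p75, 76)
  expect_equal(f$iqr, 50)
  expect_equal(f$range, 100)
  expect_equal(f$p25, oracle_quantile7(1:101, 0.25))
})

test_that("a constant masked region gives degenerate indicators", {
  fr <- make_frame(25, 12, 12)
  mask <- matrix(FALSE, 12, 12); mask[2:11, 2:11] <- TRUE
  f <- extract_features(fr, leaf_mask(mask))
  expect_equal(f$mean, 25); expect_equal(f$median, 25)
  expect_equal(f$p25, 25); expect_equal(f$p75, 25)
  expect_equal(f$std, 0); expect_equal(f$iqr, 0); expect_equal(f$range, 0)
  expect_equal(f$n_pixels_used, 100L)
  expect_equal(f$n_outliers_removed, 0L)
})

test_that("order invariants hold for random masked samples", {
  withr::local_seed(12)
  for (rep in 1:20) {
    m <- matrix(rnorm(400, 25, runif(1, 0.1, 3)), 20, 20)
    fr <- thermal_frame(m, range_check = NULL)
    mask <- matrix(runif(400) < 0.5, 20, 20)
    if (sum(mask) < 15) next
    f <- extract_features(fr, leaf_mask(mask))
    expect_true(f$min <= f$p25)
    expect_true(f$p25 <= f$median)
    expect_true(f$median <= f$p75)
    expect_true(f$p75 <= f$max)
    expect_equal(f$iqr, f$p75 - f$p25)
    expect_equal(f$range, f$max - f$min)
    expect_gte(f$std, 0)
  }
})

test_that("pixel floor violations raise informative errors", {
  fr <- make_frame(25)
  tiny <- matrix(FALSE, 10, 12); tiny[1, 1:3] <- TRUE
  expect_error(extract_features(fr, leaf_mask(tiny)),
               class = "thermoleaf_insufficient_data_error")
  small <- matrix(FALSE, 10, 12); small[1, 1:6] <- TRUE
  expect_error(extract_features(fr, leaf_mask(small), min_pixels = 10),
               class = "thermoleaf_insufficient_data_error")
})

test_that("sample and population standard deviations differ as expected", {
  fr <- thermal_frame(matrix(c(1:64), 8, 8), range_check = NULL)
  mask <- leaf_mask(matrix(TRUE, 8, 8) & (matrix(1:64, 8, 8) <= 16))
  fs <- extract_features(fr, mask, multiplier = 1e9)
  fp <- extract_features(fr, mask, multiplier = 1e9, sd_type = "population")
  n <- fs$n_pixels_used
  expect_equal(fp$std, fs$std * sqrt((n - 1) / n))
})

test_that("the fence absorbs 1-px mask dilation on high-contrast scenes", {
  # effective invariance: with a 5 degC leaf-backdrop contrast, dilating the
  # mask 1 px into the backdrop moves the location indicators by < 1% of the
  # contrast and every indicator by < 10%; unfiltered, the same dilation
  # drags min by ~100% of the contrast and mean by ~10%
  contrast <- 5
  for (i in 1:5) {
    sp <- leaf_scene_spec(noise_sd = 0, blur_sigma = 0, leaf_temp_sd = 0.3,
                          background_temp = 22, leaf_temp_mean = 22 + contrast,
                          rotation = i * 0.5, seed = 40 + i)
    s <- generate_leaf_scene(sp)
    dil <- EBImage::dilate(s$truth_mask$values * 1, EBImage::makeBrush(3, "disc")) > 0
    ring <- sum(dil) - sum(s$truth_mask$values)
    expect_lt(ring / sum(dil), 0.25)  # contamination stays a minority
    f0 <- extract_features(s$frame, s$truth_mask)
    f1 <- extract_features(s$frame, leaf_mask(dil))
    for (nm in c("mean", "median", "p25", "p75")) {
      expect_lt(abs(f1[[nm]] - f0[[nm]]), 0.01 * contrast)
    }
    for (nm in thermal_feature_names()) {
      expect_lt(abs(f1[[nm]] - f0[[nm]]), 0.10 * contrast)
    }
    # the whole contaminating ring is fenced out
    expect_gte(f1$n_outliers_removed, ring)
    # without the fence the backdrop leaks straight into the extremes
    fu <- extract_features(s$frame, leaf_mask(dil), multiplier = 1e9)
    expect_gt(abs(fu$min - f0$min), 0.5 * contrast)
  }
})
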