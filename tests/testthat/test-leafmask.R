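test_that("fences follow the quartile arithmetic", {
  # constructed so q1 = 10 and q3 = 20 exactly under type-7 interpolation
  v <- matrix(c(10, 10, 20, 20), 2, 2)
  f <- compute_fences(v)
  expect_equal(f$q1, 10)
  expect_equal(f$q3, 20)
  expect_equal(f$iqr, 10)
  expect_equal(f$thr_dw, 10 - 1.5 * 10)
  expect_equal(f$thr_up, 20 + 1.5 * 10)

  # degenerate constant gradient
  fc <- compute_fences(matrix(3.5, 5, 5))
  expect_equal(fc$thr_dw, 3.5)
  expect_equal(fc$thr_up, 3.5)

  # against the independent sort-and-interpolate oracle
  withr::local_seed(4)
  g <- matrix(runif(100, 0, 99), 10, 10)
  f2 <- compute_fences(g)
  expect_equal(f2$q1, oracle_quantile7(as.numeric(g), 0.25))
  expect_equal(f2$q3, oracle_quantile7(as.numeric(g), 0.75))
})

test_that("binarization applies the fence rule in both modes", {
  g <- matrix(c(0, 0, 0, 0, 100, 0, 0, 0, 0), 3, 3)
  f <- compute_fences(g)
  m <- binarize_gradient(g, f, mode = "two_sided")
  expect_identical(which(m$values), which(g == 100))

  # everything inside the fences -> empty raw mask
  flat <- matrix(rep(c(10, 11, 12, 13), 4), 4, 4)
  ff <- compute_fences(flat)
  expect_equal(sum(binarize_gradient(flat, ff)$values), 0)

  # literal lower-only clause is vacuous for non-negative gradients
  fneg <- compute_fences(matrix(runif(64, 0, 5), 8, 8))
  expect_lt(fneg$thr_dw, 0)
  expect_equal(sum(binarize_gradient(matrix(runif(64, 0, 5), 8, 8), fneg,
                                     mode = "low_only")$values), 0)
})

test_that("refinement keeps the largest blob and fills holes", {
  raw <- matrix(FALSE, 40, 60)
  raw[5:14, 5:9] <- TRUE        # 50 px blob
  raw[25:34, 40:42] <- TRUE     # 30 px blob, well separated
  out <- refine_mask(leaf_mask(raw), struct_radius = 1, erode_radius = 1,
                     min_area = 10)
  lab <- EBImage::bwlabel(out$values * 1)
  expect_equal(max(lab), 1)
  # survivor descends from the bigger blob
  expect_gt(sum(out$values[5:14, 5:9]), 0)
  expect_equal(sum(out$values[25:34, 40:42]), 0)

  # an annulus comes back as a solid disk
  ring <- matrix(FALSE, 40, 40)
  rr <- row(ring) - 20; cc <- col(ring) - 20
  d <- sqrt(rr^2 + cc^2)
  ring[d >= 8 & d <= 11] <- TRUE
  solid <- refine_mask(leaf_mask(ring), struct_radius = 2, erode_radius = 2,
                       min_area = 10)
  expect_true(all(solid$values[d <= 5]))
})

test_that("refinement failures carry diagnostics", {
  expect_error(refine_mask(leaf_mask(matrix(FALSE, 20, 20))),
               class = "thermoleaf_segmentation_error")
  # speckles below min_area fail too
  sp <- matrix(FALSE, 30, 30); sp[4:5, 4:5] <- TRUE
  err <- tryCatch(refine_mask(leaf_mask(sp), struct_radius = 1, erode_radius = 1,
                              min_area = 50),
                  error = function(e) e)
  expect_s3_class(err, "thermoleaf_segmentation_error")
  expect_match(conditionMessage(err), "min_area")
})

test_that("4- and 8-connectivity labeling agree on solid blobs", {
  raw <- matrix(FALSE, 30, 30)
  raw[10:20, 10:20] <- TRUE
  m8 <- refine_mask(leaf_mask(raw), struct_radius = 1, erode_radius = 1,
                    connectivity = 8, min_area = 10)
  m4 <- refine_mask(leaf_mask(raw), struct_radius = 1, erode_radius = 1,
                    connectivity = 4, min_area = 10)
  expect_identical(m8$values, m4$values)
})

test_that("segmentation recovers synthetic leaves and is deterministic", {
  ious <- iou_benchmark(noise_sd = 0.2, blur_sigma = 1)
  expect_gte(mean(ious), 0.80)

  sharp <- iou_benchmark(noise_sd = 0, blur_sigma = 0, leaf_temp_sd = 0)
  expect_gte(mean(sharp), 0.90)

  s <- generate_leaf_scene(leaf_scene_spec(seed = 30, leaf_temp_mean = 25))
  expect_identical(segment_leaf(s$frame)$values, segment_leaf(s$frame)$values)
})

test_that("final masks are single components, never the whole frame", {
  for (i in 1:5) {
    s <- generate_leaf_scene(leaf_scene_spec(seed = 100 + i, leaf_temp_mean = 25.5,
                                             rotation = i))
    mk <- segment_leaf(s$frame)
    expect_equal(max(EBImage::bwlabel(mk$values * 1)), 1)
    expect_lt(sum(mk$values), length(mk$values))
  }
})

test_that("segmentation is invariant to a constant temperature offset", {
  s <- generate_leaf_scene(leaf_scene_spec(seed = 17, leaf_temp_mean = 25))
  base <- segment_leaf(s$frame)
  for (off in c(-10, 10)) {
    shifted <- thermal_frame(s$frame$values + off)
    expect_identical(segment_leaf(shifted)$values, base$values)
  }
})

test_that("a leafless frame fails segmentation cleanly", {
  withr::local_seed(55)
  flat <- thermal_frame(matrix(22 + rnorm(96 * 128, 0, 0.2), 96, 128))
  expect_error(segment_leaf(flat, min_area = 400),
               class = "thermoleaf_segmentation_error")
})
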