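test_that("clip_hu saturates, is idempotent and monotone", {
  expect_equal(clip_hu(-1000, -325, 400), -325)
  expect_equal(clip_hu(37, -325, 400), 37)
  expect_equal(clip_hu(1e6, -325, 400), 400)
  expect_error(clip_hu(0, 10, 10), "smaller")
  set.seed(1)
  x <- array(rnorm(1000, 0, 500), c(10, 10, 10))
  once <- clip_hu(x)
  expect_equal(clip_hu(once), once)                 # idempotent
  y <- x + abs(rnorm(1000, 0, 50))                  # y >= x everywhere
  expect_true(all(clip_hu(array(y, dim(x))) >= once))  # monotone
})

test_that("foreground quantile bounds use linear-interpolation quantiles", {
  v <- array(0, c(10, 10, 10)); v[1:1000] <- 1:1000
  m <- array(1L, c(10, 10, 10))
  b <- foreground_quantile_bounds(list(v), list(m), 0.005, 0.995)
  expect_equal(b, c(5.995, 995.005))                # 1 + 0.005 * 999, etc.
  # constant foreground collapses to (c, c)
  vc <- array(42, c(4, 4, 4)); mc <- array(1L, c(4, 4, 4))
  expect_equal(foreground_quantile_bounds(list(vc), list(mc)), c(42, 42))
  # pooling is invariant under duplicating a case
  expect_equal(foreground_quantile_bounds(list(v, v), list(m, m)), b)
  expect_error(foreground_quantile_bounds(list(v), list(array(0L, dim(v)))),
               "foreground")
})

test_that("z-score normalisation follows its closed form", {
  v <- array(37.5, c(3, 3, 3))
  expect_equal(normalize_volume(v, list(mean = 37.5, sd = 10)),
               array(0, c(3, 3, 3)))
  x <- array(c(-325, 400), c(2, 1, 1))
  out <- normalize_volume(x, list(mean = 37.5, sd = 362.5))
  expect_equal(as.vector(out), c(-1, 1))
  expect_equal(normalize_volume(x, list(mean = 0, sd = 1)), x)
  expect_error(normalize_volume(x, list(mean = 0, sd = 0)), "positive")
})

test_that("resampling preserves content and the label alphabet", {
  set.seed(2)
  v <- new_volume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1, 1, 1))
  same <- resample_volume(v, c(1, 1, 1))
  expect_equal(same$voxels, v$voxels)               # identity at own spacing
  l <- new_label_map(random_labels(c(16, 16, 16)), spacing = c(1, 1, 1))
  r <- resample_labels(l, c(0.7, 1.3, 1))
  expect_true(all(r$labels %in% 0:2))
  # down-then-up of a smooth volume stays within its intensity SD
  smooth <- array(gauss_smooth3(rnorm(16^3), c(16L, 16L, 16L), c(2, 2, 2)),
                  c(16, 16, 16))
  vs <- new_volume(smooth, spacing = c(1, 1, 1))
  down <- resample_volume(vs, c(2, 2, 2))
  up <- resample_volume(down, c(1, 1, 1))
  expect_lt(mean(abs(up$voxels - vs$voxels)), sd(vs$voxels))
})

test_that("fitted preprocessing brackets the muscle intensity and aligns modalities", {
  cs <- generate_case(small_spec(), 9)
  b <- foreground_quantile_bounds(list(cs$ct), list(cs$truth))
  expect_lt(b[1], 60); expect_gt(b[2], 60)
  stats <- fit_preprocess(list(cs$ct, cs$cbct), list(cs$truth, cs$truth))
  ct_n <- apply_preprocess(cs$ct, stats)
  cb_n <- apply_preprocess(cs$cbct, stats)
  fg <- cs$truth$labels != 0
  # overlapping foreground supports: the premise of joint training
  lo <- max(min(ct_n$voxels[fg]), min(cb_n$voxels[fg]))
  hi <- min(max(ct_n$voxels[fg]), max(cb_n$voxels[fg]))
  expect_lt(lo, hi)
})
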