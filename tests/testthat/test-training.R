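test_that("the learning-rate schedule warms up linearly then decays on a cosine", {
  cfg <- train_config()          # 20000 iterations, warm-up 300, peak 0.001
  expect_equal(lr_at(0, cfg), 0)
  expect_equal(lr_at(150, cfg), cfg$base_lr / 2)
  expect_equal(lr_at(300, cfg), cfg$base_lr)
  expect_equal(lr_at(10150, cfg), cfg$base_lr / 2)   # cos(pi/2) midpoint
  expect_equal(lr_at(20000, cfg), 0, tolerance = 1e-18)
  expect_error(lr_at(-1, cfg), "range")
  expect_error(lr_at(20001, cfg), "range")
  # continuity across the warm-up boundary, maximum exactly at the boundary
  it <- 0:20000
  lr <- lr_at(it, cfg)
  expect_lt(max(abs(diff(lr))), cfg$base_lr / 50)
  expect_equal(which.max(lr) - 1, cfg$warmup_iterations)
  expect_error(train_config(total_iterations = 100, warmup_iterations = 100),
               "warmup")
})

test_that("augmentation never reflects and is reproducible", {
  set.seed(5)
  vol <- array(rnorm(12^3), c(12, 12, 12))
  lab <- random_labels(c(12, 12, 12))
  # zero rotation and unit scale: exact identity
  id <- augment(vol, lab, list(rotation_deg = 0, scale_range = c(1, 1)))
  expect_identical(id$vol, vol)
  expect_identical(id$lab, lab)
  expect_equal(id$transform, diag(3))
  # the sampled linear transform always has positive determinant
  dets <- vapply(1:100, function(i)
    det(augment(vol, lab, seed = i)$transform), 0)
  expect_true(all(dets > 0))
  a1 <- augment(vol, lab, seed = 99)
  a2 <- augment(vol, lab, seed = 99)
  expect_identical(a1$vol, a2$vol)
  expect_identical(a1$lab, a2$lab)
  expect_true(all(a1$lab %in% 0:2))
})

test_that("training is bitwise reproducible and follows the schedule", {
  set.seed(6)
  lab <- array(0L, c(16, 16, 16)); lab[9:14, 5:12, 5:12] <- 1L; lab[2:5, , ] <- 2L
  vol <- array(rnorm(16^3), c(16, 16, 16)) + 2 * (lab != 0)
  cases <- list(list(id = "a", cbct = vol, ct = vol + 0.1, truth = lab))
  cfg <- network_config(num_stages = 2L, channels = c(4L, 6L),
                        mid_channels = c(4L, 4L), rsu_depths = c(1L, 1L))
  tcfg <- train_config(total_iterations = 10L, warmup_iterations = 4L,
                       patch_size = c(16L, 16L, 16L), batch_size = 2L, seed = 2L)
  f1 <- train_model(cases, cfg, tcfg)
  f2 <- train_model(cases, cfg, tcfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(f1$log$lr, lr_at(1:10, tcfg))
  expect_true(all(is.finite(f1$log$loss)))
  expect_error(train_model(list(), cfg, tcfg), "empty")
})

test_that("augmented patches keep the left structure on the +x side", {
  # chirality preservation: with rotations bounded far below 90 degrees no
  # draw may move a lateral structure across the midline
  cs <- generate_case(small_spec(jitter = 0), 2)
  lab <- cs$truth$labels
  vol <- cs$ct$voxels
  mid <- dim(lab)[1] / 2
  for (i in 1:100) {
    a <- augment(vol, lab, seed = i)
    idx <- which(a$lab == 1L, arr.ind = TRUE)
    if (nrow(idx) > 0) expect_gt(mean(idx[, 1]), mid)
  }
})
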