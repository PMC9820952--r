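test_that("residual U-blocks preserve spatial size and map channel widths", {
  blk <- build_rsu(depth = 2, in_ch = 3, mid_ch = 4, out_ch = 5, seed = 1)
  x <- array(rnorm(16^3 * 3), c(16, 16, 16, 3))
  y <- apply_rsu(blk, x)
  expect_equal(dim(y), c(16, 16, 16, 5))
  expect_true(all(is.finite(y)))
  # dilated variant works on grids too small to pool
  dblk <- build_rsu(depth = 2, in_ch = 2, mid_ch = 4, out_ch = 3, dilated = TRUE)
  yd <- apply_rsu(dblk, array(rnorm(4^3 * 2), c(4, 4, 4, 2)))
  expect_equal(dim(yd), c(4, 4, 4, 3))
  # non-dilated depth-3 block cannot process a 4^3 grid
  blk3 <- build_rsu(depth = 3, in_ch = 1, mid_ch = 4, out_ch = 2)
  expect_error(apply_rsu(blk3, array(0, c(4, 4, 4, 1))), "2\\^depth")
  expect_error(build_rsu(0, 1, 4, 2), "depth")
})

test_that("network construction is seed-deterministic and width-monotone", {
  cfg <- tiny_cfg()
  m1 <- build_network(cfg, seed = 3)
  m2 <- build_network(cfg, seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(cfg, seed = 4)
  expect_false(identical(m1$params, m3$params))
  wide <- network_config(channels = 2L * cfg$channels,
                         mid_channels = cfg$mid_channels,
                         rsu_depths = cfg$rsu_depths)
  expect_gt(n_params(build_network(wide, 3)), n_params(m1))
  # four stages produce four side outputs plus the fused head
  fp <- forward_pass(m1, array(rnorm(16^3), c(16, 16, 16)))
  expect_length(fp$outputs, 4)
  expect_false(is.null(fp$fused))
  nofuse <- network_config(channels = cfg$channels, mid_channels = cfg$mid_channels,
                           rsu_depths = cfg$rsu_depths, include_fused_output = FALSE)
  expect_null(forward_pass(build_network(nofuse, 1),
                           array(rnorm(8^3), c(8, 8, 8)))$fused)
})

test_that("forward pass halves resolution per scale and is deterministic", {
  m <- build_network(tiny_cfg(), seed = 7)
  x <- array(rnorm(16^3), c(16, 16, 16))
  fp <- forward_pass(m, x)
  sizes <- vapply(fp$outputs, function(o) dim(o)[1], 0L)
  expect_equal(sizes, c(16L, 8L, 4L, 2L))
  expect_true(all(vapply(fp$outputs, function(o) dim(o)[4], 0L) == 3L))
  expect_equal(dim(fp$fused), c(16, 16, 16, 3))
  fp2 <- forward_pass(m, x)
  expect_identical(fp$fused, fp2$fused)
  expect_error(forward_pass(m, array(0, c(10, 16, 16))), "divisible by 8")
})

test_that("initialisation yields finite scores across many seeds", {
  x <- array(rnorm(8^3), c(8, 8, 8))
  finite <- vapply(1:100, function(s) {
    fp <- forward_pass(build_network(tiny_cfg(), seed = s), x)
    all(is.finite(fp$fused)) && all(vapply(fp$outputs, function(o) all(is.finite(o)), NA))
  }, NA)
  expect_true(all(finite))
})

test_that("a tiny network memorises a single patch (loss halves in 200 iterations)", {
  set.seed(42)
  cfg <- network_config(num_stages = 2L, channels = c(8L, 16L),
                        mid_channels = c(4L, 4L), rsu_depths = c(1L, 1L))
  lab <- array(0L, c(16, 16, 16))
  lab[4:12, 4:12, 4:12] <- 1L
  lab[13:16, , ] <- 2L
  vol <- array(rnorm(16^3, -1), c(16, 16, 16))
  vol[lab == 1L] <- vol[lab == 1L] + 2
  vol[lab == 2L] <- vol[lab == 2L] + 4
  cases <- list(list(id = "memo", ct = vol, truth = lab))
  tcfg <- train_config(total_iterations = 200L, warmup_iterations = 20L,
                       base_lr = 0.01, patch_size = c(16L, 16L, 16L),
                       batch_size = 1L, rotation_deg = 0, scale_range = c(1, 1),
                       seed = 1L)
  fit <- train_model(cases, cfg, tcfg, modalities = "ct")
  first <- mean(fit$log$loss[1:20])
  last <- mean(tail(fit$log$loss, 20))
  expect_lt(last, 0.5 * first)
})

test_that("the default full-size configuration builds and runs forward", {
  m <- build_network(network_config(), seed = 1)   # 16/32/64/128, depths 5/4/3/2
  expect_gt(n_params(m), 1e5)
  fp <- forward_pass(m, array(rnorm(32^3), c(32, 32, 32)))
  expect_length(fp$outputs, 4)
  expect_equal(dim(fp$fused), c(32, 32, 32, 3))
  expect_true(all(is.finite(fp$fused)))
})
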