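test_that("phantom generation is deterministic and validates its spec", {
  spec <- small_spec()
  a <- generate_case(spec, 11)
  b <- generate_case(spec, 11)
  expect_identical(a$cbct$voxels, b$cbct$voxels)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$truth$labels, b$truth$labels)
  c2 <- generate_case(spec, 12)
  expect_false(identical(a$cbct$voxels, c2$cbct$voxels))
  expect_error(phantom_spec(muscle_semiaxes = c(-1, 2, 3)), "semi-axes")
  expect_error(
    phantom_spec(hu = list(muscle = c(mean = 60, sd_ct = 30, sd_cbct = 10),
                           fat = c(mean = -100, sd_ct = 10, sd_cbct = 20),
                           bone = c(mean = 900, sd_ct = 10, sd_cbct = 20),
                           air = c(mean = -1000, sd_ct = 10, sd_cbct = 20))),
    "CBCT")
})

test_that("muscle HU is more variable in CBCT than CT, around the same mean", {
  cs <- generate_case(phantom_spec(), 5)   # 64^3 default: >= 1e4 muscle voxels
  fg <- cs$truth$labels != 0
  expect_gt(sum(fg), 1e4)
  expect_gt(sd(cs$cbct$voxels[fg]), sd(cs$ct$voxels[fg]))
  # compartment means converge to the configured value away from boundaries
  # (the smoothing PSF mixes compartments within ~2 voxels of an interface)
  interior <- fg
  sh <- dim(fg)
  shift_and <- function(m, k, ax) {
    i <- seq_len(sh[ax])
    idx <- pmin(pmax(i + k, 1), sh[ax])
    if (ax == 1) m & m[idx, , ] else if (ax == 2) m & m[, idx, ] else m & m[, , idx]
  }
  for (ax in 1:3) for (k in c(-3, 3)) interior <- shift_and(interior, k, ax)
  expect_gt(sum(interior), 1000)
  # the PSF correlates the noise, shrinking the effective sample size by the
  # correlation volume (2 sqrt(pi) sigma)^3 of the Gaussian kernel
  sigma_vox <- (1.2 / 2.3548) / 0.5
  n_eff <- sum(interior) / (2 * sqrt(pi) * sigma_vox)^3
  for (vol in list(cs$ct, cs$cbct)) {
    x <- vol$voxels[interior]
    expect_lt(abs(mean(x) - 60), 3 * sd(x) / sqrt(n_eff) + 1)
  }
})

test_that("zero asymmetry jitter gives exactly mirrored muscles", {
  cs <- generate_case(small_spec(jitter = 0), 3)
  n_left <- sum(cs$truth$labels == 1L)
  n_right <- sum(cs$truth$labels == 2L)
  expect_gt(n_left, 0)
  expect_equal(n_left, n_right)
  # chirality: the class-1 structure sits on the +x side
  idx <- which(cs$truth$labels == 1L, arr.ind = TRUE)
  expect_gt(mean(idx[, 1]), dim(cs$truth$labels)[1] / 2)
  idx2 <- which(cs$truth$labels == 2L, arr.ind = TRUE)
  expect_lt(mean(idx2[, 1]), dim(cs$truth$labels)[1] / 2)
})

test_that("datasets are reproducible with a disjoint deterministic split", {
  spec <- small_spec()
  d1 <- generate_dataset(spec, 10, seed = 4)
  d2 <- generate_dataset(spec, 10, seed = 4)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$cases[[7]]$cbct$voxels, d2$cases[[7]]$cbct$voxels)
  expect_equal(as.integer(table(d1$manifest$split)[c("train", "val", "test")]),
               c(6L, 2L, 2L))
  expect_equal(length(unique(d1$manifest$case_id)), 10)
  d3 <- generate_dataset(spec, 10, seed = 5)
  expect_false(identical(d1$cases[[1]]$cbct$voxels, d3$cases[[1]]$cbct$voxels))
  expect_error(generate_dataset(spec, 0, seed = 1), "n must be")
})

test_that("simulated observers degrade gracefully with magnitude", {
  cs <- generate_case(small_spec(), 6)
  expect_identical(simulate_observer(cs$truth, list(magnitude = 0), 1)$labels,
                   cs$truth$labels)
  expect_error(simulate_observer(cs$truth, list(magnitude = -1), 1), "non-negative")
  pert <- simulate_observer(cs$truth, list(magnitude = 1.5, smoothness = 3), 1)
  d <- dsc(pert$labels == 1L, cs$truth$labels == 1L)
  expect_lt(d, 1)
  expect_gt(d, 0)
  # increasing magnitude => non-increasing mean DSC over seeds
  mean_dsc <- vapply(c(0.5, 1.5, 3), function(mag) {
    mean(vapply(1:10, function(s) {
      p <- simulate_observer(cs$truth, list(magnitude = mag, smoothness = 3), s)
      dsc(p$labels != 0L, cs$truth$labels != 0L)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_dsc) <= 0))
})
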