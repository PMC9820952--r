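test_that("DSC follows its definition and conventions", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
  expect_equal(dsc(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[3:4, 4, 4] <- TRUE
  expect_equal(dsc(a, b), 0)
  # |A| = 4, |M| = 4, |A n M| = 2 -> 0.5
  a2 <- array(FALSE, c(4, 4, 4)); a2[1:4, 1, 1] <- TRUE
  m2 <- array(FALSE, c(4, 4, 4)); m2[3:4, 1, 1] <- TRUE; m2[1:2, 2, 1] <- TRUE
  expect_equal(dsc(a2, m2), 0.5)
  expect_equal(dsc(a2, m2), dsc(m2, a2))          # symmetry
  e <- array(FALSE, c(4, 4, 4))
  expect_equal(dsc(e, e), 1)                      # both empty
  expect_equal(dsc(a, e), 0)                      # exactly one empty
})

test_that("the class-mean DSC breakdown reproduces reported Mean columns", {
  # the aggregation convention applied to reported per-class values
  expect_equal(round(dsc_class_mean(c(99.96, 91.56, 90.94)), 2), 94.15)
  expect_equal(round(dsc_class_mean(c(99.96, 91.89, 91.60)), 2), 94.48)
  expect_equal(round(dsc_class_mean(c(99.97, 94.39, 93.78)), 2), 96.05)
  set.seed(9)
  auto <- random_labels(c(8, 8, 8)); manual <- random_labels(c(8, 8, 8))
  db <- dsc_breakdown(auto, manual)
  expect_equal(db$dsc_mean,
               mean(c(db$dsc_background, db$dsc_left, db$dsc_right)))
  same <- dsc_breakdown(auto, auto)
  expect_equal(c(same$dsc_background, same$dsc_left, same$dsc_right,
                 same$dsc_mean), rep(1, 4))
  # a two-class map degenerates to the literal (DSC_Seg + DSC_Back) / 2
  a1 <- auto; a1[a1 == 2L] <- 0L
  m1 <- manual; m1[m1 == 2L] <- 0L
  db1 <- dsc_breakdown(a1, m1)
  expect_true(is.na(db1$dsc_right))
  expect_equal(db1$dsc_mean, (db1$dsc_background + db1$dsc_left) / 2)
})

test_that("aHD matches hand-computed cases and scales with spacing", {
  d <- c(5L, 5L, 5L)
  a <- array(FALSE, d); a[1, 1, 1] <- TRUE
  m <- array(FALSE, d); m[1, 1, 4] <- TRUE
  r <- ahd(a, m, c(1, 1, 1))
  expect_equal(r$directed_a_to_m, 3)
  expect_equal(r$directed_m_to_a, 3)
  expect_equal(r$symmetric, 3)
  a2 <- array(FALSE, d); a2[1, 1, 1] <- TRUE; a2[1, 1, 3] <- TRUE
  m2 <- array(FALSE, d); m2[1, 1, 1] <- TRUE
  r2 <- ahd(a2, m2, c(1, 1, 1))
  expect_equal(r2$directed_a_to_m, 1)          # mean(0, 2)... over A's points
  expect_equal(r2$directed_m_to_a, 0)
  expect_equal(r2$symmetric, 0.5)
  expect_equal(ahd(a, a, c(1, 1, 1))$symmetric, 0)
  doubled <- ahd(a2, m2, c(2, 2, 2))
  expect_equal(doubled$symmetric, 2 * r2$symmetric)  # linear in spacing
  expect_error(ahd(a, array(FALSE, d), c(1, 1, 1)), "empty")
})

test_that("aHD and DSC agree with brute-force oracles on random masks", {
  set.seed(10)
  for (trial in 1:100) {
    d <- sample(3:8, 3, replace = TRUE)
    sp <- runif(3, 0.3, 2)
    a <- array(runif(prod(d)) < runif(1, 0.05, 0.4), d)
    m <- array(runif(prod(d)) < runif(1, 0.05, 0.4), d)
    if (!any(a) || !any(m)) next
    bf <- ahd_bruteforce(a, m, sp)
    r <- ahd(a, m, sp)
    expect_equal(r$directed_a_to_m, bf$directed_a_to_m, tolerance = 1e-10)
    expect_equal(r$directed_m_to_a, bf$directed_m_to_a, tolerance = 1e-10)
    expect_equal(r$symmetric, bf$symmetric, tolerance = 1e-10)
    expect_equal(dsc(a, m), 2 * sum(a & m) / (sum(a) + sum(m)))
  }
})

test_that("revision fractions count one-sided disagreements per structure", {
  rev <- array(0L, c(10, 10, 10)); rev[1:5, 1:5, 1:8] <- 1L  # 200 voxels
  rev[8:10, 8:10, 1:5] <- 2L
  orig <- rev
  expect_equal(revision_fraction(orig, rev)$mean, 0)
  orig2 <- rev; orig2[1, 1, 1] <- 0L           # one voxel differs, left has 200
  rf <- revision_fraction(orig2, rev)
  expect_equal(unname(rf$per_class["left"]), 0.5)
  # an empty original against a non-empty revision is a 100% revision
  orig3 <- rev; orig3[orig3 == 1L] <- 0L
  expect_equal(unname(revision_fraction(orig3, rev)$per_class["left"]), 100)
  # empty revision with non-empty original: denominator falls back, flagged
  rev4 <- rev; rev4[rev4 == 1L] <- 0L
  rf4 <- revision_fraction(rev, rev4)
  expect_true(rf4$flagged["left"])
  expect_equal(unname(rf4$per_class["left"]), 100)
})

test_that("case evaluation aggregates with the side-mean convention", {
  set.seed(11)
  truth <- lapply(1:3, function(i) new_label_map(random_labels(c(10, 10, 10))))
  names(truth) <- paste0("case", 1:3)
  rep0 <- evaluate_cases(truth, truth)
  expect_equal(rep0$per_case$dsc_mean, rep(1, 3))
  expect_equal(rep0$per_case$ahd_mean, rep(0, 3))
  agg <- rep0$aggregate
  expect_equal(agg$sd[agg$metric == "dsc_mean"], 0)
  expect_equal(agg$ci_hi[agg$metric == "dsc_mean"] -
                 agg$ci_lo[agg$metric == "dsc_mean"], 0)
  # side-mean aHD identity: mean over cases of (l + r)/2 = (mean l + mean r)/2
  pred <- lapply(truth, function(t) simulate_observer(t, list(magnitude = 1), 2))
  repp <- evaluate_cases(pred, truth)
  a <- repp$aggregate
  expect_equal(a$mean[a$metric == "ahd_mean"],
               (a$mean[a$metric == "ahd_left"] + a$mean[a$metric == "ahd_right"]) / 2)
  expect_equal(round(ahd_side_mean(3.22, 4.14), 2), 3.68)
  # a single case has no dispersion estimate
  rep1 <- evaluate_cases(truth[1], truth[1])
  expect_false(any(rep1$aggregate$sd_defined))
  expect_error(evaluate_cases(truth[1:2], truth[2:3]), "ids")
})
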