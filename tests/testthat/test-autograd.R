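# Gradient correctness is checked per operator: the convolution satisfies
# exact adjoint identities (it is linear in both input and weights), the
# fused norm-activation and the losses are checked against central finite
# differences in double precision, and pooling/resizing are checked as
# adjoint pairs.

ns <- asNamespace("masseg")

test_that("convolution forward matches a naive oracle and its backward is the adjoint", {
  set.seed(10)
  for (trial in 1:3) {
    dims <- sample(4:8, 3, replace = TRUE)
    cin <- sample(1:4, 1); cout <- sample(1:4, 1); d <- sample(1:2, 1)
    N <- prod(dims)
    X <- matrix(rnorm(N * cin), N, cin)
    W <- array(rnorm(27 * cin * cout), c(3, 3, 3, cin, cout))
    Wm <- matrix(W, 27 * cin, cout)
    b <- rnorm(cout)
    fw <- ns$conv3d_fw(X, dims, Wm, b, d)
    # naive zero-padded dilated convolution
    Xa <- array(X, c(dims, cin))
    Y0 <- array(0, c(dims, cout))
    for (co in 1:cout) {
      Y0[, , , co] <- b[co]
      for (ci in 1:cin) for (kz in 1:3) for (ky in 1:3) for (kx in 1:3) {
        w <- W[kx, ky, kz, ci, co]
        for (z in 1:dims[3]) for (y in 1:dims[2]) for (x in 1:dims[1]) {
          s <- c(x, y, z) + (c(kx, ky, kz) - 2) * d
          if (all(s >= 1) && all(s <= dims))
            Y0[x, y, z, co] <- Y0[x, y, z, co] + w * Xa[s[1], s[2], s[3], ci]
        }
      }
    }
    expect_lt(max(abs(fw$y - matrix(Y0, N, cout))), 1e-5 * max(1, max(abs(Y0))))
    # adjoint identities: <conv(D), R> = <D, dX> and <conv_W(DW), R> = <DW, dW>
    R <- matrix(rnorm(N * cout), N, cout)
    bw <- ns$conv3d_bw(fw$xpad, R, dims, cin, Wm, d, TRUE)
    D <- matrix(rnorm(N * cin), N, cin)
    lhs <- sum(ns$conv3d_fw(D, dims, Wm, numeric(cout), d)$y * R)
    expect_lt(abs(lhs - sum(bw$dx * D)) / max(1, abs(lhs)), 1e-5)
    DW <- matrix(rnorm(27 * cin * cout), 27 * cin, cout)
    lhs <- sum(ns$conv3d_fw(X, dims, DW, numeric(cout), d)$y * R)
    expect_lt(abs(lhs - sum(bw$dw * DW)) / max(1, abs(lhs)), 1e-5)
    expect_equal(bw$db, colSums(R), tolerance = 1e-10)
  }
})

test_that("fused instance-norm + LeakyReLU gradients match finite differences", {
  set.seed(11)
  n <- 120; C <- 3
  x <- matrix(rnorm(n * C), n, C)
  gam <- rnorm(C, 1, 0.2); bet <- rnorm(C, 0, 0.2)
  R <- matrix(rnorm(n * C), n, C)
  f <- function(x, gam, bet) sum(ns$inorm_act_fw(x, gam, bet, 0.01, 1e-5)$y * R)
  r <- ns$inorm_act_fw(x, gam, bet, 0.01, 1e-5)
  b <- ns$inorm_act_bw(R, r$y, r$istd, gam, bet, 0.01)
  eps <- 1e-6
  num_dx <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    num_dx[i] <- (f(xp, gam, bet) - f(xm, gam, bet)) / (2 * eps)
  }
  expect_lt(max(abs(num_dx - b$dx)), 1e-6)
  for (c in 1:C) {
    gp <- gam; gp[c] <- gam[c] + eps; gm <- gam; gm[c] <- gam[c] - eps
    expect_lt(abs((f(x, gp, bet) - f(x, gm, bet)) / (2 * eps) - b$dgamma[c]), 1e-6)
    bp <- bet; bp[c] <- bet[c] + eps; bm <- bet; bm[c] <- bet[c] - eps
    expect_lt(abs((f(x, gam, bp) - f(x, gam, bm)) / (2 * eps) - b$dbeta[c]), 1e-6)
  }
})

test_that("pooling and trilinear resizing backwards are exact adjoints", {
  set.seed(12)
  dims <- c(6L, 5L, 7L); C <- 3L; N <- prod(dims)
  X <- matrix(rnorm(N * C), N, C)
  mp <- ns$maxpool2_fw(X, dims)
  G <- matrix(rnorm(nrow(mp$y) * C), ncol = C)
  lhs <- sum(mp$y * G)
  # max pooling is locally linear: the adjoint scatters onto the argmax
  expect_equal(sum(X * ns$maxpool2_bw(G, mp$idx, N)), lhs, tolerance = 1e-12)
  od <- c(9L, 3L, 5L)
  G2 <- matrix(rnorm(prod(od) * C), ncol = C)
  lhs <- sum(ns$resize3_fw(X, dims, od) * G2)
  rhs <- sum(X * ns$resize3_bw(G2, dims, od))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_equal(ns$resize3_fw(X, dims, dims), X)   # identity resize
})

test_that("the combined loss gradient matches finite differences", {
  set.seed(13)
  n <- 60; C <- 3
  s <- matrix(rnorm(n * C), n, C)
  lab <- sample(0:2, n, replace = TRUE)
  r <- ns$combined_loss_grad(s, lab)
  expect_equal(r$value, combined_loss(s, lab), tolerance = 1e-12)
  eps <- 1e-6
  idx <- sample(length(s), 30)
  for (i in idx) {
    sp <- s; sp[i] <- s[i] + eps
    sm <- s; sm[i] <- s[i] - eps
    num <- (combined_loss(sp, lab) - combined_loss(sm, lab)) / (2 * eps)
    expect_lt(abs(num - r$grad[i]), 1e-6)
  }
})

test_that("a whole-network directional derivative matches the backward pass", {
  set.seed(14)
  cfg <- network_config(num_stages = 2L, channels = c(3L, 4L),
                        mid_channels = c(4L, 4L), rsu_depths = c(1L, 1L))
  model <- build_network(cfg, seed = 5)
  patch <- c(8L, 8L, 8L)
  x <- matrix(rnorm(prod(patch)), ncol = 1)
  lab <- sample(0:2, prod(patch), replace = TRUE)
  run <- function(params) {
    tape <- ns$new_tape()
    pt <- ns$make_param_tensors(params)
    out <- ns$net_forward(tape, pt, cfg, ns$tn(x, patch))
    loss <- ns$op_ds_loss(tape, out$sides, out$fused, lab, patch, NULL)
    list(tape = tape, pt = pt, loss = loss)
  }
  r <- run(model$params)
  ns$backward_tape(r$tape, r$loss)
  # random direction over all parameters
  dirs <- rapply(model$params, function(a) array(rnorm(length(a)), dim(a) %||% length(a)),
                 how = "replace")
  flat <- function(pl) unlist(pl, use.names = FALSE)
  grads <- rapply2 <- lapply(names(r$pt), function(bn) {
    blk <- r$pt[[bn]]
    lapply(blk, function(node) {
      if (is.environment(node)) { if (is.null(node$g)) node$v * 0 else node$g }
      else lapply(node, function(t) if (is.null(t$g)) t$v * 0 else t$g)
    })
  })
  analytic <- sum(flat(grads) * flat(dirs))
  eps <- 1e-3
  shift <- function(sign) {
    p <- model$params
    pf <- flat(p); df <- flat(dirs)
    relist_i <- 0
    rapply(p, function(a) {
      n <- length(a)
      out <- a + sign * eps * array(df[relist_i + seq_len(n)], dim(a) %||% n)
      relist_i <<- relist_i + n
      out
    }, how = "replace")
  }
  num <- (run(shift(1))$loss$v - run(shift(-1))$loss$v) / (2 * eps)
  # single-precision convolution arithmetic limits the attainable agreement
  expect_lt(abs(num - analytic) / max(abs(num), abs(analytic)), 0.05)
})
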