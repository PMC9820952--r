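# Minimal reverse-mode differentiation over N x C feature matrices.
#
# A "tensor" is an environment with $v (value: N x C matrix for feature
# grids, or a plain array for parameters), $g (accumulated gradient, NULL
# until backward reaches it) and $dims (spatial dims c(nx, ny, nz) for
# feature grids).  Each forward op records itself on a tape; backward walks
# the tape in reverse and calls each op's closure with the output gradient.
# The graph is rebuilt every iteration (define-by-run), which keeps the
# network wiring in plain R while all heavy arithmetic lives in compiled
# kernels.

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$steps <- vector("list", 256L)
  e$k <- 0L
  e
}

tn <- function(value, dims = NULL) {
  t <- new.env(parent = emptyenv())
  t$v <- value
  t$g <- NULL
  t$dims <- dims
  t
}

rec <- function(tape, out, ins, back) {
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$steps))
    tape$steps <- c(tape$steps, vector("list", length(tape$steps)))
  tape$steps[[tape$k]] <- list(out = out, ins = ins, back = back)
  out
}

accum_grad <- function(t, g) {
  if (is.null(t$g)) t$g <- g else t$g <- t$g + g
  invisible(NULL)
}

backward_tape <- function(tape, loss) {
  loss$g <- 1
  for (i in seq(tape$k, 1L)) {
    s <- tape$steps[[i]]
    if (is.null(s$out$g)) next
    gs <- s$back(s$out$g)
    for (j in seq_along(s$ins))
      if (!is.null(gs[[j]])) accum_grad(s$ins[[j]], gs[[j]])
  }
  invisible(NULL)
}

# --- ops ------------------------------------------------------------------

op_conv3 <- function(tape, x, w, b, dilation = 1L, need_dx = TRUE) {
  dims <- x$dims
  cin <- ncol(x$v)
  r <- conv3d_fw(x$v, dims, w$v, b$v, dilation)
  y <- tn(r$y, dims)
  xpad <- r$xpad   # packed single-precision input, reused by the backward pass
  rec(tape, y, list(x, w, b), function(g) {
    b_ <- conv3d_bw(xpad, g, dims, cin, w$v, dilation, need_dx)
    list(if (need_dx) b_$dx else NULL, b_$dw, b_$db)
  })
}

op_conv1 <- function(tape, x, w, b) {
  y <- tn(x$v %*% w$v + rep(b$v, each = nrow(x$v)), x$dims)
  rec(tape, y, list(x, w, b), function(g) {
    list(g %*% t(w$v), crossprod(x$v, g), colSums(g))
  })
}

op_inorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  n <- nrow(x$v)
  mu <- colMeans(x$v)
  xc <- x$v - rep(mu, each = n)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = n)
  y <- tn(xhat * rep(gamma$v, each = n) + rep(beta$v, each = n), x$dims)
  rec(tape, y, list(x, gamma, beta), function(g) {
    dxhat <- g * rep(gamma$v, each = n)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) *
      rep(istd, each = n)
    list(dx, colSums(g * xhat), colSums(g))
  })
}

op_lrelu <- function(tape, x, slope = 0.01) {
  f <- slope + (1 - slope) * (x$v > 0)
  y <- tn(x$v * f, x$dims)
  rec(tape, y, list(x), function(g) list(g * f))
}

op_pool2 <- function(tape, x) {
  r <- maxpool2_fw(x$v, x$dims)
  y <- tn(r$y, r$outdims)
  n_in <- nrow(x$v)
  rec(tape, y, list(x), function(g) list(maxpool2_bw(g, r$idx, n_in)))
}

op_resize <- function(tape, x, outdims) {
  indims <- x$dims
  y <- tn(resize3_fw(x$v, indims, outdims), as.integer(outdims))
  rec(tape, y, list(x), function(g) list(resize3_bw(g, indims, outdims)))
}

op_cat <- function(tape, x1, x2) {
  c1 <- ncol(x1$v)
  y <- tn(cbind(x1$v, x2$v), x1$dims)
  rec(tape, y, list(x1, x2), function(g) {
    list(g[, seq_len(c1), drop = FALSE], g[, -seq_len(c1), drop = FALSE])
  })
}

op_add <- function(tape, x1, x2) {
  y <- tn(x1$v + x2$v, x1$dims)
  rec(tape, y, list(x1, x2), function(g) list(g, g))
}

# fused instance norm + leaky relu (compiled fwd/bwd)
op_inorm_act <- function(tape, x, gamma, beta, slope, eps = 1e-5) {
  r <- inorm_act_fw(x$v, gamma$v, beta$v, slope, eps)
  y <- tn(r$y, x$dims)
  rec(tape, y, list(x, gamma, beta), function(g) {
    b <- inorm_act_bw(g, r$y, r$istd, gamma$v, beta$v, slope)
    list(b$dx, b$dgamma, b$dbeta)
  })
}
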