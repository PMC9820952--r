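# Shared fixtures: everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small phantom specification that keeps unit tests fast
small_spec <- function(...) {
  phantom_spec(shape = c(32L, 32L, 32L), spacing = c(1, 1, 1),
               muscle_center = c(8, 0, -1), muscle_semiaxes = c(4, 6, 10),
               bone_halfwidth = c(1.5, 10, 12), air_rim = 2, ...)
}

# a tiny network that exercises all four stages cheaply
tiny_cfg <- function(...) {
  network_config(channels = c(4L, 6L, 8L, 10L), mid_channels = c(4L, 4L, 4L, 4L),
                 rsu_depths = c(1L, 1L, 1L, 1L), ...)
}

# random label array with the given foreground probability per class
random_labels <- function(dims, p1 = 0.1, p2 = 0.1) {
  array(sample(0:2, prod(dims), replace = TRUE, prob = c(1 - p1 - p2, p1, p2)),
        dims)
}

# brute-force directed average Hausdorff distance over explicit point sets
ahd_bruteforce <- function(a, m, spacing) {
  coords <- function(mask) {
    idx <- which(mask) - 1L
    d <- dim(mask)
    cbind(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2])) %*%
      diag(spacing)
  }
  pa <- coords(a); pm <- coords(m)
  # cancellation-free pairwise distances (explicit coordinate differences)
  dmat <- matrix(0, nrow(pa), nrow(pm))
  for (i in seq_len(nrow(pa)))
    dmat[i, ] <- sqrt((pm[, 1] - pa[i, 1])^2 + (pm[, 2] - pa[i, 2])^2 +
                      (pm[, 3] - pa[i, 3])^2)
  d_am <- mean(apply(dmat, 1, min))
  d_ma <- mean(apply(dmat, 2, min))
  list(directed_a_to_m = d_am, directed_m_to_a = d_ma,
       symmetric = (d_am + d_ma) / 2)
}
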