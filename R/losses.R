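#' Row-wise softmax of a score matrix
#'
#' @param s numeric matrix of raw class scores, one row per voxel.
#' @return Matrix of class probabilities, each row summing to 1.
#' @export
softmax_scores <- function(s) {
  s <- as.matrix(s)
  m <- s[, 1]
  if (ncol(s) > 1) for (j in 2:ncol(s)) m <- pmax(m, s[, j])
  e <- exp(s - m)
  e / rowSums(e)
}

as_score_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 4L) return(matrix(x, prod(d[1:3]), d[4]))
  stop("scores must be a matrix or a (nx, ny, nz, classes) array")
}

one_hot <- function(labels, n_classes) {
  lab <- as.integer(as.vector(labels))
  m <- matrix(0, length(lab), n_classes)
  m[cbind(seq_along(lab), lab + 1L)] <- 1
  m
}

#' Soft Dice loss
#'
#' `1 - mean_c (2 sum(p_c g_c) + eps) / (sum(p_c) + sum(g_c) + eps)` over the
#' foreground classes (all columns except the first when more than one column
#' is given; a single-column input is treated as one foreground class).
#'
#' @param prob per-class probability matrix/array (rows sum to 1 for
#'   multi-class input).
#' @param target one-hot matrix/array of the same shape.
#' @param eps numerical smoothing, default `1e-5`.
#' @return Scalar loss in `[0, 1 + eps]`.
#' @export
soft_dice_loss <- function(prob, target, eps = 1e-5) {
  p <- as_score_matrix(prob)
  g <- as_score_matrix(target)
  if (!all(dim(p) == dim(g))) stop("probability/target shape mismatch")
  fg <- if (ncol(p) > 1) 2:ncol(p) else 1L
  dice <- vapply(fg, function(c)
    (2 * sum(p[, c] * g[, c]) + eps) / (sum(p[, c]) + sum(g[, c]) + eps), 0)
  1 - mean(dice)
}

#' Cross-entropy loss from raw scores
#'
#' Mean negative log-probability of the true class after a row-wise softmax.
#'
#' @param scores raw score matrix/array.
#' @param target integer labels in `0..C-1` (vector/array) or a one-hot
#'   matrix.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(scores, target) {
  s <- as_score_matrix(scores)
  lab <- target_to_labels(target, ncol(s), nrow(s))
  p <- softmax_scores(s)
  -mean(log(pmax(p[cbind(seq_len(nrow(s)), lab + 1L)], 1e-300)))
}

target_to_labels <- function(target, n_classes, n_vox) {
  if (is.matrix(target) && ncol(target) == n_classes && nrow(target) == n_vox)
    return(max.col(target, ties.method = "first") - 1L)
  lab <- as.integer(as.vector(as_voxel_or_vector(target)))
  if (length(lab) != n_vox) stop("target length does not match scores")
  if (any(lab < 0 | lab >= n_classes)) stop("target labels out of range")
  lab
}

as_voxel_or_vector <- function(x) {
  if (inherits(x, "mm_labelmap")) x$labels else x
}

#' Combined soft-Dice + cross-entropy loss (equal weights)
#'
#' The training objective: `soft_dice_loss(softmax(scores), onehot(target)) +
#' cross_entropy(scores, target)`, each with weight 1.
#'
#' @inheritParams cross_entropy_loss
#' @return Scalar loss.
#' @export
combined_loss <- function(scores, target) {
  s <- as_score_matrix(scores)
  lab <- target_to_labels(target, ncol(s), nrow(s))
  g <- one_hot(lab, ncol(s))
  soft_dice_loss(softmax_scores(s), g) + cross_entropy_loss(s, lab)
}

# loss value plus analytic gradient w.r.t. the raw scores, used in training
combined_loss_grad <- function(s, lab, eps = 1e-5) {
  n <- nrow(s)
  C <- ncol(s)
  p <- softmax_scores(s)
  g <- one_hot(lab, C)
  # cross entropy
  ce <- -mean(log(pmax(p[cbind(seq_len(n), lab + 1L)], 1e-300)))
  ds <- (p - g) / n
  # soft dice over foreground classes
  fg <- if (C > 1) 2:C else 1L
  dLdp <- matrix(0, n, C)
  dice_terms <- numeric(length(fg))
  for (i in seq_along(fg)) {
    c <- fg[i]
    num <- 2 * sum(p[, c] * g[, c]) + eps
    den <- sum(p[, c]) + sum(g[, c]) + eps
    dice_terms[i] <- num / den
    dLdp[, c] <- -(2 * g[, c] * den - num) / den^2 / length(fg)
  }
  dice <- 1 - mean(dice_terms)
  # chain through softmax: ds += p * (dLdp - rowSums(dLdp * p))
  ds <- ds + p * (dLdp - rowSums(dLdp * p))
  list(value = dice + ce, dice = dice, ce = ce, grad = ds)
}

# nearest-neighbour decimation of a full-resolution label grid to out_dims
downsample_labels <- function(labels, out_dims) {
  labels <- as_voxel_or_vector(labels)
  in_dims <- dim(labels)
  idx <- lapply(1:3, function(a) {
    pmin(in_dims[a], floor((seq_len(out_dims[a]) - 0.5) * in_dims[a] / out_dims[a]) + 1L)
  })
  labels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Deep-supervision loss over multi-scale outputs
#'
#' The ground truth is down-sampled by nearest-neighbour label selection to
#' each output's resolution, the combined Dice + cross-entropy loss is
#' computed per scale, and the per-scale losses are summed with the given
#' weights (all 1 by default).
#'
#' @param outputs list of raw score arrays `(nx, ny, nz, C)` (or matrices
#'   with a `dims` attribute), ordered fine to coarse.
#' @param truth full-resolution integer label array or [new_label_map()].
#' @param weights per-scale weights; default all 1.
#' @return Scalar loss.
#' @export
deep_supervision_loss <- function(outputs, truth, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(outputs))
  if (length(weights) != length(outputs))
    stop("need one weight per output scale")
  truth <- as_voxel_or_vector(truth)
  total <- 0
  for (i in seq_along(outputs)) {
    if (weights[i] == 0) next
    o <- outputs[[i]]
    od <- if (is.matrix(o)) attr(o, "dims") else dim(o)[1:3]
    if (is.null(od)) stop("output ", i, " carries no spatial dims")
    lab <- downsample_labels(truth, od)
    if (length(lab) * 1L != prod(od)) stop("resolution mismatch at scale ", i)
    total <- total + weights[i] * combined_loss(as_score_matrix(o), lab)
  }
  total
}
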