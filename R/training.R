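#' Training configuration
#'
#' Defaults mirror the published recipe: 20,000 iterations of momentum SGD
#' with two samples per batch, learning rate warming up linearly from 0 to
#' 0.001 over the first 300 iterations and then decaying to 0 along a cosine
#' curve, equally weighted Dice + cross-entropy deep-supervision loss, and
#' standard geometric augmentation (random 3D rotation, random resizing and
#' cropping) - never a flip, which would confuse the left and right side.
#' The desk-scale test configurations shrink `total_iterations` and the
#' patch size, not the schedule's shape.
#'
#' @param total_iterations total optimisation steps.
#' @param batch_size samples per step.
#' @param base_lr peak learning rate.
#' @param warmup_iterations linear warm-up length (< `total_iterations`).
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty coefficient (0 = off).
#' @param patch_size training patch, divisible by `2^(num_stages-1)`.
#' @param rotation_deg rotation range, degrees per axis (+-).
#' @param scale_range isotropic random-resize range.
#' @param fg_bias fraction of patches forced to contain muscle voxels.
#' @param ds_weights per-scale deep-supervision weights (default all 1).
#' @param seed master seed for sampling, augmentation and initialisation.
#' @return A list of class `mm_train_config`.
#' @export
train_config <- function(total_iterations = 20000L, batch_size = 2L,
                         base_lr = 0.001, warmup_iterations = 300L,
                         momentum = 0.9, weight_decay = 0,
                         patch_size = c(48L, 48L, 48L),
                         rotation_deg = 15, scale_range = c(0.85, 1.15),
                         fg_bias = 0.5, ds_weights = NULL, seed = 1L) {
  if (warmup_iterations >= total_iterations)
    stop("warmup_iterations must be smaller than total_iterations")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (base_lr <= 0) stop("base_lr must be positive")
  structure(list(total_iterations = as.integer(total_iterations),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 warmup_iterations = as.integer(warmup_iterations),
                 momentum = momentum, weight_decay = weight_decay,
                 patch_size = as.integer(patch_size),
                 rotation_deg = rotation_deg, scale_range = scale_range,
                 fg_bias = fg_bias, ds_weights = ds_weights,
                 seed = as.integer(seed)),
            class = "mm_train_config")
}

#' Learning rate at a given iteration
#'
#' Linear ramp from 0 to `base_lr` over the warm-up, then cosine decay to 0:
#' `base_lr * 0.5 * (1 + cos(pi (it - warmup)/(total - warmup)))`.
#' Continuous on `[0, total]`, maximum attained exactly at `it = warmup`.
#'
#' @param iteration iteration index (vectorised), `0 <= iteration <= total`.
#' @param cfg an [train_config()].
#' @return Learning rate(s).
#' @export
lr_at <- function(iteration, cfg) {
  if (any(iteration < 0 | iteration > cfg$total_iterations))
    stop("iteration out of range [0, total_iterations]")
  w <- cfg$warmup_iterations
  ifelse(iteration <= w,
         cfg$base_lr * iteration / w,
         cfg$base_lr * 0.5 *
           (1 + cos(pi * (iteration - w) / (cfg$total_iterations - w))))
}

# rotation matrix about axis `ax` by `ang` radians
rot3 <- function(ax, ang) {
  c_ <- cos(ang); s_ <- sin(ang)
  m <- diag(3)
  i <- switch(ax, x = c(2, 3), y = c(3, 1), z = c(1, 2))
  m[i[1], i[1]] <- c_; m[i[2], i[2]] <- c_
  m[i[1], i[2]] <- -s_; m[i[2], i[1]] <- s_
  m
}

sample_aug_transform <- function(rotation_deg, scale_range) {
  ang <- runif(3, -rotation_deg, rotation_deg) * pi / 180
  zoom <- runif(1, scale_range[1], scale_range[2])
  # linear part maps output voxel offsets to source offsets; zoom > 1 shows
  # a magnified view, so the source step is 1/zoom.  det = 1/zoom^3 > 0:
  # the sampled transform is never a reflection.
  L <- rot3("z", ang[3]) %*% rot3("y", ang[2]) %*% rot3("x", ang[1]) / zoom
  L
}

#' Random geometric augmentation of an aligned patch pair
#'
#' Applies one random rotation + isotropic resize about the patch centre to
#' both the intensity patch (trilinear) and the label patch (nearest
#' neighbour).  The linear part of every sampled transform has positive
#' determinant: reflections are never drawn, preserving the left/right
#' chirality of the labels.
#'
#' @param vol_patch numeric 3D array.
#' @param lab_patch integer 3D array aligned with `vol_patch`.
#' @param params list with `rotation_deg` (degrees) and `scale_range`.
#' @param seed optional seed for a reproducible draw.
#' @return List with `vol`, `lab`, and the sampled linear `transform`
#'   (3x3 matrix) as an attribute-free list entry.
#' @export
augment <- function(vol_patch, lab_patch,
                    params = list(rotation_deg = 15, scale_range = c(0.85, 1.15)),
                    seed = NULL) {
  if (!identical(dim(vol_patch), dim(lab_patch)))
    stop("volume and label patches must be aligned")
  if (!is.null(seed)) set.seed(seed)
  L <- sample_aug_transform(params$rotation_deg, params$scale_range)
  d <- dim(vol_patch)
  ctr <- (d - 1) / 2
  t <- ctr - L %*% ctr
  if (max(abs(L - diag(3))) == 0) {
    vol <- vol_patch; lab <- lab_patch
  } else {
    vol <- array(affine_sample(as.numeric(vol_patch), d, L, t, d, 2L, 0), d)
    lab <- array(affine_sample(as.numeric(lab_patch), d, L, t, d, 3L, 0), d)
  }
  storage.mode(lab) <- "integer"
  list(vol = vol, lab = lab, transform = L)
}

# draw one augmented training patch from a case: fg-biased centre, random
# rotation/resize, trilinear for intensities / nearest for labels
sample_training_patch <- function(vol, truth, fg_idx, patch, rotation_deg,
                                  scale_range, fg_bias) {
  d <- dim(vol)
  L <- sample_aug_transform(rotation_deg, scale_range)
  if (length(fg_idx) > 0 && runif(1) < fg_bias) {
    v <- fg_idx[sample.int(length(fg_idx), 1)] - 1L
    ctr_src <- c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2]))
  } else {
    ctr_src <- vapply(d, function(n) runif(1, 0, n - 1), 0)
  }
  ctr_out <- (patch - 1) / 2
  t <- ctr_src - L %*% ctr_out
  x <- affine_sample(as.numeric(vol), d, L, t, patch, 2L, 0)
  y <- affine_sample(as.numeric(truth), d, L, t, patch, 3L, 0)
  list(x = matrix(x, prod(patch), 1), lab = as.integer(y))
}

# deep-supervision loss as a tape op: value + gradients into all score tensors
op_ds_loss <- function(tape, sides, fused, truth_lab, patch, weights) {
  outs <- c(sides, if (!is.null(fused)) list(fused))
  if (is.null(weights)) weights <- rep(1, length(outs))
  if (length(weights) != length(outs)) stop("need one ds weight per output")
  truth_arr <- array(truth_lab, patch)
  make_back <- function(g_fixed) { force(g_fixed); function(gout) list(g_fixed * gout) }
  total <- 0
  loss_nodes <- list()
  for (i in seq_along(outs)) {
    if (weights[i] == 0) next
    o <- outs[[i]]
    lab <- as.integer(downsample_labels(truth_arr, o$dims))
    r <- combined_loss_grad(o$v, lab)
    total <- total + weights[i] * r$value
    lt <- tn(weights[i] * r$value)
    loss_nodes[[length(loss_nodes) + 1L]] <-
      rec(tape, lt, list(o), make_back(r$grad * weights[i]))
  }
  agg <- tn(total)
  nl <- length(loss_nodes)
  rec(tape, agg, loss_nodes, function(gout) as.list(rep(gout, nl)))
  agg
}

#' Train the segmentation model
#'
#' Runs momentum SGD on the deep-supervision loss over random augmented
#' patches drawn from the given cases.  CBCT and CT renderings of each case
#' are mixed in one batch stream (both carry the same ground truth), which
#' is what allows a single model to segment both modalities.  The whole run
#' is reproducible from `(cases, configs, seed)`.
#'
#' @param cases list of paired cases: each either a `mm_paired_case` or a
#'   list with numeric arrays `cbct` and/or `ct` (already preprocessed) and
#'   an integer array / label map `truth`.
#' @param net_cfg an [network_config()], or an existing `mm_model` to
#'   continue training.
#' @param cfg an [train_config()].
#' @param modalities which renderings to sample from.
#' @param verbose print progress every 50 iterations.
#' @return List with `model` (trained `mm_model`) and `log` (data.frame of
#'   iteration, lr, loss).
#' @export
train_model <- function(cases, net_cfg = network_config(), cfg = train_config(),
                        modalities = c("cbct", "ct"), verbose = FALSE) {
  if (length(cases) == 0) stop("empty training dataset")
  prep <- lapply(cases, function(cs) {
    g <- function(x) if (inherits(x, "mm_volume")) x$voxels else x
    truth <- as_voxel_or_vector(cs$truth)
    mods <- intersect(modalities, names(cs))
    if (length(mods) == 0) stop("case provides none of the requested modalities")
    list(vols = lapply(setNames(mods, mods), function(m) g(cs[[m]])),
         truth = truth, fg = which(as.vector(truth) != 0))
  })
  model <- if (inherits(net_cfg, "mm_model")) net_cfg else
    build_network(net_cfg, seed = cfg$seed)
  ncfg <- model$cfg
  patch <- cfg$patch_size
  div <- 2L^(ncfg$num_stages - 1L)
  if (any(patch %% div != 0))
    stop("patch_size must be divisible by ", div)
  set.seed(cfg$seed)
  pt <- make_param_tensors(model$params)
  vel <- rapply(model$params, function(a) a * 0, how = "replace")
  log_it <- integer(cfg$total_iterations)
  log_lr <- numeric(cfg$total_iterations)
  log_loss <- numeric(cfg$total_iterations)

  for (it in seq_len(cfg$total_iterations)) {
    lr <- lr_at(it, cfg)
    zero_param_grads(pt)
    loss_sum <- 0
    for (b in seq_len(cfg$batch_size)) {
      ci <- sample.int(length(prep), 1)
      cs <- prep[[ci]]
      mod <- names(cs$vols)[sample.int(length(cs$vols), 1)]
      sp <- sample_training_patch(cs$vols[[mod]], cs$truth, cs$fg, patch,
                                  cfg$rotation_deg, cfg$scale_range, cfg$fg_bias)
      tape <- new_tape()
      xt <- tn(sp$x, patch)
      out <- net_forward(tape, pt, ncfg, xt)
      loss <- op_ds_loss(tape, out$sides, out$fused, sp$lab, patch, cfg$ds_weights)
      if (!is.finite(loss$v))
        stop("training diverged: non-finite loss at iteration ", it)
      loss_sum <- loss_sum + loss$v
      backward_tape(tape, loss)
    }
    inv_b <- 1 / cfg$batch_size
    # momentum SGD update over the (possibly nested) parameter tree
    for (bn in names(pt)) {
      blk <- pt[[bn]]
      for (cn in names(blk)) {
        node <- blk[[cn]]
        if (is.environment(node)) {
          upd <- sgd_update(node, vel[[bn]][[cn]], lr, cfg, inv_b)
          vel[[bn]][[cn]] <- upd
        } else {
          for (tn_ in names(node)) {
            upd <- sgd_update(node[[tn_]], vel[[bn]][[cn]][[tn_]], lr, cfg, inv_b)
            vel[[bn]][[cn]][[tn_]] <- upd
          }
        }
      }
    }
    log_it[it] <- it; log_lr[it] <- lr; log_loss[it] <- loss_sum * inv_b
    if (verbose && it %% 50 == 0)
      message(sprintf("iter %d  lr %.5f  loss %.4f", it, lr, loss_sum * inv_b))
  }
  model$params <- rapply2_values(pt)
  list(model = model,
       log = data.frame(iteration = log_it, lr = log_lr, loss = log_loss))
}

sgd_update <- function(tensor, v, lr, cfg, inv_b) {
  g <- if (is.null(tensor$g)) 0 else tensor$g * inv_b
  if (cfg$weight_decay > 0) g <- g + cfg$weight_decay * tensor$v
  v <- cfg$momentum * v - lr * g
  tensor$v <- tensor$v + v
  v
}

# extract plain parameter arrays back out of the tensor tree
rapply2_values <- function(pt) {
  lapply(pt, function(blk) lapply(blk, function(node) {
    if (is.environment(node)) node$v else lapply(node, function(t) t$v)
  }))
}
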