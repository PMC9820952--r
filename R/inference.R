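#' Sliding-window inference configuration
#'
#' @param patch_size window size in voxels (divisible by
#'   `2^(num_stages - 1)`).
#' @param overlap fractional window overlap in `[0, 1)`; overlapping class
#'   probabilities are averaged uniformly.
#' @param use_fused predict from the fused full-resolution head when the
#'   model has one, otherwise from the finest side output.
#' @return List of class `mm_inference_config`.
#' @export
inference_config <- function(patch_size = c(48L, 48L, 48L), overlap = 0.5,
                             use_fused = TRUE) {
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  structure(list(patch_size = as.integer(patch_size), overlap = overlap,
                 use_fused = isTRUE(use_fused)),
            class = "mm_inference_config")
}

window_starts <- function(n, win, stride) {
  s <- seq(1L, max(1L, n - win + 1L), by = stride)
  if (s[length(s)] != n - win + 1L) s <- c(s, n - win + 1L)
  unique(s)
}

#' Predict a full-volume label map with a trained model
#'
#' Runs sliding-window inference: per-voxel class probabilities (softmax of
#' the model's prediction head) are averaged over all overlapping windows
#' and the label is the class of maximal mean probability, ties broken
#' towards the lower class index.  The input must have been preprocessed
#' with the same pipeline as training.  The output grid equals the input
#' grid, and two runs on the same inputs are identical.
#'
#' @param model a trained `mm_model`.
#' @param v preprocessed [new_volume()] or numeric 3D array.
#' @param cfg an [inference_config()].
#' @param return_probs also attach the blended per-voxel class probabilities
#'   (an `(nx, ny, nz, C)` array in the `probs` field of the result).
#' @return An [new_label_map()] on the input grid.
#' @export
predict_labels <- function(model, v, cfg = inference_config(),
                           return_probs = FALSE) {
  arr <- as_voxel_array(v)
  dims <- dim(arr)
  div <- 2L^(model$cfg$num_stages - 1L)
  win <- pmin(cfg$patch_size, (dims %/% div) * div)
  if (any(win < div))
    stop("volume ", paste(dims, collapse = "x"),
         " is too small for the network (needs >= ", div, " per axis)")
  stride <- pmax(1L, as.integer(round(win * (1 - cfg$overlap))))
  C <- model$cfg$num_classes
  psum <- matrix(0, prod(dims), C)
  cnt <- numeric(prod(dims))
  pt <- make_param_tensors(model$params)
  starts <- expand.grid(x = window_starts(dims[1], win[1], stride[1]),
                        y = window_starts(dims[2], win[2], stride[2]),
                        z = window_starts(dims[3], win[3], stride[3]))
  vox_index <- function(s) {
    ix <- s[1]:(s[1] + win[1] - 1L)
    iy <- s[2]:(s[2] + win[2] - 1L)
    iz <- s[3]:(s[3] + win[3] - 1L)
    outer(ix, outer((iy - 1L) * dims[1], (iz - 1L) * dims[1] * dims[2], "+"), "+")
  }
  for (r in seq_len(nrow(starts))) {
    s <- as.integer(starts[r, ])
    idx <- as.vector(vox_index(s))
    tape <- new_tape()
    xt <- tn(matrix(arr[idx], ncol = 1), win)
    out <- net_forward(tape, pt, model$cfg, xt)
    head <- if (cfg$use_fused && !is.null(out$fused)) out$fused else out$sides[[1]]
    p <- softmax_scores(head$v)
    psum[idx, ] <- psum[idx, ] + p
    cnt[idx] <- cnt[idx] + 1
  }
  probs <- psum / cnt
  lab <- max.col(probs, ties.method = "first") - 1L
  spacing <- if (inherits(v, "mm_volume")) v$spacing else c(1, 1, 1)
  origin <- if (inherits(v, "mm_volume")) v$origin else c(0, 0, 0)
  out <- new_label_map(array(lab, dims), spacing, origin)
  if (return_probs) out$probs <- array(probs, c(dims, C))
  out
}

#' Keep only the largest connected components of each structure
#'
#' Optional post-processing: for every foreground class the `k` largest
#' 26-connected components are kept and all remaining voxels of that class
#' are set to background.  Disabled by default in the pipeline, since the
#' evaluation convention scores the raw model output.
#'
#' @param l an [new_label_map()].
#' @param k number of components to keep per class (>= 1).
#' @return A filtered [new_label_map()].
#' @export
largest_components_filter <- function(l, k = 1L) {
  validate_label_map(l)
  if (k < 1) stop("k must be >= 1")
  dims <- dim(l$labels)
  out <- l$labels
  for (cls in c(1L, 2L)) {
    m <- l$labels == cls
    if (!any(m)) next
    cc <- cc_label26(as.vector(m), dims)
    keep <- order(cc$sizes, decreasing = TRUE)[seq_len(min(k, length(cc$sizes)))]
    drop <- m & !array(cc$labels %in% keep, dims)
    out[drop] <- 0L
  }
  new_label_map(out, l$spacing, l$origin)
}
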