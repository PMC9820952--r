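#' Configuration of the residual U-block segmentation network
#'
#' The network is a two-level U-shape: an encoder-decoder over `num_stages`
#' resolution stages whose building blocks are themselves small U-shaped
#' encoder-decoders (residual U-blocks, RSU).  Feature resolution halves
#' after every encoder stage and doubles before every decoder stage; one
#' side-output head produces class scores at every decoder scale (deep
#' supervision) and an optional fused head combines all upsampled side
#' outputs into the final full-resolution prediction.
#'
#' Channel widths and RSU internal depths are free parameters; the defaults
#' follow the small U^2-Net configuration adapted to 3D, which balances
#' computational cost against segmentation accuracy.  The deepest stage uses
#' the dilated RSU variant (no internal pooling) because its feature grid is
#' too small to pool further.
#'
#' @param num_stages number of resolution stages (>= 2; the reference model
#'   uses 4).
#' @param channels output channels per stage.
#' @param mid_channels internal RSU channels per stage; default half of
#'   `channels` (minimum 4).
#' @param rsu_depths internal encoder depth of each stage's RSU (number of
#'   2x poolings inside the block).
#' @param num_classes number of output classes (3: background, left, right).
#' @param dilated_bottleneck use the dilated RSU variant in the deepest stage.
#' @param include_fused_output add the fused full-resolution head.
#' @param negative_slope LeakyReLU negative slope.
#' @return A list of class `mm_network_config`.
#' @export
network_config <- function(num_stages = 4L,
                           channels = c(16L, 32L, 64L, 128L),
                           mid_channels = NULL,
                           rsu_depths = c(5L, 4L, 3L, 2L),
                           num_classes = 3L,
                           dilated_bottleneck = TRUE,
                           include_fused_output = TRUE,
                           negative_slope = 0.01) {
  if (num_stages < 2L) stop("num_stages must be >= 2")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (length(channels) != num_stages || any(channels <= 0))
    stop("channels must be ", num_stages, " positive integers")
  if (length(rsu_depths) != num_stages || any(rsu_depths < 1))
    stop("rsu_depths must be ", num_stages, " integers >= 1")
  if (is.null(mid_channels)) mid_channels <- pmax(4L, channels %/% 2L)
  if (length(mid_channels) != num_stages || any(mid_channels <= 0))
    stop("mid_channels must be ", num_stages, " positive integers")
  cfg <- structure(list(num_stages = as.integer(num_stages),
                        channels = as.integer(channels),
                        mid_channels = as.integer(mid_channels),
                        rsu_depths = as.integer(rsu_depths),
                        num_classes = as.integer(num_classes),
                        dilated_bottleneck = isTRUE(dilated_bottleneck),
                        include_fused_output = isTRUE(include_fused_output),
                        negative_slope = negative_slope),
                   class = "mm_network_config")
  cfg
}

# He-style initialisation for one 3x3x3 conv layer with instance norm
init_conv3 <- function(cin, cout) {
  list(w = matrix(rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))), 27 * cin, cout),
       b = rep(0, cout), g = rep(1, cout), be = rep(0, cout))
}

init_conv1 <- function(cin, cout) {
  list(w = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = rep(0, cout))
}

# parameter set of one RSU block: input transform, depth+1 encoder convs,
# dilated bottom conv, depth+1 decoder convs
init_rsu_params <- function(cin, mid, cout, depth) {
  p <- list(cin = init_conv3(cin, cout), e0 = init_conv3(cout, mid))
  for (l in seq_len(depth)) p[[paste0("e", l)]] <- init_conv3(mid, mid)
  p$bot <- init_conv3(mid, mid)
  for (l in seq(depth, 1)) p[[paste0("d", l)]] <- init_conv3(2 * mid, mid)
  p$d0 <- init_conv3(2 * mid, cout)
  p
}

#' Build the network and initialise its parameters
#'
#' Re-initialising with the same `(cfg, seed)` reproduces an identical
#' parameter collection.
#'
#' @param cfg an [network_config()].
#' @param seed integer initialisation seed.
#' @return A `mm_model`: list with `params`, `cfg`, `seed`, `config_hash`.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "mm_network_config"))
  set.seed(seed)
  S <- cfg$num_stages
  ch <- cfg$channels; mid <- cfg$mid_channels; d <- cfg$rsu_depths
  params <- list()
  for (s in seq_len(S)) {
    cin <- if (s == 1) 1L else ch[s - 1]
    params[[paste0("en", s)]] <- init_rsu_params(cin, mid[s], ch[s], d[s])
  }
  for (s in seq(S - 1, 1)) {
    params[[paste0("de", s)]] <- init_rsu_params(ch[s + 1] + ch[s], mid[s], ch[s], d[s])
  }
  for (s in seq_len(S))
    params[[paste0("side", s)]] <- init_conv1(ch[s], cfg$num_classes)
  if (cfg$include_fused_output)
    params$fuse <- init_conv1(S * cfg$num_classes, cfg$num_classes)
  structure(list(params = params, cfg = cfg, seed = as.integer(seed),
                 config_hash = hash_object(unclass(cfg)), preprocess = NULL),
            class = "mm_model")
}

#' Number of learnable parameters of a model
#' @param model a `mm_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity, 0))
}

# wrap every parameter array in a tensor once per training run
make_param_tensors <- function(params) {
  rapply(params, function(a) tn(a), how = "replace")
}

zero_param_grads <- function(pt) {
  walk_params(pt, function(t) t$g <- NULL)
}

walk_params <- function(pt, f) {
  for (blk in pt) for (t in blk) if (is.environment(t)) f(t) else
    for (u in t) f(u)
  invisible(NULL)
}

# conv3 + instance norm + leaky relu
cbr <- function(tape, x, p, slope, dilation = 1L, need_dx = TRUE) {
  op_inorm_act(tape, op_conv3(tape, x, p$w, p$b, dilation, need_dx),
               p$g, p$be, slope)
}

# one residual U-block.  Non-dilated: nested encoder-decoder over `depth`
# 2x-pooled scales with a dilation-2 bottom conv.  Dilated: same parameter
# layout, but pooling is replaced by growing dilation (1, 2, 4, ...), all at
# full resolution.  The input transform is added residually to the nested
# branch's output; spatial size is unchanged.
rsu_forward <- function(tape, x, p, depth, dilated, slope, input_grad = TRUE) {
  if (!dilated && any(x$dims < 2^depth))
    stop("RSU input spatial size ", paste(x$dims, collapse = "x"),
         " is smaller than 2^depth = ", 2^depth)
  hin <- cbr(tape, x, p$cin, slope, need_dx = input_grad)
  e <- vector("list", depth + 1)
  if (dilated) {
    e[[1]] <- cbr(tape, hin, p$e0, slope)
    for (l in seq_len(depth))
      e[[l + 1]] <- cbr(tape, e[[l]], p[[paste0("e", l)]], slope, dilation = 2L^l)
    h <- cbr(tape, e[[depth + 1]], p$bot, slope, dilation = 2L^(depth + 1))
    for (l in seq(depth, 1))
      h <- cbr(tape, op_cat(tape, h, e[[l + 1]]), p[[paste0("d", l)]], slope,
               dilation = 2L^l)
  } else {
    e[[1]] <- cbr(tape, hin, p$e0, slope)
    for (l in seq_len(depth))
      e[[l + 1]] <- cbr(tape, op_pool2(tape, e[[l]]), p[[paste0("e", l)]], slope)
    h <- cbr(tape, e[[depth + 1]], p$bot, slope, dilation = 2L)
    for (l in seq(depth, 1)) {
      h <- cbr(tape, op_cat(tape, h, e[[l + 1]]), p[[paste0("d", l)]], slope)
      h <- op_resize(tape, h, e[[l]]$dims)
    }
  }
  h <- cbr(tape, op_cat(tape, h, e[[1]]), p$d0, slope)
  op_add(tape, h, hin)
}

#' Build a standalone residual U-block
#'
#' Mainly a building block of [build_network()], exposed for inspection and
#' testing.  The block maps a feature grid with `in_ch` channels to one with
#' `out_ch` channels at unchanged spatial size.
#'
#' @param depth internal encoder depth (number of 2x poolings; >= 1).
#' @param in_ch,mid_ch,out_ch channel widths.
#' @param dilated use growing dilation instead of pooling (valid on grids
#'   too small to pool).
#' @param seed initialisation seed.
#' @return A list of class `mm_rsu` with the block parameters.
#' @export
build_rsu <- function(depth, in_ch, mid_ch, out_ch, dilated = FALSE, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  set.seed(seed)
  structure(list(params = init_rsu_params(in_ch, mid_ch, out_ch, depth),
                 depth = as.integer(depth), dilated = isTRUE(dilated),
                 in_ch = in_ch, out_ch = out_ch),
            class = "mm_rsu")
}

#' Apply a standalone residual U-block to a feature grid
#'
#' @param block an `mm_rsu` from [build_rsu()].
#' @param x numeric array of dim `(nx, ny, nz, in_ch)` (or 3D for one channel).
#' @param negative_slope LeakyReLU slope.
#' @return Array of dim `(nx, ny, nz, out_ch)`.
#' @export
apply_rsu <- function(block, x, negative_slope = 0.01) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  dims <- dim(x)[1:3]
  if (dim(x)[4] != block$in_ch) stop("input has wrong channel count")
  tape <- new_tape()
  pt <- make_param_tensors(list(b = block$params))$b
  xt <- tn(matrix(x, prod(dims), dim(x)[4]), as.integer(dims))
  y <- rsu_forward(tape, xt, pt, block$depth, block$dilated, negative_slope)
  array(y$v, c(dims, block$out_ch))
}

# full forward pass on one patch; x is an N x 1 tensor with $dims set.
# Returns list(sides = tensors fine -> coarse, fused = tensor or NULL).
net_forward <- function(tape, pt, cfg, x) {
  S <- cfg$num_stages
  div <- 2L^(S - 1L)
  if (any(x$dims %% div != 0))
    stop("patch dims ", paste(x$dims, collapse = "x"),
         " must be divisible by ", div)
  slope <- cfg$negative_slope
  enc <- vector("list", S)
  h <- x
  for (s in seq_len(S)) {
    if (s > 1) h <- op_pool2(tape, enc[[s - 1]])
    dil <- (s == S) && cfg$dilated_bottleneck
    enc[[s]] <- rsu_forward(tape, h, pt[[paste0("en", s)]], cfg$rsu_depths[s],
                            dil, slope, input_grad = (s > 1))
  }
  dec <- vector("list", S)
  dec[[S]] <- enc[[S]]
  for (s in seq(S - 1, 1)) {
    up <- op_resize(tape, dec[[s + 1]], enc[[s]]$dims)
    dec[[s]] <- rsu_forward(tape, op_cat(tape, up, enc[[s]]),
                            pt[[paste0("de", s)]], cfg$rsu_depths[s], FALSE, slope)
  }
  sides <- vector("list", S)
  for (s in seq_len(S)) {
    hp <- pt[[paste0("side", s)]]
    sides[[s]] <- op_conv1(tape, dec[[s]], hp$w, hp$b)
  }
  fused <- NULL
  if (cfg$include_fused_output) {
    upped <- lapply(sides, function(t)
      if (identical(t$dims, x$dims)) t else op_resize(tape, t, x$dims))
    cc <- upped[[1]]
    for (s in 2:S) cc <- op_cat(tape, cc, upped[[s]])
    fused <- op_conv1(tape, cc, pt$fuse$w, pt$fuse$b)
  }
  list(sides = sides, fused = fused)
}

#' Run the network forward on one patch
#'
#' Produces raw class scores (no softmax) at every decoder scale, ordered
#' fine to coarse: the side output at scale `s` has spatial size
#' `input / 2^s`, and a fused full-resolution output is appended when the
#' model was built with a fused head.  The pass is deterministic given
#' `(model, patch)`.
#'
#' @param model a `mm_model`.
#' @param patch numeric 3D array; each spatial dim must be divisible by
#'   `2^(num_stages - 1)`.
#' @return List with `outputs` (list of `(nx, ny, nz, num_classes)` score
#'   arrays, fine to coarse) and `fused` (full-resolution score array or
#'   NULL).
#' @export
forward_pass <- function(model, patch) {
  stopifnot(inherits(model, "mm_model"))
  dims <- dim(patch)
  if (length(dims) != 3L) stop("patch must be a 3-D array")
  tape <- new_tape()
  pt <- make_param_tensors(model$params)
  xt <- tn(matrix(as.numeric(patch), prod(dims), 1), as.integer(dims))
  out <- net_forward(tape, pt, model$cfg, xt)
  shape_out <- function(t) array(t$v, c(t$dims, ncol(t$v)))
  list(outputs = lapply(out$sides, shape_out),
       fused = if (!is.null(out$fused)) shape_out(out$fused))
}
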