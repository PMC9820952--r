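#' Preprocessing configuration
#'
#' Defaults follow the training recipe used for the masseter model: fixed HU
#' clipping to \[-325, 400\] (the 0.5 and 99.5 percent quantiles of the
#' foreground voxels on the training data), z-score normalisation by the
#' pooled foreground mean/SD after clipping, and a common 0.5 mm isotropic
#' grid so CBCT (0.3 mm isotropic) and CT (0.4 x 0.4 x 1 mm) volumes can be
#' mixed in one batch stream.  The quantile rule used to derive the clip
#' bounds is also exposed ([foreground_quantile_bounds()]) for recomputing
#' them on a new dataset.
#'
#' @param clip_lo,clip_hi fixed HU clipping bounds (`clip_lo < clip_hi`).
#' @param quantile_lo,quantile_hi foreground quantiles for the bound rule.
#' @param target_spacing common grid spacing in mm.
#' @param normalization normalisation mode; only `"zscore"` is implemented.
#' @return A list of class `mm_preprocess_config`.
#' @export
preprocess_config <- function(clip_lo = -325, clip_hi = 400,
                              quantile_lo = 0.005, quantile_hi = 0.995,
                              target_spacing = c(0.5, 0.5, 0.5),
                              normalization = "zscore") {
  if (clip_lo >= clip_hi) stop("clip_lo must be smaller than clip_hi")
  if (!(quantile_lo >= 0 && quantile_lo < quantile_hi && quantile_hi <= 1))
    stop("quantiles must satisfy 0 <= quantile_lo < quantile_hi <= 1")
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  structure(list(clip_lo = clip_lo, clip_hi = clip_hi,
                 quantile_lo = quantile_lo, quantile_hi = quantile_hi,
                 target_spacing = as.numeric(target_spacing),
                 normalization = normalization),
            class = "mm_preprocess_config")
}

#' Clip volume intensities to a HU window
#'
#' Saturates every voxel to `[lo, hi]`; idempotent and monotone, spacing
#' unchanged.
#'
#' @param v an [new_volume()] or numeric array.
#' @param lo,hi clipping bounds in HU, `lo < hi`.
#' @return Same type as the input.
#' @export
clip_hu <- function(v, lo = -325, hi = 400) {
  if (lo >= hi) stop("lo must be smaller than hi")
  if (inherits(v, "mm_volume")) {
    v$voxels <- pmin(pmax(v$voxels, lo), hi)
    v
  } else {
    pmin(pmax(v, lo), hi)
  }
}

#' Foreground quantile intensity bounds
#'
#' Pools the HU values at all foreground (label != 0) voxels across the given
#' cases and returns the `(qlo, qhi)` quantiles with linear interpolation
#' between order statistics - the rule that yields the \[-325, 400\] window
#' at the 0.5/99.5 percent quantiles on the training corpus.
#'
#' @param volumes list of volumes (or arrays).
#' @param masks list of label maps (or integer arrays), aligned with `volumes`.
#' @param qlo,qhi quantile levels.
#' @return Numeric length-2: the lower and upper HU bound.
#' @export
foreground_quantile_bounds <- function(volumes, masks, qlo = 0.005, qhi = 0.995) {
  if (length(volumes) != length(masks)) stop("volumes and masks must be aligned")
  vals <- unlist(lapply(seq_along(volumes), function(i) {
    v <- as_voxel_array(volumes[[i]])
    m <- as_voxel_array(masks[[i]])
    if (!identical(dim(v), dim(m))) stop("volume/mask shape mismatch in case ", i)
    v[m != 0]
  }), use.names = FALSE)
  if (length(vals) == 0) stop("no foreground voxels in any case")
  unname(quantile(vals, c(qlo, qhi), type = 7, names = FALSE))
}

#' Z-score normalise a volume by foreground statistics
#'
#' @param v an [new_volume()] or array (typically already clipped).
#' @param stats list with `mean` and `sd` (foreground mean/SD; `sd > 0`).
#' @return Same type as input, with voxels `(x - mean) / sd`.
#' @export
normalize_volume <- function(v, stats) {
  if (stats$sd <= 0) stop("normalisation SD must be positive")
  if (inherits(v, "mm_volume")) {
    v$voxels <- (v$voxels - stats$mean) / stats$sd
    v
  } else {
    (v - stats$mean) / stats$sd
  }
}

#' Fit the preprocessing statistics on a training set
#'
#' Applies the configured clipping, then records the pooled foreground mean
#' and SD used by [apply_preprocess()] at training and inference time.  When
#' `recompute_bounds` is TRUE the clip window itself is recomputed from the
#' foreground quantile rule instead of the fixed default.
#'
#' @param volumes,masks training volumes and their label maps.
#' @param cfg an [preprocess_config()].
#' @param recompute_bounds recompute clip bounds from the quantile rule.
#' @return List with `clip_lo`, `clip_hi`, `mean`, `sd`.
#' @export
fit_preprocess <- function(volumes, masks, cfg = preprocess_config(),
                           recompute_bounds = FALSE) {
  lo <- cfg$clip_lo; hi <- cfg$clip_hi
  if (recompute_bounds) {
    b <- foreground_quantile_bounds(volumes, masks, cfg$quantile_lo, cfg$quantile_hi)
    lo <- b[1]; hi <- b[2]
  }
  vals <- unlist(lapply(seq_along(volumes), function(i) {
    v <- clip_hu(as_voxel_array(volumes[[i]]), lo, hi)
    m <- as_voxel_array(masks[[i]])
    v[m != 0]
  }), use.names = FALSE)
  if (length(vals) == 0) stop("no foreground voxels")
  list(clip_lo = lo, clip_hi = hi, mean = mean(vals), sd = sd(vals))
}

#' Apply fitted preprocessing (clip then z-score) to one volume
#'
#' @param v volume or array.
#' @param stats output of [fit_preprocess()].
#' @return Same type as input.
#' @export
apply_preprocess <- function(v, stats) {
  normalize_volume(clip_hu(v, stats$clip_lo, stats$clip_hi),
                   list(mean = stats$mean, sd = stats$sd))
}

resample_grid <- function(in_dims, in_spacing, target) {
  out_dims <- pmax(1L, as.integer(round(in_dims * in_spacing / target)))
  # half-pixel centre alignment: preserves the physical extent within a voxel
  M <- diag(target / in_spacing)
  t <- 0.5 * target / in_spacing - 0.5
  list(out_dims = out_dims, M = M, t = t)
}

#' Resample a volume to a target spacing (trilinear)
#'
#' @param v an [new_volume()].
#' @param target_spacing numeric length-3, mm.
#' @return A resampled [new_volume()]; identical when the spacing is unchanged.
#' @export
resample_volume <- function(v, target_spacing) {
  validate_volume(v)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  g <- resample_grid(dim(v$voxels), v$spacing, target_spacing)
  out <- affine_sample(as.vector(v$voxels), dim(v$voxels), g$M, g$t,
                       g$out_dims, 2L, 0)
  new_volume(array(out, g$out_dims), target_spacing, v$origin)
}

#' Resample a label map to a target spacing (nearest neighbour)
#'
#' Nearest-neighbour interpolation guarantees the output contains no label
#' values absent from the input.
#'
#' @param l an [new_label_map()].
#' @inheritParams resample_volume
#' @export
resample_labels <- function(l, target_spacing) {
  validate_label_map(l)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  g <- resample_grid(dim(l$labels), l$spacing, target_spacing)
  out <- affine_sample(as.numeric(l$labels), dim(l$labels), g$M, g$t,
                       g$out_dims, 3L, 0)
  new_label_map(array(out, g$out_dims), target_spacing, l$origin)
}
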