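#' Dice similarity coefficient of two voxel sets
#'
#' `2|A n M| / (|A| + |M|)`.  By convention two empty sets have DSC 1 and
#' exactly one empty set gives 0.  Symmetric in its arguments.
#'
#' @param a,m logical arrays/vectors of equal length, or integer voxel-index
#'   vectors.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, m) {
  if (is.logical(a) && is.logical(m)) {
    if (length(a) != length(m)) stop("mask lengths differ")
    na <- sum(a); nm <- sum(m)
    if (na + nm == 0) return(1)
    2 * sum(a & m) / (na + nm)
  } else {
    a <- unique(as.integer(a)); m <- unique(as.integer(m))
    if (length(a) + length(m) == 0) return(1)
    2 * length(intersect(a, m)) / (length(a) + length(m))
  }
}

#' Class-mean aggregation of per-class DSC values
#'
#' The reporting convention for multi-structure segmentations: the "Mean"
#' DSC is the unweighted mean of the per-class values (background, left,
#' right).  With a single foreground structure this reduces to the classic
#' two-class form `(DSC_Seg + DSC_Back) / 2`.
#'
#' @param values numeric per-class DSC values.
#' @return Their unweighted mean.
#' @export
dsc_class_mean <- function(values) mean(values)

#' Side-mean aggregation of left/right distance values
#'
#' @param left,right per-side values (scalars or per-case vectors).
#' @return Element-wise mean of the two sides.
#' @export
ahd_side_mean <- function(left, right) (left + right) / 2

#' Per-class DSC breakdown of a multi-structure segmentation
#'
#' Computes DSC for the background and each foreground structure present in
#' either map, plus the class-mean aggregate ([dsc_class_mean()]).
#'
#' @param auto,manual label maps ([new_label_map()]) or integer arrays on
#'   the same grid.
#' @return List of class `mm_dsc_breakdown` with `dsc_background`,
#'   `dsc_left`, `dsc_right` (NA for a structure absent from both maps) and
#'   `dsc_mean`.
#' @export
dsc_breakdown <- function(auto, manual) {
  a <- as_voxel_or_vector(auto)
  m <- as_voxel_or_vector(manual)
  if (!identical(dim(a), dim(m))) stop("label grids are not aligned")
  per <- c(background = dsc(a == 0L, m == 0L),
           left = if (any(a == 1L) || any(m == 1L)) dsc(a == 1L, m == 1L) else NA_real_,
           right = if (any(a == 2L) || any(m == 2L)) dsc(a == 2L, m == 2L) else NA_real_)
  structure(list(dsc_background = per[["background"]],
                 dsc_left = per[["left"]], dsc_right = per[["right"]],
                 dsc_mean = dsc_class_mean(per[!is.na(per)])),
            class = "mm_dsc_breakdown")
}

#' Average Hausdorff distance between two voxel sets
#'
#' The directed aHD from A to M is the mean, over the voxels of A, of the
#' Euclidean distance (in physical mm, voxel indices scaled by spacing) to
#' the nearest voxel of M.  The symmetric value is the mean of the two
#' directions.  Undefined (error) when either set is empty.  Implemented
#' through an exact Euclidean distance transform, so it scales linearly
#' with spacing.
#'
#' @param a,m logical arrays of equal dim.
#' @param spacing voxel spacing in mm.
#' @return List of class `mm_ahd` with `directed_a_to_m`, `directed_m_to_a`
#'   and `symmetric` (all in mm).
#' @export
ahd <- function(a, m, spacing = c(1, 1, 1)) {
  if (!identical(dim(a), dim(m))) stop("mask grids are not aligned")
  if (!any(a) || !any(m)) stop("aHD undefined for empty structure")
  dims <- dim(a)
  dm <- sqrt(edt_sq(as.vector(m), dims, spacing))
  da <- sqrt(edt_sq(as.vector(a), dims, spacing))
  d_am <- mean(dm[as.vector(a)])
  d_ma <- mean(da[as.vector(m)])
  structure(list(directed_a_to_m = d_am, directed_m_to_a = d_ma,
                 symmetric = (d_am + d_ma) / 2),
            class = "mm_ahd")
}

#' Per-side aHD breakdown with the side-mean aggregate
#'
#' Symmetric aHD for the left and right structure plus their side mean
#' ([ahd_side_mean()]).  A side missing from either map yields NA.
#'
#' @inheritParams dsc_breakdown
#' @param spacing voxel spacing in mm (taken from `auto` when it is a label
#'   map).
#' @return List with `ahd_left`, `ahd_right`, `ahd_mean` (mm).
#' @export
ahd_breakdown <- function(auto, manual, spacing = NULL) {
  if (is.null(spacing))
    spacing <- if (inherits(auto, "mm_labelmap")) auto$spacing else c(1, 1, 1)
  a <- as_voxel_or_vector(auto)
  m <- as_voxel_or_vector(manual)
  side <- function(cls) {
    if (!any(a == cls) || !any(m == cls)) return(NA_real_)
    ahd(a == cls, m == cls, spacing)$symmetric
  }
  l <- side(1L); r <- side(2L)
  list(ahd_left = l, ahd_right = r, ahd_mean = ahd_side_mean(l, r))
}

#' Revision fraction between an original and a revised segmentation
#'
#' The percentage of voxels an expert changed: per class,
#' `100 * |voxels labelled c in exactly one of the two maps| / |revised == c|`,
#' averaged over the two structures.  When the revised structure is empty
#' but the original is not, the denominator falls back to the original's
#' size and a warning flag is set.
#'
#' @param original,revised label maps or integer arrays on the same grid.
#' @return List with `per_class` (named left/right percentages), `mean`, and
#'   `flagged` (logical per class).
#' @export
revision_fraction <- function(original, revised) {
  o <- as_voxel_or_vector(original)
  r <- as_voxel_or_vector(revised)
  if (!identical(dim(o), dim(r))) stop("label grids are not aligned")
  one <- function(cls) {
    denom <- sum(r == cls)
    flag <- FALSE
    if (denom == 0) {
      if (sum(o == cls) == 0) return(list(v = 0, flag = FALSE))
      denom <- sum(o == cls)
      flag <- TRUE
    }
    list(v = 100 * sum(xor(o == cls, r == cls)) / denom, flag = flag)
  }
  l <- one(1L); r2 <- one(2L)
  list(per_class = c(left = l$v, right = r2$v),
       mean = (l$v + r2$v) / 2,
       flagged = c(left = l$flag, right = r2$flag))
}

read_label_dir <- function(x) {
  if (is.character(x) && length(x) == 1 && dir.exists(x)) {
    fs <- sort(list.files(x, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    ids <- sub("\\.nii(\\.gz)?$", "", basename(fs))
    setNames(lapply(fs, read_labels), ids)
  } else x
}

#' Evaluate predicted against reference segmentations over a case set
#'
#' Computes the per-case DSC breakdown and per-side symmetric aHD, then the
#' across-case mean, SD and 95% confidence interval of the mean for each
#' metric.  The side-mean aHD is aggregated as the mean over cases of the
#' per-case `(left + right)/2`, which equals the mean of the two per-side
#' means.
#'
#' @param pred,truth named lists of label maps, or directories of NIfTI
#'   label files; case ids must match.
#' @return List of class `mm_metrics_report` with `per_case` and
#'   `aggregate` data frames and `n`.
#' @export
evaluate_cases <- function(pred, truth) {
  pred <- read_label_dir(pred)
  truth <- read_label_dir(truth)
  ids <- names(pred)
  if (is.null(ids) || !setequal(ids, names(truth)))
    stop("prediction and truth case ids do not match")
  rows <- lapply(ids, function(id) {
    db <- dsc_breakdown(pred[[id]], truth[[id]])
    ab <- ahd_breakdown(pred[[id]], truth[[id]])
    data.frame(case = id,
               dsc_mean = db$dsc_mean, dsc_background = db$dsc_background,
               dsc_left = db$dsc_left, dsc_right = db$dsc_right,
               ahd_mean = ab$ahd_mean, ahd_left = ab$ahd_left,
               ahd_right = ab$ahd_right)
  })
  per_case <- do.call(rbind, rows)
  metrics <- setdiff(names(per_case), "case")
  agg <- do.call(rbind, lapply(metrics, function(mname) {
    x <- per_case[[mname]]
    x <- x[!is.na(x)]
    if (length(x) >= 2) {
      s <- summarize_series(x)
      data.frame(metric = mname, mean = s$mean, sd = s$sd,
                 ci_lo = s$ci[1], ci_hi = s$ci[2], n = s$n,
                 sd_defined = TRUE)
    } else {
      data.frame(metric = mname, mean = if (length(x)) x else NA_real_,
                 sd = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 n = length(x), sd_defined = FALSE)
    }
  }))
  structure(list(per_case = per_case, aggregate = agg, n = length(ids)),
            class = "mm_metrics_report")
}
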