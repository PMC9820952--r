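#' In-memory 3D intensity volume
#'
#' A `mm_volume` holds a 3D grid of Hounsfield-unit (or normalised) values
#' together with the physical voxel spacing in mm, the physical coordinate of
#' voxel (1,1,1) and the axis orientation code.  Volumes are canonicalised to
#' the right-anterior-superior (RAS) frame on read, so the +x axis always
#' points to the subject's anatomical left; the structure labelled "left"
#' is the one on the +x side.
#'
#' @param voxels numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param orientation three-letter axis code; only "RAS" is used internally.
#' @return An object of class `mm_volume`.
#' @export
new_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = "RAS") {
  v <- structure(list(voxels = voxels, spacing = as.numeric(spacing),
                      origin = as.numeric(origin), orientation = orientation),
                 class = "mm_volume")
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  if (!is.array(v$voxels) || length(dim(v$voxels)) != 3L)
    stop("expected 3-D volume, got ", length(dim(v$voxels)), " dimension(s)")
  if (length(v$voxels) == 0L) stop("volume grid is empty")
  if (length(v$spacing) != 3L || any(!is.finite(v$spacing)) || any(v$spacing <= 0))
    stop("spacing must be three positive finite values")
  if (any(!is.finite(v$voxels))) stop("volume contains non-finite voxel values")
  invisible(v)
}

#' Integer label map aligned to a volume
#'
#' Classes are coded 0 = background, 1 = left masseter (the structure on the
#' subject's anatomical left, +x in the canonical RAS frame), 2 = right
#' masseter.  Any other value is rejected.
#'
#' @param labels integer-valued 3D array with values in \{0, 1, 2\}.
#' @inheritParams new_volume
#' @return An object of class `mm_labelmap`.
#' @export
new_label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          orientation = "RAS") {
  storage.mode(labels) <- "integer"
  l <- structure(list(labels = labels, spacing = as.numeric(spacing),
                      origin = as.numeric(origin), orientation = orientation),
                 class = "mm_labelmap")
  validate_label_map(l)
  l
}

validate_label_map <- function(l, companion = NULL) {
  if (!is.array(l$labels) || length(dim(l$labels)) != 3L)
    stop("expected 3-D label map")
  bad <- setdiff(unique(as.vector(l$labels)), c(0L, 1L, 2L))
  if (length(bad))
    stop("label map contains values outside {0, 1, 2}: ",
         paste(sort(bad), collapse = ", "))
  if (!is.null(companion)) {
    if (!identical(dim(l$labels), dim(companion$voxels)))
      stop("label map shape does not match its companion volume")
    if (max(abs(l$spacing - companion$spacing)) > 1e-6)
      stop("label map spacing does not match its companion volume")
  }
  invisible(l)
}

#' @export
print.mm_volume <- function(x, ...) {
  cat(sprintf("<mm_volume %s, spacing %s mm, range [%.1f, %.1f]>\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.mm_labelmap <- function(x, ...) {
  n <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("<mm_labelmap %s, spacing %s mm, voxels bg/left/right %d/%d/%d>\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              n[1], n[2], n[3]))
  invisible(x)
}

as_voxel_array <- function(x) {
  if (inherits(x, "mm_volume")) x$voxels
  else if (inherits(x, "mm_labelmap")) x$labels
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected an mm_volume, mm_labelmap or 3-D array")
}
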