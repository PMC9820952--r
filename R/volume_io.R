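#' Read a volume from a NIfTI-1 file
#'
#' The image is reoriented to the canonical RAS frame (when the file carries a
#' usable qform/sform), its spacing is taken from the header and all voxel
#' values are checked to be finite.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [new_volume()] object.
#' @export
read_volume <- function(path) {
  img <- read_nifti_canonical(path)
  new_volume(strip_attrs(as.array(img)), spacing = RNifti::pixdim(img),
             origin = nifti_origin(img), orientation = "RAS")
}

strip_attrs <- function(a) {
  array(as.vector(a), dim(a))
}

read_nifti_canonical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3-D volume, got ", length(d), "-D image in ", path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0) {
    if (!identical(RNifti::orientation(img), "RAS"))
      RNifti::orientation(img) <- "RAS"
  }
  if (any(!is.finite(as.array(img))))
    stop("non-finite voxel values in ", path)
  img
}

nifti_origin <- function(img) {
  x <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(x, "try-error")) return(c(0, 0, 0))
  as.numeric(x[1:3, 4])
}

#' Write a volume to a NIfTI-1 file
#'
#' Voxels are stored as 64-bit floats so that a read/write round trip is
#' lossless; spacing and origin are recorded in the header.
#'
#' @param v an [new_volume()] object.
#' @param path destination path (`.nii` or `.nii.gz`); its directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  validate_volume(v)
  write_nifti_canonical(v$voxels, v$spacing, v$origin, path, datatype = "double")
}

write_nifti_canonical <- function(arr, spacing, origin, path, datatype) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  ok <- try(RNifti::writeNifti(img, path, datatype = datatype), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write ", path)
  invisible(path)
}

#' Read a label map from a NIfTI-1 file
#'
#' Values outside \{0, 1, 2\} are rejected with an error that lists the
#' offending labels.
#'
#' @inheritParams read_volume
#' @return An [new_label_map()] object.
#' @export
read_labels <- function(path) {
  img <- read_nifti_canonical(path)
  arr <- strip_attrs(as.array(img))
  if (any(arr != round(arr))) stop("non-integer label values in ", path)
  new_label_map(arr, spacing = RNifti::pixdim(img),
                origin = nifti_origin(img), orientation = "RAS")
}

#' Write a label map to a NIfTI-1 file (unsigned 8-bit storage)
#'
#' @param l an [new_label_map()] object.
#' @inheritParams write_volume
#' @export
write_labels <- function(l, path) {
  validate_label_map(l)
  write_nifti_canonical(l$labels, l$spacing, l$origin, path, datatype = "uint8")
}
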