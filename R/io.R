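#' Write a label mask as NIfTI
#'
#' The affine carries the pixel spacing so downstream morphometry can recover
#' millimetre geometry from the header alone.
#'
#' @param mask Integer matrix or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixel_spacing_mm (row, col) spacing in mm; a third element (slice
#'   spacing) is appended as 1 mm when absent for 3D masks.
#' @export
write_mask_nifti <- function(mask, path, pixel_spacing_mm) {
  nd <- length(dim(mask))
  pd <- if (nd == 3 && length(pixel_spacing_mm) == 2) {
    c(pixel_spacing_mm, 1)
  } else {
    pixel_spacing_mm
  }
  arr <- array(as.integer(mask), dim = dim(mask))
  attr(arr, "pixdim") <- pd
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  invisible(path)
}

#' Read a label mask from NIfTI
#'
#' @param path NIfTI path.
#' @return List with `mask` (integer array, singleton dimensions dropped)
#'   and `pixel_spacing_mm` (row, col).
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  mask <- array(as.integer(round(img)), dim = dim(img))
  if (length(dim(mask)) > 2 && all(dim(mask)[-(1:2)] == 1)) {
    mask <- matrix(mask, dim(mask)[1], dim(mask)[2])
  }
  list(mask = mask, pixel_spacing_mm = pd[1:2])
}

#' Write a mask or label slice as 8-bit PNG
#'
#' Labels are written as-is (values must fit 0..255); use with a sidecar
#' spacing in config, since PNG carries no physical units.
#'
#' @param mask Integer or binary matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  v <- as.vector(mask)
  if (any(v < 0) || any(v > 255)) stop("labels outside 0..255 cannot be PNG-encoded")
  png::writePNG(matrix(v / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a mask slice from 8-bit PNG
#'
#' @param path PNG path.
#' @return Integer matrix of labels.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Write phantom truth as CSV
#'
#' One row per vertebra: id, heights, HLR, deformity class, fracture label
#' and 0-based pixel bounding box.
#'
#' @param phantom A `vcf_phantom` or its truth data frame.
#' @param path Output path.
#' @export
write_truth_csv <- function(phantom, path) {
  truth <- if (inherits(phantom, "vcf_phantom")) phantom$truth else phantom
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Read phantom truth from CSV
#'
#' @param path CSV path.
#' @param image_dim Optional (rows, cols) recorded as the `image_dim`
#'   attribute for normalized-box computations.
#' @return Truth data frame.
#' @export
read_truth_csv <- function(path, image_dim = NULL) {
  truth <- utils::read.csv(path)
  truth$fractured <- as.logical(truth$fractured)
  if (!is.null(image_dim)) attr(truth, "image_dim") <- image_dim
  truth
}
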