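#' Read a PET volume from a 3-D NIfTI file
#'
#' The voxel grid (spacing, origin, direction) is taken from the file's
#' affine (sform preferred); the direction matrix is polished to the nearest
#' orthonormal matrix to absorb the float32 precision of NIfTI headers.
#' 4-D or multi-channel files and files containing non-finite voxels are
#' rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return An [suv_volume()].
#' @export
read_volume <- function(path) {
  parsed <- read_nifti_array(path)
  suv_volume(parsed$values, parsed$grid)
}

#' Read a binary mask from a 3-D NIfTI file
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param threshold_nonbinary if `TRUE`, voxel values `> 0.5` become
#'   occupied; if `FALSE` (default) any value outside \{0, 1\} is an error.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, threshold_nonbinary = FALSE) {
  parsed <- read_nifti_array(path)
  vals <- parsed$values
  if (threshold_nonbinary) {
    occ <- vals > 0.5
  } else {
    if (!all(vals %in% c(0, 1)))
      stop(sprintf(
        "mask file contains %d voxel(s) outside {0, 1}; set threshold_nonbinary = TRUE to binarize",
        sum(!(vals %in% c(0, 1)))), call. = FALSE)
    occ <- vals == 1
  }
  binary_mask(array(occ, dim(vals)), parsed$grid)
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a single-channel 3-D NIfTI, got %d dimensions",
                 length(d)), call. = FALSE)
  vals <- array(as.numeric(img), d)
  nbad <- sum(!is.finite(vals))
  if (nbad > 0L)
    stop(sprintf("file contains %d non-finite voxel(s)", nbad),
         call. = FALSE)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  A <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0)) stop("degenerate affine in NIfTI header", call. = FALSE)
  direction <- sweep(A, 2L, spacing, "/")
  # nearest orthonormal matrix (headers are stored in float32)
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  grid <- image_grid(d, spacing = spacing, origin = aff[1:3, 4],
                     direction = direction)
  list(values = vals, grid = grid)
}

#' Write a volume or mask as NIfTI
#'
#' Masks are written as unsigned 8-bit \{0, 1\}; volumes as float32. The
#' grid affine is stored in both the sform and qform.
#'
#' @param x an [suv_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly `path`.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$occupancy), x$grid$shape)
    dtype <- "uint8"
  } else if (inherits(x, "suv_volume")) {
    arr <- x$values
    dtype <- "float"
  } else {
    stop("'x' must be an suv_volume or binary_mask", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  img <- RNifti::asNifti(arr)
  aff <- grid_affine(x$grid)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
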