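#' PET volume in SUV units
#'
#' A scalar field of standardized uptake values over a voxel grid. Values
#' must be finite and non-negative.
#'
#' @param values 3-D numeric array matching `grid$shape`.
#' @param grid an [image_grid()].
#' @return An object of class `suv_volume` with fields `values` and `grid`.
#' @export
suv_volume <- function(values, grid) {
  stopifnot(inherits(grid, "image_grid"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("values dimensions do not match grid shape", call. = FALSE)
  nbad <- sum(!is.finite(values))
  if (nbad > 0L)
    stop(sprintf("volume contains %d non-finite voxel(s)", nbad),
         call. = FALSE)
  if (any(values < 0))
    stop(sprintf("volume contains %d negative voxel(s); SUV must be >= 0",
                 sum(values < 0)), call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(x$grid$shape, collapse = " x "),
      " voxels @ ", paste(format(x$grid$spacing), collapse = "x"),
      " mm; SUV range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Binary delineation mask
#'
#' A boolean occupancy field over a voxel grid — the unit of every
#' delineation (an observer's gross tumour volume, a consensus contour, a
#' threshold segmentation).
#'
#' @param occupancy 3-D logical (or strictly 0/1 numeric) array matching
#'   `grid$shape`.
#' @param grid an [image_grid()].
#' @return An object of class `binary_mask` with fields `occupancy` and
#'   `grid`.
#' @export
binary_mask <- function(occupancy, grid) {
  stopifnot(inherits(grid, "image_grid"))
  occupancy <- as.array(occupancy)
  if (!identical(as.integer(dim(occupancy)), grid$shape))
    stop("occupancy dimensions do not match grid shape", call. = FALSE)
  if (!is.logical(occupancy)) {
    if (any(is.na(occupancy)) || !all(occupancy %in% c(0, 1)))
      stop("occupancy must be logical or strictly 0/1", call. = FALSE)
    occupancy <- array(occupancy == 1, dim(occupancy))
  } else if (any(is.na(occupancy))) {
    stop("occupancy must not contain NA", call. = FALSE)
  }
  structure(list(occupancy = occupancy, grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(x$grid$shape, collapse = " x "),
      " voxels @ ", paste(format(x$grid$spacing), collapse = "x"),
      " mm; ", sum(x$occupancy), " occupied (",
      format(mask_volume(x), digits = 4), " cm^3)\n", sep = "")
  invisible(x)
}

#' Set of observer delineations for one lesion
#'
#' Bundles the contours several observers drew for the same lesion under one
#' imaging condition. All masks must share one grid, observer ids must be
#' unique, and at least two observers are required (a consensus of one is
#' meaningless).
#'
#' @param masks named list of [binary_mask()] objects; names are observer
#'   ids.
#' @param lesion_id label for the lesion.
#' @param modality imaging condition label, `"MRI"` or `"MRI_PET"`.
#' @return An object of class `observer_set`.
#' @export
observer_set <- function(masks, lesion_id = "lesion", modality = c("MRI", "MRI_PET")) {
  modality <- match.arg(modality)
  if (!is.list(masks) || length(masks) < 2L)
    stop("need at least 2 observer masks", call. = FALSE)
  if (is.null(names(masks)) || anyDuplicated(names(masks)) ||
      any(!nzchar(names(masks))))
    stop("'masks' must be a named list with unique observer ids",
         call. = FALSE)
  if (!all(vapply(masks, inherits, logical(1), "binary_mask")))
    stop("all elements of 'masks' must be binary_mask objects", call. = FALSE)
  assert_same_grid(masks)
  structure(list(masks = masks, lesion_id = as.character(lesion_id),
                 modality = modality, grid = masks[[1]]$grid),
            class = "observer_set")
}

#' @export
print.observer_set <- function(x, ...) {
  cat("<observer_set> lesion '", x$lesion_id, "', condition ", x$modality,
      ", ", length(x$masks), " observers: ",
      paste(names(x$masks), collapse = ", "), "\n", sep = "")
  invisible(x)
}
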