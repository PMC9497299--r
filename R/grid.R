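#' Voxel grid geometry
#'
#' An `image_grid` describes the geometry every volume and mask in a
#' delineation study must share: the array shape (voxels per axis), the voxel
#' spacing in mm, the world-space position of the first voxel centre, and the
#' direction-cosine matrix. Together these define the NIfTI-style affine that
#' maps 0-based voxel indices to physical mm coordinates.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (each > 0).
#' @param origin numeric vector of length 3, world coordinate (mm) of the
#'   centre of the first voxel.
#' @param direction 3x3 matrix of direction cosines; columns must be
#'   orthonormal to within `1e-6`.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 32), spacing = c(4, 4, 5))
#' grid_affine(g)
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 integers, each >= 1", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)", call. = FALSE)
  if (!all(dim(direction) == c(3L, 3L)) || any(!is.finite(direction)))
    stop("'direction' must be a finite 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("'direction' columns must be orthonormal (tolerance 1e-6)",
         call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  cat("  origin (mm): ", paste(format(x$origin), collapse = ", "), "\n",
      sep = "")
  if (max(abs(x$direction - diag(3))) > 1e-12)
    cat("  non-identity direction matrix\n")
  invisible(x)
}

#' @describeIn image_grid The 4x4 affine mapping 0-based voxel indices to
#'   world mm coordinates.
#' @param grid an `image_grid`.
#' @export
grid_affine <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  rbind(cbind(grid$direction %*% diag(grid$spacing), grid$origin),
        c(0, 0, 0, 1))
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 1-based in R; the affine follows the NIfTI convention in
#' which the first voxel has (0-based) index 0 and sits at the grid origin,
#' so `voxel_to_world(grid, c(1, 1, 1))` equals `grid$origin`.
#'
#' @param grid an [image_grid()].
#' @param idx integer matrix (n x 3) or length-3 vector of 1-based voxel
#'   indices.
#' @param xyz numeric matrix (n x 3) or length-3 vector of world mm
#'   coordinates.
#' @return `voxel_to_world`: an n x 3 matrix of mm coordinates;
#'   `world_to_voxel`: an n x 3 matrix of (generally fractional) 1-based
#'   indices.
#' @export
voxel_to_world <- function(grid, idx) {
  stopifnot(inherits(grid, "image_grid"))
  idx <- rbind_coerce(idx)
  A <- grid$direction %*% diag(grid$spacing)
  sweep(t(A %*% t(idx - 1)), 2L, grid$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  stopifnot(inherits(grid, "image_grid"))
  xyz <- rbind_coerce(xyz)
  A <- grid$direction %*% diag(grid$spacing)
  t(solve(A) %*% t(sweep(xyz, 2L, grid$origin, "-"))) + 1
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  x
}

#' @describeIn image_grid Volume of one voxel in mm^3.
#' @export
voxel_volume_mm3 <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing)
}

# TRUE/character: first discordant field name, or TRUE if grids agree
# within tol (mm for spacing/origin, absolute for direction cosines).
grid_discordance <- function(a, b, tol = 1e-3) {
  if (!identical(a$shape, b$shape)) return("shape")
  if (max(abs(a$spacing - b$spacing)) > tol) return("spacing")
  if (max(abs(a$origin - b$origin)) > tol) return("origin")
  if (max(abs(a$direction - b$direction)) > tol) return("direction")
  TRUE
}

#' Test or assert that objects share one voxel grid
#'
#' Delineation metrics are only meaningful when every mask and volume lives
#' on the same grid; the package refuses mixed grids rather than silently
#' resampling. Shapes must match exactly; spacing, origin and direction must
#' agree within `tol`.
#'
#' @param ... volumes ([suv_volume()]), masks ([binary_mask()]) or
#'   `image_grid` objects, or a single list of them.
#' @param tol agreement tolerance (mm) for spacing, origin and direction.
#' @return Invisibly the common `image_grid`; errors naming the first
#'   discordant field otherwise.
#' @export
assert_same_grid <- function(..., tol = 1e-3) {
  items <- list(...)
  if (length(items) == 1L && is.list(items[[1]]) &&
      !inherits(items[[1]], c("image_grid", "binary_mask", "suv_volume")))
    items <- items[[1]]
  if (length(items) == 0L) stop("no objects supplied", call. = FALSE)
  grids <- lapply(items, grid_of)
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    dis <- grid_discordance(ref, grids[[i]], tol = tol)
    if (!isTRUE(dis))
      stop(sprintf("grid mismatch at item %d: %s differs", i, dis),
           call. = FALSE)
  }
  invisible(ref)
}

grid_of <- function(x) {
  if (inherits(x, "image_grid")) return(x)
  if (inherits(x, c("binary_mask", "suv_volume"))) return(x$grid)
  stop("cannot extract a grid from an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}
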