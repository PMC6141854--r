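#' Define a common-space volume grid
#'
#' A `volume_grid` records the sampling geometry every volume in an analysis
#' must share: the array shape (voxels per axis), the voxel size in mm, and a
#' 4x4 voxel-to-world affine. All pipeline volumes are expected to live on a
#' single normalized grid (e.g. MNI152 at 2x2x2 mm), so grid compatibility is
#' checked at every read.
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size Numeric vector of length 3, voxel edge lengths in mm
#'   (all > 0).
#' @param transform Optional 4x4 voxel-to-world affine. Defaults to a diagonal
#'   scaling by `voxel_size`.
#' @return An object of class `volume_grid`.
#' @examples
#' volume_grid(c(64, 64, 64), c(2, 2, 2))
#' @export
volume_grid <- function(shape, voxel_size, transform = NULL) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L)) {
    stop("`shape` must be three integers, all >= 1", call. = FALSE)
  }
  if (length(voxel_size) != 3L || anyNA(voxel_size) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive lengths (mm)", call. = FALSE)
  }
  if (is.null(transform)) {
    transform <- diag(c(voxel_size, 1))
  }
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4L, 4L))) {
    stop("`transform` must be a 4x4 matrix", call. = FALSE)
  }
  structure(
    list(shape = shape, voxel_size = voxel_size, transform = transform),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(
    "<volume_grid> ", paste(x$shape, collapse = " x "),
    " voxels @ ", paste(format(x$voxel_size), collapse = " x "), " mm\n",
    sep = ""
  )
  invisible(x)
}

#' Test two grids for compatibility
#'
#' Grids are compatible when shapes match exactly and voxel sizes and affine
#' entries agree within `tol` (absorbs float round-trip through NIfTI
#' headers).
#'
#' @param a,b `volume_grid` objects.
#' @param tol Numeric tolerance in mm (and per affine entry).
#' @return Logical scalar.
#' @export
grids_compatible <- function(a, b, tol = 1e-3) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol) &&
    all(abs(a$transform - b$transform) <= tol)
}

check_grid <- function(grid, expected, what = "volume") {
  if (!is.null(expected) && !grids_compatible(grid, expected)) {
    stop(
      sprintf(
        "%s grid (%s @ %s mm) does not match the expected grid (%s @ %s mm)",
        what,
        paste(grid$shape, collapse = "x"),
        paste(format(grid$voxel_size, digits = 4), collapse = "x"),
        paste(expected$shape, collapse = "x"),
        paste(format(expected$voxel_size, digits = 4), collapse = "x")
      ),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Voxel volume of a grid in millilitres
#'
#' @param grid A `volume_grid`.
#' @return Volume of one voxel in ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  prod(grid$voxel_size) / 1000
}

grid_from_nifti <- function(img) {
  volume_grid(
    shape = dim(img)[1:3],
    voxel_size = RNifti::pixdim(img)[1:3],
    transform = unclass(RNifti::xform(img))[1:4, 1:4]
  )
}

nifti_from_array <- function(data, grid) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- grid$voxel_size
  img
}
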