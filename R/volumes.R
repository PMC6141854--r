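MASK_KINDS <- c("followup_segmentation", "adc_core", "tmax_deficit", "prediction")
MAP_QUANTITIES <- c("adc", "tmax", "probability")

#' Construct a binary lesion mask
#'
#' A `lesion_mask` is a binary 3D volume on a [volume_grid()], tagged with the
#' patient it belongs to and the delineation that produced it: expert
#' segmentation of 90-day follow-up imaging, ADC-threshold core, Tmax-threshold
#' perfusion deficit, or a binarized machine-learning prediction.
#'
#' Values within `snap_tol` of 0 or 1 are snapped to exact 0/1 (thresholding
#' pipelines often emit float NIfTI); anything further away is an error.
#'
#' @param data 3D array of 0/1 values.
#' @param grid `volume_grid` the mask lives on.
#' @param patient_id Patient identifier (character scalar).
#' @param kind One of `"followup_segmentation"`, `"adc_core"`,
#'   `"tmax_deficit"`, `"prediction"`.
#' @param snap_tol Values within this distance of 0/1 are snapped.
#' @return A `lesion_mask`.
#' @export
lesion_mask <- function(data, grid, patient_id = NA_character_,
                        kind = "followup_segmentation", snap_tol = 1e-6) {
  stopifnot(inherits(grid, "volume_grid"))
  kind <- match.arg(kind, MASK_KINDS)
  data <- as.array(data)
  if (!identical(dim(data), NULL) && length(dim(data)) == 2L) {
    dim(data) <- c(dim(data), 1L)
  }
  if (length(dim(data)) != 3L || !all(dim(data) == grid$shape)) {
    stop("mask data shape does not match its grid", call. = FALSE)
  }
  v <- as.numeric(data)
  near0 <- abs(v) <= snap_tol
  near1 <- abs(v - 1) <= snap_tol
  if (!all(near0 | near1)) {
    bad <- v[!(near0 | near1)]
    stop(
      sprintf(
        "mask is not binary: %d voxel(s) outside {0,1} (range %.6g..%.6g)",
        length(bad), min(bad), max(bad)
      ),
      call. = FALSE
    )
  }
  out <- array(as.integer(near1), dim = grid$shape)
  structure(
    list(data = out, grid = grid, patient_id = as.character(patient_id),
         kind = kind),
    class = "lesion_mask"
  )
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(
    "<lesion_mask> patient ", x$patient_id, ", kind ", x$kind, ", ",
    sum(x$data), " voxel(s) on ", paste(x$grid$shape, collapse = "x"),
    " grid\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a scalar parameter map
#'
#' A `scalar_map` is a floating-point 3D volume carrying one of the
#' quantitative modalities the delineation rules consume: apparent diffusion
#' coefficient (`"adc"`, mm^2/s, >= 0), time-to-maximum of the tissue residue
#' function (`"tmax"`, s, >= 0), or a lesion probability (`"probability"`,
#' unitless in \[0, 1\]).
#'
#' @param data 3D numeric array.
#' @param grid `volume_grid`.
#' @param quantity One of `"adc"`, `"tmax"`, `"probability"`.
#' @param tol Tolerance for the range checks.
#' @return A `scalar_map`.
#' @export
scalar_map <- function(data, grid, quantity, tol = 1e-6) {
  stopifnot(inherits(grid, "volume_grid"))
  quantity <- match.arg(quantity, MAP_QUANTITIES)
  data <- as.array(data)
  if (length(dim(data)) != 3L || !all(dim(data) == grid$shape)) {
    stop("map data shape does not match its grid", call. = FALSE)
  }
  rng <- range(data)
  if (quantity %in% c("adc", "tmax") && rng[1] < -tol) {
    stop(sprintf("%s map has negative values (min %.6g)", quantity, rng[1]),
         call. = FALSE)
  }
  if (quantity == "probability" && (rng[1] < -tol || rng[2] > 1 + tol)) {
    stop(
      sprintf("probability map outside [0,1] (range %.6g..%.6g)",
              rng[1], rng[2]),
      call. = FALSE
    )
  }
  structure(
    list(data = data, grid = grid, quantity = quantity),
    class = "scalar_map"
  )
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(
    "<scalar_map> ", x$quantity, " on ",
    paste(x$grid$shape, collapse = "x"), " grid, range ",
    paste(format(range(x$data), digits = 4), collapse = ".."), "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a binary lesion mask from a NIfTI-1 file
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param expected_grid Optional `volume_grid`; a shape or voxel-size mismatch
#'   beyond tolerance is an error.
#' @param patient_id,kind Tags attached to the mask.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path, expected_grid = NULL, patient_id = NA_character_,
                      kind = "followup_segmentation") {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  check_grid(grid, expected_grid, what = paste0("mask '", path, "'"))
  lesion_mask(array(as.numeric(img), dim = grid$shape), grid,
              patient_id = patient_id, kind = kind)
}

#' Write a lesion mask to NIfTI-1
#'
#' @param mask A [lesion_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  RNifti::writeNifti(nifti_from_array(mask$data, mask$grid), path,
                     datatype = "uint8")
  invisible(path)
}

#' Read a scalar parameter map from a NIfTI-1 file
#'
#' @inheritParams read_mask
#' @param quantity Modality of the map: `"adc"`, `"tmax"` or `"probability"`.
#' @return A [scalar_map()].
#' @export
read_scalar_map <- function(path, quantity, expected_grid = NULL) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  check_grid(grid, expected_grid, what = paste0("map '", path, "'"))
  scalar_map(array(as.numeric(img), dim = grid$shape), grid, quantity)
}

#' Write a scalar map to NIfTI-1
#'
#' @param map A [scalar_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  RNifti::writeNifti(nifti_from_array(map$data, map$grid), path,
                     datatype = "double")
  invisible(path)
}
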