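#' Delineate the ischemic core by ADC thresholding
#'
#' A voxel belongs to the core when its apparent diffusion coefficient is
#' strictly below the threshold (default 600e-6 mm^2/s, the conventional
#' infarct-core cutoff). If a brain mask is supplied, voxels outside it are
#' excluded regardless of their ADC value.
#'
#' @param adc A [scalar_map()] with `quantity = "adc"` (mm^2/s).
#' @param threshold Core threshold in mm^2/s; inclusion is strict (`<`).
#' @param brain_mask Optional binary 3D array or [lesion_mask()] restricting
#'   the search to brain tissue.
#' @param patient_id Tag for the resulting mask.
#' @param min_cluster_size Optional minimum connected-component size
#'   (6-connectivity); smaller clusters are removed. `0` (default) disables
#'   the filter.
#' @return A [lesion_mask()] with `kind = "adc_core"`.
#' @examples
#' g <- volume_grid(c(3, 1, 1), c(2, 2, 2))
#' adc <- scalar_map(array(c(550e-6, 600e-6, 650e-6), c(3, 1, 1)), g, "adc")
#' delineate_adc_core(adc)$data  # only the first voxel is core
#' @export
delineate_adc_core <- function(adc, threshold = 600e-6, brain_mask = NULL,
                               patient_id = NA_character_,
                               min_cluster_size = 0L) {
  stopifnot(inherits(adc, "scalar_map"))
  if (adc$quantity != "adc") {
    stop("delineate_adc_core() needs a map with quantity 'adc', got '",
         adc$quantity, "'", call. = FALSE)
  }
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  sel <- adc$data < threshold
  sel <- apply_brain_mask(sel, brain_mask, adc$grid)
  sel <- apply_min_cluster(sel, min_cluster_size)
  lesion_mask(sel, adc$grid, patient_id = patient_id, kind = "adc_core")
}

#' Delineate the perfusion deficit by Tmax thresholding
#'
#' A voxel belongs to the perfusion deficit (penumbra proxy) when its
#' time-to-maximum is strictly above the threshold (default 6 s).
#'
#' @param tmax A [scalar_map()] with `quantity = "tmax"` (seconds).
#' @param threshold Deficit threshold in s; inclusion is strict (`>`).
#' @inheritParams delineate_adc_core
#' @return A [lesion_mask()] with `kind = "tmax_deficit"`.
#' @export
delineate_tmax_deficit <- function(tmax, threshold = 6, brain_mask = NULL,
                                   patient_id = NA_character_,
                                   min_cluster_size = 0L) {
  stopifnot(inherits(tmax, "scalar_map"))
  if (tmax$quantity != "tmax") {
    stop("delineate_tmax_deficit() needs a map with quantity 'tmax', got '",
         tmax$quantity, "'", call. = FALSE)
  }
  sel <- tmax$data > threshold
  sel <- apply_brain_mask(sel, brain_mask, tmax$grid)
  sel <- apply_min_cluster(sel, min_cluster_size)
  lesion_mask(sel, tmax$grid, patient_id = patient_id, kind = "tmax_deficit")
}

#' Binarize a lesion-prediction probability map
#'
#' Converts a continuous predicted-lesion probability map into a binary
#' delineation. The boundary is inclusive: a voxel exactly at the threshold is
#' lesion (the argmax-of-two-classes convention at 0.5).
#'
#' @param prob A [scalar_map()] with `quantity = "probability"`.
#' @param threshold Inclusion threshold in \[0, 1\]; inclusive (`>=`).
#' @inheritParams delineate_adc_core
#' @return A [lesion_mask()] with `kind = "prediction"`.
#' @export
binarize_prediction <- function(prob, threshold = 0.5,
                                patient_id = NA_character_,
                                min_cluster_size = 0L) {
  stopifnot(inherits(prob, "scalar_map"))
  if (prob$quantity != "probability") {
    stop("binarize_prediction() needs a map with quantity 'probability', got '",
         prob$quantity, "'", call. = FALSE)
  }
  sel <- prob$data >= threshold
  sel <- apply_min_cluster(sel, min_cluster_size)
  lesion_mask(sel, prob$grid, patient_id = patient_id, kind = "prediction")
}

#' Build a normalized lesion-frequency map
#'
#' The voxelwise mean of a set of binary lesion masks: 0 where no lesion in
#' the cohort touches the voxel, 1 where every lesion does. This is the
#' normalized lesion-distribution map used to visualize cohort lesion
#' topography.
#'
#' @param masks Non-empty list of [lesion_mask()] objects on one grid.
#' @return A [scalar_map()] with `quantity = "probability"`.
#' @export
lesion_frequency_map <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L) {
    stop("`masks` must be a non-empty list of lesion masks", call. = FALSE)
  }
  for (m in masks) stopifnot(inherits(m, "lesion_mask"))
  grid <- masks[[1]]$grid
  for (m in masks[-1]) {
    if (!grids_compatible(m$grid, grid)) {
      stop("all masks must share one grid", call. = FALSE)
    }
  }
  acc <- array(0, dim = grid$shape)
  for (m in masks) acc <- acc + m$data
  scalar_map(acc / length(masks), grid, "probability")
}

apply_brain_mask <- function(sel, brain_mask, grid) {
  if (is.null(brain_mask)) return(sel)
  bm <- if (inherits(brain_mask, "lesion_mask")) {
    if (!grids_compatible(brain_mask$grid, grid)) {
      stop("brain mask grid does not match the map grid", call. = FALSE)
    }
    brain_mask$data
  } else {
    as.array(brain_mask)
  }
  if (!all(dim(bm) == dim(sel))) {
    stop("brain mask shape does not match the map", call. = FALSE)
  }
  sel & (bm != 0)
}

# Remove 6-connected components smaller than min_size (off when min_size <= 1).
apply_min_cluster <- function(sel, min_size) {
  min_size <- as.integer(min_size)
  if (min_size <= 1L || !any(sel)) return(sel)
  lab <- label_components(sel)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  array(lab %in% keep, dim = dim(sel))
}

# Iterative flood fill over the 6-neighbourhood; adequate for the small
# cluster-filter use case (single pass over a frontier per component).
label_components <- function(sel) {
  d <- dim(sel)
  lab <- array(0L, dim = d)
  idx_all <- which(sel)
  nxt <- 0L
  offs <- neighbour_offsets(d)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier)) {
      nb <- unique(unlist(lapply(offs, function(o) o(frontier))))
      nb <- nb[!is.na(nb)]
      nb <- nb[sel[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab
}

# Linear-index neighbour maps with boundary guards, one per axis direction.
neighbour_offsets <- function(d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  coord <- function(i) {
    i0 <- i - 1L
    list(x = i0 %% nx, y = (i0 %/% nx) %% ny, z = i0 %/% (nx * ny))
  }
  shift <- function(dx, dy, dz) {
    force(dx); force(dy); force(dz)
    function(i) {
      c0 <- coord(i)
      x <- c0$x + dx; y <- c0$y + dy; z <- c0$z + dz
      ok <- x >= 0L & x < nx & y >= 0L & y < ny & z >= 0L & z < nz
      out <- rep(NA_integer_, length(i))
      out[ok] <- 1L + x[ok] + nx * (y[ok] + ny * z[ok])
      out
    }
  }
  list(shift(1L, 0L, 0L), shift(-1L, 0L, 0L), shift(0L, 1L, 0L),
       shift(0L, -1L, 0L), shift(0L, 0L, 1L), shift(0L, 0L, -1L))
}
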