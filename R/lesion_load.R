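#' Lesion load of one atlas region
#'
#' The lesion load of a region is the percentage of that region's voxels
#' covered by the lesion mask:
#' `100 * |{label == region_id & mask == 1}| / |{label == region_id}|`.
#'
#' @param mask A [lesion_mask()] on the atlas grid.
#' @param atlas A [lesion_atlas()].
#' @param region_id Region id present in the atlas table.
#' @return Load percentage in \[0, 100\].
#' @export
region_load <- function(mask, atlas, region_id) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(atlas, "lesion_atlas"))
  if (!grids_compatible(mask$grid, atlas$grid)) {
    stop("mask and atlas must share a grid", call. = FALSE)
  }
  region_id <- as.integer(region_id)
  if (!region_id %in% atlas$regions$region_id) {
    stop(sprintf("region id %d is not defined in the atlas", region_id),
         call. = FALSE)
  }
  in_region <- atlas$labels == region_id
  denom <- sum(in_region)
  if (denom == 0L) {
    stop(sprintf("region %d has no voxels in the label volume", region_id),
         call. = FALSE)
  }
  100 * sum(mask$data[in_region]) / denom
}

#' Total lesion volume in millilitres
#'
#' @param mask A [lesion_mask()].
#' @return Lesion voxel count times voxel volume, in ml.
#' @examples
#' g <- volume_grid(c(10, 10, 10), c(2, 2, 2))
#' m <- lesion_mask(array(1, c(10, 10, 10)), g)
#' total_volume(m)  # 1000 voxels x 0.008 ml = 8 ml
#' @export
total_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$data) * voxel_volume_ml(mask$grid)
}

#' Compute the patients-by-regions lesion-load matrix
#'
#' Overlays one lesion mask per patient on the atlas and returns a tibble with
#' one row per patient (in cohort order) and one load column per atlas region,
#' plus the total lesion volume in ml and the count of lesion voxels falling
#' on unlabeled (background) voxels. With a 121-region atlas each patient
#' contributes a feature vector of 121 regional loads plus total volume.
#'
#' Lesion voxels outside every atlas region still count toward
#' `total_volume_ml` but toward no regional load; `unlabeled_voxels` makes
#' that signal loss visible (parcellations rarely cover the whole brain).
#'
#' @param masks List of [lesion_mask()] objects, one per cohort patient, all
#'   of one delineation kind and on the atlas grid. Masks are matched to
#'   patients by `patient_id`.
#' @param atlas A [lesion_atlas()].
#' @param cohort A [cohort_table()] defining patient order.
#' @return A tibble of class `load_matrix` with columns `patient_id`, one
#'   `load_<region_id>` column per region (percent), `total_volume_ml` and
#'   `unlabeled_voxels`; the delineation kind and region ids are attached as
#'   attributes `delineation_kind` and `region_ids`.
#' @export
compute_load_matrix <- function(masks, atlas, cohort) {
  stopifnot(inherits(atlas, "lesion_atlas"))
  cohort <- cohort_table(cohort)
  for (m in masks) stopifnot(inherits(m, "lesion_mask"))
  kinds <- unique(vapply(masks, function(m) m$kind, character(1)))
  if (length(kinds) > 1L) {
    stop("masks mix delineation kinds: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  }
  ids <- vapply(masks, function(m) m$patient_id, character(1))
  if (anyDuplicated(ids)) {
    stop("multiple masks share a patient_id", call. = FALSE)
  }
  missing <- setdiff(cohort$patient_id, ids)
  if (length(missing)) {
    stop("no mask supplied for patient(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  region_ids <- sort(atlas$regions$region_id)
  lab <- as.integer(atlas$labels)
  # region denominators, computed once from the atlas
  denom <- tabulate(lab, nbins = max(region_ids))[region_ids]
  if (any(denom == 0L)) {
    stop("region(s) with zero voxels in the label volume: ",
         paste(region_ids[denom == 0L], collapse = ", "), call. = FALSE)
  }
  vox_ml <- voxel_volume_ml(atlas$grid)

  rows <- lapply(cohort$patient_id, function(pid) {
    m <- masks[[match(pid, ids)]]
    if (!grids_compatible(m$grid, atlas$grid)) {
      stop(sprintf("mask for patient '%s' is not on the atlas grid", pid),
           call. = FALSE)
    }
    lesion_labels <- lab[m$data == 1L]
    hit <- tabulate(lesion_labels, nbins = max(region_ids))[region_ids]
    tibble::tibble(
      patient_id = pid,
      region_id = region_ids,
      load = 100 * hit / denom,
      total_volume_ml = length(lesion_labels) * vox_ml,
      unlabeled_voxels = sum(lesion_labels == 0L)
    )
  })
  long <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(
    long,
    id_cols = c("patient_id", "total_volume_ml", "unlabeled_voxels"),
    names_from = "region_id", values_from = "load", names_prefix = "load_"
  )
  wide <- dplyr::relocate(wide, "total_volume_ml", "unlabeled_voxels",
                          .after = dplyr::last_col())
  structure(
    wide,
    class = c("load_matrix", class(wide)),
    delineation_kind = if (length(kinds)) kinds else NA_character_,
    region_ids = region_ids
  )
}

#' Write a load matrix as TSV
#'
#' One row per patient; columns `patient_id`, `load_<region_id>` per region,
#' `total_volume_ml` and `unlabeled_voxels`.
#'
#' @param loads A `load_matrix` tibble from [compute_load_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_load_matrix <- function(loads, path) {
  readr::write_tsv(tibble::as_tibble(loads), path, progress = FALSE)
  invisible(path)
}

#' Read a load matrix from TSV
#'
#' @param path TSV written by [write_load_matrix()].
#' @param delineation_kind Optional kind tag to reattach.
#' @return A `load_matrix` tibble.
#' @export
read_load_matrix <- function(path, delineation_kind = NA_character_) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         patient_id = readr::col_character(),
                         .default = readr::col_double()
                       ))
  region_ids <- as.integer(sub("^load_", "", grep("^load_", names(x),
                                                  value = TRUE)))
  structure(
    x,
    class = c("load_matrix", class(x)),
    delineation_kind = delineation_kind,
    region_ids = region_ids
  )
}
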