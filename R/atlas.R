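#' Construct a labeled brain atlas
#'
#' An atlas pairs an integer label volume (0 = background/unlabeled) with a
#' region table describing each parcel: its id, a human-readable name and its
#' tissue class (gray or white matter). It stands in for parcellations such as
#' the Juelich histological atlas (29 white-matter tracts + 92 gray-matter
#' areas) used for regional lesion-load extraction.
#'
#' Every nonzero label present in the volume must have a row in the region
#' table; table rows whose id never occurs in the volume are retained but
#' reported with a warning (they would yield division-by-zero loads and are
#' rejected at load-computation time).
#'
#' @param labels 3D integer(-valued) array of region labels.
#' @param grid `volume_grid` the labels live on.
#' @param regions Data frame with columns `region_id` (positive integer,
#'   unique), `name` (character) and `tissue_class` (`"gray"` or `"white"`).
#' @param int_tol Tolerance for deciding the volume is integer-valued.
#' @return An object of class `lesion_atlas`.
#' @export
lesion_atlas <- function(labels, grid, regions, int_tol = 1e-6) {
  stopifnot(inherits(grid, "volume_grid"))
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L || !all(dim(labels) == grid$shape)) {
    stop("label volume shape does not match its grid", call. = FALSE)
  }
  v <- as.numeric(labels)
  if (max(abs(v - round(v))) > int_tol) {
    stop("label volume has non-integer voxel values beyond tolerance",
         call. = FALSE)
  }
  labels <- array(as.integer(round(v)), dim = grid$shape)
  if (min(labels) < 0L) stop("label volume has negative labels", call. = FALSE)

  regions <- tibble::as_tibble(regions)
  req <- c("region_id", "name", "tissue_class")
  if (!all(req %in% names(regions))) {
    stop("region table must have columns region_id, name, tissue_class",
         call. = FALSE)
  }
  regions$region_id <- as.integer(regions$region_id)
  regions$name <- as.character(regions$name)
  regions$tissue_class <- as.character(regions$tissue_class)
  if (nrow(regions) < 1L) stop("atlas must define at least one region", call. = FALSE)
  if (anyNA(regions$region_id) || any(regions$region_id < 1L)) {
    stop("region ids must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(regions$region_id)) {
    stop("region ids must be unique", call. = FALSE)
  }
  if (!all(regions$tissue_class %in% c("gray", "white"))) {
    stop("tissue_class must be 'gray' or 'white'", call. = FALSE)
  }

  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, regions$region_id)
  if (length(missing)) {
    stop(
      sprintf("label(s) %s occur in the volume but are absent from the region table",
              paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  orphan <- setdiff(regions$region_id, present)
  if (length(orphan)) {
    warning(
      sprintf("region table row(s) with id %s never occur in the label volume",
              paste(orphan, collapse = ", ")),
      call. = FALSE
    )
  }
  structure(
    list(labels = labels, grid = grid, regions = regions),
    class = "lesion_atlas"
  )
}

#' @export
print.lesion_atlas <- function(x, ...) {
  tc <- table(x$regions$tissue_class)
  cat(
    "<lesion_atlas> ", nrow(x$regions), " regions (",
    if ("white" %in% names(tc)) tc[["white"]] else 0L, " white, ",
    if ("gray" %in% names(tc)) tc[["gray"]] else 0L, " gray) on ",
    paste(x$grid$shape, collapse = "x"), " grid\n",
    sep = ""
  )
  invisible(x)
}

#' Read an atlas from a NIfTI label volume and a TSV region table
#'
#' @param label_volume_path NIfTI-1 file with integer(-valued) labels.
#' @param region_table_path TSV with header columns `region_id`, `name`,
#'   `tissue_class`.
#' @param expected_grid Optional `volume_grid` to enforce.
#' @return A [lesion_atlas()].
#' @export
read_atlas <- function(label_volume_path, region_table_path,
                       expected_grid = NULL) {
  img <- RNifti::readNifti(label_volume_path)
  grid <- grid_from_nifti(img)
  check_grid(grid, expected_grid,
             what = paste0("atlas '", label_volume_path, "'"))
  regions <- readr::read_tsv(region_table_path, show_col_types = FALSE,
                             progress = FALSE)
  lesion_atlas(array(as.numeric(img), dim = grid$shape), grid, regions)
}

#' Write an atlas to a NIfTI label volume and a TSV region table
#'
#' @param atlas A [lesion_atlas()].
#' @param label_volume_path,region_table_path Output paths.
#' @return `label_volume_path`, invisibly.
#' @export
write_atlas <- function(atlas, label_volume_path, region_table_path) {
  stopifnot(inherits(atlas, "lesion_atlas"))
  RNifti::writeNifti(nifti_from_array(atlas$labels, atlas$grid),
                     label_volume_path, datatype = "int16")
  readr::write_tsv(atlas$regions, region_table_path, progress = FALSE)
  invisible(label_volume_path)
}
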