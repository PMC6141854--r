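#' Run the full lesion-load correlation pipeline
#'
#' Orchestrates the end-to-end analysis: obtain a cohort (simulate one, or
#' ingest a directory previously written by [generate_cohort()]), derive the
#' requested lesion delineations, compute load matrices and lesion-frequency
#' maps, dichotomize the cohort by revascularization success, correlate loads
#' with outcome per delineation kind x cohort split, rank the top regions,
#' and compare the NIHSS and mRS correlation profiles on the whole cohort.
#'
#' `config` is a named list (or path to a YAML file) with entries:
#' \describe{
#'   \item{simulation}{Arguments of the provenance schema understood by
#'     [read_simulation_config()]; mutually exclusive with `inputs`.}
#'   \item{inputs}{Path to a cohort directory in the layout written by
#'     [generate_cohort()] (atlas, cohort.tsv, per-patient volumes).}
#'   \item{delineation_kinds}{Subset of `followup_segmentation`, `adc_core`,
#'     `tmax_deficit`, `prediction` (default: first three).}
#'   \item{outcome}{`nihss_3m` (default) or `mrs_3m`.}
#'   \item{n_boot, level, seed}{Bootstrap settings (defaults 1000, 0.95; the
#'     seed defaults to the simulation master seed).}
#'   \item{out_dir}{Output directory (required).}
#' }
#'
#' Outputs land under `out_dir/<kind>/<split>/<outcome>/` (correlation and
#' top-10 TSVs), with per-kind load matrices, per-kind/per-split frequency
#' maps, the whole-cohort NIHSS-vs-mRS comparison, and `run_log.yaml`
#' recording package version, config and seed. Reruns with the same config
#' reproduce identical TSVs.
#'
#' @param config Named list or YAML path, see Details.
#' @return Invisibly, a list with the output directory, the per-combination
#'   correlation tables, and the NIHSS-vs-mRS `profile_comparison`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  kinds <- config$delineation_kinds %||%
    c("followup_segmentation", "adc_core", "tmax_deficit")
  bad <- setdiff(kinds, MASK_KINDS)
  if (length(bad)) {
    stop("unknown delineation kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  outcome <- config$outcome %||% "nihss_3m"
  n_boot <- config$n_boot %||% 1000
  level <- config$level %||% 0.95

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  data <- stage("ingest", load_pipeline_inputs(config))
  atlas <- data$atlas
  cohort <- data$cohort
  seed <- config$seed %||% data$master_seed %||% 1L

  masks_by_kind <- stage("delineate", lapply(
    stats::setNames(kinds, kinds),
    function(k) lapply(data$patients, derive_mask, kind = k)
  ))

  splits <- c(list(all = cohort), split_by_tici(cohort))
  tables <- list()
  for (k in kinds) {
    kdir <- file.path(out_dir, k)
    dir.create(kdir, recursive = TRUE, showWarnings = FALSE)
    loads <- stage("loads", compute_load_matrix(masks_by_kind[[k]], atlas,
                                                cohort))
    write_load_matrix(loads, file.path(kdir, "loads.tsv"))
    for (s in names(splits)) {
      sub <- splits[[s]]
      sdir <- file.path(kdir, s)
      if (nrow(sub) < 2L) {
        warning(sprintf("split '%s' has %d patient(s); skipping", s,
                        nrow(sub)), call. = FALSE)
        next
      }
      dir.create(file.path(sdir, outcome), recursive = TRUE,
                 showWarnings = FALSE)
      sub_masks <- masks_by_kind[[k]][match(sub$patient_id,
                                            cohort$patient_id)]
      freq <- stage("frequency_map", lesion_frequency_map(sub_masks))
      write_scalar_map(freq, file.path(sdir, "frequency_map.nii.gz"))
      sub_loads <- dplyr::filter(loads, .data$patient_id %in% sub$patient_id)
      tab <- stage("correlate", correlate_features(
        restore_load_matrix(sub_loads, loads), sub, outcome = outcome,
        n_boot = n_boot, level = level, seed = seed,
        regions = atlas$regions, cohort_tag = s
      ))
      write_correlation_table(tab, file.path(sdir, outcome,
                                             "correlations.tsv"))
      write_correlation_table(rank_top(tab, 10),
                              file.path(sdir, outcome, "top10.tsv"))
      tables[[paste(k, s, outcome, sep = "/")]] <- tab
    }
  }

  # whole-cohort NIHSS vs mRS comparison on the first delineation kind
  base_loads <- compute_load_matrix(masks_by_kind[[kinds[1]]], atlas, cohort)
  tab_nihss <- stage("compare", correlate_features(
    base_loads, cohort, "nihss_3m", n_boot = n_boot, level = level,
    seed = seed, regions = atlas$regions))
  tab_mrs <- correlate_features(
    base_loads, cohort, "mrs_3m", n_boot = n_boot, level = level,
    seed = seed, regions = atlas$regions)
  cmp <- compare_profiles(tab_nihss$r, tab_mrs$r)
  readr::write_tsv(
    tibble::tibble(statistic = cmp$statistic, p_value = cmp$p_value,
                   n_pairs = cmp$n_pairs, n_zero = cmp$n_zero,
                   n_undefined = cmp$n_undefined, method = cmp$method,
                   delineation_kind = kinds[1]),
    file.path(out_dir, "comparison_nihss_vs_mrs.tsv"), progress = FALSE
  )

  yaml::write_yaml(
    list(
      package = "lesionload",
      version = as.character(utils::packageVersion("lesionload")),
      seed = seed, n_boot = n_boot, level = level, outcome = outcome,
      delineation_kinds = kinds,
      config_hash = rlang::hash(config),
      n_patients = nrow(cohort)
    ),
    file.path(out_dir, "run_log.yaml")
  )
  invisible(list(out_dir = out_dir, tables = tables, comparison = cmp,
                 nihss_table = tab_nihss, mrs_table = tab_mrs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

restore_load_matrix <- function(sub, full) {
  structure(sub, class = class(full),
            delineation_kind = attr(full, "delineation_kind", exact = TRUE),
            region_ids = attr(full, "region_ids", exact = TRUE))
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    cfg <- if (is.character(sim)) read_simulation_config(sim) else {
      args <- sim
      if (!is.null(args$grid)) {
        args$grid <- volume_grid(unlist(args$grid$shape),
                                 unlist(args$grid$voxel_size))
      }
      for (v in c("tici_distribution", "eloquent_regions",
                  "penumbra_salvage_by_tici")) {
        if (!is.null(args[[v]])) args[[v]] <- unlist(args[[v]])
      }
      do.call(simulation_config, args)
    }
    syn <- generate_cohort(cfg)
    list(atlas = syn$atlas, cohort = syn$cohort, patients = syn$patients,
         master_seed = cfg$master_seed)
  } else if (!is.null(config$inputs)) {
    read_cohort_directory(config$inputs)
  } else {
    stop("config needs either a `simulation` block or an `inputs` directory",
         call. = FALSE)
  }
}

#' Read a cohort directory written by [generate_cohort()]
#'
#' @param dir Directory containing `atlas_labels.nii.gz`,
#'   `atlas_regions.tsv`, `cohort.tsv` and a `patients/` subdirectory.
#' @return List with `atlas`, `cohort` and per-patient volume bundles.
#' @export
read_cohort_directory <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas_labels.nii.gz"),
                      file.path(dir, "atlas_regions.tsv"))
  cohort <- read_cohort(file.path(dir, "cohort.tsv"))
  pd <- file.path(dir, "patients")
  patients <- lapply(cohort$patient_id, function(pid) {
    list(
      record = cohort[cohort$patient_id == pid, ],
      final_mask = read_mask(file.path(pd, paste0(pid, "_followup.nii.gz")),
                             atlas$grid, pid, "followup_segmentation"),
      brain_mask = read_mask(file.path(pd, paste0(pid, "_brain.nii.gz")),
                             atlas$grid, pid, "followup_segmentation"),
      adc_map = read_scalar_map(file.path(pd, paste0(pid, "_adc.nii.gz")),
                                "adc", atlas$grid),
      tmax_map = read_scalar_map(file.path(pd, paste0(pid, "_tmax.nii.gz")),
                                 "tmax", atlas$grid),
      prediction_map = read_scalar_map(
        file.path(pd, paste0(pid, "_prediction.nii.gz")), "probability",
        atlas$grid)
    )
  })
  list(atlas = atlas, cohort = cohort, patients = patients,
       master_seed = NULL)
}

derive_mask <- function(p, kind) {
  pid <- p$record$patient_id
  switch(
    kind,
    followup_segmentation = p$final_mask,
    adc_core = delineate_adc_core(p$adc_map, brain_mask = p$brain_mask,
                                  patient_id = pid),
    tmax_deficit = delineate_tmax_deficit(p$tmax_map,
                                          brain_mask = p$brain_mask,
                                          patient_id = pid),
    prediction = binarize_prediction(p$prediction_map, patient_id = pid)
  )
}

#' Render a markdown report from a completed pipeline run
#'
#' Mirrors the figures a reader expects from this analysis: per
#' delineation-kind and cohort-split top-10 correlation tables (significant
#' correlations marked with an asterisk), axial slice images of the
#' lesion-frequency maps (written as PNGs when a graphics device is
#' available), and the NIHSS-vs-mRS Wilcoxon comparison summary.
#'
#' @param results_dir Directory written by [run_pipeline()].
#' @param report_path Output markdown path (default
#'   `results_dir/report.md`).
#' @return `report_path`, invisibly.
#' @export
render_report <- function(results_dir,
                          report_path = file.path(results_dir, "report.md")) {
  log_path <- file.path(results_dir, "run_log.yaml")
  cmp_path <- file.path(results_dir, "comparison_nihss_vs_mrs.tsv")
  missing <- c(log_path, cmp_path)[!file.exists(c(log_path, cmp_path))]
  if (length(missing)) {
    stop("incomplete run directory; missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  log <- yaml::read_yaml(log_path)
  lines <- c(
    "# Lesion-load correlation report",
    "",
    sprintf("- patients: %s", log$n_patients),
    sprintf("- outcome: %s", log$outcome),
    sprintf("- bootstrap: %s resamples, level %s, seed %s",
            log$n_boot, log$level, log$seed),
    ""
  )
  fig_dir <- file.path(results_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  for (k in log$delineation_kinds) {
    kdir <- file.path(results_dir, k)
    for (s in list.dirs(kdir, recursive = FALSE, full.names = FALSE)) {
      top_path <- file.path(kdir, s, log$outcome, "top10.tsv")
      if (!file.exists(top_path)) next
      lines <- c(lines, sprintf("## %s / %s / %s", k, s, log$outcome), "")
      top <- readr::read_tsv(top_path, show_col_types = FALSE,
                             progress = FALSE)
      if (nrow(top) == 0L) {
        lines <- c(lines, "no estimable features", "")
      } else {
        lines <- c(lines, top10_markdown(top), "")
      }
      fm <- file.path(kdir, s, "frequency_map.nii.gz")
      if (file.exists(fm)) {
        png_rel <- file.path("figures", sprintf("freq_%s_%s.png", k, s))
        ok <- tryCatch({
          map <- read_scalar_map(fm, "probability")
          gg <- plot_frequency_map(map)
          suppressMessages(ggplot2::ggsave(
            file.path(results_dir, png_rel), gg,
            width = 4, height = 4, dpi = 96))
          TRUE
        }, error = function(e) FALSE)
        if (ok) {
          lines <- c(lines,
                     sprintf("![lesion frequency, %s %s](%s)", k, s, png_rel),
                     "")
        }
      }
    }
  }
  cmp <- readr::read_tsv(cmp_path, show_col_types = FALSE, progress = FALSE)
  lines <- c(
    lines, "## NIHSS vs mRS correlation profiles (whole cohort)", "",
    sprintf(
      "Wilcoxon signed-rank on %d paired regional correlations (%s): W = %g, two-sided p = %.4g.",
      cmp$n_pairs, cmp$method, cmp$statistic, cmp$p_value
    ),
    ""
  )
  writeLines(lines, report_path)
  invisible(report_path)
}

top10_markdown <- function(top) {
  hdr <- "| rank | feature | r | 95% CI | significant |"
  sep <- "|---|---|---|---|---|"
  rows <- vapply(seq_len(nrow(top)), function(i) {
    ci <- if (is.na(top$ci_low[i])) "-" else {
      sprintf("[%.3f, %.3f]", top$ci_low[i], top$ci_high[i])
    }
    sprintf("| %d | %s | %.3f | %s | %s |", top$rank[i], top$name[i],
            top$r[i], ci, if (isTRUE(top$significant[i])) "*" else "")
  }, character(1))
  c(hdr, sep, rows)
}
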