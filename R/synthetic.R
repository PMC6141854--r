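#' Configure the synthetic stroke-cohort simulator
#'
#' Bundles every knob of the generative model: the common grid, the
#' parcellation sizes (29 white-matter + 92 gray-matter regions by default,
#' the cardinality of the Juelich atlas), the cohort size and TICI-grade
#' distribution, the outcome model (linear in designated "eloquent" regional
#' loads and total volume, plus Gaussian noise), and the salvage model that
#' links revascularization success to how much penumbra escapes infarction.
#'
#' Defaults emulate the retrospective cohort structure the pipeline targets:
#' 55 patients whose TICI mix yields roughly 35 successful (2b-3) and 20
#' unsuccessful (0-2a) revascularizations, three eloquent regions carrying
#' 20 NIHSS points per fully-lesioned region, 0.05 NIHSS points per ml of
#' lesion, and NIHSS noise of 3 points. The mRS views the same impairment
#' through additional rater/physiology blur (5 NIHSS points) and the
#' conventional clinical severity banding (0-1 -> 0, 2-4 -> 1, 5-8 -> 2,
#' 9-13 -> 3, 14-20 -> 4, 21-42 -> 5), so mRS is a coarser, noisier scale
#' and NIHSS correlates better with lesion loads by construction.
#'
#' @param grid Common [volume_grid()] (default 64^3 voxels at 2 mm).
#' @param n_wm_regions,n_gm_regions White-/gray-matter region counts.
#' @param n_patients Cohort size.
#' @param tici_distribution Named probabilities over grades `0,1,2a,2b,3`
#'   (must sum to 1).
#' @param eloquent_regions Named numeric vector (region id -> NIHSS points
#'   contributed by a 100% load on that region), or `"auto"` (default) to
#'   designate three regions at the vascular-territory epicenters once the
#'   atlas is built: the region containing each hemisphere's epicenter plus
#'   the next-nearest left-territory region, 25 points each (see
#'   [default_eloquent_regions()]).
#' @param volume_weight NIHSS points per ml of final lesion.
#' @param intercept Baseline NIHSS points.
#' @param noise_sd NIHSS noise standard deviation (points, >= 0).
#' @param mrs_noise_sd Rater/physiology noise, in NIHSS points, blurring the
#'   impairment seen by the mRS assessor before severity banding.
#' @param penumbra_salvage_by_tici Named fraction in \[0,1\] of the penumbra
#'   shell salvaged per TICI grade; must be non-decreasing from grade 0 to 3.
#' @param lesion_volume_meanlog,lesion_volume_sdlog Log-normal parameters of
#'   the target penumbra volume in ml.
#' @param core_fraction Length-2 range; each patient's core is a uniformly
#'   drawn fraction of the penumbra volume inside this range.
#' @param master_seed Integer master seed; every downstream draw derives from
#'   it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    grid = volume_grid(c(64, 64, 64), c(2, 2, 2)),
    n_wm_regions = 29,
    n_gm_regions = 92,
    n_patients = 55,
    tici_distribution = c("0" = 0.07, "1" = 0.08, "2a" = 0.19,
                          "2b" = 0.26, "3" = 0.40),
    eloquent_regions = "auto",
    volume_weight = 0.05,
    intercept = 1,
    noise_sd = 3,
    mrs_noise_sd = 5,
    penumbra_salvage_by_tici = c("0" = 0.05, "1" = 0.15, "2a" = 0.30,
                                 "2b" = 0.70, "3" = 0.95),
    lesion_volume_meanlog = log(25),
    lesion_volume_sdlog = 0.8,
    core_fraction = c(0.25, 0.5),
    master_seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"))
  if (n_wm_regions + n_gm_regions < 1L) {
    stop("need at least one region", call. = FALSE)
  }
  if (n_patients < 1L) stop("`n_patients` must be >= 1", call. = FALSE)
  if (!setequal(names(tici_distribution), TICI_GRADES)) {
    stop("`tici_distribution` must name all five TICI grades", call. = FALSE)
  }
  tici_distribution <- tici_distribution[TICI_GRADES]
  if (abs(sum(tici_distribution) - 1) > 1e-8 || any(tici_distribution < 0)) {
    stop("`tici_distribution` must be probabilities summing to 1",
         call. = FALSE)
  }
  if (!setequal(names(penumbra_salvage_by_tici), TICI_GRADES)) {
    stop("`penumbra_salvage_by_tici` must name all five TICI grades",
         call. = FALSE)
  }
  penumbra_salvage_by_tici <- penumbra_salvage_by_tici[TICI_GRADES]
  if (any(penumbra_salvage_by_tici < 0) || any(penumbra_salvage_by_tici > 1)) {
    stop("salvage fractions must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(penumbra_salvage_by_tici)) {
    stop("salvage fraction must be non-decreasing in TICI grade",
         call. = FALSE)
  }
  if (noise_sd < 0 || mrs_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  if (length(core_fraction) != 2L || any(core_fraction <= 0) ||
      any(core_fraction >= 1) || core_fraction[1] > core_fraction[2]) {
    stop("`core_fraction` must be a range inside (0, 1)", call. = FALSE)
  }
  if (!identical(eloquent_regions, "auto") && length(eloquent_regions) &&
      is.null(names(eloquent_regions))) {
    stop("`eloquent_regions` must be named by region id, or \"auto\"",
         call. = FALSE)
  }
  structure(
    list(
      grid = grid, n_wm_regions = as.integer(n_wm_regions),
      n_gm_regions = as.integer(n_gm_regions),
      n_patients = as.integer(n_patients),
      tici_distribution = tici_distribution,
      eloquent_regions = eloquent_regions,
      volume_weight = volume_weight, intercept = intercept,
      noise_sd = noise_sd, mrs_noise_sd = mrs_noise_sd,
      penumbra_salvage_by_tici = penumbra_salvage_by_tici,
      lesion_volume_meanlog = lesion_volume_meanlog,
      lesion_volume_sdlog = lesion_volume_sdlog,
      core_fraction = core_fraction,
      master_seed = as.integer(master_seed)
    ),
    class = "simulation_config"
  )
}

#' Generate a synthetic brain parcellation
#'
#' Builds an ellipsoidal brain on the configured grid, splits it into an
#' inner (white-matter) compartment and an outer (gray-matter) shell, and
#' partitions each compartment into regions by nearest-seed assignment. Seeds
#' are drawn in one hemisphere and mirrored across the midsagittal plane so
#' regions come in left/right homologue pairs (an odd count places one region
#' astride the midline). White-matter regions get ids `1..n_wm`, gray-matter
#' regions `n_wm+1..n_wm+n_gm`. Deterministic given `master_seed`.
#'
#' @param config A [simulation_config()].
#' @return A [lesion_atlas()] covering the whole synthetic brain (every brain
#'   voxel is labeled).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- config$grid
  d <- grid$shape
  ctr <- (d + 1) / 2
  semi <- 0.45 * d
  ax <- arrayInd(seq_len(prod(d)), d)
  u <- ((ax[, 1] - ctr[1]) / semi[1])^2 +
    ((ax[, 2] - ctr[2]) / semi[2])^2 +
    ((ax[, 3] - ctr[3]) / semi[3])^2
  brain <- u <= 1
  wm <- u <= 0.6^2
  gm <- brain & !wm
  n_wm <- config$n_wm_regions
  n_gm <- config$n_gm_regions
  if (sum(wm) < n_wm || sum(gm) < n_gm) {
    stop(sprintf(
      "grid too small: %d white voxels for %d regions, %d gray for %d",
      sum(wm), n_wm, sum(gm), n_gm
    ), call. = FALSE)
  }

  labels <- integer(prod(d))
  with_seed(feature_seed(config$master_seed, "atlas"), {
    labels[wm] <- assign_regions(ax[wm, , drop = FALSE], n_wm, d[1])
    labels[gm] <- assign_regions(ax[gm, , drop = FALSE], n_gm, d[1]) + n_wm
  })
  regions <- tibble::tibble(
    region_id = seq_len(n_wm + n_gm),
    name = c(sprintf("wm_tract_%02d", seq_len(n_wm)),
             sprintf("gm_area_%03d", seq_len(n_gm))),
    tissue_class = c(rep("white", n_wm), rep("gray", n_gm))
  )
  lesion_atlas(array(labels, dim = d), grid, regions)
}

# Partition compartment voxels (coords: m x 3) into n regions by nearest-seed
# assignment with mirror-paired seeds across the x midplane.
assign_regions <- function(coords, n, nx) {
  if (n == 1L) return(rep(1L, nrow(coords)))
  cx <- (nx + 1) / 2
  left <- which(coords[, 1] < cx)
  k <- n %/% 2L
  if (length(left) < k) stop("not enough hemisphere voxels for seeds", call. = FALSE)
  pick <- sample(left, k)
  seeds <- coords[pick, , drop = FALSE]
  mirrored <- seeds
  mirrored[, 1] <- nx + 1 - mirrored[, 1]
  seeds <- rbind(seeds, mirrored)
  if (n %% 2L == 1L) {
    mid_cand <- which(abs(coords[, 1] - cx) == min(abs(coords[, 1] - cx)))
    seeds <- rbind(seeds, coords[sample(mid_cand, 1L), , drop = FALSE])
  }
  best <- rep.int(1L, nrow(coords))
  bestd <- colSums((t(coords) - seeds[1, ])^2)
  for (s in seq_len(nrow(seeds))[-1]) {
    ds <- colSums((t(coords) - seeds[s, ])^2)
    upd <- ds < bestd
    best[upd] <- s
    bestd[upd] <- ds[upd]
  }
  best
}

#' Territory epicenter and automatic eloquent-region selection
#'
#' The emulated cohort consists of proximal middle-cerebral-artery
#' occlusions, so synthetic lesion epicenters cluster in a fixed mid-lateral
#' territory of each hemisphere rather than anywhere in the brain.
#' `default_eloquent_regions()` designates the outcome-driving regions the
#' same way lesion-symptom cohorts behave (tracts and areas inside one
#' affected territory are the consistent, lateralized correlates): it returns
#' the 3rd-5th distinct regions by distance from the left-hemisphere
#' epicenter. Placing all designated regions in one hemisphere keeps the
#' marginal load-outcome relationship monotone for each of them (splitting
#' effects across hemispheres would make each side's lesions suppress the
#' other side's correlation), and skipping the innermost two regions gives
#' the designated regions graded partial loads rather than near-binary
#' all-or-nothing coverage, so the linear outcome model works in its
#' informative range instead of saturating the NIHSS ceiling.
#'
#' @param atlas Atlas from [generate_atlas()].
#' @param weight NIHSS points per 100% load assigned to each selected region.
#' @return Named numeric vector of three effect weights, names = region ids.
#' @export
default_eloquent_regions <- function(atlas, weight = 20) {
  ids <- epicenter_regions(atlas, "left", k = 5)[3:5]
  stats::setNames(rep(weight, length(ids)), ids)
}

# Regions nearest the territory epicenter of one hemisphere, by distance of
# their closest voxel.
epicenter_regions <- function(atlas, side, k) {
  d <- atlas$grid$shape
  epi <- territory_epicenter(d, side)
  brain_idx <- which(atlas$labels != 0L)
  coords <- arrayInd(brain_idx, d)
  dist2 <- colSums((t(coords) - epi)^2)
  labs <- atlas$labels[brain_idx][order(dist2)]
  unique(labs)[seq_len(k)]
}

# Mid-lateral epicenter of the emulated vascular territory, in voxel
# coordinates: halfway out along x, slightly above the axial midplane.
territory_epicenter <- function(shape, side) {
  ctr <- (shape + 1) / 2
  semi <- 0.45 * shape
  sgn <- if (side == "left") -1 else 1
  c(ctr[1] + sgn * 0.5 * semi[1], ctr[2], ctr[3] + 0.2 * semi[3])
}

# Conventional NIHSS severity banding onto the mRS disability scale:
# 0-1 no/minimal deficit, 2-4 minor, 5-8 moderate, 9-13 moderate-severe,
# 14-20 severe, 21+ very severe. Grade 6 (death) is never generated.
nihss_to_mrs_band <- function(nihss) {
  findInterval(nihss, c(2, 5, 9, 14, 21))
}

resolve_eloquent <- function(config, atlas) {
  if (identical(config$eloquent_regions, "auto")) {
    default_eloquent_regions(atlas)
  } else {
    config$eloquent_regions
  }
}

#' Generate one synthetic stroke patient
#'
#' Draws a TICI grade, grows a penumbra blob from a seed voxel drawn around
#' the affected hemisphere's territory epicenter (target volume log-normal),
#' erodes it to an inner core, removes
#' a TICI-dependent salvaged fraction of the penumbra shell (outermost voxels
#' first) to form the final lesion, and synthesizes ADC, Tmax and
#' prediction maps whose thresholded delineations recover the ground-truth
#' masks exactly: ADC < 600e-6 mm^2/s exactly on core voxels, Tmax > 6 s
#' exactly on penumbra voxels, prediction >= 0.5 exactly on final-lesion
#' voxels (all within the brain). The 3-month NIHSS is linear in the
#' designated eloquent-region loads of the final lesion and in total volume,
#' plus Gaussian noise, clipped to 0-42 and rounded; mRS is the clinical
#' severity banding of that NIHSS plus rater noise, clipped to 0-6 and
#' rounded.
#'
#' If the drawn target volume exceeds the chosen hemisphere, the draw is
#' retried with a fresh seed voxel and volume (at most 10 attempts).
#'
#' @param atlas Atlas from [generate_atlas()] (defines brain and regions).
#' @param config A [simulation_config()].
#' @param patient_seed Integer seed for this patient's draws.
#' @param patient_id Identifier stored in the generated record and masks.
#' @return A `synthetic_patient` list: `record` (one-row tibble),
#'   `core_mask`, `penumbra_mask`, `final_mask`, `brain_mask` (lesion_mask
#'   objects), `adc_map`, `tmax_map`, `prediction_map` (scalar_map objects),
#'   `true_loads` (tibble of per-region final-lesion loads) and
#'   `noise_draw` (the NIHSS noise realization).
#' @export
generate_patient <- function(atlas, config, patient_seed,
                             patient_id = "p001") {
  stopifnot(inherits(atlas, "lesion_atlas"),
            inherits(config, "simulation_config"))
  grid <- atlas$grid
  d <- grid$shape
  vox_ml <- voxel_volume_ml(grid)
  brain_idx <- which(atlas$labels != 0L)
  coords <- arrayInd(brain_idx, d)
  mm <- t(t(coords) * grid$voxel_size)
  eloquent <- resolve_eloquent(config, atlas)

  with_seed(patient_seed, {
    tici <- sample(TICI_GRADES, 1L, prob = config$tici_distribution)

    mid <- d[1] / 2
    hemi_left <- coords[, 1] <= mid
    placed <- FALSE
    for (attempt in seq_len(10L)) {
      side <- sample(c("left", "right"), 1L)
      in_hemi <- which(hemi_left == (side == "left"))
      target_ml <- stats::rlnorm(1, config$lesion_volume_meanlog,
                                 config$lesion_volume_sdlog)
      n_pen <- max(2L, round(target_ml / vox_ml))
      if (n_pen <= length(in_hemi)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place a lesion of the drawn volume in either hemisphere",
           call. = FALSE)
    }
    # rows index into the brain-voxel tables (coords/mm); convert to linear
    # voxel indices via brain_idx[] when touching full arrays.
    # The seed voxel is drawn around the hemisphere's territory epicenter
    # (Gaussian jitter), emulating a cohort of one-territory occlusions.
    epi <- territory_epicenter(d, side) +
      stats::rnorm(3, 0, 0.15 * 0.45 * d)
    hemi_d2 <- colSums((t(coords[in_hemi, , drop = FALSE]) - epi)^2)
    seed_row <- in_hemi[which.min(hemi_d2)]
    dist2 <- colSums((t(mm[in_hemi, , drop = FALSE]) - mm[seed_row, ])^2)
    pen_rows <- in_hemi[order(dist2)][seq_len(n_pen)]  # nearest-first growth

    f_core <- stats::runif(1, config$core_fraction[1], config$core_fraction[2])
    n_core <- max(1L, round(f_core * n_pen))
    core_rows <- pen_rows[seq_len(n_core)]             # innermost voxels
    shell_rows <- pen_rows[-seq_len(n_core)]           # ordered inner->outer
    salvage <- config$penumbra_salvage_by_tici[[tici]]
    n_salvaged <- round(salvage * length(shell_rows))
    kept_shell <- if (n_salvaged > 0L && length(shell_rows)) {
      shell_rows[seq_len(length(shell_rows) - n_salvaged)]
    } else shell_rows
    final_rows <- c(core_rows, kept_shell)
    pen_idx <- brain_idx[pen_rows]
    core_idx <- brain_idx[core_rows]
    final_idx <- brain_idx[final_rows]

    as_mask <- function(idx, kind) {
      a <- array(0L, dim = d)
      a[idx] <- 1L
      lesion_mask(a, grid, patient_id = patient_id, kind = kind)
    }
    core_mask <- as_mask(core_idx, "adc_core")
    penumbra_mask <- as_mask(pen_idx, "tmax_deficit")
    final_mask <- as_mask(final_idx, "followup_segmentation")
    brain_arr <- array(0L, dim = d)
    brain_arr[brain_idx] <- 1L
    brain_mask <- lesion_mask(brain_arr, grid, patient_id = patient_id,
                              kind = "followup_segmentation")

    nb <- length(brain_idx)
    # ADC: 750e-6 in healthy brain, 450e-6 in the core; +/-75e-6 noise keeps
    # a margin on both sides of the 600e-6 threshold. Zero outside the head.
    adc <- array(0, dim = d)
    adc[brain_idx] <- 750e-6 + stats::runif(nb, -75e-6, 75e-6)
    adc[core_idx] <- 450e-6 + stats::runif(length(core_idx), -75e-6, 75e-6)
    # Tmax: 2 s in normally perfused brain, 9 s in the perfusion deficit;
    # +/-1.5 s noise keeps a margin around the 6 s threshold.
    tmax <- array(0, dim = d)
    tmax[brain_idx] <- 2 + stats::runif(nb, -1.5, 1.5)
    tmax[pen_idx] <- 9 + stats::runif(length(pen_idx), -1.5, 1.5)
    # Prediction: confidently above 0.5 inside the final lesion, smoothly
    # decaying below 0.5 outside it (a blurred-looking map the >= 0.5 rule
    # binarizes back to the final lesion).
    pred <- array(0, dim = d)
    dist_seed <- sqrt(colSums((t(mm) - mm[seed_row, ])^2))
    r_eff <- if (length(final_rows)) max(dist_seed[final_rows]) else 0
    outside <- 0.45 * exp(-pmax(0, dist_seed - r_eff) / 8)
    pred[brain_idx] <- pmin(0.45, outside)
    pred[final_idx] <- 0.75 + stats::runif(length(final_idx), -0.15, 0.15)

    lab <- as.integer(atlas$labels)
    region_ids <- sort(atlas$regions$region_id)
    denom <- tabulate(lab, nbins = max(region_ids))[region_ids]
    hit <- tabulate(lab[final_idx], nbins = max(region_ids))[region_ids]
    true_loads <- tibble::tibble(region_id = region_ids,
                                 load = 100 * hit / denom)

    beta_ids <- as.integer(names(eloquent))
    load_term <- sum(eloquent *
                       true_loads$load[match(beta_ids, region_ids)] / 100)
    vol_ml <- length(final_idx) * vox_ml
    eps <- stats::rnorm(1, 0, config$noise_sd)
    nihss <- round(min(42, max(0, config$intercept + load_term +
                                 config$volume_weight * vol_ml + eps)))
    mrs <- min(6, max(0, nihss_to_mrs_band(
      nihss + stats::rnorm(1, 0, config$mrs_noise_sd))))

    structure(
      list(
        record = tibble::tibble(patient_id = patient_id, tici = tici,
                                nihss_3m = as.integer(nihss),
                                mrs_3m = as.integer(mrs)),
        core_mask = core_mask, penumbra_mask = penumbra_mask,
        final_mask = final_mask, brain_mask = brain_mask,
        adc_map = scalar_map(adc, grid, "adc"),
        tmax_map = scalar_map(tmax, grid, "tmax"),
        prediction_map = scalar_map(pred, grid, "probability"),
        true_loads = true_loads,
        noise_draw = eps
      ),
      class = "synthetic_patient"
    )
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Generates the atlas and `n_patients` synthetic patients (each from a seed
#' derived from the master seed), assembles the cohort table, and optionally
#' writes everything to disk: atlas label volume + region TSV, per-patient
#' NIfTI masks and maps, `cohort.tsv`, a `ground_truth.tsv` with the true
#' regional loads, outcome-model coefficients and per-patient noise draws,
#' and a `provenance.yaml` recording the configuration. Fully reproducible
#' from `config$master_seed`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return A `synthetic_cohort` list: `atlas`, `cohort` ([cohort_table()]),
#'   `patients` (list of `synthetic_patient`), `config`, and `out_dir` when
#'   written.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  atlas <- generate_atlas(config)
  ids <- sprintf("p%03d", seq_len(config$n_patients))
  patients <- lapply(seq_len(config$n_patients), function(i) {
    generate_patient(atlas, config,
                     patient_seed = feature_seed(config$master_seed, ids[i]),
                     patient_id = ids[i])
  })
  cohort <- cohort_table(dplyr::bind_rows(lapply(patients, `[[`, "record")))

  out <- structure(
    list(atlas = atlas, cohort = cohort, patients = patients,
         config = config, out_dir = out_dir),
    class = "synthetic_cohort"
  )
  if (!is.null(out_dir)) write_synthetic_cohort(out, out_dir)
  out
}

write_synthetic_cohort <- function(x, out_dir) {
  dir.create(file.path(out_dir, "patients"), recursive = TRUE,
             showWarnings = FALSE)
  write_atlas(x$atlas, file.path(out_dir, "atlas_labels.nii.gz"),
              file.path(out_dir, "atlas_regions.tsv"))
  write_cohort(x$cohort, file.path(out_dir, "cohort.tsv"))
  for (p in x$patients) {
    pid <- p$record$patient_id
    pd <- file.path(out_dir, "patients")
    write_mask(p$final_mask, file.path(pd, paste0(pid, "_followup.nii.gz")))
    write_mask(p$core_mask, file.path(pd, paste0(pid, "_core.nii.gz")))
    write_mask(p$penumbra_mask, file.path(pd, paste0(pid, "_penumbra.nii.gz")))
    write_mask(p$brain_mask, file.path(pd, paste0(pid, "_brain.nii.gz")))
    write_scalar_map(p$adc_map, file.path(pd, paste0(pid, "_adc.nii.gz")))
    write_scalar_map(p$tmax_map, file.path(pd, paste0(pid, "_tmax.nii.gz")))
    write_scalar_map(p$prediction_map,
                     file.path(pd, paste0(pid, "_prediction.nii.gz")))
  }
  elo <- resolve_eloquent(x$config, x$atlas)
  gt <- dplyr::bind_rows(lapply(x$patients, function(p) {
    loads <- p$true_loads
    loads$beta <- unname(elo[match(loads$region_id,
                                   as.integer(names(elo)))])
    loads$beta[is.na(loads$beta)] <- 0
    dplyr::mutate(loads, patient_id = p$record$patient_id,
                  noise_draw = p$noise_draw, .before = 1L)
  }))
  readr::write_tsv(gt, file.path(out_dir, "ground_truth.tsv"),
                   progress = FALSE)
  cfg <- x$config
  yaml::write_yaml(
    list(
      grid = list(shape = cfg$grid$shape, voxel_size = cfg$grid$voxel_size),
      n_wm_regions = cfg$n_wm_regions, n_gm_regions = cfg$n_gm_regions,
      n_patients = cfg$n_patients,
      tici_distribution = as.list(cfg$tici_distribution),
      eloquent_regions = as.list(cfg$eloquent_regions),
      volume_weight = cfg$volume_weight, intercept = cfg$intercept,
      noise_sd = cfg$noise_sd, mrs_noise_sd = cfg$mrs_noise_sd,
      penumbra_salvage_by_tici = as.list(cfg$penumbra_salvage_by_tici),
      lesion_volume_meanlog = cfg$lesion_volume_meanlog,
      lesion_volume_sdlog = cfg$lesion_volume_sdlog,
      core_fraction = cfg$core_fraction,
      master_seed = cfg$master_seed
    ),
    file.path(out_dir, "provenance.yaml")
  )
  invisible(out_dir)
}

#' Load a simulation configuration from a YAML file
#'
#' Reads the schema written by [generate_cohort()]'s provenance file (or
#' hand-written in the same shape) back into a [simulation_config()].
#'
#' @param path YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$grid)) {
    args$grid <- volume_grid(unlist(y$grid$shape), unlist(y$grid$voxel_size))
  }
  scalars <- c("n_wm_regions", "n_gm_regions", "n_patients", "volume_weight",
               "intercept", "noise_sd", "mrs_noise_sd",
               "lesion_volume_meanlog", "lesion_volume_sdlog", "master_seed")
  for (s in scalars) if (!is.null(y[[s]])) args[[s]] <- y[[s]]
  if (!is.null(y$core_fraction)) args$core_fraction <- unlist(y$core_fraction)
  for (v in c("tici_distribution", "eloquent_regions",
              "penumbra_salvage_by_tici")) {
    if (!is.null(y[[v]])) args[[v]] <- unlist(y[[v]])
  }
  do.call(simulation_config, args)
}
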