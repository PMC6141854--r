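test_that("generate_atlas honors the configured parcellation", {
  cfg <- small_sim_config()
  at <- generate_atlas(cfg)
  expect_equal(nrow(at$regions), 17L)
  expect_equal(sum(at$regions$tissue_class == "white"), 5L)
  expect_equal(sum(at$regions$tissue_class == "gray"), 12L)
  # every region owns at least one voxel
  expect_setequal(setdiff(unique(as.vector(at$labels)), 0L),
                  at$regions$region_id)

  # defaults produce the 121-region parcellation (29 white + 92 gray)
  cfg121 <- simulation_config(grid = volume_grid(c(48, 48, 48), c(2, 2, 2)),
                              master_seed = 2)
  at121 <- generate_atlas(cfg121)
  expect_equal(nrow(at121$regions), 121L)
  expect_equal(sum(at121$regions$tissue_class == "white"), 29L)
  expect_equal(sum(at121$regions$tissue_class == "gray"), 92L)

  # determinism
  expect_identical(generate_atlas(cfg)$labels, at$labels)

  # infeasible request
  tiny <- simulation_config(grid = volume_grid(c(6, 6, 6), c(2, 2, 2)),
                            n_wm_regions = 500, n_gm_regions = 500)
  expect_error(generate_atlas(tiny), "too small")
})

test_that("synthetic patients satisfy the nesting and threshold invariants", {
  cfg <- small_sim_config(n_patients = 8)
  syn <- generate_cohort(cfg)
  for (p in syn$patients) {
    expect_true(all(p$core_mask$data <= p$penumbra_mask$data))
    expect_true(all(p$core_mask$data <= p$final_mask$data))
    expect_true(all(p$final_mask$data <= p$penumbra_mask$data))
    # threshold consistency: delineation recovers ground truth exactly
    core <- delineate_adc_core(p$adc_map, brain_mask = p$brain_mask)
    expect_identical(core$data, p$core_mask$data)
    pen <- delineate_tmax_deficit(p$tmax_map, brain_mask = p$brain_mask)
    expect_identical(pen$data, p$penumbra_mask$data)
    pred <- binarize_prediction(p$prediction_map)
    expect_identical(pred$data, p$final_mask$data)
    # scores in range
    expect_true(p$record$nihss_3m >= 0 && p$record$nihss_3m <= 42)
    expect_true(p$record$mrs_3m >= 0 && p$record$mrs_3m <= 6)
  }
})

test_that("ideal revascularization salvages the whole penumbra shell", {
  cfg <- small_sim_config(
    tici_distribution = c("0" = 0, "1" = 0, "2a" = 0, "2b" = 0, "3" = 1),
    penumbra_salvage_by_tici = c("0" = 0, "1" = 0, "2a" = 0, "2b" = 1,
                                 "3" = 1)
  )
  at <- generate_atlas(cfg)
  p <- generate_patient(at, cfg, patient_seed = 5)
  expect_identical(p$final_mask$data, p$core_mask$data)
})

test_that("the noiseless linear outcome model is exact", {
  # single eloquent region worth 42 points, no intercept/volume term, no
  # noise, nothing salvaged: a lesion covering the region fully gives
  # NIHSS = 42
  grid <- volume_grid(c(20, 20, 20), c(2, 2, 2))
  cfg <- simulation_config(
    grid = grid, n_wm_regions = 1, n_gm_regions = 1, n_patients = 1,
    eloquent_regions = c("1" = 42), volume_weight = 0, intercept = 0,
    noise_sd = 0, mrs_noise_sd = 0,
    tici_distribution = c("0" = 1, "1" = 0, "2a" = 0, "2b" = 0, "3" = 0),
    penumbra_salvage_by_tici = c("0" = 0, "1" = 0, "2a" = 0, "2b" = 0,
                                 "3" = 0),
    lesion_volume_meanlog = log(10), lesion_volume_sdlog = 1e-8,
    master_seed = 3
  )
  at <- generate_atlas(cfg)
  # a lesion big enough to swallow the whole inner (region 1) compartment
  p <- generate_patient(at, cfg, patient_seed = 17)
  load1 <- p$true_loads$load[p$true_loads$region_id == 1]
  expected <- round(min(42, 42 * load1 / 100))
  expect_equal(p$record$nihss_3m, expected)
  # with zero rater blur, mRS is exactly the clinical severity band
  expect_equal(p$record$mrs_3m,
               findInterval(expected, c(2, 5, 9, 14, 21)))
  expect_equal(p$noise_draw, 0)
})

test_that("true loads match the lesion_load module on the final mask", {
  cfg <- small_sim_config(n_patients = 3)
  syn <- generate_cohort(cfg)
  for (p in syn$patients) {
    for (rid in syn$atlas$regions$region_id) {
      expect_equal(region_load(p$final_mask, syn$atlas, rid),
                   p$true_loads$load[p$true_loads$region_id == rid])
    }
  }
})

test_that("cohort generation is reproducible and writes a readable bundle", {
  cfg <- small_sim_config(n_patients = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  # byte-identical cohort TSV across runs
  expect_identical(readLines(file.path(d1, "cohort.tsv")),
                   readLines(file.path(d2, "cohort.tsv")))
  expect_identical(readLines(file.path(d1, "ground_truth.tsv")),
                   readLines(file.path(d2, "ground_truth.tsv")))

  # the written bundle reads back consistently
  back <- read_cohort_directory(d1)
  expect_equal(nrow(back$cohort), 4L)
  expect_identical(back$atlas$labels, generate_atlas(cfg)$labels)
  co <- read_cohort(file.path(d1, "cohort.tsv"))
  expect_equal(nrow(co), 4L)
  # provenance round-trips into an equivalent config
  cfg2 <- read_simulation_config(file.path(d1, "provenance.yaml"))
  expect_equal(cfg2$master_seed, cfg$master_seed)
  expect_equal(cfg2$eloquent_regions, cfg$eloquent_regions)
  expect_equal(cfg2$grid$shape, cfg$grid$shape)

  # single-patient cohort works
  syn1 <- generate_cohort(small_sim_config(n_patients = 1))
  expect_equal(nrow(syn1$cohort), 1L)
})

test_that("larger effect weights raise the expected load-outcome correlation", {
  # two beta levels, many tiny cohorts; region 2's correlation with NIHSS
  # should be systematically higher under the stronger effect
  r_at <- function(beta, seed) {
    cfg <- small_sim_config(
      n_patients = 14, master_seed = seed,
      noise_sd = 4
    )
    cfg$eloquent_regions <- c("2" = beta)
    syn <- generate_cohort(cfg)
    loads <- vapply(syn$patients, function(p) {
      p$true_loads$load[p$true_loads$region_id == 2]
    }, numeric(1))
    pearson_r(loads, syn$cohort$nihss_3m)
  }
  seeds <- 1:12
  r_weak <- vapply(seeds, function(s) r_at(2, s), numeric(1))
  r_strong <- vapply(seeds, function(s) r_at(40, s), numeric(1))
  expect_gt(mean(r_strong, na.rm = TRUE), mean(r_weak, na.rm = TRUE))
})
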