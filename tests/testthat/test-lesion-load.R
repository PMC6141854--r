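test_that("region_load matches its definition on constructed regions", {
  at <- toy_atlas()  # regions of 32 voxels each
  # lesion covering 8 voxels of region 1 only (region 1 = x in 1:2)
  m <- mask_from_idx(which(at$labels == 1L)[1:8], at$grid)
  expect_equal(region_load(m, at, 1), 25)
  expect_equal(region_load(m, at, 2), 0)

  empty <- mask_from_idx(integer(), at$grid)
  expect_equal(region_load(empty, at, 1), 0)
  expect_equal(region_load(empty, at, 2), 0)

  full <- lesion_mask(array(1L, at$grid$shape), at$grid)
  expect_equal(region_load(full, at, 1), 100)
  expect_equal(region_load(full, at, 2), 100)

  expect_error(region_load(m, at, 5), "not defined")
})

test_that("region_load agrees exactly with a brute-force voxel count", {
  set.seed(101)
  for (rep in 1:25) {
    d <- sample(3:16, 3, replace = TRUE)
    g <- volume_grid(d, c(2, 2, 2))
    n_regions <- sample(1:5, 1)
    lab <- array(sample(0:n_regions, prod(d), replace = TRUE), d)
    # guarantee every region occurs
    lab[seq_len(n_regions)] <- seq_len(n_regions)
    at <- lesion_atlas(lab, g, data.frame(
      region_id = seq_len(n_regions),
      name = paste0("r", seq_len(n_regions)),
      tissue_class = sample(c("gray", "white"), n_regions, replace = TRUE)
    ))
    mask <- lesion_mask(array(rbinom(prod(d), 1, 0.3), d), g)
    for (rid in seq_len(n_regions)) {
      expect_identical(region_load(mask, at, rid),
                       oracle_region_load(mask$data, lab, rid))
    }
  }
})

test_that("total_volume converts voxel counts to ml", {
  g <- volume_grid(c(10, 10, 10), c(2, 2, 2))
  expect_equal(total_volume(lesion_mask(array(1L, c(10, 10, 10)), g)), 8)
  expect_equal(total_volume(mask_from_idx(integer(), g)), 0)
  g1 <- volume_grid(c(3, 1, 1), c(1, 1, 1))
  expect_equal(total_volume(lesion_mask(array(1L, c(3, 1, 1)), g1)), 0.003)
})

test_that("compute_load_matrix builds one row per patient, one column per region", {
  at <- toy_atlas()
  co <- cohort_table(data.frame(
    patient_id = c("a", "b", "c"), tici = c("3", "0", "2b"),
    nihss_3m = c(1L, 2L, 3L), mrs_3m = c(0L, 1L, 1L)
  ))
  r1 <- which(at$labels == 1L)
  r2 <- which(at$labels == 2L)
  masks <- list(
    mask_from_idx(r1[1:8], at$grid, "a"),
    mask_from_idx(integer(), at$grid, "b"),
    mask_from_idx(r2[1], at$grid, "c")  # one voxel inside region 2
  )
  lm <- compute_load_matrix(masks, at, co)
  expect_s3_class(lm, "load_matrix")
  expect_equal(lm$patient_id, c("a", "b", "c"))
  expect_equal(names(lm)[2:3], c("load_1", "load_2"))
  expect_equal(lm$load_1, c(25, 0, 0))
  expect_equal(lm$load_2, c(0, 0, 100 / 32))
  expect_equal(lm$total_volume_ml, c(8, 0, 1) * 0.008)

  # rows follow cohort order even when masks are permuted
  lm2 <- compute_load_matrix(masks[c(3, 1, 2)], at, co)
  expect_equal(as.data.frame(lm2), as.data.frame(lm))

  expect_error(compute_load_matrix(masks[1:2], at, co), "c")
  mixed <- masks
  mixed[[2]] <- mask_from_idx(integer(), at$grid, "b", kind = "adc_core")
  expect_error(compute_load_matrix(mixed, at, co), "mix")
})

test_that("unlabeled lesion voxels count toward volume but no load", {
  g <- grid3()
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, , ] <- 1L   # half the grid unlabeled
  at <- lesion_atlas(lab, g, data.frame(region_id = 1L, name = "r1",
                                        tissue_class = "gray"))
  co <- cohort_table(data.frame(patient_id = "a", tici = "3",
                                nihss_3m = 1L, mrs_3m = 0L))
  # 4 voxels in region 1, 4 on background
  m <- mask_from_idx(c(which(lab == 1L)[1:4], which(lab == 0L)[1:4]), g, "a")
  lm <- compute_load_matrix(list(m), at, co)
  expect_equal(lm$load_1, 100 * 4 / 32)
  expect_equal(lm$total_volume_ml, 8 * 0.008)
  expect_equal(lm$unlabeled_voxels, 4L)
})

test_that("loads are conserved and monotone under mask growth", {
  set.seed(77)
  at <- toy_atlas()
  co <- cohort_table(data.frame(patient_id = "a", tici = "3",
                                nihss_3m = 1L, mrs_3m = 0L))
  for (rep in 1:10) {
    idx <- sample(64, sample(1:40, 1))
    m <- mask_from_idx(idx, at$grid, "a")
    lm <- compute_load_matrix(list(m), at, co)
    # conservation: sum of load_r/100 * |region_r| = labeled lesion voxels
    labeled <- sum(lm$load_1 / 100 * 32 + lm$load_2 / 100 * 32)
    expect_equal(labeled, length(idx) - lm$unlabeled_voxels)
    expect_true(labeled <= sum(m$data))

    # growth never decreases any load or the volume
    extra <- union(idx, sample(64, 5))
    m2 <- mask_from_idx(extra, at$grid, "a")
    lm2 <- compute_load_matrix(list(m2), at, co)
    expect_true(all(c(lm2$load_1, lm2$load_2) >= c(lm$load_1, lm$load_2)))
    expect_true(lm2$total_volume_ml >= lm$total_volume_ml)
  }
})

test_that("load matrices round-trip through TSV", {
  at <- toy_atlas()
  co <- cohort_table(data.frame(patient_id = c("a", "b"),
                                tici = c("3", "0"),
                                nihss_3m = c(1L, 2L), mrs_3m = c(0L, 1L)))
  lm <- compute_load_matrix(
    list(mask_from_idx(1:10, at$grid, "a"), mask_from_idx(40:64, at$grid, "b")),
    at, co)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_load_matrix(lm, p)
  back <- read_load_matrix(p, delineation_kind = "followup_segmentation")
  expect_equal(as.data.frame(back), as.data.frame(lm))
  expect_equal(attr(back, "region_ids"), attr(lm, "region_ids"))
})
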