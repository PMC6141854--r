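test_that("pearson_r evaluates the product-moment formula and flags degeneracy", {
  expect_equal(pearson_r(1:3, 1:3), 1)
  expect_equal(pearson_r(1:3, 3:1), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1, 1), "at least 2")
})

test_that("pearson_r respects affine invariance and sign flips", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(length(x))
    r <- pearson_r(x, y)
    expect_true(r >= -1 && r <= 1)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_r(a * x + b, y), r)
    expect_equal(pearson_r(-x, y), -r)
  }
})

test_that("bootstrap_ci is seed-reproducible and leaves the caller RNG alone", {
  set.seed(10)
  x <- rnorm(20); y <- rnorm(20)
  before <- .Random.seed
  a <- bootstrap_ci(x, y, n_boot = 200, seed = 5)
  expect_identical(.Random.seed, before)
  b <- bootstrap_ci(x, y, n_boot = 200, seed = 5)
  expect_identical(a, b)
  c2 <- bootstrap_ci(x, y, n_boot = 200, seed = 6)
  expect_false(identical(a$ci_low, c2$ci_low))
  expect_error(bootstrap_ci(x, y, n_boot = 200), "seed")
})

test_that("degenerate bootstrap inputs are handled as specified", {
  # constant y: every resample undefined -> non-estimable
  r <- bootstrap_ci(1:10, rep(2, 10), n_boot = 100, seed = 1)
  expect_false(r$estimable)
  expect_equal(r$n_dropped, 100L)
  expect_true(is.na(r$ci_low))
  expect_false(significance(r$ci_low, r$ci_high))

  # perfect linear relation: every defined resample has r = 1 -> CI [1, 1]
  x <- c(1, 2, 3, 4, 5)
  r <- bootstrap_ci(x, 2 * x + 1, n_boot = 500, seed = 2)
  expect_true(r$estimable)
  expect_equal(r$ci_low, 1)
  expect_equal(r$ci_high, 1)
})

test_that("Monte-Carlo percentile CI matches exhaustive enumeration at n = 3", {
  x <- c(0.2, 1.7, 3.1)
  y <- c(0.5, 2.2, 2.4)
  oracle <- oracle_boot_ci_n3(x, y)
  mc <- bootstrap_ci(x, y, n_boot = 1e5, seed = 99)
  expect_lt(abs(mc$ci_low - oracle[1]), 0.02)
  expect_lt(abs(mc$ci_high - oracle[2]), 0.02)

  # second instance with a negative association
  x <- c(1, 2, 5); y <- c(4, 4.5, 1)
  oracle <- oracle_boot_ci_n3(x, y)
  mc <- bootstrap_ci(x, y, n_boot = 1e5, seed = 100)
  expect_lt(abs(mc$ci_low - oracle[1]), 0.02)
  expect_lt(abs(mc$ci_high - oracle[2]), 0.02)
})

test_that("significance is the closed-interval zero-exclusion predicate", {
  expect_true(significance(0.2, 0.8))
  expect_true(significance(-0.8, -0.2))
  expect_false(significance(-0.1, 0.5))
  expect_false(significance(0.0, 0.5))   # endpoint at zero: insignificant
  expect_false(significance(-0.5, 0.0))
  expect_false(significance(NA, NA))
})

test_that("correlate_features yields one record per region plus total volume", {
  at <- toy_atlas()
  set.seed(8)
  n <- 12
  co <- cohort_table(data.frame(
    patient_id = paste0("p", 1:n),
    tici = sample(c("0", "2b", "3"), n, replace = TRUE),
    nihss_3m = sample(0:42, n), mrs_3m = sample(0:6, n, replace = TRUE)
  ))
  r1 <- which(at$labels == 1L)  # lesions confined to region 1
  masks <- lapply(co$patient_id, function(pid) {
    mask_from_idx(sample(r1, sample(0:20, 1)), at$grid, pid)
  })
  lm <- compute_load_matrix(masks, at, co)
  tab <- correlate_features(lm, co, "nihss_3m", n_boot = 200, seed = 4,
                            regions = at$regions)
  expect_equal(nrow(tab), 3L)  # 2 regions + total_volume
  expect_setequal(tab$feature_id, c("1", "2", "total_volume"))
  expect_equal(tab$significant,
               as.vector(significance(tab$ci_low, tab$ci_high)))

  # region never lesioned: undefined r, non-estimable, insignificant
  expect_true(all(lm$load_2 == 0))
  rec <- tab[tab$feature_id == "2", ]
  expect_true(is.na(rec$r))
  expect_false(rec$estimable)
  expect_false(rec$significant)

  # a feature identical to the outcome correlates perfectly
  lm$load_1 <- co$nihss_3m
  tab2 <- correlate_features(lm, co, "nihss_3m", n_boot = 100, seed = 4)
  expect_equal(tab2$r[tab2$feature_id == "1"], 1)
  expect_true(tab2$significant[tab2$feature_id == "1"])
})

test_that("per-feature seed streams are independent of column order", {
  at <- toy_atlas()
  set.seed(12)
  n <- 10
  co <- cohort_table(data.frame(
    patient_id = paste0("p", 1:n), tici = rep("3", n),
    nihss_3m = sample(0:42, n), mrs_3m = sample(0:6, n, replace = TRUE)
  ))
  masks <- lapply(co$patient_id, function(pid) {
    mask_from_idx(sample(64, 15), at$grid, pid)
  })
  lm <- compute_load_matrix(masks, at, co)
  tab <- correlate_features(lm, co, "nihss_3m", n_boot = 100, seed = 9)
  # permuting load columns does not change any feature's interval
  lmp <- lm[, c("patient_id", "load_2", "load_1", "total_volume_ml",
                "unlabeled_voxels")]
  lmp <- structure(lmp, class = class(lm),
                   delineation_kind = attr(lm, "delineation_kind"),
                   region_ids = attr(lm, "region_ids"))
  tabp <- correlate_features(lmp, co, "nihss_3m", n_boot = 100, seed = 9)
  for (f in c("1", "2", "total_volume")) {
    expect_equal(tabp$ci_low[tabp$feature_id == f],
                 tab$ci_low[tab$feature_id == f])
  }
})

test_that("rank_top orders by r, breaks ties by id, and drops undefined", {
  tbl <- tibble::tibble(
    feature_id = c("5", "2", "9", "total_volume", "1"),
    name = letters[1:5],
    r = c(0.9, 0.5, NA, 0.5, 0.2),
    ci_low = c(0.5, 0.1, NA, 0.1, -0.2),
    ci_high = c(0.99, 0.8, NA, 0.8, 0.5),
    significant = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    estimable = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    n_boot_used = 100L, n_boot_dropped = 0L
  )
  class(tbl) <- c("correlation_table", class(tbl))
  top <- rank_top(tbl, 3)
  expect_equal(top$feature_id, c("5", "2", "total_volume"))
  expect_equal(top$rank, 1:3)
  # k beyond the defined records returns all of them in order
  top_all <- rank_top(tbl, 10)
  expect_equal(top_all$feature_id, c("5", "2", "total_volume", "1"))
  expect_error(rank_top(tbl, 0), ">= 1")

  # all-equal r ranks by ascending region id
  tbl2 <- tbl
  tbl2$r <- 0.4
  expect_equal(rank_top(tbl2, 5)$feature_id,
               c("1", "2", "5", "9", "total_volume"))
})

test_that("bootstrap CI coverage is near nominal under a bivariate normal", {
  # true r = 0.5, n = 55; modest replicate count for the routine suite
  n <- 55; rho <- 0.5; B <- 200
  cover <- logical(B)
  set.seed(2024)
  seeds <- sample.int(1e6, B)
  for (i in seq_len(B)) {
    set.seed(seeds[i])
    z1 <- rnorm(n); z2 <- rnorm(n)
    ci <- bootstrap_ci(z1, rho * z1 + sqrt(1 - rho^2) * z2,
                       n_boot = 400, seed = seeds[i])
    cover[i] <- ci$ci_low <= rho && rho <= ci$ci_high
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.97)
})
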