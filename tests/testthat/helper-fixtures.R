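# Shared fixtures and independent oracles, all built in code at test time.

grid3 <- function(shape = c(4, 4, 4), vox = c(2, 2, 2)) {
  volume_grid(shape, vox)
}

# A tiny hand-constructed atlas: region 1 fills the lower x-half, region 2
# the upper x-half of a 4x4x4 grid (32 voxels each).
toy_atlas <- function() {
  g <- grid3()
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, , ] <- 1L
  lab[3:4, , ] <- 2L
  lesion_atlas(lab, g, data.frame(
    region_id = c(1L, 2L),
    name = c("lower", "upper"),
    tissue_class = c("white", "gray")
  ))
}

mask_from_idx <- function(idx, grid, pid = "p1",
                          kind = "followup_segmentation") {
  a <- array(0L, grid$shape)
  a[idx] <- 1L
  lesion_mask(a, grid, patient_id = pid, kind = kind)
}

small_sim_config <- function(n_patients = 6, master_seed = 11, ...) {
  simulation_config(
    grid = volume_grid(c(32, 32, 32), c(2, 2, 2)),
    n_wm_regions = 5, n_gm_regions = 12,
    n_patients = n_patients,
    eloquent_regions = c("2" = 25, "8" = 25),
    master_seed = master_seed,
    ...
  )
}

# --- independent oracles -----------------------------------------------------

# Brute-force region load: explicit triple loop over voxels.
oracle_region_load <- function(mask_arr, label_arr, region_id) {
  d <- dim(label_arr)
  n_region <- 0L
  n_hit <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (label_arr[i, j, k] == region_id) {
      n_region <- n_region + 1L
      if (mask_arr[i, j, k] == 1L) n_hit <- n_hit + 1L
    }
  }
  100 * n_hit / n_region
}

# Exact bootstrap percentile interval at n = 3 by enumerating all 27
# equally likely resamples; undefined (zero-variance) resamples dropped.
oracle_boot_ci_n3 <- function(x, y, level = 0.95) {
  stopifnot(length(x) == 3, length(y) == 3)
  rs <- c()
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    xi <- x[c(i, j, k)]; yi <- y[c(i, j, k)]
    if (var(xi) > 0 && var(yi) > 0) rs <- c(rs, cor(xi, yi))
  }
  alpha <- (1 - level) / 2
  unname(quantile(rs, c(alpha, 1 - alpha), type = 7))
}

# Exact two-sided signed-rank p by looping over every sign assignment.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  mu <- sum(rk) / 2
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  ws <- apply(signs, 1, function(s) sum(rk[as.logical(s)]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
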