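test_that("bundle activation on a constant volume equals that constant", {
  g <- grid_spec(c(-5, -5, -5), 1, c(11, 11, 11))
  v <- density_volume(g, array(2.5, c(11, 11, 11)))
  expect_equal(bundle_activation(v, list(center = c(0, 0, 0), radius = 3)), 2.5)
  expect_equal(bundle_activation(v, list(center = c(1.2, -0.7, 2), radius = 1.1)), 2.5)
})

test_that("a sub-half-voxel sphere centered on a voxel center picks that voxel", {
  v <- random_volume(dims = c(7L, 7L, 7L), origin = c(0, 0, 0), seed = 21)
  expect_equal(bundle_activation(v, list(center = c(3, 4, 2), radius = 0.4)),
               v$values[4, 5, 3])
})

test_that("bundle activation equals the exhaustive in-sphere mean", {
  set.seed(22)
  for (case in 1:100) {
    dims <- sample(5:9, 3, replace = TRUE)
    vs <- sample(c(0.5, 1), 1)
    origin <- runif(3, -4, -2)
    v <- density_volume(grid_spec(origin, vs, dims),
                        array(runif(prod(dims)), dims))
    center <- origin + runif(3, 0.2, 0.8) * (dims - 1) * vs
    radius <- runif(1, 0.7 * vs, 3.1 * vs)
    got <- bundle_activation(v, list(center = center, radius = radius))
    expect_equal(got, oracle_sphere_mean(v, center, radius), tolerance = 1e-12)
  }
})

test_that("degenerate spheres raise out-of-bounds or resolution errors", {
  v <- random_volume(seed = 23)
  expect_error(bundle_activation(v, list(center = c(100, 100, 100), radius = 2)),
               class = "out_of_bounds")
  v2 <- density_volume(grid_spec(c(0, 0, 0), 4, c(5L, 5L, 5L)),
                       array(1, c(5, 5, 5)))
  expect_error(bundle_activation(v2, list(center = c(2, 2, 2), radius = 1)),
               class = "resolution_error")
})

test_that("activation is invariant under joint rigid translation", {
  v <- random_volume(seed = 24)
  site <- list(center = c(0.3, 0.5, -0.2), radius = 2.2)
  a1 <- bundle_activation(v, site)
  shift <- c(5.5, -3.3, 1.1)
  v2 <- density_volume(grid_spec(v$grid$origin + shift, v$grid$voxel_size,
                                 v$grid$dims), v$values)
  a2 <- bundle_activation(v2, list(center = site$center + shift, radius = 2.2))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("observation tables have one row per patient-hemisphere-structure", {
  contacts <- fixed_contacts(n = 26L)
  sites <- build_sites(contacts)
  g <- grid_spec(c(-30, -30, -30), 2, c(31L, 31L, 31L))
  set.seed(25)
  densities <- setNames(lapply(1:7, function(i)
    density_volume(g, array(runif(prod(g$dims)), g$dims))),
    paste0("s", 1:7))
  outcomes <- data.frame(patient_id = unique(contacts$patient_id),
                         improvement = runif(26))
  obs <- build_observations(densities, sites, outcomes)
  expect_equal(nrow(obs), 364L)   # 26 patients x 2 hemispheres x 7 structures
  expect_equal(anyDuplicated(obs[, c("patient_id", "hemisphere", "structure")]), 0L)
  # all-zero structure gives all-zero activations
  densities$s1 <- density_volume(g, array(0, g$dims))
  obs0 <- build_observations(densities, sites, outcomes)
  expect_true(all(obs0$activation[obs0$structure == "s1"] == 0))
  # permuting input rows leaves the canonical table unchanged
  perm <- sample(nrow(sites))
  obs_p <- build_observations(densities, sites[perm, ], outcomes)
  expect_equal(obs_p, obs0)
  # missing outcome is a validation error
  expect_error(build_observations(densities, sites, outcomes[-1, ]),
               class = "validation_error")
})

test_that("scaling densities scales activations but not regression statistics", {
  contacts <- fixed_contacts(n = 8L)
  sites <- build_sites(contacts)
  g <- grid_spec(c(-30, -30, -30), 2, c(31L, 31L, 31L))
  set.seed(26)
  v <- density_volume(g, array(runif(prod(g$dims)), g$dims))
  outcomes <- data.frame(patient_id = unique(contacts$patient_id),
                         improvement = runif(8))
  obs1 <- build_observations(list(a = v), sites, outcomes)
  v3 <- density_volume(g, 3 * v$values)
  obs3 <- build_observations(list(a = v3), sites, outcomes)
  expect_equal(obs3$activation, 3 * obs1$activation, tolerance = 1e-12)
  f1 <- fit_univariate(obs1$activation, obs1$improvement)
  f3 <- fit_univariate(obs3$activation, obs3$improvement)
  expect_equal(f3$r2_adj, f1$r2_adj, tolerance = 1e-10)
  expect_equal(f3$slope_p, f1$slope_p, tolerance = 1e-10)
})

test_that("per-streamline correlations match a brute-force Pearson oracle", {
  set.seed(27)
  t <- random_tractogram(n = 6L, npts = 10L, scale = 6)
  contacts <- fixed_contacts(n = 3L, current = 3)
  contacts$x_mm <- rep(c(-4, 4), 3) + rnorm(6, 0, 2)
  contacts$y_mm <- rnorm(6, 0, 2)
  contacts$z_mm <- rnorm(6, 0, 2)
  sites <- build_sites(contacts)
  outcomes <- data.frame(patient_id = unique(contacts$patient_id),
                         improvement = c(0.2, 0.5, 0.8))
  res <- streamline_response_correlation(t, sites, outcomes, step = 0.5)
  imp <- outcomes$improvement[match(sites$patient_id, outcomes$patient_id)]
  for (si in 1:6) {
    pts <- resample_polyline(t$streamlines[[si]], 0.5)
    ov <- sapply(seq_len(nrow(sites)), function(k)
      mean(rowSums(sweep(pts, 2, as.numeric(sites[k, c("x_mm", "y_mm", "z_mm")]))^2)
           <= sites$radius_mm[k]^2))
    if (var(ov) == 0) {
      expect_false(res$defined[si])
    } else {
      # brute-force Pearson from first principles
      r_oracle <- sum((ov - mean(ov)) * (imp - mean(imp))) /
        sqrt(sum((ov - mean(ov))^2) * sum((imp - mean(imp))^2))
      expect_equal(res$r[si], r_oracle, tolerance = 1e-12)
    }
  }
})

test_that("undefined correlations are flagged, never reported as zero", {
  t <- tractogram(list(cbind(seq(-5, 5, 0.5), 0, 0)))
  contacts <- fixed_contacts(n = 3L)
  sites <- build_sites(contacts)
  outcomes <- data.frame(patient_id = unique(contacts$patient_id),
                         improvement = 0.4)   # constant outcome
  res <- streamline_response_correlation(t, sites, outcomes)
  expect_false(any(res$defined))
  expect_true(all(is.na(res$r)))
  expect_error(streamline_response_correlation(t, sites[1:2, ], outcomes),
               class = "insufficient_data")
})

test_that("overlap aligned with outcome gives a positive correlation", {
  # streamline through the high-improvement sites only
  t <- tractogram(list(cbind(0, 0, seq(-2, 2, 0.2))))
  contacts <- data.frame(patient_id = rep(c("hi1", "hi2", "lo1", "lo2"), each = 2),
                         hemisphere = rep(c("L", "R"), 4),
                         x_mm = c(0, 0, 0, 0, 30, 30, 30, 30),
                         y_mm = 0, z_mm = 0, current_mA = 2)
  sites <- build_sites(contacts)
  outcomes <- data.frame(patient_id = c("hi1", "hi2", "lo1", "lo2"),
                         improvement = c(0.8, 0.7, 0.1, 0.2))
  res <- streamline_response_correlation(t, sites, outcomes, binary = TRUE)
  expect_gt(res$r[1], 0)
})
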