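test_that("zero-dispersion bundles reproduce the resampled centerline", {
  cl <- cbind(seq(0, 20, 5), 0, 0)
  spec <- bundle_spec("b", cl, n_streamlines = 1L, lateral_sd = 0, step = 1,
                      seed = 1)
  t <- generate_bundle(spec)
  expect_equal(t$streamlines[[1]], resample_polyline(cl, 1))
})

test_that("bundle generation is deterministic given the seed", {
  spec <- bundle_spec("b", cbind(seq(0, 30, 5), 0, 0), n_streamlines = 20L,
                      lateral_sd = 2, step = 1, seed = 42)
  expect_identical(generate_bundle(spec), generate_bundle(spec))
  spec2 <- spec; spec2$seed <- 43L
  expect_false(identical(generate_bundle(spec), generate_bundle(spec2)))
})

test_that("lateral dispersion matches the requested SD", {
  # straight centerline along x: y and z offsets are pure dispersion
  spec <- bundle_spec("b", cbind(seq(-50, 50, 10), 0, 0),
                      n_streamlines = 500L, lateral_sd = 2, step = 1, seed = 7)
  t <- generate_bundle(spec)
  offs <- do.call(rbind, t$streamlines)[, 2:3]
  expect_equal(sd(as.numeric(offs)), 2, tolerance = 0.1)
})

test_that("invalid bundle specs are rejected", {
  expect_error(bundle_spec("b", cbind(0, 0, 0)), class = "parameter_error")
  expect_error(bundle_spec("b", cbind(0:1, 0, 0), n_streamlines = 0),
               class = "parameter_error")
  expect_error(bundle_spec("b", cbind(0:1, 0, 0), step = 0),
               class = "parameter_error")
  expect_error(bundle_spec("b", cbind(0:1, 0, 0), lateral_sd = -1),
               class = "parameter_error")
})

test_that("cohort generation has the right cardinality and placement", {
  spec <- cohort_spec("c", n_patients = 12L, placement_sd = 0, seed = 5)
  cd <- generate_cohort(spec)
  expect_equal(nrow(cd$outcomes), 12L)
  expect_equal(nrow(cd$contacts), 24L)
  # zero jitter: contacts exactly at the hemisphere targets
  L <- cd$contacts[cd$contacts$hemisphere == "L", ]
  expect_true(all(L$x_mm == -10 & L$y_mm == 0 & L$z_mm == 0))
  expect_identical(generate_cohort(spec), generate_cohort(spec))
})

test_that("improvement follows the relative-reduction definition with rounding", {
  # baseline 34.3, improvement 0.44: follow-up 19.208 rounds to 19
  followup <- round(34.3 * (1 - 0.44))
  expect_equal(followup, 19)
  out <- stimtract:::finalize_outcomes("p1", 34.3, 0.44)
  expect_equal(out$ybocs_followup, 19)
  expect_equal(out$improvement, (34.3 - 19) / 34.3)
})

test_that("cohort outcomes respect the domain invariants", {
  for (s in 1:5) {
    cd <- generate_cohort(cohort_spec("c", n_patients = 30L, seed = s,
                                      improvement_mean = 0.45,
                                      improvement_sd = 0.4))
    expect_true(all(cd$outcomes$ybocs_baseline >= 8 &
                    cd$outcomes$ybocs_baseline <= 40))
    expect_true(all(cd$outcomes$improvement <= 1))
    expect_true(all(cd$contacts$current_mA > 0))
    expect_true(all(cd$outcomes$ybocs_followup == round(cd$outcomes$ybocs_followup)))
  }
})

test_that("noiseless simulated outcomes are exactly linear in activation", {
  cl <- cbind(seq(-30, 30, 5), 0, 0)
  t <- generate_bundle(bundle_spec("b", cl, 80L, lateral_sd = 2, step = 1,
                                   seed = 2))
  v <- rasterize(t, raster_config(voxel_size = 1, smoothing_sigma = 2))
  contacts <- fixed_contacts(n = 8L)
  # a small slope keeps improvements below the ceiling of 1
  out <- simulate_outcomes(contacts, v, effect_slope = 0.01, noise_sd = 0,
                           seed = 3)
  sites <- build_sites(contacts)
  act <- vapply(seq_len(nrow(sites)), function(i)
    bundle_activation(v, sites[i, ]), numeric(1))
  ids <- sort(unique(sites$patient_id))
  act_pat <- vapply(ids, function(p) mean(act[sites$patient_id == p]), numeric(1))
  fit <- fit_univariate(act_pat, out$improvement)
  expect_equal(fit$slope, 0.01, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # identical contacts and currents -> identical improvements under zero noise
  dup <- contacts
  dup$patient_id <- sub("p01", "p99", dup$patient_id)
  dup <- rbind(contacts, dup[dup$patient_id == "p99", ])
  out2 <- simulate_outcomes(dup, v, effect_slope = 0.01, noise_sd = 0, seed = 3)
  expect_equal(out2$improvement[out2$patient_id == "p99"],
               out2$improvement[out2$patient_id == "p01"])
})

test_that("a zero effect slope yields null slope estimates across seeds", {
  cl <- cbind(seq(-30, 30, 5), 0, 0)
  t <- generate_bundle(bundle_spec("b", cl, 80L, lateral_sd = 2, step = 1,
                                   seed = 2))
  v <- rasterize(t, raster_config(voxel_size = 1, smoothing_sigma = 2))
  covered <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    cd <- generate_cohort(cohort_spec("c", n_patients = 10L, placement_sd = 1.5,
                                      seed = 100 + s))
    out <- simulate_outcomes(cd$contacts, v, effect_slope = 0, noise_sd = 0.1,
                             seed = 200 + s)
    sites <- build_sites(cd$contacts)
    act <- vapply(seq_len(nrow(sites)), function(i)
      bundle_activation(v, sites[i, ]), numeric(1))
    ids <- sort(unique(sites$patient_id))
    act_pat <- vapply(ids, function(p) mean(act[sites$patient_id == p]),
                      numeric(1))
    fit <- fit_univariate(act_pat, out$improvement)
    se <- abs(fit$slope / qt(fit$slope_p / 2, df = fit$n - 2, lower.tail = FALSE))
    ci <- fit$slope + c(-1, 1) * qt(0.975, fit$n - 2) * se
    if (ci[1] <= 0 && ci[2] >= 0) covered <- covered + 1L
  }
  expect_gte(covered, ceiling(0.8 * n_rep))   # nominal 95% coverage
})

test_that("contacts outside the density grid raise an out-of-bounds error", {
  v <- random_volume(seed = 9)
  contacts <- fixed_contacts(n = 2L)
  contacts$x_mm <- contacts$x_mm + 500
  expect_error(simulate_outcomes(contacts, v, 1, 0, seed = 1),
               class = "out_of_bounds")
})
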