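test_that("spherical selection matches the exhaustive distance oracle", {
  set.seed(41)
  for (case in 1:10) {
    t <- random_tractogram(n = 8L, npts = 6L, scale = 8)
    center <- runif(3, -6, 6)
    diameter <- runif(1, 1, 8)
    sel <- select_by_sphere(t, center, diameter = diameter, step = 0.25)
    keep <- sapply(t$streamlines, function(m) {
      pts <- resample_polyline(m, 0.25)
      min(sqrt(rowSums(sweep(pts, 2, center)^2))) <= diameter / 2
    })
    expect_identical(attr(sel, "indices"), which(keep))
    # original point sequences preserved
    for (j in seq_along(attr(sel, "indices")))
      expect_identical(sel$streamlines[[j]],
                       t$streamlines[[attr(sel, "indices")[j]]])
  }
})

test_that("selection handles the trivial hit and miss cases", {
  t <- tractogram(list(cbind(seq(-5, 5, 0.5), 0, 0)))
  expect_equal(n_streamlines(select_by_sphere(t, c(0, 0, 0))), 1L)
  expect_equal(n_streamlines(select_by_sphere(t, c(100, 0, 0))), 0L)
})

test_that("selection is monotone in the diameter", {
  t <- random_tractogram(n = 20L, seed = 42)
  center <- c(0, 0, 0)
  prev <- integer(0)
  for (d in c(1, 2, 4, 8, 16)) {
    idx <- attr(select_by_sphere(t, center, diameter = d), "indices")
    expect_true(all(prev %in% idx))
    prev <- idx
  }
})

test_that("group fingerprints use set-union semantics over site selections", {
  # one long streamline near both sites plus two site-exclusive ones
  shared <- cbind(seq(-12, 12, 0.5), 0, 0)
  only_a <- cbind(-10, seq(-6, 6, 0.5), 3)
  only_b <- cbind(10, seq(-6, 6, 0.5), -3)
  t <- tractogram(list(shared, only_a, only_b))
  cfg <- raster_config(1, 0, bbox = rbind(c(-20, -10, -8), c(20, 10, 8)),
                       mode = "terminal")
  f1 <- group_fingerprint(t, rbind(c(-10, 0, 0)), cfg = cfg, diameter = 8)
  expect_equal(sum(f1$values), 4)          # shared + only_a: 2 streamlines
  f2 <- group_fingerprint(t, rbind(c(-10, 0, 0), c(10, 0, 0)), cfg = cfg,
                          diameter = 8)
  # shared streamline counted once despite being selected by both sites
  expect_equal(sum(f2$values), 6)
  expect_identical(attr(f2, "indices"), 1:3)
  # disjoint selections: mass adds
  fa <- group_fingerprint(t, rbind(c(-10, 0, 3)), cfg = cfg, diameter = 2)
  fb <- group_fingerprint(t, rbind(c(10, 0, -3)), cfg = cfg, diameter = 2)
  expect_equal(sum(fa$values) + sum(fb$values), 4)
})

test_that("a single selected streamline yields unsmoothed terminal mass two", {
  t <- tractogram(list(cbind(seq(-5, 5, 0.5), 0, 0)))
  cfg <- raster_config(1, 0, bbox = rbind(c(-8, -4, -4), c(8, 4, 4)),
                       mode = "terminal")
  f <- group_fingerprint(t, rbind(c(0, 0, 0)), cfg = cfg)
  expect_equal(sum(f$values), 2)
})

test_that("peak detection follows the strict 26-neighborhood definition", {
  dims <- c(15L, 15L, 15L)
  g <- grid_spec(c(0, 0, 0), 1, dims)
  arr <- array(0, dims); arr[8, 8, 8] <- 1
  v <- gaussian_smooth(density_volume(g, arr), 1.5)
  pk <- find_peaks(v, min_value = 1e-6)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$x_mm, pk$y_mm, pk$z_mm), c(7, 7, 7))
  # constant volumes have no strict local maxima
  vc <- density_volume(g, array(1, dims))
  expect_equal(nrow(find_peaks(vc, min_value = 0.5)), 0L)
})

test_that("planted blobs are recovered within one voxel and suppressed by distance", {
  dims <- c(40L, 20L, 20L)
  g <- grid_spec(c(0, 0, 0), 1, dims)
  arr <- array(0, dims)
  arr[10, 10, 10] <- 2
  arr[30, 10, 10] <- 1    # 20 mm apart
  v <- gaussian_smooth(density_volume(g, arr), 2)
  pk <- find_peaks(v, min_value = 1e-6, min_separation_mm = 10)
  expect_equal(nrow(pk), 2L)
  expect_true(all(abs(pk$x_mm - c(9, 29)) <= 1))
  expect_true(all(abs(pk$y_mm - 9) <= 1) && all(abs(pk$z_mm - 9) <= 1))
  # suppression: peaks closer than the separation keep the larger
  arr2 <- array(0, dims)
  arr2[10, 10, 10] <- 2
  arr2[14, 10, 10] <- 1    # 4 mm apart
  v2 <- gaussian_smooth(density_volume(g, arr2), 1)
  pk2 <- find_peaks(v2, min_value = 1e-6, min_separation_mm = 10)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$x_mm, 9)
})

test_that("peak coordinates are invariant under positive rescaling", {
  v <- gaussian_smooth(random_volume(dims = c(12L, 12L, 12L), seed = 43), 1.5)
  pk1 <- find_peaks(v, min_value = 1e-9)
  v2 <- density_volume(v$grid, 5 * v$values)
  pk2 <- find_peaks(v2, min_value = 5e-9)
  expect_equal(pk1[, c("x_mm", "y_mm", "z_mm")], pk2[, c("x_mm", "y_mm", "z_mm")])
})

test_that("conjugation of a volume with itself pairs every peak", {
  v <- gaussian_smooth(random_volume(dims = c(14L, 14L, 14L), seed = 44), 1.5)
  rep <- conjugation(v, v, threshold_quantile = 0.9, pairing_mm = 1)
  expect_equal(nrow(rep$peaks_A), nrow(rep$peaks_B))
  expect_gte(nrow(rep$conjugations), nrow(rep$peaks_A))
  expect_true(all(seq_len(nrow(rep$peaks_A)) %in% rep$conjugations$peak_A))
  expect_identical(rep$mask, v$values > rep$thresholds[["A"]])
})

test_that("disjoint supports yield no conjugations", {
  dims <- c(30L, 10L, 10L)
  g <- grid_spec(c(0, 0, 0), 1, dims)
  a <- array(0, dims); a[5, 5, 5] <- 1
  b <- array(0, dims); b[25, 5, 5] <- 1
  vA <- gaussian_smooth(density_volume(g, a), 1.5)
  vB <- gaussian_smooth(density_volume(g, b), 1.5)
  rep <- conjugation(vA, vB, threshold_quantile = 0.95, pairing_mm = 5)
  expect_equal(sum(rep$mask), 0L)
  expect_equal(nrow(rep$conjugations), 0L)
  g2 <- grid_spec(c(1, 0, 0), 1, dims)
  expect_error(conjugation(vA, density_volume(g2, b)), class = "geometry_error")
})

test_that("a planted shared blob appears as the only conjugation", {
  dims <- c(40L, 16L, 16L)
  g <- grid_spec(c(0, 0, 0), 1, dims)
  a <- array(0, dims); a[10, 8, 8] <- 1; a[32, 8, 8] <- 1   # shared + A-only
  b <- array(0, dims); b[10, 8, 8] <- 1; b[5, 8, 8] <- 1    # shared + B-only
  vA <- gaussian_smooth(density_volume(g, a), 1.5)
  vB <- gaussian_smooth(density_volume(g, b), 1.5)
  rep <- conjugation(vA, vB, threshold_quantile = 0.98, pairing_mm = 4,
                     min_separation_mm = 3)
  expect_equal(nrow(rep$conjugations), 1L)
  expect_equal(rep$conjugations$xA_mm, 9)
  expect_equal(rep$conjugations$xB_mm, 9)
})

test_that("surface projection is exact trilinear interpolation", {
  v <- random_volume(dims = c(6L, 6L, 6L), origin = c(0, 0, 0), seed = 45)
  # constant volume: every vertex gets the constant
  vc <- density_volume(v$grid, array(2, c(6, 6, 6)))
  mesh <- list(vertices = rbind(c(1.2, 2.7, 3.1), c(2, 3, 4)),
               faces = rbind(c(1, 2, 1)))
  expect_equal(project_to_surface(vc, mesh), c(2, 2))
  # vertex on a voxel center: that voxel's value
  mesh2 <- list(vertices = rbind(c(2, 3, 4)), faces = NULL)
  expect_equal(project_to_surface(v, mesh2), v$values[3, 4, 5])
  # midway between two centers along x: their mean
  mesh3 <- list(vertices = rbind(c(2.5, 3, 4)), faces = NULL)
  expect_equal(project_to_surface(v, mesh3),
               (v$values[3, 4, 5] + v$values[4, 4, 5]) / 2)
  # outside vertices get zero with a warning
  mesh4 <- list(vertices = rbind(c(-3, 0, 0), c(2, 3, 4)), faces = NULL)
  expect_warning(out <- project_to_surface(v, mesh4), "outside")
  expect_equal(out, c(0, v$values[3, 4, 5]))
  expect_error(project_to_surface(v, list(vertices = matrix(0, 0, 3))),
               class = "parameter_error")
})

test_that("OFF meshes round-trip through the ASCII reader", {
  mesh <- list(vertices = rbind(c(0.5, -1.25, 3), c(2, 0, 1), c(-1, 4, 2)),
               faces = rbind(c(1L, 2L, 3L)))
  f <- withr::local_tempfile(fileext = ".off")
  write_mesh(mesh, f)
  back <- read_mesh(f)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-9)
  expect_identical(back$faces, mesh$faces)
})
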