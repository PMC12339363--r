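# Fixtures built in code: random tractograms, volumes and site tables used
# across the suite.

random_tractogram <- function(n = 5L, npts = 8L, scale = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tractogram(lapply(seq_len(n), function(i) {
    start <- runif(3, -scale, scale)
    steps <- matrix(runif(3 * (npts - 1L), -2, 2), ncol = 3L)
    rbind(start, start + apply(steps, 2L, cumsum))
  }))
}

random_volume <- function(dims = c(8L, 9L, 7L), voxel_size = 1,
                          origin = c(-4, -4, -3), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  density_volume(grid_spec(origin, voxel_size, dims),
                 array(runif(prod(dims)), dim = dims))
}

# Brute-force oracle: deposit resampled points into voxels by explicit
# per-point search over all voxel centers.
oracle_deposit <- function(points, grid) {
  arr <- array(0, dim = grid$dims)
  for (r in seq_len(nrow(points))) {
    idx <- round((points[r, ] - grid$origin) / grid$voxel_size)
    if (all(idx >= 0) && all(idx < grid$dims))
      arr[idx[1] + 1, idx[2] + 1, idx[3] + 1] <-
        arr[idx[1] + 1, idx[2] + 1, idx[3] + 1] + 1
  }
  arr
}

# Exhaustive in-sphere voxel-center mean.
oracle_sphere_mean <- function(v, center, radius) {
  g <- v$grid
  vals <- c()
  for (i in 0:(g$dims[1] - 1)) for (j in 0:(g$dims[2] - 1))
    for (k in 0:(g$dims[3] - 1)) {
      w <- g$origin + c(i, j, k) * g$voxel_size
      if (sum((w - center)^2) <= radius^2)
        vals <- c(vals, v$values[i + 1, j + 1, k + 1])
    }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

# Closed-form OLS oracle from the normal equations, independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(resid^2) / (n - 2)
  t_stat <- slope / sqrt(sigma2 / sxx)
  p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, p = p, r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# A contact table for n bilateral patients at fixed coordinates.
fixed_contacts <- function(n = 4L, current = 2) {
  ids <- sprintf("p%02d", seq_len(n))
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(patient_id = ids[i], hemisphere = c("L", "R"),
               x_mm = c(-10, 10) + 0.3 * i, y_mm = 0.2 * i, z_mm = -0.1 * i,
               current_mA = current, stringsAsFactors = FALSE)))
}
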