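#' Bundle activation score of a stimulation site
#'
#' The activation of a streamline bundle by a stimulation site is the mean
#' of the bundle's density image over all voxels whose CENTERS lie within
#' the site's activation radius of the site center. Units are the arbitrary
#' density units of the image; scores are comparable across patients within
#' one bundle, not across bundles.
#'
#' @param density a [density_volume()].
#' @param site a list or one-row data frame with `center` (world mm) and
#'   `radius` (mm); site rows from [build_sites()] (columns `x_mm`..`z_mm`,
#'   `radius_mm`) are also accepted.
#' @return scalar mean density.
#' @export
bundle_activation <- function(density, site) {
  assert_that(inherits(density, "density_volume"), "parameter_error",
              "density must be a density_volume")
  site <- as_site(site)
  grid <- density$grid
  # grid extent = union of voxel volumes (centers +/- half a voxel)
  ext_lo <- grid$origin - grid$voxel_size / 2
  ext_hi <- grid$origin + (grid$dims - 0.5) * grid$voxel_size
  if (any(site$center + site$radius < ext_lo |
          site$center - site$radius > ext_hi))
    st_stop("out_of_bounds", "activation sphere (center %s, radius %.3g mm) lies outside the density grid",
            paste(sprintf("%.2f", site$center), collapse = ", "), site$radius)
  lo <- pmax(ceiling((site$center - site$radius - grid$origin) / grid$voxel_size), 0)
  hi <- pmin(floor((site$center + site$radius - grid$origin) / grid$voxel_size),
             grid$dims - 1L)
  if (any(hi < lo))
    st_stop("resolution_error",
            "no voxel centers inside radius %.3g mm; use a smaller voxel_size than %.3g mm",
            site$radius, grid$voxel_size)
  ii <- lo[1L]:hi[1L]; jj <- lo[2L]:hi[2L]; kk <- lo[3L]:hi[3L]
  centers <- as.matrix(expand.grid(x = ii, y = jj, z = kk))
  world <- voxel_to_world(grid, centers)
  d2 <- rowSums(sweep(world, 2L, site$center)^2)
  inside <- d2 <= site$radius^2
  if (!any(inside))
    st_stop("resolution_error",
            "no voxel centers inside radius %.3g mm; use a smaller voxel_size than %.3g mm",
            site$radius, grid$voxel_size)
  sel <- centers[inside, , drop = FALSE]
  vals <- density$values[sel + 1L]          # 0-based index -> R matrix index
  mean(vals)
}

as_site <- function(site) {
  if (is.data.frame(site) || (is.list(site) && !is.null(site$x_mm))) {
    center <- as.numeric(c(site$x_mm, site$y_mm, site$z_mm))
    radius <- as.numeric(site$radius_mm %||% site$radius)
  } else {
    center <- as.numeric(site$center)
    radius <- as.numeric(site$radius)
  }
  assert_that(is_point3(center), "parameter_error", "site center must be a 3D point")
  assert_that(is_number(radius) && radius > 0, "parameter_error",
              "site radius must be > 0")
  list(center = center, radius = radius)
}

#' Build the observation table for regression
#'
#' One row per patient x hemisphere x structure: the structure's activation
#' score at that hemisphere's stimulation site, joined to the patient's
#' improvement. Left and right hemispheres are pooled as separate
#' observations (each carries its patient's improvement), as in the
#' regression design this package implements.
#'
#' @param densities named list of [density_volume()], one per structure.
#' @param sites site table from [build_sites()].
#' @param outcomes outcome table (`patient_id`, `improvement`, optionally
#'   `cohort`).
#' @return data frame with columns `patient_id`, `hemisphere`, `structure`,
#'   `activation`, `improvement` (plus `cohort` if supplied), sorted by
#'   structure, patient, hemisphere.
#' @export
build_observations <- function(densities, sites, outcomes) {
  assert_that(is.list(densities) && length(densities) > 0 &&
              !is.null(names(densities)) && all(nzchar(names(densities))),
              "parameter_error", "densities must be a named list of volumes")
  missing_pat <- setdiff(sites$patient_id, outcomes$patient_id)
  assert_that(length(missing_pat) == 0L, "validation_error",
              "no outcome for patient(s): %s", paste(missing_pat, collapse = ", "))
  imp <- outcomes$improvement[match(sites$patient_id, outcomes$patient_id)]
  rows <- lapply(names(densities), function(sname) {
    act <- vapply(seq_len(nrow(sites)), function(i)
      bundle_activation(densities[[sname]], sites[i, ]), numeric(1))
    df <- data.frame(patient_id = sites$patient_id,
                     hemisphere = sites$hemisphere,
                     structure = sname, activation = act,
                     improvement = imp, stringsAsFactors = FALSE)
    if (!is.null(outcomes$cohort))
      df$cohort <- outcomes$cohort[match(sites$patient_id, outcomes$patient_id)]
    df
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$structure, out$patient_id, out$hemisphere), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-streamline correlation of VAT overlap with clinical response
#'
#' For each streamline, its overlap with every stimulation site is the
#' fraction of the streamline's resampled points lying inside that site's
#' activation sphere (or 0/1 when `binary = TRUE`); the streamline's value
#' is the Pearson correlation of these overlaps with the pooled
#' improvements. Used to color streamlines by how strongly their
#' stimulation tracks response. Streamlines whose overlaps do not vary
#' across sites have no defined correlation and are flagged, never reported
#' as 0.
#'
#' @param t a [tractogram()].
#' @param sites site table from [build_sites()].
#' @param outcomes outcome table with `patient_id` and `improvement`.
#' @param step resampling step for the point-in-sphere test, mm.
#' @param binary use any-point-inside (0/1) instead of the point fraction.
#' @return data frame: `streamline` (index), `r` (correlation, `NA` when
#'   undefined), `defined` (logical).
#' @export
streamline_response_correlation <- function(t, sites, outcomes, step = 0.5,
                                            binary = FALSE) {
  assert_that(inherits(t, "tractogram"), "parameter_error", "t must be a tractogram")
  assert_that(nrow(sites) >= 3L, "insufficient_data",
              "need >= 3 observations for per-streamline correlations, got %d",
              nrow(sites))
  imp <- outcomes$improvement[match(sites$patient_id, outcomes$patient_id)]
  assert_that(all(!is.na(imp)), "validation_error",
              "every site's patient needs an improvement value")
  centers <- site_centers(sites)
  radii <- sites$radius_mm
  imp_var <- stats::var(imp) > 0
  res <- lapply(seq_len(n_streamlines(t)), function(si) {
    pts <- resample_polyline(t$streamlines[[si]], step)
    ov <- vapply(seq_len(nrow(sites)), function(k) {
      d2 <- rowSums(sweep(pts, 2L, centers[k, ])^2)
      frac <- mean(d2 <= radii[k]^2)
      if (binary) as.numeric(frac > 0) else frac
    }, numeric(1))
    if (!imp_var || stats::var(ov) == 0)
      return(data.frame(streamline = si, r = NA_real_, defined = FALSE))
    data.frame(streamline = si, r = stats::cor(ov, imp), defined = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
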