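#' Select streamlines by a spherical ROI
#'
#' Returns the streamlines having at least one point within `diameter / 2`
#' of `center`. Streamlines are resampled to `step` mm before the distance
#' test (so selection is robust to sparse polylines) but the ORIGINAL point
#' sequences are returned. The default 2 mm diameter matches the ROI size
#' used to probe normative connectomes at stimulation coordinates. Selection
#' is monotone in the diameter.
#'
#' @param t a [tractogram()].
#' @param center world-mm ROI center.
#' @param diameter ROI diameter in mm (> 0).
#' @param step resampling step for the distance test, mm.
#' @return A [tractogram()] (possibly empty) with attribute `"indices"`
#'   giving the selected streamline indices in `t`.
#' @export
select_by_sphere <- function(t, center, diameter = 2, step = 0.5) {
  assert_that(inherits(t, "tractogram"), "parameter_error", "t must be a tractogram")
  assert_that(is_point3(center), "parameter_error", "center must be a 3D point")
  assert_that(is_number(diameter) && diameter > 0, "parameter_error",
              "diameter must be > 0")
  r2 <- (diameter / 2)^2
  keep <- vapply(t$streamlines, function(m) {
    pts <- resample_polyline(m, step)
    min(rowSums(sweep(pts, 2L, center)^2)) <= r2
  }, logical(1))
  idx <- which(keep)
  out <- structure(list(streamlines = t$streamlines[idx],
                        space_tag = t$space_tag), class = "tractogram")
  attr(out, "indices") <- idx
  out
}

#' Group-level cortical fingerprint of stimulation sites
#'
#' Selects streamlines around every site of a group (union of the per-site
#' spherical selections, each streamline counted once) and renders their
#' terminal density. This is the group's cortical "fingerprint": where the
#' streamlines reachable from the group's stimulation sites terminate.
#'
#' @param t the normative [tractogram()].
#' @param sites site table ([build_sites()]) or an n x 3 matrix of world-mm
#'   stimulation coordinates.
#' @param cfg a [raster_config()] with `mode = "terminal"` (default 1 mm
#'   voxels, 3 mm kernel).
#' @param diameter,step passed to [select_by_sphere()].
#' @return A [density_volume()] with attribute `"indices"` (selected
#'   streamline indices). With an empty selection and an explicit bbox, an
#'   all-zero volume is returned with a warning.
#' @export
group_fingerprint <- function(t, sites,
                              cfg = raster_config(voxel_size = 1,
                                                  smoothing_sigma = 3,
                                                  mode = "terminal"),
                              diameter = 2, step = 0.5) {
  centers <- if (is.data.frame(sites)) site_centers(sites) else rbind(sites)
  assert_that(nrow(centers) >= 1L, "parameter_error", "need >= 1 site")
  idx <- sort(unique(unlist(lapply(seq_len(nrow(centers)), function(k) {
    attr(select_by_sphere(t, centers[k, ], diameter = diameter, step = step),
         "indices")
  }))))
  if (length(idx) == 0L) {
    warning("no streamlines selected for this group; fingerprint is empty",
            call. = FALSE)
    assert_that(!identical(cfg$bbox, "auto"), "parameter_error",
                "empty selection needs an explicit bbox to define the grid")
    grid <- grid_for(matrix(0, 0L, 3L), cfg)
    out <- density_volume(grid, array(0, grid$dims))
  } else {
    sub <- structure(list(streamlines = t$streamlines[idx],
                          space_tag = t$space_tag), class = "tractogram")
    out <- terminal_density(sub, cfg)
  }
  attr(out, "indices") <- idx
  out
}

#' Local maxima of a density volume
#'
#' A peak is a voxel strictly greater than all of its 26 neighbors with
#' value at least `min_value`. Peaks closer than `min_separation_mm` (world
#' distance) are suppressed keeping the larger peak; ties keep the
#' lexicographically smallest voxel index. Results are sorted by value,
#' descending, and reported in world mm.
#'
#' @param v a [density_volume()].
#' @param min_value minimum peak value (> 0).
#' @param min_separation_mm minimum distance between reported peaks (>= 0).
#' @return data frame: `x_mm`, `y_mm`, `z_mm`, `value`, `i`, `j`, `k`
#'   (0-based voxel indices); zero rows when there is no peak.
#' @export
find_peaks <- function(v, min_value, min_separation_mm = 0) {
  assert_that(inherits(v, "density_volume"), "parameter_error",
              "v must be a density_volume")
  assert_that(is_number(min_value) && min_value > 0, "parameter_error",
              "min_value must be > 0")
  assert_that(is_number(min_separation_mm) && min_separation_mm >= 0,
              "parameter_error", "min_separation_mm must be >= 0")
  arr <- v$values
  dims <- dim(arr)
  # pad with -Inf so boundary voxels compare against "nothing"
  pad <- array(-Inf, dims + 2L)
  pad[2:(dims[1L] + 1L), 2:(dims[2L] + 1L), 2:(dims[3L] + 1L)] <- arr
  is_max <- array(TRUE, dims)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2:(dims[1L] + 1L)) + dx, (2:(dims[2L] + 1L)) + dy,
              (2:(dims[3L] + 1L)) + dz]
    is_max <- is_max & (arr > nb)
  }
  cand <- which(is_max & arr >= min_value, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      value = numeric(0), i = integer(0), j = integer(0),
                      k = integer(0)))
  vals <- arr[cand]
  idx0 <- cand - 1L                       # 0-based
  # order: value desc, then lexicographic index for ties
  ord <- order(-vals, idx0[, 1L], idx0[, 2L], idx0[, 3L])
  idx0 <- idx0[ord, , drop = FALSE]
  vals <- vals[ord]
  world <- voxel_to_world(v$grid, idx0)
  keep <- logical(length(vals))
  for (p in seq_along(vals)) {
    if (min_separation_mm == 0 || !any(keep)) { keep[p] <- TRUE; next }
    d <- sqrt(rowSums(sweep(world[keep, , drop = FALSE], 2L, world[p, ])^2))
    keep[p] <- all(d >= min_separation_mm)
  }
  data.frame(x_mm = world[keep, 1L], y_mm = world[keep, 2L],
             z_mm = world[keep, 3L], value = vals[keep],
             i = idx0[keep, 1L], j = idx0[keep, 2L], k = idx0[keep, 3L])
}

#' Conjugation (overlap) of two terminal-density fingerprints
#'
#' Thresholds each volume at its own `threshold_quantile`, forms the overlap
#' mask (voxels supra-threshold in BOTH), and pairs peaks of A with peaks of
#' B that lie within `pairing_mm` of each other and inside or adjacent
#' (26-neighborhood) to the mask. Such paired peaks mark cortical zones
#' where both groups' fingerprints penetrate — conjugation regions.
#'
#' @param vA,vB [density_volume()]s on identical grids.
#' @param threshold_quantile per-volume quantile defining "supra-threshold"
#'   (default 0.95).
#' @param pairing_mm maximum world distance between paired peaks.
#' @param min_separation_mm peak suppression distance passed to
#'   [find_peaks()].
#' @return An object of class `conjugation_report`: list with `peaks_A`,
#'   `peaks_B` (peak tables), `conjugations` (data frame of paired peaks:
#'   coordinates and values from both sources), `mask` (logical array),
#'   `thresholds` (the two absolute thresholds used).
#' @export
conjugation <- function(vA, vB, threshold_quantile = 0.95, pairing_mm = 10,
                        min_separation_mm = 5) {
  assert_that(inherits(vA, "density_volume") && inherits(vB, "density_volume"),
              "parameter_error", "vA and vB must be density_volumes")
  same <- identical(vA$grid$dims, vB$grid$dims) &&
    isTRUE(all.equal(vA$grid$origin, vB$grid$origin, tolerance = 1e-9)) &&
    isTRUE(all.equal(vA$grid$voxel_size, vB$grid$voxel_size, tolerance = 1e-9))
  assert_that(same, "geometry_error", "vA and vB must share one grid")
  assert_that(is_number(threshold_quantile) && threshold_quantile > 0 &&
              threshold_quantile < 1, "parameter_error",
              "threshold_quantile must be in (0, 1)")
  qA <- stats::quantile(vA$values, threshold_quantile, names = FALSE)
  qB <- stats::quantile(vB$values, threshold_quantile, names = FALSE)
  mask <- vA$values > qA & vB$values > qB
  min_A <- max(qA, .Machine$double.xmin)
  min_B <- max(qB, .Machine$double.xmin)
  peaks_A <- find_peaks(vA, min_value = min_A, min_separation_mm = min_separation_mm)
  peaks_B <- find_peaks(vB, min_value = min_B, min_separation_mm = min_separation_mm)
  conj <- list()
  if (nrow(peaks_A) > 0L && nrow(peaks_B) > 0L) {
    for (a in seq_len(nrow(peaks_A))) {
      pa <- c(peaks_A$x_mm[a], peaks_A$y_mm[a], peaks_A$z_mm[a])
      for (b in seq_len(nrow(peaks_B))) {
        pb <- c(peaks_B$x_mm[b], peaks_B$y_mm[b], peaks_B$z_mm[b])
        if (sqrt(sum((pa - pb)^2)) > pairing_mm) next
        near_mask <- mask_adjacent(mask, unlist(peaks_A[a, c("i", "j", "k")])) ||
          mask_adjacent(mask, unlist(peaks_B[b, c("i", "j", "k")]))
        if (!near_mask) next
        conj[[length(conj) + 1L]] <- data.frame(
          peak_A = a, peak_B = b,
          xA_mm = pa[1L], yA_mm = pa[2L], zA_mm = pa[3L],
          xB_mm = pb[1L], yB_mm = pb[2L], zB_mm = pb[3L],
          value_A = peaks_A$value[a], value_B = peaks_B$value[b],
          distance_mm = sqrt(sum((pa - pb)^2)))
      }
    }
  }
  conj <- if (length(conj)) do.call(rbind, conj) else
    data.frame(peak_A = integer(0), peak_B = integer(0),
               xA_mm = numeric(0), yA_mm = numeric(0), zA_mm = numeric(0),
               xB_mm = numeric(0), yB_mm = numeric(0), zB_mm = numeric(0),
               value_A = numeric(0), value_B = numeric(0),
               distance_mm = numeric(0))
  structure(list(peaks_A = peaks_A, peaks_B = peaks_B, conjugations = conj,
                 mask = mask, thresholds = c(A = qA, B = qB)),
            class = "conjugation_report")
}

# TRUE if any voxel of the 3x3x3 neighborhood around 0-based index ijk is
# inside the mask.
mask_adjacent <- function(mask, ijk) {
  dims <- dim(mask)
  rng <- lapply(1:3, function(d) max(1L, ijk[d]):min(dims[d], ijk[d] + 2L))
  any(mask[rng[[1L]], rng[[2L]], rng[[3L]]])
}

#' @export
print.conjugation_report <- function(x, ...) {
  cat(sprintf("conjugation report: %d + %d peaks, %d conjugation(s), %d mask voxel(s)\n",
              nrow(x$peaks_A), nrow(x$peaks_B), nrow(x$conjugations),
              sum(x$mask)))
  invisible(x)
}

#' Sample a volume on a surface mesh
#'
#' Trilinear interpolation of the volume at each mesh vertex, e.g. to
#' project terminal densities onto the gray/white matter transition
#' surface. Vertices outside the grid get value 0 (with one warning giving
#' the count).
#'
#' @param v a [density_volume()].
#' @param mesh a list with `vertices` (n x 3 world mm) and `faces` (m x 3,
#'   1-based vertex indices), e.g. from [read_mesh()].
#' @return numeric vector of per-vertex values.
#' @export
project_to_surface <- function(v, mesh) {
  assert_that(inherits(v, "density_volume"), "parameter_error",
              "v must be a density_volume")
  assert_that(is.list(mesh) && !is.null(mesh$vertices) &&
              nrow(rbind(mesh$vertices)) > 0L, "parameter_error",
              "mesh must have a non-empty vertex list")
  verts <- rbind(mesh$vertices)
  grid <- v$grid
  f <- sweep(verts, 2L, grid$origin) / grid$voxel_size    # continuous voxel
  out <- numeric(nrow(verts))
  inside <- f[, 1L] >= 0 & f[, 1L] <= grid$dims[1L] - 1L &
            f[, 2L] >= 0 & f[, 2L] <= grid$dims[2L] - 1L &
            f[, 3L] >= 0 & f[, 3L] <= grid$dims[3L] - 1L
  if (any(!inside))
    warning(sprintf("%d mesh vertex(es) outside the grid set to 0", sum(!inside)),
            call. = FALSE)
  if (any(inside)) {
    fi <- f[inside, , drop = FALSE]
    i0 <- pmin(floor(fi), matrix(rep(grid$dims - 2L, each = nrow(fi)), ncol = 3L))
    i0 <- pmax(i0, 0)
    w <- fi - i0
    acc <- numeric(nrow(fi))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[, 1L] else 1 - w[, 1L]) *
            (if (dy) w[, 2L] else 1 - w[, 2L]) *
            (if (dz) w[, 3L] else 1 - w[, 3L])
      idx <- cbind(i0[, 1L] + dx, i0[, 2L] + dy, i0[, 3L] + dz) + 1L
      acc <- acc + wt * v$values[idx]
    }
    out[inside] <- acc
  }
  out
}

#' Read and write a simple ASCII triangle mesh (OFF format)
#'
#' Minimal reader/writer for the Object File Format: a header line `OFF`, a
#' count line `n_vertices n_faces n_edges`, `n_vertices` coordinate lines
#' (world mm) and `n_faces` face lines (`3 i j k`, 0-based on disk, 1-based
#' in R).
#'
#' @param path file path.
#' @param mesh list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @return `read_mesh()`: the mesh list; `write_mesh()`: `path` invisibly.
#' @export
read_mesh <- function(path) {
  assert_that(file.exists(path), "parameter_error", "no such file: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  assert_that(length(lines) >= 2L && toupper(lines[1L]) == "OFF",
              "format_error", "not an OFF mesh file")
  counts <- as.integer(strsplit(lines[2L], "\\s+")[[1L]])
  nv <- counts[1L]; nf <- counts[2L]
  assert_that(is.finite(nv) && nv >= 1L, "parameter_error", "mesh has no vertices")
  vs <- do.call(rbind, lapply(lines[3:(2L + nv)], function(l)
    as.numeric(strsplit(l, "\\s+")[[1L]][1:3])))
  fs <- if (nf > 0L)
    do.call(rbind, lapply(lines[(3L + nv):(2L + nv + nf)], function(l) {
      p <- as.integer(strsplit(l, "\\s+")[[1L]])
      assert_that(p[1L] == 3L, "format_error", "only triangle faces are supported")
      p[2:4] + 1L
    }))
  else matrix(integer(0), 0L, 3L)
  list(vertices = vs, faces = fs)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  verts <- rbind(mesh$vertices)
  faces <- if (is.null(mesh$faces)) matrix(integer(0), 0L, 3L) else rbind(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(verts), nrow(faces)), con)
  writeLines(apply(verts, 1L, function(r) paste(format(r, digits = 10),
                                                collapse = " ")), con)
  if (nrow(faces) > 0L)
    writeLines(apply(faces, 1L, function(r) paste(c(3L, r - 1L), collapse = " ")),
               con)
  invisible(path)
}

#' Export a peak table in stereotactic-report layout
#'
#' Writes peaks (and optional conjugation pairing flags) as TSV with world
#' mm coordinates, the layout used for reporting cortical penetration peaks.
#'
#' @param peaks peak table from [find_peaks()].
#' @param path output TSV path.
#' @param label optional region label column (recycled).
#' @param paired optional logical vector flagging conjugated peaks.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, label = NA_character_, paired = FALSE) {
  out <- data.frame(label = label, x_mm = peaks$x_mm, y_mm = peaks$y_mm,
                    z_mm = peaks$z_mm, value = peaks$value, paired = paired,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
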