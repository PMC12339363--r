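#' Isotropic axis-aligned grid specification
#'
#' One fixed world-coordinate convention is used everywhere: world
#' millimetres, RAS+, with `origin` the world coordinate of the CENTER of
#' voxel (0, 0, 0) and 0-based voxel indices internally. Voxel index `i`
#' maps to world `origin + i * voxel_size`.
#'
#' @param origin world-mm coordinate (length 3) of the center of voxel
#'   (0, 0, 0).
#' @param voxel_size isotropic voxel edge length in mm (> 0).
#' @param dims integer vector of 3 positive grid dimensions.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin, voxel_size, dims) {
  assert_that(is_point3(origin), "parameter_error", "origin must be 3 finite numbers")
  assert_that(is_number(voxel_size) && voxel_size > 0, "parameter_error",
              "voxel_size must be a positive number")
  dims <- as.integer(dims)
  assert_that(length(dims) == 3L && all(dims >= 1L), "parameter_error",
              "dims must be 3 positive integers")
  structure(list(origin = as.numeric(origin), voxel_size = voxel_size,
                 dims = dims), class = "grid_spec")
}

#' Scalar density volume on an isotropic grid
#'
#' Holds non-negative per-voxel values (streamline visitation or terminal
#' densities) together with the [grid_spec()] giving their world placement.
#'
#' @param grid a [grid_spec()].
#' @param values numeric array matching `grid$dims`; all values must be
#'   non-negative and finite.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(grid, values) {
  assert_that(inherits(grid, "grid_spec"), "parameter_error", "grid must be a grid_spec")
  values <- as.array(values)
  assert_that(identical(dim(values), as.integer(grid$dims)), "parameter_error",
              "values shape does not match grid dims")
  assert_that(all(is.finite(values)) && all(values >= 0), "parameter_error",
              "density values must be finite and non-negative")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat(sprintf("density_volume: %s voxels @ %.3g mm, origin (%s), mass %.6g\n",
              paste(x$grid$dims, collapse = "x"), x$grid$voxel_size,
              paste(sprintf("%.2f", x$grid$origin), collapse = ", "),
              sum(x$values)))
  invisible(x)
}

#' World/voxel coordinate mapping
#'
#' `world_to_voxel()` returns 0-based voxel indices (rounded to the nearest
#' voxel center); `voxel_to_world()` returns the world-mm coordinates of
#' voxel centers. Composing the two is the identity on indices.
#'
#' @param grid a [grid_spec()].
#' @param pts n x 3 matrix of world-mm points (or 0-based indices).
#' @return n x 3 matrix of 0-based indices (or world-mm points).
#' @export
world_to_voxel <- function(grid, pts) {
  pts <- rbind(pts)
  idx <- round(sweep(pts, 2L, grid$origin) / grid$voxel_size)
  storage.mode(idx) <- "integer"
  idx
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(grid, pts) {
  pts <- rbind(pts)
  sweep(pts * grid$voxel_size, 2L, grid$origin, `+`)
}

grid_affine <- function(grid) {
  a <- diag(c(rep(grid$voxel_size, 3L), 1))
  a[1:3, 4L] <- grid$origin
  a
}

#' Read and write density volumes as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 with the affine encoding the grid: diagonal
#' `voxel_size`, translation `origin` (voxel-center convention, RAS+). Only
#' isotropic axis-aligned grids are supported; any sheared, rotated or
#' anisotropic affine raises an `unsupported_geometry` error.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param v a [density_volume()].
#' @return `read_volume()` returns a [density_volume()];
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), "parameter_error", "no such file: %s", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  rot <- aff[1:3, 1:3]
  off <- rot - diag(diag(rot))
  d <- diag(rot)
  if (any(abs(off) > 1e-6) || any(d <= 0) || max(d) - min(d) > 1e-6 * max(d))
    st_stop("unsupported_geometry",
            "only isotropic axis-aligned RAS+ grids are supported (affine diag: %s)",
            paste(sprintf("%.4g", d), collapse = ", "))
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))   # drop RNifti image attributes
  assert_that(length(dim(vals)) == 3L, "unsupported_geometry",
              "expected a 3D volume, got %dD", length(dim(vals)))
  density_volume(grid_spec(aff[1:3, 4L], mean(d), dim(vals)), vals)
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  assert_that(inherits(v, "density_volume"), "parameter_error",
              "v must be a density_volume")
  img <- RNifti::asNifti(v$values)
  aff <- structure(grid_affine(v$grid), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tractogram file formats. Two dialects are supported and both are converted
# to world mm (RAS+) on read:
#   TCK (MRtrix): points already stored in world/scanner mm.
#   TRK (TrackVis): points stored in "voxmm" (voxel indices scaled by
#     voxel_size, measured from the CORNER of voxel (0,0,0)); the header's
#     vox_to_ras affine maps voxel indices to world mm, so
#     world = M %*% (voxmm / voxel_size - 0.5).

#' Read a tractogram from TRK or TCK
#'
#' All points are returned in world mm (RAS+) regardless of the on-disk
#' voxel/corner convention. TRK files must be version 2 with a valid
#' `vox_to_ras` affine.
#'
#' @param path file path.
#' @param format `"TRK"` or `"TCK"`; default guesses from the extension.
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, format = c("auto", "TRK", "TCK")) {
  format <- match.arg(toupper(format[1L]), c("AUTO", "TRK", "TCK"))
  if (format == "AUTO")
    format <- toupper(tools::file_ext(path))
  assert_that(format %in% c("TRK", "TCK"), "format_error",
              "unknown tractogram format '%s'", format)
  assert_that(file.exists(path), "parameter_error", "no such file: %s", path)
  if (format == "TRK") read_trk(path) else read_tck(path)
}

#' Write a tractogram to TRK or TCK
#'
#' @param t a [tractogram()].
#' @param path output path.
#' @param format `"TRK"` or `"TCK"` (default from the extension).
#' @param voxel_size for TRK only: the voxel size used for the on-disk voxmm
#'   encoding (the world coordinates are unchanged; this only exercises the
#'   format's voxel-order convention). Default 1.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path, format = c("auto", "TRK", "TCK"),
                             voxel_size = 1) {
  assert_that(inherits(t, "tractogram"), "parameter_error", "t must be a tractogram")
  format <- match.arg(toupper(format[1L]), c("AUTO", "TRK", "TCK"))
  if (format == "AUTO")
    format <- toupper(tools::file_ext(path))
  assert_that(format %in% c("TRK", "TCK"), "format_error",
              "unknown tractogram format '%s'", format)
  if (format == "TRK") write_trk(t, path, voxel_size) else write_tck(t, path)
  invisible(path)
}

write_trk <- function(t, path, voxel_size = 1) {
  con <- file(path, "wb")
  on.exit(close(con))
  vs <- rep(voxel_size, 3L)
  aff <- diag(c(vs, 1))                      # vox_to_ras
  writeChar("TRACK", con, nchars = 5L, eos = NULL)
  writeBin(raw(1L), con)
  writeBin(as.integer(c(1L, 1L, 1L)), con, size = 2L, endian = "little")
  writeBin(vs, con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")   # origin (unused)
  writeBin(0L, con, size = 2L, endian = "little")            # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")            # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(aff)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)
  writeChar("RAS", con, nchars = 3L, eos = NULL); writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                     # pad2
  writeBin(numeric(6L), con, size = 4L, endian = "little")   # orientation
  writeBin(raw(2L), con)                                     # pad1
  writeBin(raw(6L), con)                                     # invert/swap flags
  writeBin(length(t$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")            # version
  writeBin(1000L, con, size = 4L, endian = "little")         # hdr_size
  for (m in t$streamlines) {
    voxmm <- sweep(sweep(m, 2L, vs, `/`) + 0.5, 2L, vs, `*`)
    writeBin(nrow(m), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5L, useBytes = TRUE)
  assert_that(identical(magic, "TRACK"), "format_error",
              "not a TRK file (bad magic '%s')", magic)
  readBin(con, "raw", 1L)
  readBin(con, "integer", 3L, size = 2L, endian = "little")  # dim
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")  # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  assert_that(hdr_size == 1000L, "format_error", "TRK header size %d != 1000", hdr_size)
  assert_that(version == 2L && abs(aff[4L, 4L] - 1) < 1e-6, "format_error",
              "only TRK version 2 with a valid vox_to_ras affine is supported")
  assert_that(all(vs > 0), "format_error", "TRK voxel_size must be positive")
  streamlines <- list()
  i <- 0L
  repeat {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n) == 0L) break
    i <- i + 1L
    if (n < 2L)
      st_stop("format_error", "TRK record %d has %d point(s); streamlines need >= 2", i, n)
    pts <- matrix(readBin(con, "numeric", n * (3L + n_scalars), size = 4L,
                          endian = "little"), ncol = 3L + n_scalars, byrow = TRUE)
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L, endian = "little")
    voxmm <- pts[, 1:3, drop = FALSE]
    vox <- sweep(voxmm, 2L, vs, `/`) - 0.5
    world <- cbind(vox, 1) %*% t(aff)
    streamlines[[i]] <- world[, 1:3, drop = FALSE]
  }
  assert_that(n_count == 0L || n_count == length(streamlines), "format_error",
              "TRK header count %d does not match %d streamlines read",
              n_count, length(streamlines))
  tractogram(streamlines)
}

write_tck <- function(t, path) {
  body_lines <- c("mrtrix tracks", "datatype: Float32LE",
                  sprintf("count: %d", length(t$streamlines)))
  # the 'file: . <offset>' field must state the byte offset of the binary
  # section, which depends on its own printed length; iterate to fixpoint
  offset <- 0L
  repeat {
    hdr <- paste0(paste(c(body_lines, sprintf("file: . %d", offset), "END"),
                        collapse = "\n"), "\n")
    if (nchar(hdr, type = "bytes") == offset) break
    offset <- nchar(hdr, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (m in t$streamlines) {
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
}

read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  end_at <- grepRaw("END\n", raw, fixed = TRUE)
  assert_that(length(end_at) == 1L && end_at > 0L, "format_error",
              "TCK header lacks an END marker")
  head_txt <- rawToChar(raw[seq_len(end_at + 3L)])
  assert_that(startsWith(head_txt, "mrtrix tracks"), "format_error",
              "not a TCK file (bad magic)")
  m <- regmatches(head_txt, regexec("file:\\s*\\.\\s*(\\d+)", head_txt))[[1L]]
  assert_that(length(m) == 2L, "format_error", "TCK header lacks a 'file: .' offset")
  offset <- as.integer(m[2L])
  dt <- regmatches(head_txt, regexec("datatype:\\s*(\\S+)", head_txt))[[1L]]
  assert_that(length(dt) == 2L && dt[2L] %in% c("Float32LE", "Float32BE"),
              "format_error", "unsupported TCK datatype")
  endian <- if (dt[2L] == "Float32LE") "little" else "big"
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                  (length(raw) - offset) %/% 4L, size = 4L, endian = endian)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  is_sep <- is.nan(pts[, 1L])
  is_end <- is.infinite(pts[, 1L])
  streamlines <- list()
  start <- 1L
  rec <- 0L
  for (r in seq_len(nrow(pts))) {
    if (is_sep[r] || is_end[r]) {
      len <- r - start
      if (len > 0L) {
        rec <- rec + 1L
        if (len < 2L)
          st_stop("format_error", "TCK record %d has %d point(s); streamlines need >= 2",
                  rec, len)
        streamlines[[rec]] <- pts[start:(r - 1L), , drop = FALSE]
      } else if (is_sep[r] && (r == 1L || is_sep[r - 1L])) {
        # a NaN separator with no points before it: an empty streamline record
        # (a trailing NaN directly before the Inf terminator is legal)
        st_stop("format_error", "TCK record %d is empty", rec + 1L)
      }
      start <- r + 1L
      if (is_end[r]) break
    }
  }
  tractogram(streamlines)
}
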