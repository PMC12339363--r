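#' Streamline tractogram in world millimetre coordinates
#'
#' A tractogram is a collection of streamlines, each an ordered polyline of
#' three-dimensional points in world millimetres (RAS+). This is the unit of
#' connectomic anatomy used throughout the package: atlas-style bundles,
#' normative-connectome selections and synthetic test anatomy are all
#' tractograms. All coordinates are world mm regardless of how a file stored
#' them on disk.
#'
#' @param streamlines list of numeric matrices, each with 3 columns (x, y, z
#'   in mm) and at least 2 rows.
#' @param space_tag identifier of the reference space the coordinates live
#'   in (default `"MNI"`).
#' @return An object of class `tractogram`: a list with elements
#'   `streamlines` and `space_tag`.
#' @examples
#' t <- tractogram(list(cbind(0:4, 0, 0)))
#' n_streamlines(t)
#' @export
tractogram <- function(streamlines, space_tag = "MNI") {
  assert_that(is.list(streamlines), "parameter_error",
              "streamlines must be a list of point matrices")
  streamlines <- lapply(seq_along(streamlines), function(i) {
    m <- streamlines[[i]]
    if (is.data.frame(m)) m <- as.matrix(m)
    assert_that(is.matrix(m) && ncol(m) == 3L, "format_error",
                "streamline %d is not an n x 3 matrix", i)
    assert_that(nrow(m) >= 2L, "format_error",
                "streamline %d has fewer than 2 points", i)
    assert_that(all(is.finite(m)), "format_error",
                "streamline %d contains non-finite coordinates", i)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  structure(list(streamlines = streamlines, space_tag = space_tag),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("tractogram: %d streamlines, %d points, space %s\n",
              length(x$streamlines), sum(npts), x$space_tag))
  invisible(x)
}

#' Number of streamlines in a tractogram
#' @param t a [tractogram()].
#' @return integer count.
#' @export
n_streamlines <- function(t) length(t$streamlines)

#' Resample a polyline at (approximately) fixed arc-length spacing
#'
#' Linear interpolation along the cumulative arc length. The first and last
#' point are always preserved exactly; intermediate points are spaced at most
#' `step` mm apart (evenly, at `L / ceiling(L / step)` where `L` is the total
#' length).
#'
#' @param points n x 3 matrix of world-mm points.
#' @param step target spacing in mm (> 0).
#' @return m x 3 matrix of resampled points.
#' @export
resample_polyline <- function(points, step) {
  assert_that(is_number(step) && step > 0, "parameter_error",
              "step must be a positive number")
  points <- as.matrix(points)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L == 0) return(points[c(1L, nrow(points)), , drop = FALSE])
  targets <- seq(0, L, length.out = max(2L, ceiling(L / step) + 1L))
  out <- vapply(1:3, function(d) stats::approx(s, points[, d], xout = targets,
                                               ties = "ordered")$y,
                numeric(length(targets)))
  matrix(out, ncol = 3L)
}

# Resample every streamline; returns a list of matrices (not a tractogram,
# the space tag is unchanged by construction).
resample_all <- function(t, step) lapply(t$streamlines, resample_polyline, step = step)
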