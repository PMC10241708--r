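# Minimal Feret diameter (caliper width) of pixel objects and polygons.
#
# The minimum over orientations of the distance between two parallel tangent
# lines of a convex set is attained with one tangent flush against a hull
# edge (rotating-calipers theorem), so it suffices to test each hull edge
# direction. For pixel footprints the hull is taken over the four corner
# points of every pixel, so a single pixel has caliper width 1 px.

# min Feret of a set of planar points, in the same units as the coordinates
min_feret_points <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(0)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hull)
  if (n == 2L) return(0)  # degenerate: collinear points have zero width
  widths <- vapply(seq_len(n), function(i) {
    p1 <- hull[i, ]; p2 <- hull[if (i == n) 1L else i + 1L, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    # distance of every hull point from the line through the edge
    d <- abs((hull[, 1] - p1[1]) * (-e[2]) + (hull[, 2] - p1[2]) * e[1]) / len
    max(d)
  }, numeric(1))
  min(widths)
}

# min Feret of a pixel footprint given n x 2 (x, y) pixel-centre coordinates,
# in pixel units; uses pixel corner points so a 1-px object has width 1
min_feret_px <- function(coords) {
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 1L)
  corners <- rbind(cbind(coords[, 1] - 0.5, coords[, 2] - 0.5),
                   cbind(coords[, 1] + 0.5, coords[, 2] - 0.5),
                   cbind(coords[, 1] - 0.5, coords[, 2] + 0.5),
                   cbind(coords[, 1] + 0.5, coords[, 2] + 0.5))
  min_feret_points(corners)
}

#' Minimal Feret diameter of a pixel footprint
#'
#' The minimal Feret diameter is the minimal distance between two parallel
#' tangents of the object — its caliper width. It is insensitive to
#' elongation from non-tangential sectioning, which is why it is preferred
#' over area-equivalent diameters for vessel size. Computed by rotating
#' calipers on the convex hull of the pixel corner points.
#'
#' @param footprint either a logical/0-1 matrix (the object's mask) or an
#'   n x 2 matrix of pixel (x, y) coordinates.
#' @param resolution_px_per_um pixels per micrometre.
#' @return the minimal Feret diameter in micrometres.
#' @export
min_feret <- function(footprint, resolution_px_per_um) {
  stopifnot(resolution_px_per_um > 0)
  if (is.matrix(footprint) && ncol(footprint) != 2L) {
    idx <- which(footprint != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("empty footprint")
    coords <- cbind(idx[, 2], idx[, 1])
  } else {
    coords <- footprint
    if (nrow(coords) == 0L) stop("empty footprint")
  }
  min_feret_px(coords) / resolution_px_per_um
}
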