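# Binary morphology helpers shared by the segmentation stages. All stages
# are binary-in / binary-out; each records itself in the mask's provenance.

disc_kernel <- function(radius_px) EBImage::makeBrush(2L * radius_px + 1L, "disc")

as_mask <- function(m, provenance = character(0)) {
  stopifnot(is.matrix(m))
  m <- m != 0
  attr(m, "provenance") <- provenance
  class(m) <- c("vessel_mask", class(m))
  m
}

add_step <- function(mask, step) {
  p <- c(attr(mask, "provenance"), step)
  as_mask(unclass(mask), p)
}

#' Binarize a stain layer
#'
#' Thresholds the 256-grade CD34 layer: mask is true where the layer is at
#' least `threshold`. With `threshold = "otsu"` the threshold maximising
#' between-class variance over the 256 grey levels is computed and recorded
#' in the mask's provenance.
#'
#' @param cd34_layer integer matrix 0..255 (from [quantize_256()]).
#' @param threshold integer 0-255 or `"otsu"`.
#' @return A binary `vessel_mask` with a `provenance` attribute listing the
#'   applied steps and parameters.
#' @export
binarize <- function(cd34_layer, threshold = "otsu") {
  if (length(cd34_layer) == 0L) stop("empty image")
  layer <- unclass(cd34_layer)
  attributes(layer) <- list(dim = dim(cd34_layer))
  if (identical(threshold, "otsu")) {
    t_raw <- EBImage::otsu(EBImage::Image(layer / 255), range = c(0, 1),
                           levels = 256L)
    # otsu's convention is x > t; convert to the smallest integer threshold
    # with layer >= t equivalent for integer data
    threshold <- floor(t_raw * 255) + 1L
    src <- "otsu"
  } else {
    stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 255)
    src <- "fixed"
  }
  m <- layer >= threshold
  as_mask(m, sprintf("binarize(threshold=%d,%s)", as.integer(threshold), src))
}

# Majority vote over a disc neighbourhood; the binary median filter and the
# binary mean filter (> 0.5 rule) coincide in this form. The border is
# replicated so constant masks are fixed points.
binary_majority <- function(m, radius_px) {
  k <- disc_kernel(radius_px)
  cnt <- EBImage::filter2(m + 0, k, boundary = "replicate")
  round(cnt) > sum(k) / 2
}

#' Despeckle a binary mask with a median filter
#'
#' Binary median filter over a disc of the given radius; removes isolated
#' pixels and speckle noise that survives thresholding.
#'
#' @param mask a binary `vessel_mask`.
#' @param radius_px disc radius in pixels (default 2).
#' @return the filtered `vessel_mask`.
#' @export
despeckle <- function(mask, radius_px = 2) {
  stopifnot(radius_px >= 1)
  out <- binary_majority(unclass(mask), radius_px)
  as_mask(out, c(attr(mask, "provenance"),
                 sprintf("despeckle(median,r=%d)", as.integer(radius_px))))
}

#' Repair broken vessel walls
#'
#' Handles incompletely stained vessels (walls with breaks, objects with
#' holes): dilate by `enlarge_radius_px`, fill enclosed holes, smooth with a
#' binary mean (majority) then median filter of radius `smooth_radius_px`,
#' and erode back to original size. A C-shaped wall with a gap of at most
#' `2 * enlarge_radius_px` becomes a single filled object covering the lumen.
#' Holes touching the image border are not filled.
#'
#' @param mask a binary `vessel_mask`.
#' @param enlarge_radius_px dilation/erosion radius (default 3 px = 0.75 um
#'   at 4 px/um, sized to close sub-cell-width staining breaks).
#' @param smooth_radius_px radius of the mean and median smoothing filters
#'   (default 2).
#' @return the repaired `vessel_mask`; provenance records all five steps.
#' @export
repair_vessels <- function(mask, enlarge_radius_px = 3, smooth_radius_px = 2) {
  stopifnot(enlarge_radius_px >= 1, smooth_radius_px >= 1)
  kb <- disc_kernel(enlarge_radius_px)
  m <- unclass(mask) + 0
  m <- EBImage::dilate(m, kb)
  m <- EBImage::fillHull(m)
  m <- binary_majority(m, smooth_radius_px) + 0   # mean filter, majority rule
  m <- binary_majority(m, smooth_radius_px) + 0   # median filter
  m <- EBImage::erode(m, kb)
  as_mask(m != 0, c(attr(mask, "provenance"),
                    sprintf("dilate(r=%d)", enlarge_radius_px), "fill_holes",
                    sprintf("mean(r=%d)", smooth_radius_px),
                    sprintf("median(r=%d)", smooth_radius_px),
                    sprintf("erode(r=%d)", enlarge_radius_px)))
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that meet
# diagonally are merged through a union-find pass over diagonal neighbour
# pairs.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0)
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Label vessels and apply the size filter
#'
#' Labels 8-connected components of the repaired mask, computes each
#' component's minimal Feret diameter, and discards components below the
#' size floor — the rule that excludes single CD34+ cells. The floor
#' defaults to 4 um, the caliper width of the smallest vessels retained.
#'
#' @param mask a repaired binary `vessel_mask`.
#' @param resolution_px_per_um pixels per micrometre.
#' @param min_feret_floor_um minimum retained minimal Feret diameter (um).
#' @param min_area_um2 optional additional minimum area filter (um^2).
#' @param exclusion_mask optional binary matrix of pixels excluded from
#'   analysis (artifacts, fat, necrosis); components overlapping it are
#'   dropped and excluded pixels do not count as tissue area.
#' @return A `vessel_set`: list with `table` (data frame: label, centroid_x_px,
#'   centroid_y_px, area_um2, min_feret_um), `labels` (integer label matrix
#'   over retained vessels, relabelled 1..n), `resolution_px_per_um`,
#'   `tissue_area_mm2`, and the inherited `provenance`.
#' @export
label_vessels <- function(mask, resolution_px_per_um, min_feret_floor_um = 4,
                          min_area_um2 = 0, exclusion_mask = NULL) {
  stopifnot(resolution_px_per_um > 0)
  res <- resolution_px_per_um
  m <- unclass(mask)
  if (!is.null(exclusion_mask)) m <- m & !(exclusion_mask != 0)
  lab <- label8(m)
  n <- max(lab)
  keep <- integer(0); rows <- list()
  if (n > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    ids <- lab[lab > 0]
    by_id <- split(seq_len(nrow(idx)), ids)
    for (id in seq_len(n)) {
      px <- idx[by_id[[as.character(id)]], , drop = FALSE]
      mf <- min_feret_px(cbind(px[, 2], px[, 1])) / res
      area <- nrow(px) / res^2
      if (mf >= min_feret_floor_um && area >= min_area_um2) {
        keep <- c(keep, id)
        rows[[length(rows) + 1L]] <- data.frame(
          label = id, centroid_x_px = mean(px[, 2]),
          centroid_y_px = mean(px[, 1]), area_um2 = area, min_feret_um = mf)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), centroid_x_px = numeric(0),
               centroid_y_px = numeric(0), area_um2 = numeric(0),
               min_feret_um = numeric(0))
  relab <- matrix(0L, nrow(m), ncol(m))
  if (length(keep)) {
    map <- integer(n); map[keep] <- seq_along(keep)
    sel <- lab > 0 & lab %in% keep
    relab[sel] <- map[lab[sel]]
    tab$label <- seq_along(keep)
  }
  tissue_px <- length(m) - if (is.null(exclusion_mask)) 0 else sum(exclusion_mask != 0)
  structure(list(table = tab, labels = relab, resolution_px_per_um = res,
                 tissue_area_mm2 = tissue_px / (res * 1000)^2,
                 provenance = c(attr(mask, "provenance"),
                                sprintf("label8+size_filter(floor=%g um)",
                                        min_feret_floor_um))),
            class = "vessel_set")
}

#' @export
print.vessel_set <- function(x, ...) {
  cat("vessel_set:", nrow(x$table), "vessels over", round(x$tissue_area_mm2, 4),
      "mm^2 at", x$resolution_px_per_um, "px/um\n")
  invisible(x)
}
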