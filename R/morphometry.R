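#' Vessel density
#'
#' Number of detected vessels per mm^2 of analysed tissue; the area already
#' excludes pixels under any exclusion mask (see [label_vessels()]).
#'
#' @param vessels a `vessel_set`, or a vessel count.
#' @param tissue_area_mm2 analysed tissue area in mm^2; defaults to the
#'   vessel set's own.
#' @return vessels per mm^2.
#' @export
vessel_density <- function(vessels, tissue_area_mm2 = NULL) {
  n <- if (inherits(vessels, "vessel_set")) nrow(vessels$table) else vessels
  if (is.null(tissue_area_mm2) && inherits(vessels, "vessel_set"))
    tissue_area_mm2 <- vessels$tissue_area_mm2
  if (is.null(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop("tissue_area_mm2 must be positive")
  n / tissue_area_mm2
}

#' Median vessel diameter
#'
#' Median of the per-vessel minimal Feret diameters (midpoint of the two
#' central order statistics for even counts). An empty vessel set yields NA
#' with a warning rather than an error — the metric is undefined, not the
#' computation broken.
#'
#' @param vessels a `vessel_set` or a numeric vector of diameters (um).
#' @return median diameter in um, or NA if there are no vessels.
#' @export
median_vessel_diameter <- function(vessels) {
  d <- if (inherits(vessels, "vessel_set")) vessels$table$min_feret_um else vessels
  if (length(d) == 0L) {
    warning("no vessels: median diameter undefined")
    return(NA_real_)
  }
  stats::median(d)
}

#' Perivascular rings
#'
#' The perivascular space of a vessel is the band of pixels within
#' `ring_distance_px` (Euclidean) of its footprint, excluding pixels of any
#' vessel. Pixels within reach of two vessels are assigned to the nearer
#' one; exact ties go to the lower label, so rings are pairwise disjoint.
#'
#' @param vessels a `vessel_set` from [label_vessels()].
#' @param ring_distance_px band width in pixels (default 10, i.e. 2.5 um at
#'   4 px/um).
#' @return integer matrix of the mask's shape: 0 outside rings, otherwise
#'   the label of the owning vessel; attribute `ring_distance_px`.
#' @export
perivascular_rings <- function(vessels, ring_distance_px = 10) {
  stopifnot(inherits(vessels, "vessel_set"), ring_distance_px >= 1)
  lab <- vessels$labels
  n <- max(lab)
  h <- nrow(lab); w <- ncol(lab)
  ring <- matrix(0L, h, w)
  if (n > 0) {
    best_d <- matrix(Inf, h, w)
    best_lab <- matrix(0L, h, w)
    for (id in seq_len(n)) {
      # distance of every non-vessel pixel to vessel id (distmap measures
      # foreground distance to nearest background, so invert)
      d <- EBImage::distmap(matrix(as.numeric(lab != id), h, w))
      upd <- d < best_d    # strict: ties keep the earlier (lower) label
      best_d[upd] <- d[upd]
      best_lab[upd] <- id
    }
    sel <- best_d > 0 & best_d <= ring_distance_px & lab == 0L
    ring[sel] <- best_lab[sel]
  }
  attr(ring, "ring_distance_px") <- ring_distance_px
  ring
}

#' Perivascular a-SMA intensity
#'
#' Median a-SMA OD over each vessel's perivascular ring, and the image-level
#' perivascular intensity (PVI): the median over all ring pixels of the
#' image. a-SMA staining outside perivascular regions (e.g. from
#' cancer-associated fibroblasts) is ignored.
#'
#' @param rings ring label matrix from [perivascular_rings()].
#' @param sma_od numeric matrix of a-SMA OD, co-registered with the rings.
#' @return list with `per_vessel` (data frame: label, pv_od_median,
#'   ring_area_px) and `pvi` (image median over ring pixels; NA if no ring
#'   pixels).
#' @export
perivascular_intensity <- function(rings, sma_od) {
  stopifnot(all(dim(rings) == dim(sma_od)))
  sel <- rings > 0
  labs <- rings[sel]; vals <- sma_od[sel]
  n <- if (length(labs)) max(labs) else 0L
  per <- data.frame(label = seq_len(n), pv_od_median = NA_real_,
                    ring_area_px = 0L)
  if (length(labs)) {
    med <- tapply(vals, labs, stats::median)
    cnt <- tapply(vals, labs, length)
    ids <- as.integer(names(med))
    per$pv_od_median[ids] <- as.numeric(med)
    per$ring_area_px[ids] <- as.integer(cnt)
  }
  empty <- per$ring_area_px == 0L
  if (any(empty))
    warning(sum(empty), " vessel(s) with empty perivascular ring excluded from PVI")
  list(per_vessel = per,
       pvi = if (length(vals)) stats::median(vals) else NA_real_)
}

#' Fraction of covered vessels
#'
#' FCV: the fraction of vessels whose perivascular a-SMA OD exceeds the
#' cutoff (strictly; ties count as uncovered). The default cutoff convention
#' is the cohort-level median of per-vessel perivascular OD — a per-case
#' median would force FCV toward 0.5 for every case and carry no information.
#'
#' @param per_vessel_pv_od numeric vector of per-vessel perivascular OD
#'   medians (NA entries — empty rings — are dropped).
#' @param cutoff the covered/uncovered OD cutoff.
#' @return FCV in `[0, 1]`, or NA (with warning) if there are no vessels.
#' @export
fraction_covered <- function(per_vessel_pv_od, cutoff) {
  v <- per_vessel_pv_od[!is.na(per_vessel_pv_od)]
  if (length(v) == 0L) {
    warning("no vessels: FCV undefined")
    return(NA_real_)
  }
  mean(v > cutoff)
}

#' Stromal a-SMA metrics
#'
#' Stroma is defined by marker expression: pixels whose a-SMA OD is at least
#' `stroma_threshold_od`, outside vessel footprints and exclusions. Returns
#' the stromal area (mm^2) and the median stromal a-SMA OD.
#'
#' @param sma_od numeric matrix of a-SMA OD.
#' @param vessel_mask binary matrix of vessel pixels (excluded from stroma);
#'   may be NULL.
#' @param exclusion_mask optional binary matrix of excluded pixels.
#' @param stroma_threshold_od OD threshold defining marker-positive stroma
#'   (default 0.15).
#' @param resolution_px_per_um pixels per micrometre.
#' @return list `stromal_area_mm2`, `stromal_sma_od_median` (NA with warning
#'   when no stroma pixels).
#' @export
stromal_metrics <- function(sma_od, vessel_mask = NULL, exclusion_mask = NULL,
                            stroma_threshold_od = 0.15, resolution_px_per_um) {
  stopifnot(resolution_px_per_um > 0)
  sel <- sma_od >= stroma_threshold_od
  if (!is.null(vessel_mask)) sel <- sel & !(unclass(vessel_mask) != 0)
  if (!is.null(exclusion_mask)) sel <- sel & !(exclusion_mask != 0)
  n <- sum(sel)
  if (n == 0L) {
    warning("no stroma pixels: stromal metrics undefined")
    return(list(stromal_area_mm2 = 0, stromal_sma_od_median = NA_real_))
  }
  list(stromal_area_mm2 = n / (resolution_px_per_um * 1000)^2,
       stromal_sma_od_median = stats::median(sma_od[sel]))
}

#' Measure one image end to end
#'
#' Convenience wrapper running stain separation, segmentation and
#' morphometry on one RGB image, returning the per-image metrics and the
#' per-vessel table.
#'
#' @param image h x w x 3 integer RGB array with `resolution_px_per_um`
#'   attribute (or pass `resolution_px_per_um`).
#' @param stains a [stain_model()].
#' @param threshold binarization threshold (integer or "otsu").
#' @param od_max OD scale of the 256-grade layer.
#' @param despeckle_radius_px,enlarge_radius_px,smooth_radius_px pipeline
#'   radii (see the stage functions).
#' @param min_feret_floor_um,ring_distance_px,stroma_threshold_od size floor,
#'   perivascular band width and stroma threshold (see the stage functions).
#' @param exclusion_mask optional binary exclusion matrix.
#' @param resolution_px_per_um pixels per micrometre; default read from the
#'   image attribute.
#' @param fcv_cutoff optional covered/uncovered cutoff; if NULL the FCV is
#'   left NA for later cohort-level computation.
#' @return list with `metrics` (one-row data frame: n_vessels, density,
#'   median_diameter_um, pvi, fcv, stromal_area_mm2, stromal_od,
#'   tissue_area_mm2), `per_vessel` (table with pv_od_median appended),
#'   `vessels` (the `vessel_set`), `rings`.
#' @export
measure_image <- function(image, stains = default_stain_model(),
                          threshold = "otsu", od_max = 2,
                          despeckle_radius_px = 2, enlarge_radius_px = 3,
                          smooth_radius_px = 2, min_feret_floor_um = 4,
                          ring_distance_px = 10, stroma_threshold_od = 0.15,
                          exclusion_mask = NULL,
                          resolution_px_per_um = attr(image, "resolution_px_per_um"),
                          fcv_cutoff = NULL) {
  if (is.null(resolution_px_per_um))
    stop("resolution_px_per_um missing on image and not supplied")
  od <- rgb_to_od(image)
  amounts <- deconvolve(od, stains)
  cd34 <- quantize_256(amounts[, , "CD34"], od_max = od_max)
  sma_od <- amounts[, , "aSMA"]
  mask <- binarize(cd34, threshold)
  mask <- despeckle(mask, despeckle_radius_px)
  mask <- repair_vessels(mask, enlarge_radius_px, smooth_radius_px)
  vessels <- label_vessels(mask, resolution_px_per_um, min_feret_floor_um,
                           exclusion_mask = exclusion_mask)
  rings <- perivascular_rings(vessels, ring_distance_px)
  pv <- perivascular_intensity(rings, sma_od)
  per_vessel <- merge(vessels$table,
                      pv$per_vessel[, c("label", "pv_od_median")],
                      by = "label", all.x = TRUE)
  strom <- stromal_metrics(sma_od, vessel_mask = vessels$labels > 0,
                           exclusion_mask = exclusion_mask,
                           stroma_threshold_od = stroma_threshold_od,
                           resolution_px_per_um = resolution_px_per_um)
  fcv <- if (is.null(fcv_cutoff)) NA_real_ else
    fraction_covered(per_vessel$pv_od_median, fcv_cutoff)
  metrics <- data.frame(
    n_vessels = nrow(per_vessel),
    density = vessel_density(vessels),
    median_diameter_um = if (nrow(per_vessel)) stats::median(per_vessel$min_feret_um) else NA_real_,
    pvi = pv$pvi, fcv = fcv,
    stromal_area_mm2 = strom$stromal_area_mm2,
    stromal_od = strom$stromal_sma_od_median,
    tissue_area_mm2 = vessels$tissue_area_mm2)
  list(metrics = metrics, per_vessel = per_vessel, vessels = vessels,
       rings = rings)
}
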