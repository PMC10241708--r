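#' Generate a ground-truth vessel layout
#'
#' Places `n_vessels` non-overlapping elliptical vessels (open lumen,
#' endothelial wall) on an image grid, plus optional sub-resolution CD34+
#' distractor dots that exercise the size filter. Lumen minor-axis diameters
#' are drawn log-normal and floored at 4 um, the caliper width of the
#' smallest vessels the detector is meant to keep. A chosen fraction of
#' vessels carries a perivascular a-SMA ring (pericyte coverage).
#'
#' The reported ground-truth `diameter_um` per vessel is the OUTER minor-axis
#' diameter (lumen + 2 x wall): the minimal Feret diameter of the filled
#' object that segmentation reconstructs after wall repair.
#'
#' @param n_vessels number of vessels to place (>= 0).
#' @param diameter_log_mean,diameter_log_sd meanlog / sdlog of the log-normal
#'   lumen-diameter distribution, in log-um. Defaults give a median near
#'   10 um with right skew, a realistic capillary-to-venule range.
#' @param image_size_px integer `(height, width)` in pixels.
#' @param resolution_px_per_um pixels per micrometre (default 4).
#' @param sma_covered_fraction fraction of vessels flagged as a-SMA covered,
#'   rounded to the nearest count.
#' @param wall_thickness_um range (min, max) of uniform wall thickness.
#' @param eccentricity_max maximum ellipse eccentricity (in `[0, 1)`).
#' @param gap_fraction fraction of vessels rendered with a broken
#'   ("C-shaped") wall; the gap chord is at most `gap_px_max` pixels, the
#'   defect the repair stage closes.
#' @param gap_px_max maximum wall-gap chord in pixels (default 4).
#' @param n_distractors number of single-cell-sized CD34+ dots (diameter
#'   1.5-3 um, below the 4 um floor) scattered between vessels; default 20.
#' @param covered_ring_od,uncovered_ring_od a-SMA OD amount of the
#'   perivascular ring for covered / uncovered vessels.
#' @param background_stroma_od uniform low a-SMA OD amount of the stroma.
#' @param margin_px minimum clearance kept between rendered objects so
#'   morphological closing cannot merge neighbours (default 12).
#' @param max_retries placement attempts per object before the layout is
#'   declared infeasible.
#' @param seed integer seed; mandatory for reproducible layouts.
#' @return A `vq_layout`: list with `image_size_px`, `resolution_px_per_um`,
#'   `vessels` (data frame: vessel_id, center_x, center_y, lumen_diameter_um,
#'   wall_thickness_um, diameter_um, orientation_rad, eccentricity,
#'   has_sma_ring, sma_ring_od, gap_px), `distractors` (data frame),
#'   `background_stroma_od`, `seed`.
#' @export
generate_vessel_layout <- function(n_vessels,
                                   diameter_log_mean = log(10),
                                   diameter_log_sd = 0.45,
                                   image_size_px = c(512L, 512L),
                                   resolution_px_per_um = 4,
                                   sma_covered_fraction = 0.5,
                                   wall_thickness_um = c(1.5, 3),
                                   eccentricity_max = 0.6,
                                   gap_fraction = 0.3,
                                   gap_px_max = 4,
                                   n_distractors = 20,
                                   covered_ring_od = 0.8,
                                   uncovered_ring_od = 0.05,
                                   background_stroma_od = 0.05,
                                   margin_px = 12,
                                   max_retries = 200,
                                   seed) {
  stopifnot(n_vessels >= 0, length(image_size_px) == 2L,
            resolution_px_per_um > 0,
            sma_covered_fraction >= 0, sma_covered_fraction <= 1)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  h <- as.integer(image_size_px[1]); w <- as.integer(image_size_px[2])
  res <- resolution_px_per_um

  lumen <- if (n_vessels > 0)
    pmax(4, stats::rlnorm(n_vessels, diameter_log_mean, diameter_log_sd)) else numeric(0)
  wall <- stats::runif(n_vessels, wall_thickness_um[1], wall_thickness_um[2])
  ecc <- stats::runif(n_vessels, 0, eccentricity_max)
  ori <- stats::runif(n_vessels, 0, pi)
  n_cov <- round(sma_covered_fraction * n_vessels)
  covered <- rep(FALSE, n_vessels)
  if (n_cov > 0) covered[sample.int(n_vessels, n_cov)] <- TRUE
  gap <- rep(0, n_vessels)
  n_gap <- round(gap_fraction * n_vessels)
  if (n_gap > 0) gap[sample.int(n_vessels, n_gap)] <- stats::runif(n_gap, 2, gap_px_max)

  # effective footprint radius in px, including the a-SMA ring extent
  ring_w_px <- 2 * res                      # ring width 2 um
  b_out <- (lumen / 2 + wall) * res         # outer semi-minor axis, px
  a_out <- b_out / sqrt(1 - ecc^2)          # outer semi-major axis, px
  reach <- a_out + ring_w_px

  place <- function(reach_i, centers, reaches) {
    if (reach_i + 1 >= w - reach_i - 1 || reach_i + 1 >= h - reach_i - 1)
      return(NULL)   # object wider than the image
    for (try in seq_len(max_retries)) {
      cx <- stats::runif(1, reach_i + 1, w - reach_i - 1)
      cy <- stats::runif(1, reach_i + 1, h - reach_i - 1)
      if (nrow(centers) == 0L) return(c(cx, cy))
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (all(d > reaches + reach_i + margin_px)) return(c(cx, cy))
    }
    NULL
  }

  centers <- matrix(numeric(0), ncol = 2)
  reaches <- numeric(0)
  ord <- order(reach, decreasing = TRUE)    # place big vessels first
  cxy <- matrix(NA_real_, n_vessels, 2)
  for (i in ord) {
    p <- place(reach[i], centers, reaches)
    if (is.null(p)) stop("layout infeasible: could not place all vessels without overlap")
    cxy[i, ] <- p
    centers <- rbind(centers, p)
    reaches <- c(reaches, reach[i])
  }

  dist_df <- data.frame(center_x = numeric(0), center_y = numeric(0),
                        diameter_um = numeric(0))
  if (n_distractors > 0) {
    dd <- stats::runif(n_distractors, 1.5, 3)
    for (i in seq_len(n_distractors)) {
      r_i <- dd[i] / 2 * res
      p <- place(r_i, centers, reaches)
      if (is.null(p)) next                   # distractors are best-effort
      centers <- rbind(centers, p)
      reaches <- c(reaches, r_i)
      dist_df <- rbind(dist_df, data.frame(center_x = p[1], center_y = p[2],
                                           diameter_um = dd[i]))
    }
  }

  vessels <- data.frame(
    vessel_id = seq_len(n_vessels),
    center_x = cxy[, 1], center_y = cxy[, 2],
    lumen_diameter_um = lumen,
    wall_thickness_um = wall,
    diameter_um = lumen + 2 * wall,
    orientation_rad = ori,
    eccentricity = ecc,
    has_sma_ring = covered,
    sma_ring_od = ifelse(covered, covered_ring_od, uncovered_ring_od),
    gap_px = gap)

  structure(list(image_size_px = c(h, w), resolution_px_per_um = res,
                 vessels = vessels, distractors = dist_df,
                 background_stroma_od = background_stroma_od,
                 ring_width_px = ring_w_px, seed = as.integer(seed)),
            class = "vq_layout")
}

#' @export
print.vq_layout <- function(x, ...) {
  cat("vq_layout:", nrow(x$vessels), "vessels,", nrow(x$distractors),
      "distractors on", x$image_size_px[1], "x", x$image_size_px[2],
      "px at", x$resolution_px_per_um, "px/um\n")
  invisible(x)
}

# Per-pixel stain amount maps for a layout. Returns list(cd34, sma) matrices.
layout_amount_maps <- function(layout, cd34_od = 1.0) {
  h <- layout$image_size_px[1]; w <- layout$image_size_px[2]
  cd34 <- matrix(0, h, w)
  sma <- matrix(layout$background_stroma_od, h, w)
  xg <- matrix(rep(seq_len(w), each = h), h, w)   # x = column index
  yg <- matrix(rep(seq_len(h), times = w), h, w)  # y = row index
  v <- layout$vessels
  for (i in seq_len(nrow(v))) {
    b <- (v$lumen_diameter_um[i] / 2 + v$wall_thickness_um[i]) *
      layout$resolution_px_per_um
    a <- b / sqrt(1 - v$eccentricity[i]^2)
    wall_px <- v$wall_thickness_um[i] * layout$resolution_px_per_um
    th <- v$orientation_rad[i]
    dx <- xg - v$center_x[i]; dy <- yg - v$center_y[i]
    u <- dx * cos(th) + dy * sin(th)       # along major axis
    s <- -dx * sin(th) + dy * cos(th)      # along minor axis
    r_out <- sqrt((u / a)^2 + (s / b)^2)
    a_in <- max(a - wall_px, 0.5); b_in <- max(b - wall_px, 0.5)
    r_in <- sqrt((u / a_in)^2 + (s / b_in)^2)
    wall_mask <- r_out <= 1 & r_in > 1
    if (v$gap_px[i] > 0) {
      # remove an angular wedge of the wall whose chord ~ gap_px
      half_ang <- asin(min(1, v$gap_px[i] / (2 * b)))
      ang <- atan2(s, u)
      wall_mask <- wall_mask & !(abs(ang) < half_ang)
    }
    cd34[wall_mask] <- cd34[wall_mask] + cd34_od
    # a-SMA ring: annulus just outside the outer ellipse
    rw <- layout$ring_width_px
    r_ring <- sqrt((u / (a + rw))^2 + (s / (b + rw))^2)
    ring_mask <- r_out > 1 & r_ring <= 1
    sma[ring_mask] <- sma[ring_mask] + v$sma_ring_od[i]
  }
  d <- layout$distractors
  for (i in seq_len(nrow(d))) {
    r_px <- d$diameter_um[i] / 2 * layout$resolution_px_per_um
    dx <- xg - d$center_x[i]; dy <- yg - d$center_y[i]
    cd34[dx^2 + dy^2 <= r_px^2] <- cd34_od
  }
  list(cd34 = cd34, sma = sma)
}

#' Render a dual-chromogen brightfield image from a layout
#'
#' Forward Beer-Lambert model: each pixel's channel intensity is
#' `round(255 * 10^(-sum_s A_s(p) * V_s[c]))` clipped to 0..255, where
#' `A_s(p)` is stain s's OD amount at pixel p (vessel walls carry the CD34
#' chromogen, perivascular rings and stroma the a-SMA chromogen) and `V_s`
#' its unit colour vector. Gaussian noise of sd `noise_sd_od` is added to the
#' amount maps (clipped at 0) before the transform.
#'
#' @param layout a `vq_layout` from [generate_vessel_layout()].
#' @param stains a [stain_model()] with at least 2 linearly independent
#'   vectors; default [default_stain_model()].
#' @param noise_sd_od stain-amount noise sd in OD units (default 0).
#' @param cd34_od OD amount of the CD34 chromogen in vessel walls and
#'   distractor dots (default 1).
#' @param seed integer seed for the noise draw.
#' @return list with `image` (h x w x 3 integer array 0..255, attribute
#'   `resolution_px_per_um`), `amounts` (list of the realized per-stain
#'   amount maps, including any noise — the true OD content of the image),
#'   and `truth` (the layout's vessel table).
#' @export
render_ihc_image <- function(layout, stains = default_stain_model(),
                             noise_sd_od = 0, cd34_od = 1.0, seed = layout$seed) {
  stopifnot(inherits(layout, "vq_layout"), inherits(stains, "stain_model"))
  if (ncol(stains$vectors) < 2L) stop("need >= 2 stain vectors")
  am <- layout_amount_maps(layout, cd34_od = cd34_od)
  A <- cbind(as.numeric(am$cd34), as.numeric(am$sma))
  if (noise_sd_od > 0) {
    set.seed(as.integer(seed))
    A <- A + matrix(stats::rnorm(length(A), 0, noise_sd_od), nrow(A))
    A[A < 0] <- 0
    # the realized (noisy) amounts are the actual OD content of the image
    # and hence the ground truth any unmixing can be held to
    am$cd34 <- matrix(A[, 1], nrow(am$cd34))
    am$sma <- matrix(A[, 2], nrow(am$sma))
  }
  img <- amounts_to_rgb(A, stains, dim = layout$image_size_px)
  attr(img, "resolution_px_per_um") <- layout$resolution_px_per_um
  list(image = img, amounts = am, truth = layout$vessels)
}

# Beer-Lambert forward transform of an n x k amount matrix to an
# h x w x 3 8-bit image.
amounts_to_rgb <- function(A, stains, dim) {
  OD <- A %*% t(stains$vectors[, seq_len(ncol(A)), drop = FALSE])
  I <- round(255 * 10^(-OD))
  I[I < 0] <- 0; I[I > 255] <- 255
  array(as.integer(I), dim = c(dim, 3L))
}

#' Write a rendered image and its ground truth to disk
#'
#' @param rendered output of [render_ihc_image()].
#' @param image_path path of the 8-bit RGB TIFF to write.
#' @param truth_path optional path of the ground-truth CSV (one row per
#'   vessel).
#' @return `image_path`, invisibly.
#' @export
write_ihc_image <- function(rendered, image_path, truth_path = NULL) {
  img <- rendered$image
  # EBImage expects x,y,c in [0,1]
  eb <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  EBImage::writeImage(eb, image_path, type = "tiff", bits.per.sample = 8L)
  if (!is.null(truth_path))
    utils::write.csv(rendered$truth, truth_path, row.names = FALSE)
  invisible(image_path)
}

#' Read an 8-bit RGB image (TIFF/PNG)
#'
#' @param path image file path.
#' @param resolution_px_per_um physical resolution to attach (default 4).
#' @return h x w x 3 integer array 0..255 with `resolution_px_per_um`
#'   attribute.
#' @export
read_ihc_image <- function(path, resolution_px_per_um = 4) {
  eb <- EBImage::readImage(path)
  a <- EBImage::imageData(eb)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3L))
  img <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
  img <- array(as.integer(round(img * 255)), dim = dim(img))
  attr(img, "resolution_px_per_um") <- resolution_px_per_um
  img
}
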