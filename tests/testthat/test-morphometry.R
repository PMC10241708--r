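test_that("min Feret matches closed forms on canonical shapes", {
  # axis-aligned 40 x 16 px rectangle at 4 px/um -> 16 px = 4 um
  r <- matrix(FALSE, 60, 60); r[10:49, 20:35] <- TRUE
  expect_equal(min_feret(r, 4), 4)

  # disc of radius 20 px -> 10 um within one pixel-quantization unit
  d <- disc_mask(64, 32, 32, 20)
  expect_equal(min_feret(d, 4), 10, tolerance = 0.25 / 10)

  # rotated rectangle, rasterized with pixel-centre inclusion: the caliper
  # width of the corner hull can exceed the ideal 16 px width by up to
  # (|cos| + |sin|) px of staircase overhang — one pixel-quantization unit
  # in the corner convention
  th <- 30 * pi / 180
  m <- matrix(FALSE, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    u <- (j - 40) * cos(th) + (i - 40) * sin(th)
    v <- -(j - 40) * sin(th) + (i - 40) * cos(th)
    if (abs(u) <= 20 && abs(v) <= 8) m[i, j] <- TRUE
  }
  quant <- (abs(cos(th)) + abs(sin(th))) / 4
  mf <- min_feret(m, 4)
  expect_gte(mf, 4 - quant)
  expect_lte(mf, 4 + quant)
  # and it agrees with the sweep oracle on the same raster
  coords <- which(m, arr.ind = TRUE)[, c(2, 1)]
  expect_equal(mf * 4, feret_sweep(pixel_corners(coords)), tolerance = 1e-6)

  # single pixel has caliper width one pixel
  p <- matrix(FALSE, 5, 5); p[3, 3] <- TRUE
  expect_equal(min_feret(p, 1), 1)
  expect_error(min_feret(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("rotating calipers equals the exhaustive angle sweep", {
  set.seed(41)
  for (i in 1:20) {
    pts <- matrix(runif(2 * sample(5:40, 1), 0, 100), ncol = 2)
    hullw <- vesselquant:::min_feret_points(pts)
    expect_equal(hullw, feret_sweep(pts), tolerance = 1e-6)
  }
  # rasterized: compare through pixel corners
  for (i in 1:5) {
    m <- disc_mask(50, 25, 25, 5 + 3 * i)
    coords <- which(m, arr.ind = TRUE)[, c(2, 1)]
    expect_equal(vesselquant:::min_feret_px(coords),
                 feret_sweep(pixel_corners(coords)), tolerance = 1e-6)
  }
})

test_that("min Feret is rotation-invariant within pixel quantization", {
  base <- NULL
  for (th in c(0, 20, 45, 70, 110) * pi / 180) {
    m <- matrix(FALSE, 90, 90)
    for (i in 1:90) for (j in 1:90) {
      u <- (j - 45) * cos(th) + (i - 45) * sin(th)
      v <- -(j - 45) * sin(th) + (i - 45) * cos(th)
      if ((u / 25)^2 + (v / 12)^2 <= 1) m[i, j] <- TRUE
    }
    f <- min_feret(m, 4)
    if (is.null(base)) base <- f else expect_equal(f, base, tolerance = 2 / 4 / base)
  }
})

test_that("vessel density is exact arithmetic, inversely scaling with area", {
  # 5 vessels on 1000 x 1000 px at 4 px/um = 0.0625 mm^2 -> 80 per mm^2
  expect_equal(vessel_density(5, 1000 * 1000 / 4000^2), 80)
  expect_equal(vessel_density(0, 0.0625), 0)
  # half the image excluded: 12 vessels over 0.03125 mm^2 -> 384
  expect_equal(vessel_density(12, 0.03125), 384)
  expect_error(vessel_density(5, 0), "positive")
  expect_equal(vessel_density(7, 0.5) * 2, vessel_density(7, 0.25))
})

test_that("median vessel diameter uses midpoint order statistics", {
  expect_equal(median_vessel_diameter(c(4, 6, 20)), 6)
  expect_equal(median_vessel_diameter(c(4, 6, 10, 20)), 8)
  expect_warning(res <- median_vessel_diameter(numeric(0)), "undefined")
  expect_true(is.na(res))
})

test_that("perivascular rings are Euclidean bands, disjoint and clipped", {
  # single disc: ring area within 2% of the analytic annulus
  m <- disc_mask(120, 60, 60, 15)
  vs <- label_vessels(as_mask_for_test(m), 4)
  rings <- perivascular_rings(vs, 10)
  r_eff <- sqrt(sum(m) / pi)   # effective radius of the rasterized disc
  analytic <- pi * ((r_eff + 10)^2 - r_eff^2)
  expect_lt(abs(sum(rings > 0) - analytic) / analytic, 0.02)
  expect_true(all(rings[m] == 0))  # disjoint from the footprint
  # every ring pixel within 10 px of the footprint
  idx <- which(rings > 0, arr.ind = TRUE)
  fp <- which(m, arr.ind = TRUE)
  dmin <- apply(idx, 1, function(p) sqrt(min((fp[, 1] - p[1])^2 + (fp[, 2] - p[2])^2)))
  expect_true(all(dmin <= 10 + 1e-9))

  # two close vessels: rings disjoint from both footprints, split by distance
  m2 <- disc_mask(120, 40, 60, 12) | disc_mask(120, 40 + 2 * 12 + 4, 60, 12)
  vs2 <- label_vessels(as_mask_for_test(m2), 2)
  r2 <- perivascular_rings(vs2, 10)
  expect_true(all(r2[m2] == 0))
  expect_identical(sort(unique(as.integer(r2))), c(0L, 1L, 2L))

  # vessel at the border: ring clipped to image bounds, no error
  m3 <- disc_mask(60, 3, 30, 8)
  vs3 <- label_vessels(as_mask_for_test(m3), 2)
  r3 <- perivascular_rings(vs3, 10)
  expect_gt(sum(r3 > 0), 0)
})

test_that("perivascular intensity takes ring medians and ignores the rest", {
  m <- disc_mask(80, 40, 40, 12)
  vs <- label_vessels(as_mask_for_test(m), 4)
  rings <- perivascular_rings(vs, 10)
  sma <- matrix(0.7, 80, 80)
  pv <- perivascular_intensity(rings, sma)
  expect_equal(pv$per_vessel$pv_od_median, 0.7)
  expect_equal(pv$pvi, 0.7)
  # zero a-SMA -> PVI 0
  expect_equal(perivascular_intensity(rings, matrix(0, 80, 80))$pvi, 0)
  # staining outside the ring must not leak in
  sma2 <- matrix(0.1, 80, 80); sma2[rings > 0] <- 0.5; sma2[1:5, 1:5] <- 3
  expect_equal(perivascular_intensity(rings, sma2)$pvi, 0.5)
})

test_that("FCV follows the strict-cutoff rule and the median self-property", {
  expect_equal(fraction_covered(c(0.6, 0.7, 0.9), 0.5), 1)
  expect_equal(fraction_covered(c(0.1, 0.2, 0.8, 0.9), 0.5), 0.5)
  expect_warning(res <- fraction_covered(numeric(0), 0.5), "undefined")
  expect_true(is.na(res))
  # cutoff = median of own inputs -> FCV 0.5 within 1/n for distinct values
  set.seed(42)
  v <- runif(101)
  expect_lt(abs(fraction_covered(v, median(v)) - 0.5), 1 / length(v))
})

test_that("stromal metrics equal direct arithmetic", {
  # OD 0.6 on half a 1000 x 1000 image at 4 px/um, threshold 0.3
  sma <- matrix(0, 1000, 1000); sma[, 1:500] <- 0.6
  s <- stromal_metrics(sma, stroma_threshold_od = 0.3, resolution_px_per_um = 4)
  expect_equal(s$stromal_area_mm2, 0.03125)
  expect_equal(s$stromal_sma_od_median, 0.6)
  # all-zero a-SMA: area 0, intensity undefined
  expect_warning(s0 <- stromal_metrics(matrix(0, 10, 10),
                                       stroma_threshold_od = 0.15,
                                       resolution_px_per_um = 4), "undefined")
  expect_equal(s0$stromal_area_mm2, 0)
  expect_true(is.na(s0$stromal_sma_od_median))
  # median matches brute-force sort of the ground-truth values
  set.seed(43)
  field <- matrix(runif(400, 0, 1), 20, 20)
  s2 <- stromal_metrics(field, stroma_threshold_od = 0.15,
                        resolution_px_per_um = 4)
  vals <- sort(field[field >= 0.15])
  n <- length(vals)
  bf <- if (n %% 2) vals[(n + 1) / 2] else mean(vals[n / 2 + 0:1])
  expect_equal(s2$stromal_sma_od_median, bf)
})

test_that("covered and uncovered vessels separate by perivascular OD", {
  lay <- generate_vessel_layout(8, sma_covered_fraction = 0.5,
                                image_size_px = c(512, 512), seed = 44)
  ren <- render_ihc_image(lay, noise_sd_od = 0.02, seed = 45)
  m <- measure_image(ren$image)
  expect_identical(m$metrics$n_vessels, nrow(ren$truth))
  tr <- ren$truth; dt <- m$per_vessel
  match_idx <- vapply(seq_len(nrow(tr)), function(i)
    which.min((dt$centroid_x_px - tr$center_x[i])^2 +
                (dt$centroid_y_px - tr$center_y[i])^2), integer(1))
  pv <- dt$pv_od_median[match_idx]
  expect_gt(min(pv[tr$has_sma_ring]), max(pv[!tr$has_sma_ring]))
})
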