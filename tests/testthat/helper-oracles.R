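# Independent brute-force oracles, kept deliberately naive and separate from
# the implementations they check.

# Minimum caliper width of a point set by exhaustive projection sweep.
# Projection width has a kink (piecewise-linear minimum) at the optimal
# orientation, so a uniform angle grid alone stops short of the true minimum
# by O(width * step); the candidate set therefore also includes every hull
# edge's normal direction, computed here directly from the point set.
feret_sweep <- function(pts, n_angles = 3600) {
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  e <- diff(rbind(hull, hull[1, , drop = FALSE]))
  th <- c(th, atan2(e[, 2], e[, 1]) + pi / 2)
  widths <- vapply(th, function(a) {
    p <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  min(widths)
}

# uniform-grid-only sweep: upper bound on the true caliper width
feret_sweep_grid <- function(pts, n_angles = 3600) {
  th <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  min(vapply(th, function(a) {
    p <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(p) - min(p)
  }, numeric(1)))
}

# pixel footprint -> corner cloud for the sweep oracle
pixel_corners <- function(coords) {
  rbind(cbind(coords[, 1] - 0.5, coords[, 2] - 0.5),
        cbind(coords[, 1] + 0.5, coords[, 2] - 0.5),
        cbind(coords[, 1] - 0.5, coords[, 2] + 0.5),
        cbind(coords[, 1] + 0.5, coords[, 2] + 0.5))
}

# Exhaustive Otsu: best integer threshold t (mask = layer >= t) by
# between-class variance over all 256 candidate levels.
otsu_sweep <- function(layer) {
  v <- as.numeric(layer)
  best_t <- NA; best_var <- -1
  for (t in 1:255) {
    fg <- v >= t
    n1 <- sum(fg); n0 <- length(v) - n1
    if (n1 == 0 || n0 == 0) next
    bc <- n0 * n1 * (mean(v[fg]) - mean(v[!fg]))^2
    if (bc > best_var) { best_var <- bc; best_t <- t }
  }
  best_t
}

# Structuring-element offsets: the disc footprint is shared configuration;
# the naive per-pixel loops below are the independent computation.
kernel_offsets <- function(kernel) {
  r <- (nrow(kernel) - 1) / 2
  idx <- which(kernel != 0, arr.ind = TRUE)
  cbind(dy = idx[, 1] - r - 1, dx = idx[, 2] - r - 1)
}

# Direct neighbourhood-majority filter with replicated borders.
majority_ref <- function(m, kernel) {
  offs <- kernel_offsets(kernel)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    yy <- pmin(pmax(i + offs[, "dy"], 1), h)
    xx <- pmin(pmax(j + offs[, "dx"], 1), w)
    out[i, j] <- sum(m[cbind(yy, xx)]) > nrow(offs) / 2
  }
  out
}

# Naive binary morphology for the repair-sequence reference; hole fill by
# flood fill from the border.
dilate_ref <- function(m, kernel) {
  offs <- kernel_offsets(kernel)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    yy <- i + offs[, "dy"]; xx <- j + offs[, "dx"]
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    out[i, j] <- any(m[cbind(yy[ok], xx[ok])] != 0)
  }
  out
}
erode_ref <- function(m, kernel) !dilate_ref(!(m != 0), kernel)
fill_holes_ref <- function(m) {
  h <- nrow(m); w <- ncol(m)
  outside <- matrix(FALSE, h, w)
  queue <- which(!m & (row(m) %in% c(1, h) | col(m) %in% c(1, w)))
  outside[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    i <- (idx - 1) %% h + 1; j <- (idx - 1) %/% h + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        k <- (jj - 1) * h + ii
        if (!m[k] && !outside[k]) { outside[k] <- TRUE; queue <- c(queue, k) }
      }
    }
  }
  m | !outside
}

# One-dimensional brute-force maximizer of the written-out Breslow partial
# log-likelihood for a single binary covariate.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}
cox_brute <- function(time, event, x) {
  stats::optimize(function(b) breslow_loglik(b, time, event, x),
                  c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# Spearman p by exhaustive permutation of one margin (n = 8 feasible).
spearman_perm <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- all_perms(n)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(1:n, function(i)
    cbind(i, matrix(ifelse(sub >= i, sub + 1, sub), nrow(sub)))))
}

# small helpers for fixtures
disc_mask <- function(size, cx, cy, r) {
  m <- matrix(FALSE, size, size)
  for (i in 1:size) for (j in 1:size)
    if ((j - cx)^2 + (i - cy)^2 <= r^2) m[i, j] <- TRUE
  m
}
annulus_mask <- function(size, cx, cy, r_in, r_out, gap_ang = NULL) {
  m <- matrix(FALSE, size, size)
  for (i in 1:size) for (j in 1:size) {
    rr <- sqrt((j - cx)^2 + (i - cy)^2)
    if (rr >= r_in && rr <= r_out) {
      if (!is.null(gap_ang)) {
        a <- atan2(i - cy, j - cx)
        if (abs(a) < gap_ang) next
      }
      m[i, j] <- TRUE
    }
  }
  m
}

# wrap a logical matrix as a vessel_mask fixture
as_mask_for_test <- function(m) vesselquant:::as_mask(m, "fixture")

# fabricate a measure_image()-shaped core result from bare numbers
fake_core <- function(diams, pv_od = rep(0.5, length(diams)),
                      area_mm2 = 0.01, fcv = NA_real_,
                      stromal_area = 0.002, stromal_od = 0.3) {
  n <- length(diams)
  list(metrics = data.frame(
    n_vessels = n, density = n / area_mm2,
    median_diameter_um = if (n) median(diams) else NA_real_,
    pvi = if (n) median(pv_od) else NA_real_, fcv = fcv,
    stromal_area_mm2 = stromal_area, stromal_od = stromal_od,
    tissue_area_mm2 = area_mm2),
    per_vessel = data.frame(label = seq_len(n),
                            centroid_x_px = seq_len(n),
                            centroid_y_px = seq_len(n),
                            area_um2 = rep(50, n),
                            min_feret_um = diams, pv_od_median = pv_od))
}

# drop mask attributes (provenance etc.) for exact value comparisons
strip_mask <- function(m) array(as.logical(m), dim(m))
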