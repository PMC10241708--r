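#' Convert an 8-bit RGB image to optical density
#'
#' Transmitted-light pixel intensity I relates to chromogen amount through the
#' Beer-Lambert law; optical density OD = log10(I0 / I) with I0 = 255 is
#' linear in the amount of absorbing stain. Intensity 255 means complete
#' absence of staining (OD 0); intensity 0 means complete absorption and is
#' clamped at `i_floor` so the OD stays finite and order-preserving.
#'
#' @param image integer array, height x width x 3 (or a single channel
#'   matrix), values 0-255.
#' @param i_floor minimum intensity used in the ratio; default 1, giving a
#'   maximum representable OD of log10(255) ~ 2.407.
#' @return numeric array of the same shape holding per-channel OD, with the
#'   `resolution_px_per_um` attribute of the input carried over if present.
#' @export
rgb_to_od <- function(image, i_floor = 1) {
  if (length(image) == 0L) stop("empty image")
  v <- as.numeric(image)
  if (any(is.na(v)) || any(v < 0) || any(v > 255) || any(v != floor(v)))
    stop("image must contain 8-bit integer intensities in 0..255")
  od <- log10(255 / pmax(v, i_floor))
  od <- array(od, dim = dim(image) %||% length(image))
  attr(od, "resolution_px_per_um") <- attr(image, "resolution_px_per_um")
  od
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unmix an OD image into per-stain amount maps
#'
#' Solves, pixel-wise, the linear model OD(p) = V a(p) where V holds the unit
#' stain colour vectors, by ordinary least squares; negative amounts (noise
#' overshoot) are clipped to zero. With `method = "nnls"` the non-negative
#' least-squares solution is computed instead (slower; requires pracma).
#'
#' @param od numeric array height x width x 3 of per-channel OD
#'   (from [rgb_to_od()]), or a 3-column matrix of pixel OD vectors.
#' @param stains a [stain_model()].
#' @param method `"ols"` (clip negatives, default) or `"nnls"`.
#' @return numeric array height x width x k (k = number of stains), dimnames
#'   on the stain axis; or a k-column matrix when `od` was a matrix.
#' @export
deconvolve <- function(od, stains, method = c("ols", "nnls")) {
  method <- match.arg(method)
  stopifnot(inherits(stains, "stain_model"))
  V <- stains$vectors
  if (qr(V)$rank < ncol(V)) stop("rank-deficient stain matrix")
  as_matrix <- is.matrix(od) && ncol(od) == 3L && length(dim(od)) == 2L
  if (as_matrix) {
    P <- od
    dims <- NULL
  } else {
    d <- dim(od)
    if (length(d) != 3L || d[3] != 3L)
      stop("od must be an h x w x 3 array or a 3-column matrix")
    P <- matrix(od, ncol = 3L)
    dims <- d[1:2]
  }
  if (method == "ols") {
    A <- P %*% V %*% solve(crossprod(V))   # (V'V)^-1 V' od, transposed form
    A[A < 0] <- 0
  } else {
    if (!requireNamespace("pracma", quietly = TRUE))
      stop("method 'nnls' requires the pracma package")
    A <- t(apply(P, 1L, function(p) pracma::lsqnonneg(V, p)$x))
  }
  colnames(A) <- stains$names
  if (is.null(dims)) return(A)
  out <- array(A, dim = c(dims, ncol(V)),
               dimnames = list(NULL, NULL, stains$names))
  attr(out, "resolution_px_per_um") <- attr(od, "resolution_px_per_um")
  out
}

#' Quantize a stain OD map to a 256-grade 8-bit layer
#'
#' Maps OD linearly from `[0, od_max]` onto integers 0-255 (half-up rounding),
#' saturating at 255 above `od_max`. This is the single-stain layer that the
#' segmentation stage thresholds.
#'
#' @param stain_od non-negative numeric matrix of one stain's OD amounts.
#' @param od_max OD mapped to 255; default 2, covering realistic chromogen
#'   densities.
#' @return integer matrix of the same shape, values 0-255.
#' @export
quantize_256 <- function(stain_od, od_max = 2) {
  if (od_max <= 0) stop("od_max must be positive")
  if (any(stain_od < 0)) stop("stain OD must be non-negative")
  q <- floor(stain_od / od_max * 255 + 0.5)
  q[q > 255] <- 255L
  out <- array(as.integer(q), dim = dim(stain_od) %||% length(stain_od))
  attr(out, "resolution_px_per_um") <- attr(stain_od, "resolution_px_per_um")
  out
}
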