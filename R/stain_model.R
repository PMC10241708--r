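#' Stain colour model for brightfield deconvolution
#'
#' A stain model holds one unit optical-density colour vector per chromogen.
#' Each vector gives the relative absorbance of the chromogen in the R, G and
#' B channels; vectors are normalised to Euclidean length 1 and the matrix of
#' vectors must have full column rank, otherwise unmixing is ill-posed.
#'
#' @param vectors numeric matrix with 3 rows (R, G, B absorbance) and one
#'   column per stain, or a list of length-3 numeric vectors. Components must
#'   be non-negative; columns are re-normalised to unit length.
#' @param names character vector of stain names, one per column.
#' @return An object of class `stain_model`: list with elements `names` and
#'   `vectors` (3 x k matrix, unit-norm columns).
#' @examples
#' sm <- stain_model(cbind(c(0.21, 0.85, 0.48), c(0.75, 0.61, 0.27)),
#'                   names = c("CD34", "aSMA"))
#' @export
stain_model <- function(vectors, names = NULL) {
  if (is.list(vectors)) vectors <- do.call(cbind, vectors)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L)
    stop("stain vectors must have 3 components (R, G, B)")
  if (any(vectors < 0))
    stop("stain vector components must be non-negative")
  nrm <- sqrt(colSums(vectors^2))
  if (any(nrm == 0)) stop("zero-length stain vector")
  vectors <- sweep(vectors, 2L, nrm, "/")
  if (qr(vectors)$rank < ncol(vectors))
    stop("stain vectors are collinear: stain matrix is rank-deficient")
  if (is.null(names)) names <- paste0("stain", seq_len(ncol(vectors)))
  if (length(names) != ncol(vectors))
    stop("one name per stain vector required")
  colnames(vectors) <- names
  structure(list(names = names, vectors = vectors), class = "stain_model")
}

#' Default CD34 / a-SMA stain model
#'
#' Brightfield presets for a red endothelial chromogen (liquid permanent red,
#' marking CD34) and a blue perivascular chromogen (marking a-SMA), taken from
#' published colour-deconvolution presets for fast red / fast blue and
#' unit-normalised. The vectors are configuration, not measurements: override
#' them when stain batches differ.
#'
#' @return A `stain_model` with stains `CD34` and `aSMA`.
#' @export
default_stain_model <- function() {
  stain_model(cbind(c(0.21393921, 0.85112669, 0.47794022),
                    c(0.74890292, 0.60624161, 0.26731082)),
              names = c("CD34", "aSMA"))
}

#' @export
print.stain_model <- function(x, ...) {
  cat("stain_model with", length(x$names), "stains:",
      paste(x$names, collapse = ", "), "\n")
  print(round(x$vectors, 4))
  invisible(x)
}
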