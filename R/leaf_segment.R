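#' Fit the plant/background pixel classifier
#'
#' Trains a two-class support vector machine on labeled plant and
#' background pixel spectra. The strong contrast between substrate and
#' plant material makes this a nearly separable problem, so a linear
#' kernel with feature scaling is used.
#'
#' @param plantPixels,backgroundPixels spectra tables (or plain matrices)
#'   of labeled pixels, one row per pixel.
#' @param seed integer seed (training is deterministic given the data;
#'   the seed fixes any internal randomization).
#' @return an object of class "backgroundModel" usable with
#'   [segmentPlant()].
#' @export
fitBackgroundModel <- function(plantPixels, backgroundPixels, seed = 1L) {
  toMat <- function(x) if (is.data.frame(x)) spectraMatrix(x) else as.matrix(x)
  P <- toMat(plantPixels); B <- toMat(backgroundPixels)
  if (nrow(P) < 2L || nrow(B) < 2L)
    stop("need at least two example pixels in each class")
  if (ncol(P) != ncol(B)) stop("plant and background spectra differ in bands")
  X <- rbind(P, B)
  y <- factor(rep(c("plant", "background"), c(nrow(P), nrow(B))),
              levels = c("background", "plant"))
  fit <- withSeed(seed, e1071::svm(X, y, kernel = "linear", scale = TRUE))
  structure(list(fit = fit, nBands = ncol(X)), class = "backgroundModel")
}

#' Segment plant pixels in a cube
#'
#' Applies a fitted background model pixel-wise; 1 marks plant.
#'
#' @param cube a [Hypercube-class].
#' @param model a "backgroundModel" from [fitBackgroundModel()].
#' @return logical H x W mask (TRUE = plant) with a
#'   \code{"provenance"} attribute of "background-model".
#' @export
segmentPlant <- function(cube, model) {
  stopifnot(inherits(model, "backgroundModel"))
  X <- pixelMatrix(cube)
  if (ncol(X) != model$nBands)
    stop("cube has ", ncol(X), " bands but the model was trained on ",
         model$nBands)
  pred <- stats::predict(model$fit, X)
  d <- dim(cubeValues(cube))
  mask <- matrix(pred == "plant", d[1], d[2])
  attr(mask, "provenance") <- "background-model"
  mask
}

#' Binary mask erosion (5 x 5 structuring element)
#'
#' Morphological erosion with an all-ones square structuring element under
#' zero padding: pixels outside the image count as background, so the
#' mask shrinks at image borders. This removes pixels with mixed
#' plant/background spectral character at mask edges. The output is
#' always a subset of the input.
#'
#' @param mask logical (or 0/1) H x W matrix.
#' @param size odd side length of the structuring element (default 5).
#' @return eroded logical mask.
#' @export
erodeMask <- function(mask, size = 5L) {
  m <- asLogicalMask(mask)
  if (size %% 2L == 0L) stop("structuring element size must be odd")
  r <- (size - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  padded <- matrix(FALSE, h + 2L * r, w + 2L * r)
  padded[(r + 1L):(r + h), (r + 1L):(r + w)] <- m
  out <- matrix(TRUE, h, w)
  for (dy in -r:r) for (dx in -r:r)
    out <- out & padded[(r + 1L + dy):(r + h + dy),
                        (r + 1L + dx):(r + w + dx)]
  attr(out, "provenance") <- attr(m, "provenance")
  out
}

#' Extract per-pixel spectra under a mask
#'
#' @param cube a [Hypercube-class].
#' @param mask logical H x W mask; must contain at least one pixel.
#' @return data.frame with pixel coordinates \code{y}, \code{x} and one
#'   \code{R_<wavelength>} column per band, one row per masked pixel.
#' @export
extractRoiSpectra <- function(cube, mask) {
  m <- asLogicalMask(mask)
  d <- dim(cubeValues(cube))
  if (!identical(dim(m), d[1:2])) stop("mask shape does not match cube")
  idx <- which(m)
  if (!length(idx)) stop("mask is empty")
  X <- pixelMatrix(cube)[idx, , drop = FALSE]
  colnames(X) <- bandColumnNames(wavelengths(cube))
  coords <- arrayInd(idx, d[1:2])
  cbind(data.frame(y = coords[, 1L], x = coords[, 2L]), as.data.frame(X))
}

#' Band-wise mean spectrum of a spectra table
#'
#' @param table a spectra table with \code{R_<wavelength>} columns.
#' @return numeric mean spectrum named by band column.
#' @export
meanSpectrum <- function(table) {
  colMeans(spectraMatrix(table))
}

#' Rasterize a polygon ROI to a mask
#'
#' Vertex lists use \code{y,x} pixel coordinates (1-based, row-major), as
#' read from a two-column CSV. A pixel belongs to the ROI when its center
#' lies inside the polygon (even-odd rule).
#'
#' @param vertices two-column matrix/data.frame of y,x vertices.
#' @param height,width mask dimensions.
#' @return logical mask.
#' @export
polygonMask <- function(vertices, height, width) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L) stop("need >= 3 vertices of (y, x)")
  py <- v[, 1L]; px <- v[, 2L]
  mask <- matrix(FALSE, height, width)
  for (yy in seq_len(height)) for (xx in seq_len(width)) {
    inside <- FALSE
    j <- nrow(v)
    for (i in seq_len(nrow(v))) {
      if ((py[i] > yy) != (py[j] > yy) &&
          xx < (px[j] - px[i]) * (yy - py[i]) / (py[j] - py[i]) + px[i])
        inside <- !inside
      j <- i
    }
    mask[yy, xx] <- inside
  }
  mask
}
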