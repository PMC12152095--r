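#' Reflectance calibration from white and dark references
#'
#' Converts a raw cube to reflectance as
#' \deqn{R = (raw - dark) / (white - dark)} element-wise. The white and
#' dark references may be full cubes or single-line frames (1 x W x L),
#' which are broadcast along the scan axis as in push-broom acquisition.
#' Negative reflectance values are preserved (they are only clipped later
#' when band probabilities are formed for SID).
#'
#' @param raw,white,dark [Hypercube-class] objects on the same grid.
#' @return a reflectance [Hypercube-class]; elements where
#'   white = dark are set to 0 and flagged via the
#'   \code{"flaggedFill"} attribute on the returned cube's values.
#' @export
calibrateReflectance <- function(raw, white, dark) {
  rv <- cubeValues(raw)
  d <- dim(rv)
  expand <- function(ref, what) {
    x <- cubeValues(ref)
    dx <- dim(x)
    if (identical(dx, d)) return(x)
    if (dx[1] == 1L && dx[2] == d[2] && dx[3] == d[3]) {
      frame <- array(x, dim = dx[2:3])          # W x L single-line frame
      return(array(rep(frame, each = d[1]), dim = d))
    }
    stop(what, " reference shape ", paste(dx, collapse = "x"),
         " incompatible with raw cube ", paste(d, collapse = "x"))
  }
  wv <- expand(white, "white")
  dv <- expand(dark, "dark")
  denom <- wv - dv
  # a band whose white and dark frames coincide everywhere is unusable
  bandBad <- apply(denom == 0, 3L, all)
  if (any(bandBad))
    stop("white and dark references coincide over entire band(s): ",
         paste(which(bandBad), collapse = ", "))
  zero <- denom == 0
  denom[zero] <- 1
  R <- (rv - dv) / denom
  R[zero] <- 0
  if (any(zero)) attr(R, "flaggedFill") <- which(zero)
  out <- Hypercube(R, wavelengths(raw))
  out
}

#' Standard normal variate (SNV) transform
#'
#' Standardizes a spectrum across its bands to mean 0 and sample standard
#' deviation 1 (n-1 denominator), removing per-spectrum multiplicative
#' scatter and baseline offsets.
#'
#' @param x numeric spectrum (length >= 2, non-constant).
#' @return the standardized spectrum.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (length(x) < 2L) stop("SNV needs at least two bands")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("SNV undefined for a constant spectrum")
  (x - mean(x)) / s
}

# row-wise SNV for a samples x bands matrix
snvRows <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1L))
  if (any(s == 0)) stop("SNV undefined for constant spectra (rows: ",
                        paste(which(s == 0), collapse = ", "), ")")
  (X - mu) / s
}

#' Absorbance-style log(1/R) transform
#'
#' Computes \eqn{\log_{10}(1 / \max(R, \mathrm{floor}))} per band; the
#' floor guards zeros and negative reflectance.
#'
#' @param x numeric reflectance spectrum.
#' @param floor positive lower clip applied before the logarithm.
#' @return transformed spectrum.
#' @examples
#' logInverseR(0.5)  # log10(2)
#' @export
logInverseR <- function(x, floor = 1e-4) {
  if (floor <= 0) stop("floor must be positive")
  log10(1 / pmax(x, floor))
}

#' Savitzky-Golay spectral derivative
#'
#' First or second derivative (with respect to band index on the uniform
#' grid) by Savitzky-Golay local polynomial filtering. Edge bands use the
#' polynomial fit within the edge window, so derivatives of polynomials
#' up to \code{polyorder} are reproduced exactly everywhere.
#'
#' @param x numeric spectrum.
#' @param order derivative order, 1 or 2.
#' @param window odd filter length, > polyorder and <= length(x).
#' @param polyorder local polynomial degree (>= order).
#' @return the derivative spectrum.
#' @export
sgDerivative <- function(x, order = 1L, window = 7L, polyorder = 2L) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (polyorder < order) stop("polyorder must be >= derivative order")
  if (window > length(x)) stop("window exceeds spectrum length")
  signal::sgolayfilt(x, p = polyorder, n = window, m = order)
}

#' Resolve a wavelength window to band indices
#'
#' Maps a [lo, hi] nanometre window onto the nearest band indices of a
#' grid, inclusive on both ends. Exact half-way ties round toward the
#' interior of the window.
#'
#' @param wavelengths ascending band centers (nm).
#' @param loNm,hiNm window bounds, loNm < hiNm, overlapping the grid.
#' @return list of class "BandWindow" with loNm, hiNm, loIdx, hiIdx
#'   (1-based, inclusive) and nBands.
#' @examples
#' w <- resolveWindow(defaultGrid(), 710, 825)
#' w$nBands  # 42
#' @export
resolveWindow <- function(wavelengths, loNm, hiNm) {
  if (loNm >= hiNm) stop("window requires loNm < hiNm")
  if (loNm < min(wavelengths) || hiNm > max(wavelengths))
    stop(sprintf("window [%g, %g] outside grid range [%g, %g]",
                 loNm, hiNm, min(wavelengths), max(wavelengths)))
  nearest <- function(target, towardHigher) {
    d <- abs(wavelengths - target)
    cand <- which(d == min(d))
    if (towardHigher) max(cand) else min(cand)
  }
  loIdx <- nearest(loNm, towardHigher = TRUE)    # ties round inward
  hiIdx <- nearest(hiNm, towardHigher = FALSE)
  if (loIdx > hiIdx) stop("window resolves to an empty band set")
  structure(list(loNm = loNm, hiNm = hiNm, loIdx = loIdx, hiIdx = hiIdx,
                 nBands = hiIdx - loIdx + 1L),
            class = "BandWindow")
}

#' Read or write spectra tables as CSV
#'
#' Tables use one row per sample with leading id/label/count columns and
#' one \code{R_<wavelength>} column per band.
#'
#' @param table a spectra data.frame.
#' @param path file path.
#' @return \code{writeSpectraCSV}: invisibly the path;
#'   \code{readSpectraCSV}: the data.frame.
#' @export
writeSpectraCSV <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# apply a named pre-treatment chain to a samples x bands matrix
applyPretreatment <- function(X, treatment,
                              floor = 1e-4, window = 7L, polyorder = 2L) {
  switch(treatment,
    raw = X,
    snv = snvRows(X),
    log1r = t(apply(X, 1L, logInverseR, floor = floor)),
    d1 = t(apply(X, 1L, sgDerivative, order = 1L, window = window,
                 polyorder = polyorder)),
    d2 = t(apply(X, 1L, sgDerivative, order = 2L, window = window,
                 polyorder = polyorder)),
    stop("unknown pre-treatment: ", treatment)
  )
}
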