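#' Convert a spectrum segment to a band-probability vector
#'
#' Each spectral vector is interpreted as a discrete probability
#' distribution over its bands: entries below \code{floor} (including
#' negatives from reflectance calibration) are clipped to \code{floor},
#' then the vector is normalized to sum to one. A segment with no
#' strictly positive entry is rejected.
#'
#' @param x numeric spectrum segment.
#' @param floor positive clip value (default 1e-12).
#' @return probability vector summing to 1, all entries > 0.
#' @examples
#' toProbability(c(3, 1))  # 0.75 0.25
#' @export
toProbability <- function(x, floor = 1e-12) {
  if (floor <= 0) stop("floor must be positive")
  if (!any(x > 0))
    stop("spectrum segment has no positive entry; cannot form probabilities")
  p <- pmax(x, floor)
  p / sum(p)
}

#' Shannon entropy of a band-probability vector (nats)
#'
#' \deqn{H(p) = -\sum_l p_l \log p_l} with natural logarithm.
#'
#' @param p probability vector (as from [toProbability()]).
#' @return non-negative entropy in nats.
#' @examples
#' spectralEntropy(c(0.5, 0.5))  # log(2)
#' @export
spectralEntropy <- function(p) {
  -sum(p * log(p))
}

#' Relative entropy (Kullback-Leibler divergence) between band
#' distributions
#'
#' \deqn{D(p \| q) = \sum_l p_l \log(p_l / q_l)} in nats; non-negative,
#' zero iff p = q.
#'
#' @param p,q probability vectors of equal length, strictly positive.
#' @return non-negative divergence.
#' @export
relativeEntropy <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  sum(p * (log(p) - log(q)))
}

#' Spectral Information Divergence between two spectra
#'
#' The symmetric information-theoretic similarity measure
#' \deqn{\mathrm{SID}(x, y) = D(p \| q) + D(q \| p)}
#' where p and q are the band-probability vectors of x and y. SID is
#' symmetric, non-negative, zero iff the normalized spectra coincide, and
#' invariant to positive scaling of either spectrum.
#'
#' @param x,y numeric spectra of equal length.
#' @param floor clip value passed to [toProbability()].
#' @return non-negative SID in nats.
#' @examples
#' sid(c(1, 1), c(3, 1))  # 0.2746531
#' @export
sid <- function(x, y, floor = 1e-12) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  p <- toProbability(x, floor)
  q <- toProbability(y, floor)
  relativeEntropy(p, q) + relativeEntropy(q, p)
}

#' Per-pixel SID map against a reference within a band window
#'
#' Computes the SID of every plant pixel against the reference spectrum
#' using only the bands of the window (default 710--825 nm, the red-edge
#' region where sub-leaf aphid accumulation is most visible). Non-plant
#' pixels carry NA.
#'
#' @param cube a [Hypercube-class].
#' @param mask logical plant mask (non-empty).
#' @param reference full-grid reference spectrum (e.g. from
#'   [buildReference()]).
#' @param window a [resolveWindow()] result; default 710--825 nm on the
#'   cube grid.
#' @param floor probability clip value.
#' @return a [SIDMap-class].
#' @export
sidMap <- function(cube, mask, reference,
                   window = resolveWindow(wavelengths(cube), 710, 825),
                   floor = 1e-12) {
  m <- asLogicalMask(mask)
  idx <- which(m)
  if (!length(idx)) stop("mask is empty")
  if (length(reference) != length(wavelengths(cube)))
    stop("reference length does not match cube grid")
  bands <- window$loIdx:window$hiIdx
  X <- pixelMatrix(cube)[idx, bands, drop = FALSE]
  q <- toProbability(reference[bands], floor)

  P <- pmax(X, floor)
  P <- P / rowSums(P)
  logP <- log(P)
  dPQ <- rowSums(P * logP) - as.numeric(P %*% log(q))
  dQP <- sum(q * log(q)) - as.numeric(logP %*% q)
  scores <- pmax(dPQ + dQP, 0)

  d <- dim(cubeValues(cube))
  vals <- matrix(NA_real_, d[1], d[2])
  vals[idx] <- scores
  new("SIDMap", values = vals, window = unclass(window),
      reference = as.numeric(reference))
}

#' Threshold a SID map into an infestation mask
#'
#' Pixels whose divergence from the infested reference is at or below
#' the threshold (i.e. spectra similar to the reference) are marked
#' infested. The threshold is either Otsu's value computed on the finite
#' scores or a fixed user value; it is recorded on the returned mask.
#'
#' @param map a [SIDMap-class].
#' @param method "otsu" or "fixed".
#' @param t threshold when \code{method = "fixed"}.
#' @return logical mask (TRUE = infested) with attributes
#'   \code{"threshold"} and \code{"provenance"}.
#' @export
thresholdSid <- function(map, method = c("otsu", "fixed"), t = NULL) {
  method <- match.arg(method)
  v <- sidValues(map)
  finite <- v[is.finite(v)]
  if (!length(finite)) stop("SID map has no finite scores")
  if (method == "otsu") {
    rng <- range(finite)
    if (diff(rng) == 0)
      stop("SID map is constant; Otsu undefined -- use a fixed threshold")
    scaled <- (finite - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(matrix(scaled, nrow = 1L)),
                           range = c(0, 1))
    thr <- rng[1] + thr01 * diff(rng)
  } else {
    if (is.null(t)) stop("fixed method requires t")
    thr <- t
  }
  mask <- is.finite(v) & v <= thr
  attr(mask, "threshold") <- thr
  attr(mask, "provenance") <- "SID-threshold"
  mask
}

#' Export a SID map as PNG and JSON sidecar
#'
#' Writes the scores as an 8-bit grayscale PNG (min/max scaled; non-plant
#' pixels black) plus a JSON sidecar recording the scaling, window and
#' (optionally) threshold, so the quantitative map can be reconstructed.
#'
#' @param map a [SIDMap-class].
#' @param path output PNG path; the sidecar gets ".json" appended.
#' @param threshold optional threshold to record.
#' @return invisibly the PNG path.
#' @export
writeSIDMapPNG <- function(map, path, threshold = NULL) {
  v <- sidValues(map)
  finite <- is.finite(v)
  rng <- range(v[finite])
  img <- matrix(0, nrow(v), ncol(v))
  img[finite] <- if (diff(rng) > 0) (v[finite] - rng[1]) / diff(rng) else 0.5
  png::writePNG(img, path)
  sidecar <- list(min = rng[1], max = rng[2],
                  window = map@window[c("loNm", "hiNm", "loIdx", "hiIdx")],
                  threshold = threshold)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
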