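#' @import methods
NULL

#' Default VNIR wavelength grid
#'
#' Band centers of the visible/near-infrared grid used throughout the
#' package: 224 bands spanning 380--1000 nm on a uniform spacing of
#' 620/223 (about 2.78) nm, matching a push-broom VNIR line-scan camera.
#'
#' @param nBands number of bands.
#' @param loNm,hiNm wavelength range in nanometres.
#' @return numeric vector of strictly increasing band centers (nm).
#' @export
defaultGrid <- function(nBands = 224L, loNm = 380, hiNm = 1000) {
  if (nBands < 2L || hiNm <= loNm) stop("invalid grid specification")
  seq(loNm, hiNm, length.out = nBands)
}

#' Hypercube: a reflectance cube bound to a wavelength grid
#'
#' An H x W x L array of (dimensionless) reflectance values together with
#' the L band-center wavelengths in nanometres. Every stage of the
#' pipeline consumes and produces this container.
#'
#' @slot values numeric array, H x W x L.
#' @slot wavelengths strictly increasing numeric vector of length L (nm).
#' @export
setClass("Hypercube",
  representation(values = "array", wavelengths = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3-d array (H x W x L)")
    if (length(object@wavelengths) != d[3L])
      return("length(wavelengths) must equal the number of bands")
    if (any(!is.finite(object@values))) return("values must be finite")
    if (is.unsorted(object@wavelengths, strictly = TRUE))
      return("wavelengths must be strictly increasing")
    TRUE
  }
)

#' Construct a Hypercube
#'
#' @param values H x W x L numeric array of reflectance.
#' @param wavelengths length-L numeric vector of band centers (nm);
#'   defaults to [defaultGrid()] when L = 224.
#' @return a [Hypercube-class] object.
#' @export
Hypercube <- function(values, wavelengths = NULL) {
  if (is.null(wavelengths)) {
    if (dim(values)[3L] != 224L)
      stop("wavelengths must be supplied unless the cube has 224 bands")
    wavelengths <- defaultGrid()
  }
  new("Hypercube", values = values, wavelengths = as.numeric(wavelengths))
}

#' @describeIn Hypercube array of reflectance values
#' @param object,x a Hypercube
#' @export
setGeneric("cubeValues", function(object) standardGeneric("cubeValues"))

#' @rdname Hypercube-class
#' @export
setMethod("cubeValues", "Hypercube", function(object) object@values)

#' Wavelength accessor
#' @param object an object carrying a wavelength grid
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname Hypercube-class
#' @export
setMethod("wavelengths", "Hypercube", function(object) object@wavelengths)

#' @rdname Hypercube-class
#' @export
setMethod("dim", "Hypercube", function(x) dim(x@values))

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@values)
  cat(sprintf("Hypercube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
  cat(sprintf("  reflectance range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

#' SceneTruth: pixel-level ground truth for a synthetic scene
#'
#' Carries the leaf and infested-patch masks, the per-leaf aphid count,
#' the true endmember spectra and the true per-pixel abundances used to
#' build the scene. Stands in for clip-caged ground truth.
#'
#' @slot leafMask,infestedMask H x W logical matrices; the infested mask
#'   is always contained in the leaf mask.
#' @slot aphidCount integer count of aphids planted under the leaf.
#' @slot endmembers K x L matrix of the true pure spectra.
#' @slot abundance H x W x K array of true fractional abundances;
#'   non-negative and summing to one per pixel.
#' @export
setClass("SceneTruth",
  representation(leafMask = "matrix", infestedMask = "matrix",
                 aphidCount = "integer", endmembers = "matrix",
                 abundance = "array"),
  validity = function(object) {
    if (!is.logical(object@leafMask) || !is.logical(object@infestedMask))
      return("masks must be logical matrices")
    if (any(object@infestedMask & !object@leafMask))
      return("infested mask must be contained in the leaf mask")
    if (object@aphidCount < 0L) return("aphidCount must be >= 0")
    if (any(object@abundance < -1e-12)) return("abundances must be non-negative")
    TRUE
  }
)

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d leaf px, %d infested px, %d aphids, %d endmembers\n",
              sum(object@leafMask), sum(object@infestedMask),
              object@aphidCount, nrow(object@endmembers)))
})

#' @describeIn SceneTruth leaf mask accessor
#' @param object a SceneTruth
#' @export
setGeneric("leafMask", function(object) standardGeneric("leafMask"))
#' @rdname SceneTruth-class
#' @export
setMethod("leafMask", "SceneTruth", function(object) object@leafMask)

#' @describeIn SceneTruth infested-patch mask accessor
#' @export
setGeneric("infestedMask", function(object) standardGeneric("infestedMask"))
#' @rdname SceneTruth-class
#' @export
setMethod("infestedMask", "SceneTruth", function(object) object@infestedMask)

#' @describeIn SceneTruth aphid count accessor
#' @export
setGeneric("aphidCount", function(object) standardGeneric("aphidCount"))
#' @rdname SceneTruth-class
#' @export
setMethod("aphidCount", "SceneTruth", function(object) object@aphidCount)

#' @describeIn SceneTruth true abundance array accessor
#' @export
setGeneric("trueAbundance", function(object) standardGeneric("trueAbundance"))
#' @rdname SceneTruth-class
#' @export
setMethod("trueAbundance", "SceneTruth", function(object) object@abundance)

#' @describeIn SceneTruth true endmember matrix accessor
#' @export
setGeneric("trueEndmembers", function(object) standardGeneric("trueEndmembers"))
#' @rdname SceneTruth-class
#' @export
setMethod("trueEndmembers", "SceneTruth", function(object) object@endmembers)

#' EndmemberSet: pure-pixel spectra extracted from a cube
#'
#' Rows are spectra of pixels actually present in the source cube
#' (pure-pixel assumption of N-FINDR).
#'
#' @slot spectra K x L matrix, one endmember per row.
#' @slot wavelengths length-L band centers (nm).
#' @slot source provenance tag, e.g. "healthy-image" or "infested-image".
#' @slot pixelIdx integer indices of the chosen pixels among the masked
#'   pixels they were drawn from.
#' @export
setClass("EndmemberSet",
  representation(spectra = "matrix", wavelengths = "numeric",
                 source = "character", pixelIdx = "integer"),
  validity = function(object) {
    if (nrow(object@spectra) < 1L) return("need at least one endmember")
    if (ncol(object@spectra) != length(object@wavelengths))
      return("spectra columns must match wavelength grid")
    TRUE
  }
)

#' Construct an EndmemberSet
#' @param spectra K x L matrix of endmember spectra.
#' @param wavelengths band centers (nm).
#' @param source provenance tag ("healthy-image" or "infested-image").
#' @param pixelIdx optional pixel indices of the endmembers.
#' @export
EndmemberSet <- function(spectra, wavelengths, source = "infested-image",
                         pixelIdx = integer(0)) {
  new("EndmemberSet", spectra = as.matrix(spectra),
      wavelengths = as.numeric(wavelengths), source = source,
      pixelIdx = as.integer(pixelIdx))
}

#' @describeIn EndmemberSet matrix of endmember spectra (rows)
#' @param object an EndmemberSet
#' @export
setGeneric("endmemberSpectra", function(object) standardGeneric("endmemberSpectra"))
#' @rdname EndmemberSet-class
#' @export
setMethod("endmemberSpectra", "EndmemberSet", function(object) object@spectra)

#' @rdname EndmemberSet-class
#' @export
setMethod("wavelengths", "EndmemberSet", function(object) object@wavelengths)

setMethod("show", "EndmemberSet", function(object) {
  cat(sprintf("EndmemberSet: %d endmembers x %d bands (source: %s)\n",
              nrow(object@spectra), ncol(object@spectra), object@source))
})

#' AbundanceMaps: per-pixel fractional endmember weights
#'
#' Result of fully constrained linear unmixing: non-negative fractions
#' summing to one per pixel, plus the per-pixel residual norm of the fit.
#'
#' @slot values H x W x K array of fractions.
#' @slot residual H x W matrix of least-squares residual norms.
#' @export
setClass("AbundanceMaps",
  representation(values = "array", residual = "matrix"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L) return("values must be H x W x K")
    if (any(object@values < -1e-9)) return("abundances must be non-negative")
    TRUE
  }
)

#' @describeIn AbundanceMaps abundance array accessor
#' @param object an AbundanceMaps
#' @export
setGeneric("abundanceValues", function(object) standardGeneric("abundanceValues"))
#' @rdname AbundanceMaps-class
#' @export
setMethod("abundanceValues", "AbundanceMaps", function(object) object@values)

#' @describeIn AbundanceMaps residual-norm matrix accessor
#' @export
setGeneric("unmixResidual", function(object) standardGeneric("unmixResidual"))
#' @rdname AbundanceMaps-class
#' @export
setMethod("unmixResidual", "AbundanceMaps", function(object) object@residual)

setMethod("show", "AbundanceMaps", function(object) {
  d <- dim(object@values)
  cat(sprintf("AbundanceMaps: %d x %d pixels, %d endmembers, max residual %.3g\n",
              d[1], d[2], d[3], max(object@residual)))
})

#' SIDMap: per-pixel spectral information divergence scores
#'
#' Divergence of each plant pixel against a reference spectrum within a
#' band window; non-plant pixels carry NA.
#'
#' @slot values H x W matrix of non-negative SID scores (nats); NA off
#'   the plant mask.
#' @slot window the [BandWindow] the scores were computed in.
#' @slot reference the reference spectrum (full grid).
#' @export
setClass("SIDMap",
  representation(values = "matrix", window = "list", reference = "numeric"),
  validity = function(object) {
    v <- object@values[is.finite(object@values)]
    if (length(v) && min(v) < -1e-12) return("SID scores must be non-negative")
    TRUE
  }
)

#' @describeIn SIDMap score matrix accessor
#' @param object a SIDMap
#' @export
setGeneric("sidValues", function(object) standardGeneric("sidValues"))
#' @rdname SIDMap-class
#' @export
setMethod("sidValues", "SIDMap", function(object) object@values)

setMethod("show", "SIDMap", function(object) {
  v <- object@values[is.finite(object@values)]
  cat(sprintf("SIDMap: %d x %d, %d plant px, window %.0f-%.0f nm, scores [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values), length(v),
              object@window$loNm, object@window$hiNm,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})
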