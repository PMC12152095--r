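#' Scene configuration for the synthetic VNIR leaf generator
#'
#' Bundles every knob of the synthetic scene: image size, the parametric
#' spectral archetypes (background substrate, healthy leaf, aphid-covered
#' leaf), the depth of the near-infrared depression caused by aphid
#' bodies under the leaf, the noise model, and the mapping from aphid
#' count to mixing fraction.
#'
#' The archetypes are smooth parametric curves (a logistic red edge plus
#' Gaussian pigment features), not measured spectra: the generator
#' emulates the qualitative contrasts of real VNIR leaf imagery -- a
#' dark, nearly flat background, a healthy leaf with a strong 725--1000 nm
#' reflectance plateau, and infested tissue whose NIR reflectance is
#' depressed most strongly across the red edge (710--825 nm).
#'
#' @param height,width image size in pixels.
#' @param wavelengths band-center grid (nm); default 224 bands, 380--1000 nm.
#' @param nirDepth depth of the aphid-induced NIR depression, in [0, 1];
#'   1 removes the healthy NIR plateau entirely.
#' @param gainSd standard deviation of the per-pixel lognormal
#'   multiplicative gain (the scatter that SNV is designed to remove).
#' @param additiveSd standard deviation of the per-element additive
#'   Gaussian noise (reflectance units).
#' @param aphidCount number of aphids planted under the leaf.
#' @param countSlope linear count-to-abundance slope; the aphid mixing
#'   fraction is min(1, countSlope * count).
#' @param countRange inclusive integer range counts are drawn from when a
#'   labeled dataset is generated. The default spans the Low (<20),
#'   Medium (20--50) and High (>50) severity bands and starts at the
#'   five-adult founding colony placed under each infested leaf, so
#'   counts below the inoculum size never occur.
#' @param patchFraction fraction of leaf pixels covered by the infested
#'   patch (approximate; the patch is an ellipse inside the leaf).
#' @return a list of class "SceneConfig".
#' @export
sceneConfig <- function(height = 64L, width = 64L,
                        wavelengths = defaultGrid(),
                        nirDepth = 0.6,
                        gainSd = 0.05, additiveSd = 0.005,
                        aphidCount = 40L,
                        countSlope = 0.01,
                        countRange = c(5L, 100L),
                        patchFraction = 0.25) {
  if (height < 8L || width < 8L) stop("image size must be at least 8 x 8")
  if (nirDepth < 0 || nirDepth > 1) stop("nirDepth must lie in [0, 1]")
  if (gainSd < 0 || additiveSd < 0) stop("noise sds must be >= 0")
  if (countSlope <= 0) stop("countSlope must be positive")
  cfg <- list(height = as.integer(height), width = as.integer(width),
              wavelengths = wavelengths, nirDepth = nirDepth,
              gainSd = gainSd, additiveSd = additiveSd,
              aphidCount = as.integer(aphidCount),
              countSlope = countSlope,
              countRange = as.integer(countRange),
              patchFraction = patchFraction)
  class(cfg) <- "SceneConfig"
  cfg
}

# parametric spectral archetypes ------------------------------------------

logisticEdge <- function(wl, center, scale) 1 / (1 + exp(-(wl - center) / scale))

backgroundArchetype <- function(wl) 0.05 + 5e-5 * (wl - 380)

healthyArchetype <- function(wl) {
  0.06 +
    0.04 * exp(-((wl - 550) / 35)^2) -       # green reflectance bump
    0.015 * exp(-((wl - 670) / 20)^2) +      # chlorophyll absorption dip
    0.52 * logisticEdge(wl, 715, 12)         # red edge / NIR plateau
}

aphidArchetype <- function(wl, depth) {
  healthyArchetype(wl) -
    depth * (0.42 * exp(-((wl - 770) / 70)^2) +  # strongest over 710-825 nm
             0.15 * logisticEdge(wl, 720, 15))   # sustained NIR depression
}

trueEndmemberMatrix <- function(cfg) {
  wl <- cfg$wavelengths
  rbind(background = backgroundArchetype(wl),
        healthy = healthyArchetype(wl),
        aphid = aphidArchetype(wl, cfg$nirDepth))
}

# count -> aphid mixing fraction, saturating at 1
countToAbundance <- function(count, slope) pmin(1, slope * count)

ellipseMask <- function(h, w, cy, cx, ry, rx) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Generate a synthetic VNIR leaf scene with ground truth
#'
#' Builds a single-leaf scene: a filled ellipse of the healthy-leaf
#' archetype on a dark background, with an infested elliptical patch
#' inside the leaf whose pixels are convex mixtures
#' \eqn{(1 - a)\,\mathrm{healthy} + a\,\mathrm{aphid}} where the mixing
#' fraction \eqn{a} increases linearly with the aphid count (saturating
#' at 1). Per-pixel lognormal multiplicative gain and additive Gaussian
#' noise are applied after mixing. Identical (config, seed) pairs give
#' bit-identical output.
#'
#' @param config a [sceneConfig()].
#' @param seed integer RNG seed.
#' @return a list with elements \code{cube} (a [Hypercube-class]) and
#'   \code{truth} (a [SceneTruth-class]).
#' @examples
#' sc <- makeScene(sceneConfig(gainSd = 0, additiveSd = 0), seed = 1)
#' sum(leafMask(sc$truth))
#' @export
makeScene <- function(config = sceneConfig(), seed = 1L) {
  stopifnot(inherits(config, "SceneConfig"))
  stopifnotScalarSeed(seed)
  h <- config$height; w <- config$width
  wl <- config$wavelengths; L <- length(wl)

  leaf <- ellipseMask(h, w, cy = h / 2, cx = w / 2,
                      ry = 0.32 * h, rx = 0.22 * w)
  # infested patch sized so that area ~ patchFraction of the leaf,
  # offset toward the lower-right but kept inside the leaf
  ry <- sqrt(config$patchFraction) * 0.32 * h * 0.95
  rx <- sqrt(config$patchFraction) * 0.22 * w * 0.95
  patch <- ellipseMask(h, w, cy = h / 2 + 0.08 * h, cx = w / 2 + 0.05 * w,
                       ry = ry, rx = rx) & leaf

  em <- trueEndmemberMatrix(config)
  a <- countToAbundance(config$aphidCount, config$countSlope)

  abundance <- array(0, dim = c(h, w, 3L))
  abundance[, , 1L][!leaf] <- 1
  abundance[, , 2L][leaf] <- 1
  abundance[, , 2L][patch] <- 1 - a
  abundance[, , 3L][patch] <- a

  flatAb <- matrix(abundance, nrow = h * w, ncol = 3L)
  clean <- flatAb %*% em                      # (H*W) x L

  values <- withSeed(seed, {
    gain <- exp(stats::rnorm(h * w, 0, config$gainSd))
    noisy <- clean * gain +
      matrix(stats::rnorm(h * w * L, 0, config$additiveSd), h * w, L)
    noisy
  })
  values <- pmax(values, 0)

  cube <- Hypercube(array(values, dim = c(h, w, L)), wl)
  truth <- new("SceneTruth", leafMask = leaf, infestedMask = patch,
               aphidCount = config$aphidCount, endmembers = em,
               abundance = abundance)
  list(cube = cube, truth = truth)
}

#' Generate a labeled table of mean-leaf spectra
#'
#' Emulates the per-plant mean spectra that the imaging pipeline extracts
#' from segmented leaves: for each sample the leaf-average spectrum is
#' synthesized directly from the archetypes (healthy, or a
#' patch-weighted healthy/aphid mixture whose aphid fraction grows with a
#' randomly drawn count), then degraded with the configured multiplicative
#' gain and additive noise. Counts are drawn uniformly over
#' \code{config$countRange}, spanning the Low (<20), Medium (20--50) and
#' High (>50) severity bands.
#'
#' @param nPerClass samples per class (healthy / infested).
#' @param config a [sceneConfig()].
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{sample_id}, \code{label}
#'   ("healthy"/"infested"), \code{aphid_count} (0 for healthy rows) and
#'   one \code{R_<wavelength>} column per band.
#' @examples
#' tab <- makeLabeledDataset(5, sceneConfig(), seed = 1)
#' table(tab$label)
#' @export
makeLabeledDataset <- function(nPerClass = 168L, config = sceneConfig(),
                               seed = 1L) {
  if (nPerClass < 1L) stop("nPerClass must be >= 1")
  stopifnot(inherits(config, "SceneConfig"))
  stopifnotScalarSeed(seed)
  wl <- config$wavelengths; L <- length(wl)
  em <- trueEndmemberMatrix(config)
  healthy <- em["healthy", ]; aphid <- em["aphid", ]
  n <- 2L * nPerClass

  withSeed(seed, {
    counts <- sample(seq(config$countRange[1L], config$countRange[2L]),
                     nPerClass, replace = TRUE)
    aFrac <- config$patchFraction * countToAbundance(counts, config$countSlope)
    clean <- rbind(
      matrix(healthy, nPerClass, L, byrow = TRUE),
      (1 - aFrac) %o% healthy + aFrac %o% aphid
    )
    gain <- exp(stats::rnorm(n, 0, config$gainSd))
    spectra <- clean * gain +
      matrix(stats::rnorm(n * L, 0, config$additiveSd), n, L)
    spectra <- pmax(spectra, 0)
    out <- data.frame(
      sample_id = sprintf("s%03d", seq_len(n)),
      label = rep(c("healthy", "infested"), each = nPerClass),
      aphid_count = c(rep(0L, nPerClass), as.integer(counts)),
      stringsAsFactors = FALSE
    )
    colnames(spectra) <- bandColumnNames(wl)
    cbind(out, as.data.frame(spectra))
  })
}
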