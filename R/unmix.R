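#' Volume of the simplex spanned by K points in K-1 dimensions
#'
#' The N-FINDR objective: for K points \eqn{v_1,\dots,v_K} in
#' \eqn{R^{K-1}}, the simplex volume is
#' \deqn{V = \frac{|\det [\,1\; v_1\; \cdots\; 1\; v_K\,]|}{(K-1)!}.}
#' Coincident or affinely dependent points give volume 0.
#'
#' @param points K x (K-1) matrix, one point per row.
#' @return non-negative simplex volume.
#' @examples
#' simplexVolume(rbind(c(0, 0), c(1, 0), c(0, 1)))  # 0.5
#' @export
simplexVolume <- function(points) {
  p <- as.matrix(points)
  K <- nrow(p)
  if (ncol(p) != K - 1L)
    stop("need K points in K-1 dimensions, got ", K, " x ", ncol(p))
  M <- cbind(1, p)
  abs(det(M)) / factorial(K - 1L)
}

# PCA projection of masked pixel spectra to K-1 dims (scores)
projectForNfindr <- function(X, K) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ncomp <- min(K - 1L, ncol(pc$x))
  S <- pc$x[, seq_len(ncomp), drop = FALSE]
  if (ncomp < K - 1L)  # degenerate data: pad with zero coordinates
    S <- cbind(S, matrix(0, nrow(S), K - 1L - ncomp))
  S
}

#' N-FINDR endmember extraction
#'
#' Finds K pure-pixel endmembers by inflating a simplex inside the data:
#' masked pixel spectra are projected to K-1 dimensions by PCA, a random
#' seeded set of K pixels initializes the simplex, and each vertex is
#' repeatedly tested against every candidate pixel, accepting any
#' replacement that strictly increases the simplex volume, until a full
#' sweep makes no replacement (or \code{maxSweeps} is reached). Because a
#' single run is sensitive to initialization, \code{restarts} independent
#' seeded runs are performed and the largest-volume simplex is returned.
#'
#' @param cube a [Hypercube-class].
#' @param mask logical mask of candidate pixels (>= K pixels).
#' @param K number of endmembers (default 6).
#' @param seed master seed; restart r uses seed + r - 1.
#' @param maxSweeps maximum replacement sweeps per restart.
#' @param restarts independent random initializations.
#' @param source provenance tag for the returned set.
#' @return an [EndmemberSet-class]; \code{pixelIdx} holds the chosen
#'   pixels' linear indices into the cube.
#' @export
nfindr <- function(cube, mask, K = 6L, seed = 1L, maxSweeps = 20L,
                   restarts = 10L, source = "infested-image") {
  m <- asLogicalMask(mask)
  idx <- which(m)
  if (K < 2L) stop("K must be >= 2")
  if (length(idx) < K)
    stop("mask has ", length(idx), " pixels; need at least K = ", K)
  X <- pixelMatrix(cube)[idx, , drop = FALSE]
  N <- nrow(X)
  if (N == K) {
    return(EndmemberSet(X, wavelengths(cube), source, pixelIdx = idx))
  }
  S <- projectForNfindr(X, K)

  runOne <- function(s) {
    sel <- withSeed(s, sample.int(N, K))
    vol <- simplexVolume(S[sel, , drop = FALSE])
    for (sweep in seq_len(maxSweeps)) {
      improved <- FALSE
      for (j in seq_len(K)) {
        # volume as a function of candidate in vertex slot j is |affine|;
        # evaluate for all candidates via cofactor expansion
        M <- cbind(1, S[sel, , drop = FALSE])
        best <- vol; bestI <- 0L
        for (i in seq_len(N)) {
          if (i %in% sel) next
          M[j, ] <- c(1, S[i, ])
          v <- abs(det(M)) / factorial(K - 1L)
          if (v > best + 1e-15) { best <- v; bestI <- i }
        }
        if (bestI > 0L) {
          sel[j] <- bestI
          vol <- best
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(sel = sel, vol = vol)
  }

  runs <- lapply(seq_len(restarts), function(r) runOne(seed + r - 1L))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "vol"))]]
  sel <- sort(best$sel)
  EndmemberSet(X[sel, , drop = FALSE], wavelengths(cube), source,
               pixelIdx = idx[sel])
}

# fully constrained least squares for one pixel:
# min ||E a - x||^2  s.t.  sum(a) = 1, a >= 0   (active-set on the bounds)
fclsSolve <- function(G, f, K) {
  solveEq <- function(free) {
    k <- length(free)
    A <- rbind(cbind(G[free, free, drop = FALSE], 1), c(rep(1, k), 0))
    b <- c(f[free], 1)
    sol <- solve(A, b)
    sol[seq_len(k)]
  }
  free <- seq_len(K)
  a <- rep(0, K)
  for (it in seq_len(2L * K)) {
    af <- tryCatch(solveEq(free), error = function(e) NULL)
    if (is.null(af)) { # fall back: uniform over free set
      af <- rep(1 / length(free), length(free))
    }
    if (all(af >= -1e-10) || length(free) == 1L) {
      a[] <- 0
      a[free] <- pmax(af, 0)
      a <- a / sum(a)
      return(a)
    }
    free <- free[-which.min(af)]
  }
  a[] <- 0; a[free] <- 1 / length(free)
  a
}

#' Fully constrained linear unmixing
#'
#' Decomposes every pixel spectrum into fractional abundances of the
#' endmembers by least squares subject to non-negativity and sum-to-one
#' (fully constrained LS, solved by an active-set method on the
#' non-negativity bounds). The per-pixel residual norm of the fit is
#' returned alongside the abundances.
#'
#' @param cube a [Hypercube-class].
#' @param endmembers an [EndmemberSet-class] on the same grid, K <= L.
#' @return an [AbundanceMaps-class].
#' @export
unmixLinear <- function(cube, endmembers) {
  E <- t(endmemberSpectra(endmembers))          # L x K
  if (!isTRUE(all.equal(wavelengths(cube), wavelengths(endmembers))))
    stop("cube and endmembers are on different wavelength grids")
  K <- ncol(E); L <- nrow(E)
  if (K > L) stop("more endmembers than bands")
  G <- crossprod(E)
  if (rcond(G) < 1e-12)
    stop(sprintf(
      "endmember matrix is rank-deficient (rcond(E'E) = %.3g); %s",
      rcond(G), "endmembers are (near-)collinear"))
  X <- pixelMatrix(cube)                        # N x L
  N <- nrow(X)
  Fmat <- X %*% E                               # N x K, rows are E'x

  # unconstrained sum-to-one solution for all pixels at once
  Ginv <- solve(G)
  ones <- rep(1, K)
  Gi1 <- Ginv %*% ones
  denom <- as.numeric(crossprod(ones, Gi1))
  A0 <- Fmat %*% Ginv
  lambda <- (rowSums(A0) - 1) / denom
  A <- A0 - outer(lambda, as.numeric(Gi1))

  neg <- which(apply(A, 1L, function(a) any(a < -1e-10)))
  for (i in neg) A[i, ] <- fclsSolve(G, Fmat[i, ], K)
  A[A < 0] <- 0
  A <- A / rowSums(A)

  resid <- sqrt(pmax(rowSums((X - A %*% t(E))^2), 0))
  d <- dim(cubeValues(cube))
  new("AbundanceMaps",
      values = array(A, dim = c(d[1], d[2], K)),
      residual = matrix(resid, d[1], d[2]))
}

#' Identify aphid-indicative endmembers
#'
#' Among the endmembers extracted from an infested image, only some carry
#' the aphid signature; the rest are healthy-tissue variants. This
#' selector scores each endmember by its SID (within the given window)
#' against the plant-mean spectrum of the source cube and returns the
#' endmembers with above-average divergence -- the ones spectrally
#' farthest from the bulk of the leaf, i.e. the aphid-indicative subset.
#'
#' @param endmembers an [EndmemberSet-class] from the infested cube.
#' @param cube the source [Hypercube-class].
#' @param mask logical plant mask used for the plant-mean spectrum.
#' @param window a [resolveWindow()] result (default 710--825 nm).
#' @return integer indices of the aphid-indicative endmembers, with the
#'   per-endmember divergences as attribute \code{"divergence"}.
#' @export
aphidEndmembers <- function(endmembers, cube, mask,
                            window = resolveWindow(wavelengths(cube),
                                                   710, 825)) {
  m <- asLogicalMask(mask)
  leafMean <- colMeans(pixelMatrix(cube)[which(m), , drop = FALSE])
  bands <- window$loIdx:window$hiIdx
  d <- apply(endmemberSpectra(endmembers), 1L,
             function(e) sid(e[bands], leafMean[bands]))
  idx <- which(d > mean(d))
  if (!length(idx)) idx <- which.max(d)
  attr(idx, "divergence") <- d
  idx
}

#' Build the infested reference spectrum
#'
#' Band-wise arithmetic mean of the endmember spectra (optionally of a
#' subset), used as the comparison baseline for SID mapping. The
#' reference is defined from endmembers of infested imagery; averaging a
#' healthy-sourced set triggers a warning.
#'
#' @param endmembers an [EndmemberSet-class].
#' @param subset optional integer vector of endmember rows to average
#'   (e.g. only the aphid-indicative ones).
#' @return numeric reference spectrum with a \code{"wavelengths"}
#'   attribute.
#' @export
buildReference <- function(endmembers, subset = NULL) {
  if (!identical(endmembers@source, "infested-image"))
    warning("reference is defined from infested-image endmembers; got source '",
            endmembers@source, "'")
  S <- endmemberSpectra(endmembers)
  if (!is.null(subset)) S <- S[subset, , drop = FALSE]
  ref <- colMeans(S)
  attr(ref, "wavelengths") <- wavelengths(endmembers)
  ref
}
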