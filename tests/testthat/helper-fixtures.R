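# shared fixture builders for the test suite

noiselessConfig <- function(...) sceneConfig(gainSd = 0, additiveSd = 0, ...)

# tiny cube whose pixels are convex mixtures of K planted vertex spectra;
# the planted vertices themselves are included as pixels
mixtureToyCube <- function(nPixels, nBands = 8L, K = 3L, seed = 1L) {
  set.seed(seed)
  V <- matrix(runif(K * nBands), K, nBands)
  A <- matrix(stats::rexp(nPixels * K), nPixels, K)
  A <- A / rowSums(A)
  A[seq_len(K), ] <- diag(K)
  X <- A %*% V
  list(cube = Hypercube(array(X, c(nPixels, 1L, nBands)),
                        seq(400, 700, length.out = nBands)),
       mask = matrix(TRUE, nPixels, 1L),
       vertices = V, vertexIdx = seq_len(K), abundance = A, pixels = X)
}

# labeled table with class signal confined to a planted band set
plantedSignalTable <- function(n = 120L, informativeIdx, shift = 2,
                               seed = 1L, wl = defaultGrid()) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * length(wl)), n, length(wl))
  y <- rep(c("healthy", "infested"), each = n / 2L)
  X[y == "infested", informativeIdx] <-
    X[y == "infested", informativeIdx] + shift
  sp <- stats::setNames(as.data.frame(X), sprintf("R_%.2f", wl))
  cbind(data.frame(sample_id = sprintf("s%03d", seq_len(n)), label = y),
        sp)
}

# SNV-pretreat the band columns of a labeled table
snvTable <- function(table) {
  cols <- grep("^R_", names(table), value = TRUE)
  M <- as.matrix(table[, cols])
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2) / (ncol(M) - 1L))
  table[, cols] <- (M - mu) / s
  table
}

# independent SID oracle: SID(x,y) = sum (p - q) (log p - log q),
# an algebraically different route, accumulated with Kahan compensation
sidOracle <- function(x, y, floor = 1e-12) {
  norm1 <- function(v) { v <- pmax(v, floor); v / sum(v) }
  p <- norm1(x); q <- norm1(y)
  terms <- (p - q) * (log(p) - log(q))
  s <- 0; comp <- 0
  for (t in terms) {
    yy <- t - comp
    tt <- s + yy
    comp <- (tt - s) - yy
    s <- tt
  }
  s
}

# brute-force binary erosion by definition (min over SE neighborhood,
# zero padding)
bruteErode <- function(m, size = 5L) {
  r <- (size - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (yy in seq_len(h)) for (xx in seq_len(w)) {
    ok <- TRUE
    for (dy in -r:r) for (dx in -r:r) {
      py <- yy + dy; px <- xx + dx
      v <- if (py < 1L || py > h || px < 1L || px > w) FALSE else m[py, px]
      if (!v) { ok <- FALSE; break }
    }
    out[yy, xx] <- ok
  }
  out
}

maskIoU <- function(a, b) sum(a & b) / sum(a | b)
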