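test_that("simplex volume matches hand-computed cases", {
  expect_equal(simplexVolume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(simplexVolume(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)
  expect_equal(simplexVolume(rbind(c(0, 0, 0), c(1, 0, 0),
                                   c(0, 1, 0), c(0, 0, 1))), 1 / 6)
  expect_error(simplexVolume(matrix(0, 3, 3)), "K-1")
})

test_that("simplex volume is permutation-invariant and homogeneous", {
  set.seed(4)
  for (K in c(3L, 4L, 5L)) {
    P <- matrix(stats::rnorm(K * (K - 1L)), K)
    v <- simplexVolume(P)
    for (i in 1:5)
      expect_equal(simplexVolume(P[sample(K), , drop = FALSE]), v)
    for (c in c(0.5, 2, 10))
      expect_equal(simplexVolume(P * c), v * c^(K - 1L))
  }
})

test_that("N-FINDR recovers planted vertices and matches exhaustive search", {
  for (s in 1:6) {
    toy <- mixtureToyCube(nPixels = 40L, seed = s)
    em <- nfindr(toy$cube, toy$mask, K = 3L, seed = s)
    # exhaustive max-volume oracle over all pixel triples
    S <- stats::prcomp(toy$pixels, center = TRUE)$x[, 1:2]
    combos <- utils::combn(nrow(toy$pixels), 3L)
    vols <- apply(combos, 2L, function(ix) simplexVolume(S[ix, ]))
    best <- sort(combos[, which.max(vols)])
    expect_identical(sort(em@pixelIdx), best)
    expect_identical(best, 1:3)          # the planted vertices
  }
})

test_that("N-FINDR edge cases behave per contract", {
  toy <- mixtureToyCube(nPixels = 5L, seed = 2)
  all5 <- nfindr(toy$cube, toy$mask, K = 5L, seed = 1)
  expect_identical(nrow(endmemberSpectra(all5)), 5L)
  expect_error(nfindr(toy$cube, toy$mask, K = 6L, seed = 1), "need at least")
  # accepted volume never below the seeded initial simplex volume
  toy2 <- mixtureToyCube(nPixels = 30L, seed = 3)
  em <- nfindr(toy2$cube, toy2$mask, K = 3L, seed = 3, restarts = 1L)
  S <- stats::prcomp(toy2$pixels, center = TRUE)$x[, 1:2]
  init <- aphidSID:::withSeed(3, sample.int(30L, 3L))
  expect_gte(simplexVolume(S[em@pixelIdx, ]), simplexVolume(S[init, ]))
})

test_that("fully constrained unmixing inverts exact mixtures", {
  set.seed(5)
  E <- matrix(stats::runif(4 * 20, 0.1, 1), 4, 20)   # 4 endmembers
  mix <- rbind(0.5 * E[1, ] + 0.5 * E[2, ], E[3, ],
               0.2 * E[1, ] + 0.3 * E[2, ] + 0.5 * E[4, ])
  cube <- Hypercube(array(mix, c(3, 1, 20)), seq(400, 900, length.out = 20))
  em <- EndmemberSet(E, wavelengths(cube), "infested-image")
  A <- matrix(abundanceValues(unmixLinear(cube, em)), ncol = 4)
  expect_equal(A[1, ], c(0.5, 0.5, 0, 0), tolerance = 1e-8)
  expect_equal(A[2, ], c(0, 0, 1, 0), tolerance = 1e-8)
  expect_equal(A[3, ], c(0.2, 0.3, 0, 0.5), tolerance = 1e-8)
})

test_that("unmixing a noiseless scene recovers the planted abundances", {
  sc <- makeScene(noiselessConfig(height = 32L, width = 32L), seed = 7)
  em <- EndmemberSet(trueEndmembers(sc$truth), wavelengths(sc$cube),
                     "infested-image")
  ab <- unmixLinear(sc$cube, em)
  expect_lt(max(abs(abundanceValues(ab) - trueAbundance(sc$truth))), 1e-6)
  expect_lt(max(unmixResidual(ab)), 1e-9)
})

test_that("abundances are simplex-valued even under noise", {
  sc <- makeScene(sceneConfig(height = 24L, width = 24L, gainSd = 0.1,
                              additiveSd = 0.02), seed = 8)
  em <- EndmemberSet(trueEndmembers(sc$truth), wavelengths(sc$cube),
                     "infested-image")
  A <- matrix(abundanceValues(unmixLinear(sc$cube, em)), ncol = 3)
  expect_true(all(A >= 0))
  expect_true(all(A <= 1 + 1e-9))
  expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
})

test_that("rank-deficient endmember matrices are rejected with diagnostics", {
  E <- rbind(rep(1, 10), rep(1, 10), stats::runif(10))
  cube <- Hypercube(array(stats::runif(40), c(4, 1, 10)),
                    seq(400, 900, length.out = 10))
  expect_error(unmixLinear(cube, EndmemberSet(E, wavelengths(cube))),
               "rank-deficient")
})

test_that("aphid-indicative endmembers are the ones divergent from the
           leaf mean, and their average localizes the colony", {
  for (s in c(2L, 9L)) {
    sc <- makeScene(sceneConfig(), seed = s)
    lm <- leafMask(sc$truth)
    em <- nfindr(sc$cube, lm, K = 6L, seed = s)
    idx <- aphidEndmembers(em, sc$cube, lm)
    expect_gte(length(idx), 1L)
    expect_lt(length(idx), 6L)
    d <- attr(idx, "divergence")
    expect_true(all(d[idx] > d[setdiff(1:6, idx)][1] |
                      length(setdiff(1:6, idx)) == 0))
    ref <- buildReference(em, subset = idx)
    m <- sidMap(sc$cube, lm, ref)
    expect_gte(maskIoU(thresholdSid(m, "otsu"), infestedMask(sc$truth)),
               0.9)
  }
})

test_that("the reference spectrum is the endmember mean", {
  wl <- seq(400, 900, length.out = 6)
  em2 <- EndmemberSet(rbind(rep(0, 6), rep(2, 6)), wl, "infested-image")
  expect_equal(unname(buildReference(em2)), rep(1, 6), ignore_attr = TRUE)
  em1 <- EndmemberSet(matrix(3, 1, 6), wl, "infested-image")
  expect_equal(as.numeric(buildReference(em1)), rep(3, 6))
  set.seed(9)
  S <- matrix(stats::runif(36), 6, 6)
  em6 <- EndmemberSet(S, wl, "infested-image")
  expect_equal(as.numeric(buildReference(em6)),
               apply(S, 2L, mean))                  # independent column mean
  expect_warning(buildReference(EndmemberSet(S, wl, "healthy-image")),
                 "infested")
  expect_equal(as.numeric(suppressWarnings(
    buildReference(em6, subset = 1:2))), colMeans(S[1:2, ]))
})
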