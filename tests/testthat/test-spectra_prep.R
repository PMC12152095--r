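cubeOf <- function(vals, wl = seq_along(vals) * 100 + 300) {
  Hypercube(array(vals, c(1, 1, length(vals))), wl)
}

test_that("reflectance calibration follows (raw - dark)/(white - dark)", {
  raw <- cubeOf(c(50, 10, 10))
  dark <- cubeOf(c(10, 10, 20))
  white <- cubeOf(c(90, 90, 120))
  R <- cubeValues(calibrateReflectance(raw, white, dark))
  expect_equal(R[1, 1, 1], 0.5)        # midpoint
  expect_equal(R[1, 1, 2], 0.0)        # raw = dark
  expect_equal(R[1, 1, 3], -0.1)       # negative values preserved
})

test_that("calibration is invariant to a common gain and broadcasts frames", {
  set.seed(2)
  mk <- function(a) Hypercube(a, seq(400, 700, length.out = 4))
  raw <- array(stats::runif(3 * 2 * 4, 10, 80), c(3, 2, 4))
  dark <- array(stats::runif(3 * 2 * 4, 0, 5), c(3, 2, 4))
  white <- array(stats::runif(3 * 2 * 4, 90, 120), c(3, 2, 4))
  R1 <- cubeValues(calibrateReflectance(mk(raw), mk(white), mk(dark)))
  R2 <- cubeValues(calibrateReflectance(mk(raw * 3.7), mk(white * 3.7),
                                        mk(dark * 3.7)))
  expect_lt(max(abs(R1 - R2)), 1e-12)
  # single-line white/dark frames broadcast along the scan axis
  line <- function(a) Hypercube(a[1, , , drop = FALSE],
                                seq(400, 700, length.out = 4))
  darkB <- array(rep(dark[1, , ], each = 3), c(3, 2, 4))
  whiteB <- array(rep(white[1, , ], each = 3), c(3, 2, 4))
  R3 <- cubeValues(calibrateReflectance(mk(raw), line(white), line(dark)))
  R4 <- cubeValues(calibrateReflectance(mk(raw), mk(whiteB), mk(darkB)))
  expect_equal(R3, R4)
})

test_that("degenerate calibration inputs are rejected with the band named", {
  raw <- cubeOf(c(50, 10))
  white <- cubeOf(c(90, 30))
  darkSame <- cubeOf(c(10, 30))      # band 2 has white == dark
  expect_error(calibrateReflectance(raw, white, darkSame), "band.*2")
  small <- Hypercube(array(1, c(2, 2, 2)), c(400, 500))
  expect_error(calibrateReflectance(small, white, darkSame), "incompatible")
})

test_that("SNV standardizes to mean 0 and sample sd 1", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  x <- snv(stats::rnorm(50, 3, 7))
  expect_lt(abs(mean(x)), 1e-10)
  expect_lt(abs(stats::sd(x) - 1), 1e-10)
  expect_lt(max(abs(snv(x) - x)), 1e-12)       # idempotent
  expect_error(snv(c(5, 5, 5)), "constant")
  set.seed(3)
  for (i in 1:20) {
    z <- snv(stats::runif(30) * 10^sample(-2:2, 1))
    expect_lt(abs(mean(z)), 1e-10)
    expect_lt(abs(stats::sd(z) - 1), 1e-10)
  }
})

test_that("log(1/R) uses base 10 with a positive floor", {
  expect_equal(logInverseR(0.5), log10(2), tolerance = 1e-12)
  expect_equal(logInverseR(1), 0)
  expect_equal(logInverseR(0, floor = 1e-4), 4)
  expect_equal(logInverseR(-0.3, floor = 1e-4), 4)   # negatives floored
  expect_error(logInverseR(0.5, floor = 0), "positive")
})

test_that("Savitzky-Golay derivatives are exact on polynomials", {
  i <- 0:40
  expect_equal(sgDerivative(3.5 * i, order = 1), rep(3.5, 41))
  expect_equal(sgDerivative(2 + 5 * i, order = 2), rep(0, 41))
  expect_equal(sgDerivative(i^2, order = 2, window = 5, polyorder = 2),
               rep(2, 41))
  # edges included: quadratic second derivative exact everywhere
  d <- sgDerivative(1 + 2 * i + 0.5 * i^2, order = 2, window = 7,
                    polyorder = 2)
  expect_lt(max(abs(d - 1)), 1e-9)
})

test_that("invalid Savitzky-Golay settings are rejected", {
  x <- stats::rnorm(20)
  expect_error(sgDerivative(x, window = 6), "odd")
  expect_error(sgDerivative(x, window = 3, polyorder = 3), "exceed")
  expect_error(sgDerivative(x, order = 2, polyorder = 1), ">=")
  expect_error(sgDerivative(x, window = 21), "length")
})

test_that("band windows resolve to nearest inclusive indices", {
  wl <- defaultGrid()
  w <- resolveWindow(wl, 710, 825)
  expect_identical(w$loIdx, 120L)     # 0-based 119
  expect_identical(w$hiIdx, 161L)     # 0-based 160
  expect_identical(w$nBands, 42L)
  full <- resolveWindow(wl, 380, 1000)
  expect_identical(c(full$loIdx, full$hiIdx, full$nBands), c(1L, 224L, 224L))
  expect_error(resolveWindow(wl, 370, 390), "outside")
  expect_error(resolveWindow(wl, 825, 710), "loNm < hiNm")
  # half-way ties round toward the window interior
  g <- c(100, 200, 300)
  expect_identical(resolveWindow(g, 150, 250)$loIdx, 2L)
  expect_identical(resolveWindow(g, 150, 250)$hiIdx, 2L)
})

test_that("spectra tables round-trip through CSV", {
  tab <- makeLabeledDataset(3L, sceneConfig(), seed = 2)
  p <- file.path(tempdir(), "spectra_rt.csv")
  writeSpectraCSV(tab, p)
  back <- readSpectraCSV(p)
  expect_identical(names(back), names(tab))
  expect_equal(as.matrix(back[, -(1:3)]), as.matrix(tab[, -(1:3)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
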