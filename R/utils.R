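# internal helpers shared across modules

# run code under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# band columns of a spectra table are named R_<wavelength>
bandColumns <- function(table) grep("^R_", names(table), value = TRUE)

# extract the numeric band matrix (rows = samples) from a spectra table
spectraMatrix <- function(table) {
  cols <- bandColumns(table)
  if (!length(cols)) stop("table has no band columns (named R_<wavelength>)")
  as.matrix(table[, cols, drop = FALSE])
}

# wavelengths encoded in the band column names
tableWavelengths <- function(table) {
  as.numeric(sub("^R_", "", bandColumns(table)))
}

bandColumnNames <- function(wl) sprintf("R_%.2f", wl)

# flatten cube pixels to an (H*W) x L matrix, row-major over (row, col)
pixelMatrix <- function(cube) {
  v <- cubeValues(cube)
  d <- dim(v)
  matrix(v, nrow = d[1] * d[2], ncol = d[3])
}

asLogicalMask <- function(mask) {
  m <- mask
  if (is.numeric(m)) m <- m != 0
  if (!is.logical(m) || !is.matrix(m)) stop("mask must be a logical H x W matrix")
  m
}

stopifnotScalarSeed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  invisible(as.integer(seed))
}
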