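#' Write a Hypercube as an ENVI image (header + binary)
#'
#' Writes \code{<path>.hdr} (plain-text ENVI header) and \code{<path>.dat}
#' (binary cube): band-sequential (BSQ) interleave, 32-bit little-endian
#' IEEE floats (ENVI data type 4), samples varying fastest within a line.
#' The wavelength grid is stored in the header.
#'
#' @param cube a [Hypercube-class].
#' @param path output path without extension.
#' @return invisibly, the header path.
#' @export
writeENVI <- function(cube, path) {
  v <- cubeValues(cube)
  d <- dim(v)
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = { %s }",
            paste(sprintf("%.4f", wavelengths(cube)), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: per band, lines x samples with samples fastest -> transpose each band
  for (l in seq_len(d[3]))
    writeBin(as.numeric(t(v[, , l])), con, size = 4L, endian = "little")
  invisible(paste0(path, ".hdr"))
}

parseEnviHeader <- function(hdrPath) {
  txt <- readLines(hdrPath, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  getField <- function(name) {
    m <- regmatches(joined,
                    regexpr(sprintf("(?mi)^%s\\s*=\\s*[^\n{]+", name),
                            joined, perl = TRUE))
    if (!length(m)) return(NA_character_)
    trimws(sub("^[^=]*=", "", m))
  }
  wlm <- regmatches(joined,
                    regexpr("(?si)wavelength\\s*=\\s*\\{[^}]*\\}", joined,
                            perl = TRUE))
  wl <- if (length(wlm)) {
    as.numeric(strsplit(gsub("[{}]|wavelength\\s*=", "", wlm), ",")[[1]])
  } else NULL
  list(samples = as.integer(getField("samples")),
       lines = as.integer(getField("lines")),
       bands = as.integer(getField("bands")),
       dataType = as.integer(getField("data type")),
       interleave = tolower(getField("interleave")),
       byteOrder = as.integer(getField("byte order")),
       wavelengths = wl)
}

#' Read an ENVI image into a Hypercube
#'
#' Supports the subset of ENVI this package writes: BSQ interleave, data
#' type 4 (float32) or 5 (float64), little-endian. The wavelength grid is
#' taken from the header when present, else defaults to [defaultGrid()]
#' for 224-band cubes.
#'
#' @param path path to the \code{.hdr} file or to the stem without
#'   extension.
#' @return a [Hypercube-class].
#' @export
readENVI <- function(path) {
  hdrPath <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  stem <- sub("\\.hdr$", "", hdrPath)
  h <- parseEnviHeader(hdrPath)
  if (!identical(h$interleave, "bsq"))
    stop("only BSQ interleave is supported, got: ", h$interleave)
  if (!h$dataType %in% c(4L, 5L))
    stop("only float32/float64 ENVI data types are supported")
  datPath <- if (file.exists(paste0(stem, ".dat"))) paste0(stem, ".dat")
             else stem
  size <- if (h$dataType == 4L) 4L else 8L
  n <- h$samples * h$lines * h$bands
  con <- file(datPath, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = size, endian = "little")
  # stored samples-fastest per line, lines per band
  arr <- array(raw, dim = c(h$samples, h$lines, h$bands))
  arr <- aperm(arr, c(2L, 1L, 3L))
  wl <- if (!is.null(h$wavelengths) && length(h$wavelengths) == h$bands)
    h$wavelengths else defaultGrid(h$bands)
  Hypercube(arr, wl)
}

#' Read or write a binary mask as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with 0 = background and
#' 255 = foreground.
#'
#' @param mask logical H x W matrix.
#' @param path file path.
#' @return \code{writeMaskPNG}: invisibly the path; \code{readMaskPNG}:
#'   a logical matrix.
#' @export
writeMaskPNG <- function(mask, path) {
  m <- asLogicalMask(mask)
  png::writePNG(m * 1, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}
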