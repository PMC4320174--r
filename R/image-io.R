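#' Read an 8-bit raster image
#'
#' Decodes PNG, TIFF, PPM (binary P6) or JPEG into an [rgb_image()]. Grayscale
#' images are promoted to three identical channels; an alpha channel is
#' dropped. Decoded 8-bit sample values are returned unchanged as reals in
#' `[0, 255]`.
#'
#' JPEG support is provided through the EBImage package (listed in Suggests)
#' and is lossy; all lossless work should go through PNG, TIFF or PPM.
#'
#' @param path path to an image file; format is inferred from the extension.
#' @return an [rgb_image()].
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw01 <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    ppm = return(read_ppm(path)),
    jpg = ,
    jpeg = read_jpeg_array(path),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  arr <- promote_channels(raw01, path)
  # codecs above return samples scaled to [0,1]; recover the 8-bit levels
  rgb_image(round(arr * 255))
}

promote_channels <- function(a, path) {
  if (is.matrix(a)) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    if (nc == 1L) {
      a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
    } else if (nc == 2L) {            # gray + alpha
      a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
    } else if (nc >= 4L) {            # drop alpha
      a <- a[, , 1:3, drop = FALSE]
    }
  } else {
    stop("cannot decode ", path, " as an 8-bit raster image", call. = FALSE)
  }
  a
}

read_jpeg_array <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("reading JPEG requires the EBImage package", call. = FALSE)
  }
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  # EBImage stores x (width) first; transpose to row-major H x W
  if (is.matrix(a)) t(a) else aperm(a, c(2L, 1L, 3L))
}

#' Write an image to disk
#'
#' Quantizes to 8-bit (see [quantize()]) and encodes as PNG, TIFF, PPM
#' (binary P6) or JPEG according to the file extension. For the lossless
#' formats, `read_image(write_image(img, f))` reproduces `quantize(img)`
#' exactly.
#'
#' @param img an [rgb_image()] (real-valued allowed; quantized on output).
#' @param path output path; extension selects the codec.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  q <- quantize(rgb_image(unclass(img)))
  ext <- tolower(tools::file_ext(path))
  a01 <- unclass(q) / 255
  switch(ext,
    png = png::writePNG(a01, target = path),
    tif = ,
    tiff = tiff::writeTIFF(a01, where = path, bits.per.sample = 8L),
    ppm = write_ppm(q, path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("writing JPEG requires the EBImage package", call. = FALSE)
      }
      EBImage::writeImage(
        EBImage::Image(aperm(a01, c(2L, 1L, 3L)), colormode = "Color"), path)
    },
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  invisible(path)
}

# Binary PPM (P6), maxval 255. Header tokens may be separated by arbitrary
# whitespace and '#' comments; pixel data is row-major interleaved RGB.
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PPM header in ", path, call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (magic != "P6") {
    stop("not a binary PPM (P6) file: ", path, call. = FALSE)
  }
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (is.na(w) || is.na(h) || is.na(maxval)) {
    stop("malformed PPM header in ", path, call. = FALSE)
  }
  if (maxval != 255L) {
    stop("only 8-bit PPM (maxval 255) is supported: ", path, call. = FALSE)
  }
  bytes <- readBin(con, "raw", n = 3L * w * h)
  if (length(bytes) < 3L * w * h) stop("truncated PPM data in ", path, call. = FALSE)
  v <- as.integer(bytes)
  # stream order: for each row, for each column, R G B
  arr <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) {
    arr[, , k] <- matrix(v[seq(k, length(v), by = 3L)], nrow = h, byrow = TRUE)
  }
  rgb_image(arr)
}

write_ppm <- function(img, path) {
  q <- unclass(quantize(img))
  h <- dim(q)[1L]; w <- dim(q)[2L]
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  inter <- aperm(q, c(3L, 2L, 1L))  # channel fastest, then column, then row
  writeBin(as.raw(as.integer(inter)), con)
  invisible(path)
}
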