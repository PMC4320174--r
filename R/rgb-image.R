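#' Construct an RGB image
#'
#' The package's working representation of an image is a plain numeric
#' `H x W x 3` array with channels ordered red, green, blue. Values are
#' real-valued intensities on the nominal 8-bit scale `[0, 255]`; intermediate
#' pipeline stages may carry values outside that range and [quantize()] maps
#' them back to integers at output time.
#'
#' @param pixels numeric `H x W x 3` array (or an `H x W` matrix, which is
#'   promoted to three identical channels).
#' @return a numeric array of class `rgb_image`.
#' @examples
#' img <- rgb_image(array(128, dim = c(4, 4, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[3L] != 3L) {
    stop("image must have exactly 3 channels (R, G, B), got ", d[3L],
         call. = FALSE)
  }
  if (d[1L] < 1L || d[2L] < 1L) {
    stop("image dimensions must be at least 1 x 1", call. = FALSE)
  }
  if (!is.numeric(pixels)) stop("`pixels` must be numeric", call. = FALSE)
  if (!all(is.finite(pixels))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(pixels, class = c("rgb_image", "array"))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d, range [%.6g, %.6g]\n",
              d[1L], d[2L], min(x), max(x)))
  cat(sprintf("  channel means: R %.3f  G %.3f  B %.3f\n",
              mean(x[, , 1L]), mean(x[, , 2L]), mean(x[, , 3L])))
  invisible(x)
}

as_rgb_array <- function(img) {
  if (inherits(img, "rgb_image")) return(unclass(img))
  rgb_image(img)
  unclass(rgb_image(img))
}

#' Quantize an image to 8-bit integer values
#'
#' Clips every value to `[0, 255]` and rounds half away from zero
#' (`floor(x + 0.5)` for non-negative `x`). This is the common imaging
#' convention; it is stated explicitly because R's `round()` rounds half to
#' even. The operation is idempotent.
#'
#' @param img `rgb_image` or numeric array/matrix.
#' @return object of the same shape with integer-valued (still double-stored)
#'   pixels in `[0, 255]`.
#' @examples
#' quantize(rgb_image(array(c(127.5, 260, -3), dim = c(1, 1, 3))))[1, 1, ]
#' @export
quantize <- function(img) {
  x <- if (inherits(img, "rgb_image")) unclass(img) else img
  if (!all(is.finite(x))) stop("cannot quantize non-finite values", call. = FALSE)
  x <- pmin(pmax(x, 0), 255)
  x <- floor(x + 0.5)  # half away from zero; all values are >= 0 after clipping
  if (inherits(img, "rgb_image")) structure(x, class = class(img)) else x
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

is_quantized <- function(x) all(is.finite(x)) && all(x >= 0 & x <= 255) &&
  all(x == floor(x))

#' Run code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generators never perturb the global random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}
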