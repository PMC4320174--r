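#' Compose two images by pixel-wise averaging
#'
#' The dual Rayleigh stretch yields an over-enhanced (bright) and an
#' under-enhanced (dark) rendition of the same scene; their per-pixel mean is
#' the contrast-corrected result. Averaging is done in real arithmetic before
#' any quantization. No registration is needed: both inputs derive from the
#' same source image, so corresponding pixel locations already align.
#'
#' @param img_a,img_b images of identical dimensions ([rgb_image()] or plain
#'   arrays).
#' @return the element-wise mean, as an [rgb_image()] when either input is
#'   one.
#' @export
compose_average <- function(img_a, img_b) {
  a <- if (inherits(img_a, "rgb_image")) unclass(img_a) else img_a
  b <- if (inherits(img_b, "rgb_image")) unclass(img_b) else img_b
  if (!identical(dim(a), dim(b))) {
    stop("dimension mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  out <- (a + b) / 2
  if (inherits(img_a, "rgb_image") || inherits(img_b, "rgb_image")) {
    out <- rgb_image(out)
  }
  out
}
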