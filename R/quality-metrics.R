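#' Discrete entropy of an 8-bit image
#'
#' `H = -sum p(x) log2 p(x)` over the 256 gray levels, with `0 log 0 := 0`;
#' a proxy for image information content, bounded by 8 bits. The input must
#' already be quantized (see [quantize()]) so the gray-level histogram is
#' well defined.
#'
#' The paper-style tables do not state how color is collapsed, so two modes
#' are offered: `"per_channel_mean"` (default) averages the three per-channel
#' entropies; `"grayscale"` first converts with the usual luma weights
#' (0.299, 0.587, 0.114) and rounds.
#'
#' @param img quantized [rgb_image()].
#' @param channel_mode `"per_channel_mean"` or `"grayscale"`.
#' @return entropy in bits, in `[0, 8]`.
#' @export
img_entropy <- function(img, channel_mode = c("per_channel_mean", "grayscale")) {
  channel_mode <- match.arg(channel_mode)
  x <- as_rgb_array(img)
  if (!is_quantized(x)) {
    stop("entropy requires 8-bit integer values; quantize() the image first",
         call. = FALSE)
  }
  plane_entropy <- function(p) {
    pr <- tabulate(as.integer(p) + 1L, nbins = 256L) / length(p)
    pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }
  if (channel_mode == "grayscale") {
    y <- floor(0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L] + 0.5)
    plane_entropy(y)
  } else {
    mean(vapply(1:3, function(k) plane_entropy(x[, , k]), numeric(1)))
  }
}

#' Mean squared error between two images
#'
#' Mean over all pixels and all three channels of the squared intensity
#' difference; the cumulative squared error between a processed image and
#' its original.
#'
#' @param ref,test quantized [rgb_image()]s of identical dimensions.
#' @return non-negative MSE in squared intensity levels.
#' @export
img_mse <- function(ref, test) {
  a <- as_rgb_array(ref); b <- as_rgb_array(test)
  if (!identical(dim(a), dim(b))) {
    stop("dimension mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10((2^B - 1)^2 / MSE)` in dB for `B` bits per sample. Note
#' the squared peak: the frequently mis-typeset form `20 log10((2^B-1)/MSE)`
#' omits the square root of the MSE and reproduces no published value;
#' reference MSE/PSNR tables for 8-bit imagery are consistent with the form
#' used here to the printed 0.01 dB.
#'
#' @param mse_value non-negative MSE; `0` yields `Inf` (identical images),
#'   not an error.
#' @param bits_per_sample sample depth, default 8.
#' @return PSNR in dB.
#' @examples
#' img_psnr(65025)   # MSE equal to the squared peak: 0 dB
#' @export
img_psnr <- function(mse_value, bits_per_sample = 8L) {
  if (!is.finite(mse_value) || mse_value < 0) {
    stop("mse_value must be a non-negative finite number", call. = FALSE)
  }
  peak <- 2^bits_per_sample - 1
  if (mse_value == 0) return(Inf)
  10 * log10(peak^2 / mse_value)
}

#' Quality report for an image pair
#'
#' Quantizes both images, then reports the entropy of the processed image
#' and the MSE / PSNR against the original.
#'
#' @param original,enhanced images of identical dimensions.
#' @param entropy_mode passed to [img_entropy()].
#' @return a `quality_report` list: `entropy` (bits), `mse`, `psnr` (dB,
#'   `Inf` for identical pairs), `bits_per_sample`.
#' @export
evaluate_quality <- function(original, enhanced,
                             entropy_mode = c("per_channel_mean", "grayscale")) {
  entropy_mode <- match.arg(entropy_mode)
  o <- quantize(rgb_image(as_rgb_array(original)))
  e <- quantize(rgb_image(as_rgb_array(enhanced)))
  m <- img_mse(o, e)
  structure(list(entropy = img_entropy(e, entropy_mode),
                 mse = m,
                 psnr = img_psnr(m),
                 bits_per_sample = 8L),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> entropy %.3f bits | MSE %.1f | PSNR %s\n",
              x$entropy, x$mse,
              if (is.infinite(x$psnr)) "Inf (identical)" else
                sprintf("%.2f dB", x$psnr)))
  invisible(x)
}

#' Write a table of quality reports
#'
#' Serializes a batch of per-image quality measurements (columns `image`,
#' `method`, `entropy`, `mse`, `psnr`) to CSV and/or JSON.
#'
#' @param reports data.frame with the columns above.
#' @param csv,json output paths; `NULL` skips that format.
#' @return `reports`, invisibly.
#' @export
write_quality_reports <- function(reports, csv = NULL, json = NULL) {
  need <- c("image", "method", "entropy", "mse", "psnr")
  if (!all(need %in% names(reports))) {
    stop("reports must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(csv)) utils::write.csv(reports, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(reports, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(reports)
}
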