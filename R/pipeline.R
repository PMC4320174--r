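#' Pipeline configuration
#'
#' Collects the tunable parameters of the enhancement chain. The defaults
#' reproduce the full described pipeline: median-referenced Von Kries
#' balancing, global stretch, mean-split dual Rayleigh stretching with
#' `alpha = 0.4` in quantile mode, averaging composition, and HSV S/V
#' stretching at the 1%/99% percentiles. The skip flags are ablation
#' switches.
#'
#' @param alpha Rayleigh scale as a fraction of the dynamic range.
#' @param mode `"quantile"` (histogram specification, default) or
#'   `"literal"` (transfer-curve evaluation); see
#'   [rayleigh_region_stretch()].
#' @param sv_lo,sv_hi saturation/value percentile limits in percent.
#' @param skip_color_balance,skip_hsv ablation switches.
#' @param verbose emit one message per stage with channel means and split
#'   points.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.4, mode = c("quantile", "literal"),
                            sv_lo = 1, sv_hi = 99,
                            skip_color_balance = FALSE, skip_hsv = FALSE,
                            verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, sv_lo < sv_hi, is.logical(skip_color_balance),
            is.logical(skip_hsv))
  structure(list(alpha = alpha, mode = mode, sv_lo = sv_lo, sv_hi = sv_hi,
                 skip_color_balance = skip_color_balance,
                 skip_hsv = skip_hsv, verbose = verbose),
            class = "pipeline_config")
}

#' Enhance an underwater image
#'
#' Runs the full enhancement chain:
#' 1. channel decomposition and Von Kries balancing toward the median-mean
#'    channel ([apply_color_balance()]);
#' 2. per-channel global min-max stretch to `[0, 255]`
#'    ([global_stretch()]);
#' 3. per-channel split at the (post-stretch) mean and dual Rayleigh
#'    stretching of both regions to the full range
#'    ([dual_stretch_channel()]);
#' 4. recomposition of the three lower-region maps into a bright image and
#'    the three upper-region maps into a dark image, then pixel-wise
#'    averaging ([compose_average()]);
#' 5. HSV saturation/value percentile stretch ([correct_color()]);
#' 6. quantization to 8-bit ([quantize()]).
#'
#' Degenerate (constant-channel) conditions surface as warnings and never
#' abort the chain. The whole computation is deterministic.
#'
#' @param img an [rgb_image()] (or array) with 8-bit-derived values.
#' @param config a [pipeline_config()].
#' @param save_stages optional directory; when given, each intermediate
#'   stage is written there as a PNG for inspection.
#' @return enhanced [rgb_image()], integer-valued in `[0, 255]`, same
#'   dimensions as the input.
#' @export
enhance <- function(img, config = pipeline_config(), save_stages = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- rgb_image(as_rgb_array(img))
  dump_stage <- function(im, name) {
    if (!is.null(save_stages)) {
      dir.create(save_stages, showWarnings = FALSE, recursive = TRUE)
      write_image(im, file.path(save_stages, paste0(name, ".png")))
    }
  }
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))

  if (!config$skip_color_balance) {
    x <- apply_color_balance(x)
    say("color balance: channel means now %.2f / %.2f / %.2f",
        mean(x[, , 1]), mean(x[, , 2]), mean(x[, , 3]))
    dump_stage(x, "01_color_balance")
  }

  params <- rayleigh_params(alpha = config$alpha, mode = config$mode)
  a <- as_rgb_array(x)
  lower <- upper <- array(0, dim = dim(a))
  for (k in 1:3) {
    g <- global_stretch(a[, , k], 0, 255)
    ds <- dual_stretch_channel(g, params)
    lower[, , k] <- ds$lower
    upper[, , k] <- ds$upper
    say("channel %d: stretched, split at %.2f (range [%.2f, %.2f])",
        k, ds$bounds$split, ds$bounds$lo, ds$bounds$hi)
  }
  bright <- rgb_image(lower)
  dark <- rgb_image(upper)
  dump_stage(bright, "02_lower_region_bright")
  dump_stage(dark, "03_upper_region_dark")

  out <- compose_average(bright, dark)
  dump_stage(out, "04_composed")

  if (!config$skip_hsv) {
    out <- correct_color(out, config$sv_lo, config$sv_hi)
    dump_stage(out, "05_hsv_corrected")
  }
  quantize(rgb_image(as_rgb_array(out)))
}

#' Per-channel histogram equalization (baseline)
#'
#' Classic cumulative-histogram equalization applied to each RGB channel
#' independently: level `v` maps to
#' `round(255 * (cdf(v) - cdf_min) / (n - cdf_min))` where `cdf_min` is the
#' CDF at the lowest occupied level. An image with a uniform histogram is a
#' fixed point (up to rounding). Provided as the standard comparison
#' baseline.
#'
#' @param img an [rgb_image()]; quantized internally.
#' @return equalized [rgb_image()], integer-valued in `[0, 255]`.
#' @export
histogram_equalization <- function(img) {
  x <- unclass(quantize(rgb_image(as_rgb_array(img))))
  for (k in 1:3) {
    ch <- as.integer(x[, , k])
    counts <- tabulate(ch + 1L, nbins = 256L)
    cdf <- cumsum(counts)
    n <- length(ch)
    cdf_min <- min(cdf[cdf > 0])
    if (n == cdf_min) next  # constant channel: equalization is the identity
    map <- floor(255 * (cdf - cdf_min) / (n - cdf_min) + 0.5)
    x[, , k] <- array(map[ch + 1L], dim = dim(x)[1:2])
  }
  rgb_image(x)
}

#' Batch evaluation over a scene suite
#'
#' Runs the proposed pipeline and/or the HE baseline on each degraded image
#' of a [scene_suite()] (or any list of `list(clean, degraded)` pairs) and
#' collects quality metrics of each output against its degraded input.
#'
#' @param suite list of scene pairs as returned by [scene_suite()].
#' @param methods subset of `c("proposed", "he")`.
#' @param config [pipeline_config()] used for the proposed method.
#' @param entropy_mode passed to [evaluate_quality()].
#' @return data.frame with columns `image`, `method`, `entropy`, `mse`,
#'   `psnr` (one row per image and method), suitable for
#'   [write_quality_reports()].
#' @export
batch_evaluate <- function(suite, methods = c("proposed", "he"),
                           config = pipeline_config(),
                           entropy_mode = "per_channel_mean") {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (i in seq_along(suite)) {
    degraded <- suite[[i]]$degraded
    for (m in methods) {
      out <- switch(m,
                    proposed = enhance(degraded, config),
                    he = histogram_equalization(degraded))
      q <- evaluate_quality(degraded, out, entropy_mode)
      rows[[length(rows) + 1L]] <- data.frame(
        image = sprintf("scene_%02d", i), method = m,
        entropy = q$entropy, mse = q$mse, psnr = q$psnr)
    }
  }
  do.call(rbind, rows)
}
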