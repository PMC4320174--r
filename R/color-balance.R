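#' Mean intensity of one color channel
#'
#' Arithmetic mean of all `M x N` pixel values of a channel; the quantity the
#' Von Kries gains are computed from.
#'
#' @param channel numeric matrix (one color plane).
#' @return scalar mean.
#' @export
channel_mean <- function(channel) {
  if (length(channel) == 0L) stop("empty channel", call. = FALSE)
  mean(channel)
}

#' Von Kries gains toward the median-mean channel
#'
#' The classic Von Kries white-balance variant scales channels toward the
#' dominant (maximum-mean) channel, which forces a very large multiplier on
#' the weakest channel of a blue-green underwater scene and over-corrects its
#' color. Here the channel whose mean is the *median* of the three is used as
#' the reference instead: the minimum-mean channel is multiplied by
#' `A = median/min >= 1` and the maximum-mean channel by
#' `B = median/max <= 1`; the reference channel is left untouched.
#'
#' Ties are broken by ranking channels on (mean, then fixed order R < G < B),
#' so equal means give identity gains deterministically.
#'
#' @param r_avg,g_avg,b_avg strictly positive channel means.
#' @return a `channel_gains` list: `reference` ("R", "G" or "B") and `gains`,
#'   a named length-3 vector of per-channel multipliers.
#' @examples
#' compute_gains(50, 100, 150)   # A = 2 on red, B = 2/3 on blue
#' @export
compute_gains <- function(r_avg, g_avg, b_avg) {
  means <- c(R = r_avg, G = g_avg, B = b_avg)
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop("channel means must be strictly positive; got (",
         paste(signif(means, 6), collapse = ", "),
         ") - a zero-mean channel cannot be rescaled to a positive target",
         call. = FALSE)
  }
  ord <- order(means)           # stable: ties keep R < G < B order
  med <- means[[ord[2L]]]
  gains <- c(R = 1, G = 1, B = 1)
  gains[ord[1L]] <- med / means[[ord[1L]]]
  gains[ord[3L]] <- med / means[[ord[3L]]]
  structure(list(reference = names(means)[ord[2L]], gains = gains),
            class = "channel_gains")
}

#' @export
print.channel_gains <- function(x, ...) {
  cat(sprintf("<channel_gains> reference %s; R %.4f  G %.4f  B %.4f\n",
              x$reference, x$gains[["R"]], x$gains[["G"]], x$gains[["B"]]))
  invisible(x)
}

#' Balance channel means toward the median-mean channel
#'
#' Applies the gains from [compute_gains()] computed on the input image
#' itself (one-shot, no iteration). After balancing, all three channel means
#' equal the median of the original means. Values are *not* clipped: the
#' subsequent global stretch renormalizes, and clipping here would destroy
#' the mean-equalization property.
#'
#' @param img an [rgb_image()] with positive channel means.
#' @return balanced [rgb_image()] (real-valued; may exceed 255).
#' @export
apply_color_balance <- function(img) {
  x <- as_rgb_array(img)
  g <- compute_gains(mean(x[, , 1L]), mean(x[, , 2L]), mean(x[, , 3L]))
  for (k in 1:3) x[, , k] <- x[, , k] * g$gains[[k]]
  rgb_image(x)
}
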