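#' RGB / HSV conversion (hexcone model)
#'
#' Standard hexcone conversions operating on whole planes. `rgb_to_hsv`
#' expects intensities in `[0, 255]` (callers clip first) and returns hue in
#' degrees `[0, 360)` with the achromatic hue defined as 0, and saturation
#' and value in `[0, 1]`. `hsv_to_rgb` inverts it; a round trip reproduces
#' the input to well within 0.5 intensity levels.
#'
#' @param img an [rgb_image()] with values in `[0, 255]`.
#' @param hsv an `hsv_image` list with matrices `h`, `s`, `v`.
#' @return `rgb_to_hsv`: an `hsv_image`; `hsv_to_rgb`: an [rgb_image()].
#' @export
rgb_to_hsv <- function(img) {
  x <- as_rgb_array(img) / 255
  nr <- dim(x)[1L]; nc <- dim(x)[2L]
  r <- matrix(x[, , 1L], nr, nc)
  g <- matrix(x[, , 2L], nr, nc)
  b <- matrix(x[, , 3L], nr, nc)
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  s <- ifelse(v > 0, d / v, 0)
  h <- matrix(0, nr, nc)
  chrom <- d > 0
  rmax <- chrom & v == r
  gmax <- chrom & !rmax & v == g
  bmax <- chrom & !rmax & !gmax
  h[rmax] <- 60 * (((g[rmax] - b[rmax]) / d[rmax]) %% 6)
  h[gmax] <- 60 * ((b[gmax] - r[gmax]) / d[gmax] + 2)
  h[bmax] <- 60 * ((r[bmax] - g[bmax]) / d[bmax] + 4)
  h <- h %% 360
  structure(list(h = h, s = s, v = v), class = "hsv_image")
}

#' @rdname rgb_to_hsv
#' @export
hsv_to_rgb <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_image"))
  h <- hsv$h %% 360; s <- hsv$s; v <- hsv$v
  c_ <- v * s
  hp <- h / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- v - c_
  sector <- pmin(floor(hp), 5)
  r <- g <- b <- matrix(0, nrow(h), ncol(h))
  pick <- function(sec) sector == sec
  r[pick(0)] <- c_[pick(0)]; g[pick(0)] <- x[pick(0)]
  r[pick(1)] <- x[pick(1)];  g[pick(1)] <- c_[pick(1)]
  g[pick(2)] <- c_[pick(2)]; b[pick(2)] <- x[pick(2)]
  g[pick(3)] <- x[pick(3)];  b[pick(3)] <- c_[pick(3)]
  r[pick(4)] <- x[pick(4)];  b[pick(4)] <- c_[pick(4)]
  r[pick(5)] <- c_[pick(5)]; b[pick(5)] <- x[pick(5)]
  out <- array(0, dim = c(nrow(h), ncol(h), 3L))
  out[, , 1L] <- (r + m) * 255
  out[, , 2L] <- (g + m) * 255
  out[, , 3L] <- (b + m) * 255
  rgb_image(out)
}

#' Percentile-limited stretch of a unit-range plane
#'
#' Stretches a saturation or value plane between its `p_lo`-th and `p_hi`-th
#' percentiles onto `[0, 1]`, clipping outside. Limiting the stretch to the
#' 1%/99% points (the defaults) protects against a single extreme pixel
#' dictating the range and deliberately saturates about 1% of pixels at each
#' end. Percentiles use the linear-interpolation definition
#' (`stats::quantile` type 7). A (near-)constant plane is returned unchanged
#' with a warning.
#'
#' @param plane numeric matrix with values in `[0, 1]`.
#' @param p_lo,p_hi percentile limits in percent, `p_lo < p_hi`.
#' @return stretched plane in `[0, 1]`.
#' @export
percentile_stretch <- function(plane, p_lo = 1, p_hi = 99) {
  if (!(p_lo < p_hi)) stop("need p_lo < p_hi", call. = FALSE)
  q <- stats::quantile(plane, c(p_lo, p_hi) / 100, names = FALSE, type = 7)
  if (q[2L] == q[1L]) {
    warning("near-constant plane: percentile stretch is undefined, ",
            "returning input", call. = FALSE)
    return(plane)
  }
  pmin(pmax((plane - q[1L]) / (q[2L] - q[1L]), 0), 1)
}

#' HSV color correction
#'
#' Converts to HSV, stretches the saturation and value planes independently
#' between their 1st and 99th percentiles ([percentile_stretch()]), leaves
#' hue untouched, and converts back to RGB. Out-of-range reals from earlier
#' stages are clipped to `[0, 255]` before conversion.
#'
#' @param img an [rgb_image()].
#' @param p_lo,p_hi percentile limits passed to [percentile_stretch()].
#' @return color-corrected [rgb_image()] with values in `[0, 255]`.
#' @export
correct_color <- function(img, p_lo = 1, p_hi = 99) {
  x <- rgb_image(clip255(as_rgb_array(img)))
  hsv <- rgb_to_hsv(x)
  hsv$s <- percentile_stretch(hsv$s, p_lo, p_hi)
  hsv$v <- percentile_stretch(hsv$v, p_lo, p_hi)
  hsv_to_rgb(hsv)
}
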