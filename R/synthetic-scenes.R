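#' Specification of a synthetic underwater scene
#'
#' Parameters of the paired clean/degraded scene generator. The degradation
#' model is deliberately simple — per-channel attenuation, additive
#' blue-green veiling light, contrast compression about the channel mean,
#' and mild Gaussian sensor noise — because the enhancement method only
#' needs its statistical signature (strong blue-green cast with the red mean
#' far below green/blue, compressed dynamic range, coexisting bright and
#' dark regions), not a physically accurate radiative-transfer model.
#'
#' Defaults emulate a few meters of clear tropical water: red retains about a
#' quarter of its signal while green/blue retain most of theirs, the veiling
#' light is blue-green, and sensor noise is a couple of intensity levels.
#'
#' @param height,width scene size in pixels.
#' @param attenuation fraction of signal retained per channel (R, G, B);
#'   red lowest.
#' @param veil additive veiling-light color, RGB in `[0, 255]`.
#' @param veil_weight mixing weight of the veiling light in `[0, 1]`.
#' @param contrast_compression range shrink factor about the channel mean,
#'   in `(0, 1]`.
#' @param noise_sd Gaussian sensor-noise standard deviation in intensity
#'   levels.
#' @param seed integer; fully determines the generated pair.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(height = 96L, width = 128L,
                       attenuation = c(0.25, 0.70, 0.85),
                       veil = c(35, 140, 165),
                       veil_weight = 0.25,
                       contrast_compression = 0.6,
                       noise_sd = 2,
                       seed = 1L) {
  stopifnot(height >= 1, width >= 1,
            length(attenuation) == 3L, all(attenuation >= 0 & attenuation <= 1),
            length(veil) == 3L, all(veil >= 0 & veil <= 255),
            veil_weight >= 0, veil_weight <= 1,
            contrast_compression > 0, contrast_compression <= 1,
            noise_sd >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 attenuation = as.numeric(attenuation),
                 veil = as.numeric(veil),
                 veil_weight = veil_weight,
                 contrast_compression = contrast_compression,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Elliptical region mask
#'
#' Logical `H x W` mask of pixels whose centers satisfy
#' `((col - cx)/rx)^2 + ((row - cy)/ry)^2 <= 1`. Used to rasterize the
#' coral/fish blobs of the synthetic scenes; exported so the rasterization
#' can be checked against its analytic area.
#'
#' @param height,width mask size.
#' @param cx,cy ellipse center (column, row).
#' @param rx,ry semi-axes in pixels.
#' @return logical matrix.
#' @export
ellipse_mask <- function(height, width, cx, cy, rx, ry) {
  row <- matrix(seq_len(height), height, width)
  col <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((col - cx) / rx)^2 + ((row - cy) / ry)^2 <= 1
}

#' Generate a clean synthetic underwater scene
#'
#' Deterministic (seed-driven) composite of a smooth illumination gradient,
#' a bright sand-like band along the bottom, and several textured elliptical
#' "coral/fish" blobs with distinct hues — guaranteeing bright and dark
#' areas in one scene and a rich (>= 64 gray levels per channel) intensity
#' distribution. The blob parameters used are attached as attribute
#' `"blobs"` (a data.frame of centers and semi-axes).
#'
#' @param spec a [scene_spec()].
#' @return clean [rgb_image()] with integer-valued pixels in `[0, 255]`.
#' @export
make_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    row <- matrix(seq_len(h), h, w)
    col <- matrix(seq_len(w), h, w, byrow = TRUE)
    # smooth illumination: brighter toward the top and one side
    base_v <- 60 + 90 * (1 - row / h) + 30 * col / w
    img <- array(0, dim = c(h, w, 3L))
    img[, , 1L] <- base_v * 0.9
    img[, , 2L] <- base_v * 1.0
    img[, , 3L] <- base_v * 1.05
    # bright sand band along the bottom quarter, with ripple texture
    sand <- row > 0.75 * h
    ripple <- 15 * sin(2 * pi * col / 12 + 2 * pi * row / 40)
    for (k in 1:3) {
      plane <- img[, , k]
      plane[sand] <- (c(225, 215, 195)[k] + ripple[sand])
      img[, , k] <- plane
    }
    # textured elliptical blobs with distinct hues
    n_blob <- 5L
    blobs <- data.frame(
      cx = stats::runif(n_blob, 0.1 * w, 0.9 * w),
      cy = stats::runif(n_blob, 0.1 * h, 0.65 * h),
      rx = stats::runif(n_blob, 0.06 * w, 0.16 * w),
      ry = stats::runif(n_blob, 0.06 * h, 0.18 * h)
    )
    hue <- (seq_len(n_blob) - 1) * 360 / n_blob + stats::runif(n_blob, 0, 20)
    sat <- stats::runif(n_blob, 0.55, 0.9)
    val <- stats::runif(n_blob, 0.35, 0.95)
    for (i in seq_len(n_blob)) {
      m <- ellipse_mask(h, w, blobs$cx[i], blobs$cy[i], blobs$rx[i], blobs$ry[i])
      rgb1 <- grDevices::col2rgb(grDevices::hsv(hue[i] %% 360 / 360,
                                                sat[i], val[i]))
      tex <- 12 * sin(2 * pi * (row + 3 * i) / 9)[m]
      for (k in 1:3) {
        plane <- img[, , k]
        plane[m] <- rgb1[k] + tex
        img[, , k] <- plane
      }
    }
    out <- quantize(rgb_image(img))
    attr(out, "blobs") <- blobs
    out
  })
}

#' Degrade a clean scene into an underwater-looking one
#'
#' Per channel `c`:
#' `out = (1 - veil_weight) * attenuation_c * compress(clean_c)
#'        + veil_weight * veil_c + noise`, clipped to `[0, 255]`, where
#' `compress` shrinks the range about the channel mean by
#' `contrast_compression` and the noise is seeded Gaussian with standard
#' deviation `noise_sd`. With identity parameters (attenuation 1, weight 0,
#' compression 1, noise 0) the output equals the input.
#'
#' @param clean clean [rgb_image()], e.g. from [make_scene()].
#' @param spec the [scene_spec()] holding the degradation parameters; the
#'   noise stream is seeded from `spec$seed` (offset so it is independent of
#'   the scene-layout stream).
#' @return degraded [rgb_image()] (real-valued in `[0, 255]`).
#' @export
degrade_scene <- function(clean, spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  x <- as_rgb_array(clean)
  out <- array(0, dim = dim(x))
  for (k in 1:3) {
    ch <- x[, , k]
    m <- mean(ch)
    comp <- m + (ch - m) * spec$contrast_compression
    out[, , k] <- (1 - spec$veil_weight) * spec$attenuation[k] * comp +
      spec$veil_weight * spec$veil[k]
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 10000L,
                       stats::rnorm(length(out), sd = spec$noise_sd))
    out <- out + array(noise, dim = dim(out))
  }
  rgb_image(clip255(out))
}

#' Seeded suite of clean/degraded scene pairs
#'
#' Generates `n` scene specifications whose layout seeds derive from a base
#' seed, and the corresponding clean and degraded images; the default suite
#' of 20 scenes is what the package's behavioral checks run on.
#'
#' @param n number of scenes.
#' @param seed base seed; scene `i` uses `seed + i`.
#' @param ... further arguments forwarded to [scene_spec()].
#' @return list of `n` elements, each `list(spec, clean, degraded)`.
#' @export
scene_suite <- function(n = 20L, seed = 7L, ...) {
  lapply(seq_len(n), function(i) {
    sp <- scene_spec(seed = as.integer(seed) + i, ...)
    cl <- make_scene(sp)
    list(spec = sp, clean = cl, degraded = degrade_scene(cl, sp))
  })
}

#' Write a clean/degraded pair to disk
#'
#' Emits `<stem>_clean.png`, `<stem>_degraded.png` and a JSON sidecar
#' `<stem>_spec.json` describing the [scene_spec()].
#'
#' @param spec a [scene_spec()].
#' @param stem output path stem.
#' @return named character vector of the three paths, invisibly.
#' @export
write_scene_pair <- function(spec, stem) {
  cl <- make_scene(spec)
  dg <- degrade_scene(cl, spec)
  paths <- c(clean = paste0(stem, "_clean.png"),
             degraded = paste0(stem, "_degraded.png"),
             spec = paste0(stem, "_spec.json"))
  write_image(cl, paths[["clean"]])
  write_image(dg, paths[["degraded"]])
  jsonlite::write_json(unclass(spec), paths[["spec"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
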