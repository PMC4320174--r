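test_that("scene generation is bitwise deterministic under a fixed seed", {
  sp <- scene_spec(seed = 5)
  a <- make_scene(sp)
  b <- make_scene(sp)
  expect_identical(unclass(a), unclass(b))
  expect_identical(unclass(degrade_scene(a, sp)), unclass(degrade_scene(b, sp)))
  # a different seed gives a different layout
  expect_false(identical(unclass(a), unclass(make_scene(scene_spec(seed = 6)))))
})

test_that("seeded generation does not perturb the caller's RNG stream", {
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  invisible(make_scene(scene_spec(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("clean scenes are rich: many gray levels, bright and dark areas", {
  img <- make_scene(scene_spec(seed = 3))
  for (k in 1:3) {
    expect_gte(length(unique(as.vector(img[, , k]))), 64)
  }
  expect_gt(max(img), 200)   # sand-like bright region
  expect_lt(min(img), 80)    # dark region coexists
})

test_that("blob rasterization matches an independent mask evaluation", {
  sp <- scene_spec(seed = 8)
  img <- make_scene(sp)
  blobs <- attr(img, "blobs")
  expect_equal(nrow(blobs), 5)
  for (i in seq_len(nrow(blobs))) {
    m <- ellipse_mask(sp$height, sp$width,
                      blobs$cx[i], blobs$cy[i], blobs$rx[i], blobs$ry[i])
    # brute-force double loop over pixel centers
    count <- 0L
    for (r in seq_len(sp$height)) for (c in seq_len(sp$width)) {
      if (((c - blobs$cx[i]) / blobs$rx[i])^2 +
          ((r - blobs$cy[i]) / blobs$ry[i])^2 <= 1) count <- count + 1L
    }
    expect_identical(sum(m), count)
    # rasterized area tracks the analytic ellipse area to boundary accuracy
    expect_lt(abs(sum(m) - pi * blobs$rx[i] * blobs$ry[i]),
              2 * (blobs$rx[i] + blobs$ry[i]) + 4)
  }
})

test_that("identity degradation parameters reproduce the clean scene", {
  sp <- scene_spec(attenuation = c(1, 1, 1), veil_weight = 0,
                   contrast_compression = 1, noise_sd = 0, seed = 2)
  cl <- make_scene(sp)
  expect_equal(unclass(degrade_scene(cl, sp)), unclass(cl),
               ignore_attr = TRUE)
})

test_that("default degradation reproduces the underwater problem signature", {
  for (seed in c(1, 11, 21)) {
    sp <- scene_spec(seed = seed)
    cl <- make_scene(sp)
    dg <- quantize(degrade_scene(cl, sp))
    # strong blue-green cast: red mean far below blue mean
    expect_lt(mean(dg[, , 1]), 0.6 * mean(dg[, , 3]))
    expect_lt(mean(dg[, , 1]), mean(dg[, , 2]))
    # information loss
    expect_lt(img_entropy(dg), img_entropy(cl))
    # compressed dynamic range (plus a noise allowance)
    for (k in 1:3) {
      clean_range <- diff(range(cl[, , k]))
      expect_lt(diff(range(dg[, , k])),
                sp$contrast_compression * clean_range + 8 * sp$noise_sd + 1)
    }
  }
})

test_that("scene pairs serialize to PNG plus a JSON sidecar", {
  dir <- withr::local_tempdir()
  sp <- scene_spec(seed = 4)
  paths <- write_scene_pair(sp, file.path(dir, "scene"))
  expect_true(all(file.exists(paths)))
  back <- read_image(paths[["clean"]])
  expect_equal(unclass(back), unclass(quantize(make_scene(sp))),
               ignore_attr = TRUE, tolerance = 0)
  side <- jsonlite::read_json(paths[["spec"]], simplifyVector = TRUE)
  expect_equal(side$seed, 4)
  expect_equal(side$attenuation, sp$attenuation)
})
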