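test_that("global stretch maps extremes to the output range (affine)", {
  ch <- matrix(c(50, 150, 100, 120), 2, 2)
  out <- global_stretch(ch)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 255)
  expect_equal(out[1, 2], 127.5)
  full <- matrix(c(0, 255, 17, 180), 2, 2)
  expect_equal(global_stretch(full), full)
  expect_warning(out_c <- global_stretch(matrix(9, 2, 2)), "constant")
  expect_equal(out_c, matrix(9, 2, 2))
})

test_that("global stretch agrees with the elementwise oracle", {
  set.seed(11)
  for (rep in 1:4) {
    ch <- matrix(runif(9, 5, 240), 3, 3)
    expect_equal(global_stretch(ch), oracle_affine_stretch(ch),
                 tolerance = 1e-12)
  }
})

test_that("Rayleigh CDF and quantile are exact closed forms and inverses", {
  sigma <- 102
  expect_equal(rayleigh_cdf(sigma, sigma), 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(rayleigh_icdf(0, sigma), 0)
  for (x in c(0.1 * sigma, sigma, 3 * sigma)) {
    expect_equal(rayleigh_icdf(rayleigh_cdf(x, sigma), sigma), x,
                 tolerance = 1e-12)
  }
  expect_error(rayleigh_icdf(1, sigma), "diverges")
  expect_error(rayleigh_cdf(10, -1), "sigma")
})

test_that("quantile-mode region stretch hits endpoints and the sigma point", {
  p <- rayleigh_params(alpha = 0.4)
  ch <- matrix(c(0, 128, 30, 90), 2, 2)
  out <- rayleigh_region_stretch(ch, 0, 128, p)
  expect_identical(out[1, 1], 0)
  expect_identical(out[2, 1], 255)
  # the input fraction u = F(sigma)/F(255) must land exactly on sigma = 102
  u_sigma <- rayleigh_cdf(102, 102) / rayleigh_cdf(255, 102)
  out2 <- rayleigh_region_stretch(matrix(u_sigma * 128, 1, 1), 0, 128, p)
  expect_equal(out2[1, 1], 102, tolerance = 1e-9)
  expect_error(rayleigh_region_stretch(ch, 128, 128, p), "degenerate region")
})

test_that("quantile-mode map agrees with numeric CDF inversion (oracle)", {
  p <- rayleigh_params(alpha = 0.4)
  vals <- c(0, 60, 128, 200, 255)
  got <- rayleigh_region_stretch(matrix(vals, 1), 0, 128, p)
  want <- oracle_rayleigh_map(vals, 0, 128, alpha = 0.4)
  expect_equal(as.vector(got), want, tolerance = 1e-7)
  # a second region and alpha
  p2 <- rayleigh_params(alpha = 0.25)
  vals2 <- seq(40, 220, by = 20)
  expect_equal(as.vector(rayleigh_region_stretch(matrix(vals2, 1), 50, 210, p2)),
               oracle_rayleigh_map(vals2, 50, 210, alpha = 0.25),
               tolerance = 1e-7)
})

test_that("quantile-mode map is monotonic and range-bounded", {
  p <- rayleigh_params()
  x <- matrix(seq(-20, 280, length.out = 301), 1)
  y <- as.vector(rayleigh_region_stretch(x, 10, 230, p))
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 255))
})

test_that("quantile-mode output of uniform samples follows the truncated Rayleigh law", {
  set.seed(2024)
  n <- 100000
  samp <- matrix(runif(n, 10, 200), 1)
  p <- rayleigh_params(alpha = 0.4)
  y <- as.vector(rayleigh_region_stretch(samp, 10, 200, p))
  sigma <- 0.4 * 255
  trunc_cdf <- function(x) rayleigh_cdf(pmin(x, 255), sigma) / rayleigh_cdf(255, sigma)
  ks <- suppressWarnings(stats::ks.test(y, trunc_cdf))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("literal mode evaluates the transfer curve and spans the range", {
  p <- rayleigh_params(alpha = 0.4, mode = "literal")
  ch <- matrix(seq(0, 128, length.out = 64), 8, 8)
  out <- rayleigh_region_stretch(ch, 0, 128, p)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  # curve peaks where the scaled value equals sigma, i.e. inside the range:
  # the map is non-monotonic by construction
  y <- as.vector(rayleigh_region_stretch(matrix(seq(0, 128, 1), 1), 0, 128, p))
  expect_true(any(diff(y) < 0))
})

test_that("split_at_mean returns extremes and the brute-force mean", {
  ch <- matrix(runif(64, 0, 255), 8, 8)
  b <- split_at_mean(ch)
  expect_equal(b$lo, min(ch))
  expect_equal(b$hi, max(ch))
  expect_equal(b$split, sum(as.vector(ch)) / 64)
  bc <- split_at_mean(matrix(7, 2, 2))
  expect_true(bc$degenerate)
  expect_equal(c(bc$lo, bc$split, bc$hi), c(7, 7, 7))
})

test_that("dual stretch saturates across the split and lower dominates upper", {
  set.seed(5)
  ch <- matrix(runif(16, 20, 240), 4, 4)
  ds <- dual_stretch_channel(ch)
  m <- mean(ch)
  expect_true(all(ds$lower[ch >= m] == 255))
  expect_true(all(ds$upper[ch <= m] == 0))
  expect_true(all(ds$lower >= ds$upper))
  # per-pixel oracle for both maps
  expect_equal(as.vector(ds$lower),
               oracle_rayleigh_map(as.vector(ch), min(ch), m, 0.4),
               tolerance = 1e-7)
  expect_equal(as.vector(ds$upper),
               oracle_rayleigh_map(as.vector(ch), m, max(ch), 0.4),
               tolerance = 1e-7)
  expect_warning(dc <- dual_stretch_channel(matrix(3, 2, 2)), "constant")
  expect_equal(dc$lower, matrix(3, 2, 2))
})
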