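# preprocessing, watershed and the correction model

test_that("bilateral filter matches a direct double-loop oracle", {
  set.seed(21)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  img[, 17:32] <- img[, 17:32] + 120
  out <- denoise_bilateral(img, spatial_sigma = 1.5, range_sigma = 20)
  # brute-force reference with replicated borders
  ssig <- 1.5; rsig <- 20; r <- ceiling(2 * ssig)
  ref <- img
  for (y in 1:32) for (x in 1:32) {
    num <- 0; den <- 0
    for (dy in -r:r) for (dx in -r:r) {
      yy <- min(max(y + dy, 1), 32); xx <- min(max(x + dx, 1), 32)
      w <- exp(-(dy^2 + dx^2) / (2 * ssig^2)) *
        exp(-(img[yy, xx] - img[y, x])^2 / (2 * rsig^2))
      num <- num + w * img[yy, xx]; den <- den + w
    }
    ref[y, x] <- num / den
  }
  expect_equal(out, ref, tolerance = 1e-10)
})

test_that("bilateral filter preserves edges and reduces noise", {
  expect_equal(denoise_bilateral(matrix(50, 10, 10), 2, 5),
               matrix(50, 10, 10))
  set.seed(22)
  step <- matrix(rep(c(40, 200), each = 16 * 32), 32, 32)
  noisy <- step + matrix(rnorm(1024, 0, 8), 32, 32)
  sm <- denoise_bilateral(noisy, 2)
  # edge column stays the gradient maximum
  grad <- colMeans(abs(sm[, -1] - sm[, -32]))
  expect_equal(which.max(grad), 16)
  expect_lt(var(as.vector(sm - step)), var(as.vector(noisy - step)))
  expect_error(denoise_bilateral(noisy, -1), "positive")
})

test_that("CLAHE keeps constants and expands low-contrast range", {
  const <- clahe_enhance(matrix(100, 64, 64))
  expect_lt(diff(range(const)), 1e-6)
  ramp <- matrix(rep(seq(100, 140, length.out = 64), each = 64), 64, 64,
                 byrow = FALSE)
  out <- clahe_enhance(t(ramp))
  expect_gte(diff(range(out)), 40 - 1e-6)
  expect_error(clahe_enhance(matrix(1, 4, 4), tiles = 8), "tile")
})

test_that("watershed splits touching discs without over-splitting", {
  one <- disc_mask(60, 60, 30, 30, 12)
  expect_equal(max(watershed_split(one)), 1)
  two <- disc_mask(60, 90, 30, 25, 12) + disc_mask(60, 90, 30, 65, 12)
  expect_equal(max(watershed_split(pmin(two, 1))), 2)
  # overlapping discs, centers 1.5 r apart
  r <- 12
  ovl <- pmin(disc_mask(60, 90, 30, 35, r) + disc_mask(60, 90, 30, 53, r), 1)
  lab <- watershed_split(ovl)
  expect_equal(max(lab), 2)
  props <- phenocount:::object_props(lab)
  d1 <- min(sqrt((props$x - 35)^2 + (props$y - 30)^2))
  d2 <- min(sqrt((props$x - 53)^2 + (props$y - 30)^2))
  expect_lt(d1, r / 2)
  expect_lt(d2, r / 2)
  empty <- watershed_split(matrix(0, 20, 20))
  expect_equal(max(empty), 0)
})

test_that("correction model learns factors and beats the always-1 baseline", {
  # fixtures: discs at varying contrast over a lifted background, so the
  # optimal triangle correction differs from 1
  set.seed(77)
  make_fix <- function() {
    m <- disc_mask(64, 64, sample(20:44, 1), sample(20:44, 1), 10)
    bg <- runif(1, 20, 60)
    fg <- bg + runif(1, 60, 160)
    img <- m * fg + (1 - m) * bg + matrix(rnorm(4096, 0, 6), 64, 64)
    list(img = pmin(pmax(img, 0), 255), mask = m)
  }
  fx <- replicate(56, make_fix(), simplify = FALSE)
  imgs <- lapply(fx, `[[`, "img")
  msks <- lapply(fx, `[[`, "mask")
  cm <- train_correction_model(imgs, msks, seed = 5, ntree = 150)
  expect_s3_class(cm, "correction_model")
  expect_lt(cm$mae, cm$baseline_mae)
  # determinism: same seed, same metrics
  cm2 <- train_correction_model(imgs, msks, seed = 5, ntree = 150)
  expect_equal(cm$rmse, cm2$rmse)
  expect_equal(cm$mae, cm2$mae)
  # predictions stay inside the grid for arbitrary feature vectors
  set.seed(6)
  rnd <- matrix(rnorm(20 * 166, 0, 50), 20, 166)
  p <- predict_correction_factor(rnd, cm)
  expect_true(all(p >= 0.2 & p <= 3.0))
  p0 <- predict_correction_factor(rep(0, 166), cm)
  expect_true(is.finite(p0) && p0 > 0)
  # too few fixtures errors; degenerate fixtures are dropped with a warning
  expect_error(train_correction_model(imgs[1:10], msks[1:10], seed = 1),
               "at least 50")
  expect_warning(
    expect_error(
      train_correction_model(c(imgs[1:20], list(matrix(5, 64, 64))),
                             c(msks[1:20], list(matrix(0, 64, 64))),
                             seed = 1),
      "at least 50"),
    "degenerate")
})

test_that("corrected_threshold composes raw value and prediction", {
  img <- matrix(c(rep(30, 70), rep(220, 30)), 10, 10)
  d <- corrected_threshold(img)          # no model: factor 1
  expect_equal(d$correction_factor, 1)
  expect_equal(d$final_threshold, d$raw_threshold)
})

test_that("grayscale conversion uses luminance weights and rejects >3 channels", {
  g <- matrix(runif(36, 0, 255), 6, 6)
  expect_identical(to_gray(g), g)                    # grayscale: identity
  white <- array(1, dim = c(4, 4, 3))
  expect_equal(to_gray(white), matrix(1, 4, 4))      # pure white -> max
  red <- array(0, dim = c(4, 4, 3)); red[, , 1] <- 255
  expect_equal(to_gray(red), matrix(0.299 * 255, 4, 4))
  expect_error(to_gray(array(0, dim = c(4, 4, 5))), "channel")
})
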