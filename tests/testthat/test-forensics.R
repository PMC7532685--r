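# forensics: robust PCA, detectors, block noise, tamper localization

test_that("robust PCA keeps clean Gaussian clouds mostly regular", {
  set.seed(50)
  flagged <- c()
  for (s in 1:3) {
    z <- rnorm(300)
    X <- cbind(z, matrix(rnorm(300 * 20, 0, 0.2), 300, 20))
    m <- fit_robust_pca(X, k = 1, alpha = 0.70, seed = s)
    d <- diagnose(X, m)
    expect_true(all(d$category %in% c("regular", "good_leverage",
                                      "orthogonal_outlier", "bad_leverage")))
    flagged <- c(flagged, mean(d$anomalous))
    expect_gte(mean(d$category == "regular"), 0.90)
  }
  expect_lte(mean(flagged), 0.075)
})

test_that("robust PCA rejects degenerate input", {
  X <- matrix(rep(c(1, 2, 3), each = 20), 20, 3)
  expect_error(fit_robust_pca(X), "degenerate")
  expect_error(fit_robust_pca(matrix(rnorm(8), 4, 2)), "too few")
})

test_that("robust fit resists 30% orthogonal contamination", {
  set.seed(51)
  n <- 200
  z <- rnorm(n)
  X <- cbind(z, matrix(rnorm(n * 10, 0, 0.2), n, 10))
  bad <- 1:60                             # 30% shifted off-subspace
  X[bad, 5] <- X[bad, 5] + 8
  m <- fit_robust_pca(X, k = 1, alpha = 0.70, seed = 1)
  d <- diagnose(X, m)
  expect_gte(mean(d$orthogonal_distance[bad] > m$cutoff_od), 0.95)
  # robust center of the clean coordinates stays near zero
  clean_mean <- mean(X[-bad, 5])
  expect_lt(abs(m$col_med[5] - clean_mean),
            2 * sd(X[-bad, 5]) / sqrt(n - 60) + 0.1)
})

test_that("diagnosis categories follow the 2x2 distance rule", {
  set.seed(52)
  z <- rnorm(200)
  X <- cbind(z, matrix(rnorm(200 * 5, 0, 0.2), 200, 5))
  m <- fit_robust_pca(X, k = 1, seed = 2)
  # a point far along the retained component only: good leverage.
  # construct it exactly on the fitted PC line (white-box inverse mapping)
  z_t <- m$center + 10 * sqrt(m$eigenvalues[1]) * m$loadings[, 1]
  xs <- as.vector(m$V %*% z_t) + m$svd_center
  far <- xs * m$col_mad + m$col_med
  d1 <- diagnose(far, m)
  expect_equal(d1$category, "good_leverage")
  expect_false(d1$anomalous)
  # category is a pure function of the two distances
  d <- diagnose(X, m)
  recomputed <- ifelse(d$score_distance > m$cutoff_sd &
                         d$orthogonal_distance > m$cutoff_od, "bad_leverage",
                ifelse(d$score_distance > m$cutoff_sd, "good_leverage",
                ifelse(d$orthogonal_distance > m$cutoff_od,
                       "orthogonal_outlier", "regular")))
  expect_equal(d$category, recomputed)
})

test_that("anomaly screen flags generator anomalies end to end", {
  X <- clean_features()
  m <- fit_robust_pca(X, k = 1, alpha = 0.70, seed = 3)
  d <- diagnose(X, m)
  expect_lte(mean(d$anomalous), 0.075)
  base <- small_set()[[1]]$fov$nucleus
  anomalies <- rbind(
    extract_features(make_anomaly(base, "noise", seed = 1)),
    extract_features(make_anomaly(base, "saturated")),
    extract_features(make_anomaly(base, "off_modality")))
  da <- diagnose(anomalies, m)
  expect_gte(mean(da$anomalous), 2 / 3)
})

test_that("detectors separate a separable problem and are reproducible", {
  set.seed(53)
  X <- matrix(rnorm(120 * 8), 120, 8)
  y <- as.integer(X[, 1] > 0)
  X[, 1] <- X[, 1] + 2 * y               # widen the margin
  for (kind in c("tamper", "synthetic")) {
    det <- train_detector(X, y, kind, seed = 4)
    expect_gte(det$accuracy, 0.95)
    det2 <- train_detector(X, y, kind, seed = 4)
    expect_equal(det$accuracy, det2$accuracy)
    expect_equal(det$sensitivity, det2$sensitivity)
  }
  expect_error(train_detector(X, rep(1, 120), "tamper"), "single class")
})

test_that("block noise estimation recovers planted sigma", {
  flat <- matrix(0.5, 64, 64)
  bn <- estimate_block_noise(flat, 64)
  expect_lt(bn$sigma[1, 1], 1e-6)
  set.seed(54)
  sig <- 5
  ests <- replicate(50, {
    blk <- matrix(120, 64, 64) + matrix(rnorm(64 * 64, 0, sig), 64, 64)
    phenocount:::block_noise_sigma(blk)
  })
  expect_lt(abs(median(ests) - sig) / sig, 0.2)
  img <- matrix(runif(200 * 130), 200, 130)
  bn2 <- estimate_block_noise(img, 64)
  expect_equal(dim(bn2$sigma), c(ceiling(200 / 64), ceiling(130 / 64)))
  expect_error(estimate_block_noise(matrix(0, 10, 10), 64), "smaller")
})

test_that("tamper localization finds a high-noise splice and stays minority", {
  set.seed(55)
  img <- matrix(0.5, 256, 256) + matrix(rnorm(256^2, 0, 0.01), 256, 256)
  # homogeneous noise: one cluster, empty mask
  loc0 <- localize_tamper(img)
  expect_equal(loc0$k_coarse, 1)
  expect_equal(sum(loc0$tamper_mask), 0)
  expect_null(loc0$tamper_box)
  # planted 3x-noise region (~1.5% of pixels)
  timg <- img
  timg[97:128, 97:128] <- 0.5 + rnorm(32 * 32, 0, 0.05)
  loc <- localize_tamper(timg)
  truth <- matrix(0, 256, 256); truth[97:128, 97:128] <- 1
  inter <- sum(loc$tamper_mask * truth)
  uni <- sum(pmax(loc$tamper_mask, truth))
  expect_gt(inter / uni, 0.3)
  expect_lte(mean(loc$tamper_mask), 0.5)
  box <- loc$tamper_box
  expect_true(box["x0"] < 128 && box["x1"] > 97 - 1)
})

test_that("classify_image composes the three layers deterministically", {
  X <- clean_features()
  n <- nrow(X)
  anomaly <- fit_robust_pca(X, k = 1, alpha = 0.70, seed = 6)
  set.seed(56)
  # synthetic labels from a constructed contrast so training is possible
  fake <- X + matrix(rnorm(length(X), 0, 0.05), n, ncol(X))
  fake[, 1] <- fake[, 1] + 10 * sd(X[, 1])
  Xall <- rbind(X, fake)
  yall <- rep(0:1, each = n)
  tam <- train_detector(Xall, yall, "tamper", seed = 7)
  syn <- train_detector(Xall, yall, "synthetic", seed = 8)
  models <- list(anomaly = anomaly, tamper = tam, synthetic = syn)
  img <- small_set()[[1]]$fov$nucleus
  v1 <- classify_image(img, models)
  v2 <- classify_image(img, models)
  expect_s3_class(v1, "forensics_verdict")
  expect_identical(v1$synthetic, v2$synthetic)
  expect_identical(v1$tampered, v2$tampered)
  expect_identical(v1$anomalous, v2$anomalous)
  # verdict CSV writer
  path <- tempfile(fileext = ".csv")
  write_verdicts_csv(list(img1 = v1), path)
  got <- read.csv(path)
  expect_equal(nrow(got), 1)
  expect_equal(got$tampered, v1$tampered)
})
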