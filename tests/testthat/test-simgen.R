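# synthetic generator: conservation, determinism, jitter calibration,
# forgeries, augmentation, anomalies

test_that("phenotype registry has 20 phenotypes with at least one marker", {
  reg <- default_phenotype_registry()
  expect_equal(nrow(reg), 20)
  expect_equal(anyDuplicated(reg$name), 0)
  pats <- apply(reg[, c("c1", "c2", "c3")], 1, paste, collapse = "")
  expect_equal(anyDuplicated(pats), 0)
  has_plus <- apply(reg[, c("c1", "c2", "c3")], 1, function(r) any(r == "+"))
  expect_equal(sum(!has_plus), 1)          # only the nucleus-only phenotype
})

test_that("ground-truth counts equal the multiset tally of cells", {
  for (e in small_set()) {
    tb <- table(e$truth$cells$phenotype)
    for (ph in names(e$truth$counts)) {
      expect_equal(unname(e$truth$counts[ph]),
                   if (ph %in% names(tb)) unname(as.integer(tb[ph])) else 0L)
    }
    expect_equal(sum(e$truth$counts), nrow(e$truth$cells))
  }
})

test_that("empty scenes and exact requests behave by construction", {
  reg <- default_phenotype_registry()
  mix0 <- setNames(c(0L, 0L), reg$name[1:2])
  sp <- fov_spec(width = 96, height = 96, phenotype_mix = mix0,
                 registry = reg, n_marker_channels = 3,
                 ccd_noise_variance = 0, seed = 1)
  g <- generate_fov(sp)
  expect_equal(sum(g$truth$counts), 0)
  expect_equal(nrow(g$truth$cells), 0)
  expect_lt(max(g$fov$nucleus), 0.3)       # background only

  mix50 <- setNames(50L, reg$name[4])
  sp50 <- fov_spec(width = 520, height = 520, phenotype_mix = mix50,
                   registry = reg, n_marker_channels = 3, seed = 2)
  g50 <- generate_fov(sp50)
  expect_equal(sum(g50$truth$counts), 50)
})

test_that("identical seeds give bit-identical images and ground truth", {
  reg <- default_phenotype_registry()
  mix <- setNames(c(4L, 3L), reg$name[c(1, 7)])
  sp <- fov_spec(width = 128, height = 128, phenotype_mix = mix,
                 registry = reg, n_marker_channels = 3, seed = 77)
  a <- generate_fov(sp); b <- generate_fov(sp)
  expect_identical(a$fov$nucleus, b$fov$nucleus)
  expect_identical(a$fov$markers, b$fov$markers)
  expect_identical(a$truth$cells, b$truth$cells)
  s1 <- generate_phenotype_set(2, seed = 5, width = 96, height = 96,
                               mean_count = 2)
  s2 <- generate_phenotype_set(2, seed = 5, width = 96, height = 96,
                               mean_count = 2)
  expect_identical(lapply(s1, `[[`, "truth"), lapply(s2, `[[`, "truth"))
})

test_that("placement failure raises an explicit error", {
  reg <- default_phenotype_registry()
  mix <- setNames(500L, reg$name[1])
  sp <- fov_spec(width = 100, height = 100, phenotype_mix = mix,
                 registry = reg, n_marker_channels = 3, seed = 3)
  expect_error(generate_fov(sp, nucleus_spec(clustering_probability = 0)),
               "placement failure")
})

test_that("realized radii match the jitter model within Monte-Carlo error", {
  # ~1000 cells; radius jitter is uniform on +/- 10% of 13
  reg <- default_phenotype_registry()
  radii <- c()
  set.seed(30)
  for (r in 1:12) {
    mix <- setNames(90L, reg$name[4])
    sp <- fov_spec(width = 696, height = 520, phenotype_mix = mix,
                   registry = reg, n_marker_channels = 0, seed = NULL,
                   bright_field = FALSE)
    g <- generate_fov(sp, nucleus_spec(clustering_probability = 0),
                      markers = list())
    radii <- c(radii, g$truth$cells$radius)
  }
  n <- length(radii)
  expect_gte(n, 1000)
  se <- sd(radii) / sqrt(n)
  expect_lt(abs(mean(radii) - 13), 2 * se + 1e-9)
  expect_true(all(radii >= 13 * 0.9 - 1e-9 & radii <= 13 * 1.1 + 1e-9))
})

test_that("phenotype set has the 4 x n group structure covering 20 phenotypes", {
  s <- generate_phenotype_set(1, seed = 44, width = 96, height = 96,
                              mean_count = 1)
  expect_length(s, 4)
  s2 <- small_set()
  expect_length(s2, 8)
  phns <- unlist(lapply(s2, function(e) e$phenotypes$name))
  expect_setequal(unique(phns), default_phenotype_registry()$name)
  # realized patterns are distinct within every FOV
  for (e in s2) expect_equal(anyDuplicated(e$phenotypes$pattern), 0)
})

test_that("splice forgeries alter exactly the tamper mask", {
  set.seed(33)
  target <- matrix(runif(100 * 100, 0.4, 0.6), 100, 100)
  donor <- matrix(1, 100, 100)             # constant bright donor
  dmask <- disc_mask(100, 100, 30, 30, 8)
  out <- splice_tamper(target, donor, dmask, max_objects = 3, seed = 9)
  expect_true(out$record$n_objects_pasted >= 1 &&
                out$record$n_objects_pasted <= 3)
  m <- out$record$tamper_mask
  expect_equal(out$record$tampered_pixel_fraction, mean(m))
  # pixelwise diff oracle: output differs from target exactly inside mask
  expect_true(all(out$image[m == 0] == target[m == 0]))
  expect_true(all(out$image[m == 1] != target[m == 1]))
  # 10x10 square into 100x100 -> fraction 0.01 when one object pasted
  sq <- matrix(0, 100, 100); sq[41:50, 41:50] <- 1
  out2 <- splice_tamper(target, donor, sq, max_objects = 1, seed = 4)
  expect_equal(out2$record$tampered_pixel_fraction, 0.01)
  expect_error(splice_tamper(target, donor, matrix(0, 100, 100)),
               "connected components")
  expect_error(splice_tamper(target, donor, dmask, max_objects = 0),
               "max_objects")
})

test_that("mirror augmentation is a 4-image involution", {
  const <- matrix(5, 8, 8)
  a <- augment_mirror(const)
  expect_length(a, 4)
  for (im in a) expect_equal(im, const)
  set.seed(34)
  img <- matrix(runif(63), 7, 9)
  b <- augment_mirror(img)
  # pairwise distinct for an asymmetric pattern
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(isTRUE(all.equal(b[[i]], b[[j]])))
  }
  # applying the same flip twice recovers the original
  expect_equal(augment_mirror(b$horizontal)$horizontal, img)
  expect_equal(augment_mirror(b$vertical)$vertical, img)
  expect_equal(augment_mirror(b$both)$both, img)
})

test_that("anomaly modes produce the contracted images", {
  base <- matrix(runif(64 * 64), 64, 64)
  expect_equal(make_anomaly(base, "blank"), matrix(0, 64, 64))
  sat <- make_anomaly(base, "saturated")
  expect_gte(mean(sat == max(sat)), 0.99)
  nz <- make_anomaly(base, "noise", seed = 2)
  expect_gt(sd(nz), 0.2)
  om <- make_anomaly(base, "off_modality")
  expect_equal(dim(om), c(64, 64))
})

test_that("FOV sets round-trip through the file convention", {
  s <- small_set()[1:2]
  dir <- file.path(tempdir(), "fovset")
  write_fov_set(s, dir, format = "png")
  expect_true(file.exists(file.path(dir, "ground_truth_cells.csv")))
  counts <- read.csv(file.path(dir, "ground_truth_counts.csv"))
  expect_equal(sum(counts$count[counts$fov == s[[1]]$fov_id]),
               sum(s[[1]]$truth$counts))
  fov <- read_fov(dir, s[[1]]$fov_id, n_markers = length(s[[1]]$fov$markers))
  expect_equal(dim(fov$nucleus), dim(s[[1]]$fov$nucleus))
  # 8-bit quantization: intensities within half a gray level
  expect_lt(max(abs(fov$nucleus - s[[1]]$fov$nucleus)), 1 / 255)
  unlink(dir, recursive = TRUE)
})
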