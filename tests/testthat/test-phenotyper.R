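# rule-based phenotyping: filters, masks, ratio test, end-to-end recovery

test_that("nucleus filter applies the area and eccentricity rules", {
  img <- matrix(0, 200, 260)
  img <- img + disc_mask(200, 260, 50, 50, 13)          # area ~531, kept
  img <- img + disc_mask(200, 260, 50, 150, 5)          # area ~79, removed
  img[150:153, 40:139] <- 1                             # 4x100 bar, removed
  lab <- matrix(as.integer(EBImage::bwlabel(img)), 200, 260)
  out <- filter_nucleus_objects(lab)
  props <- phenocount:::object_props(out)
  expect_equal(nrow(props), 1)
  expect_lt(abs(props$x - 50), 1)
  expect_lt(abs(props$y - 50), 1)
  # a big blob above the area cap is removed too
  img2 <- disc_mask(200, 260, 100, 100, 30)             # area ~2827
  lab2 <- matrix(as.integer(EBImage::bwlabel(img2)), 200, 260)
  expect_equal(max(filter_nucleus_objects(lab2)), 0)
})

test_that("cytoplasmic masks multiply per pattern with inversion", {
  c1 <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  c2 <- matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)
  m <- build_cytoplasm_mask(list(c1, c2), c("+", "-"))
  expect_equal(m, c1 * (1 - c2))
  expect_equal(build_cytoplasm_mask(list(c1, c2), c("+", "0")), c1)
  all1 <- matrix(1, 2, 2)
  expect_equal(build_cytoplasm_mask(list(all1, all1), c("+", "+")), all1)
  expect_error(build_cytoplasm_mask(list(c1, matrix(0, 3, 3)), c("+", "+")),
               "mismatch")
  # the 2^k patterns partition every pixel, k = 3
  set.seed(40)
  ms <- replicate(3, matrix(rbinom(64, 1, 0.5), 8, 8), simplify = FALSE)
  acc <- matrix(0, 8, 8)
  for (p1 in c("+", "-")) for (p2 in c("+", "-")) for (p3 in c("+", "-")) {
    acc <- acc + build_cytoplasm_mask(ms, c(p1, p2, p3))
  }
  expect_equal(acc, matrix(1, 8, 8))
})

test_that("area-ratio filter enforces the strict 0.6 cutoff", {
  base <- disc_mask(80, 80, 40, 40, 16)                  # area ~804
  lab <- matrix(as.integer(EBImage::bwlabel(base)), 80, 80)
  # identical masks: ratio 1, kept
  k1 <- area_ratio_filter(base, lab)
  expect_equal(nrow(k1), 1)
  expect_equal(k1$ratio, 1)
  # masked covers half (ratio ~0.5): removed
  half <- base; half[, 40:80] <- 0
  expect_equal(nrow(area_ratio_filter(half, lab)), 0)
  # masked covers ~70%: kept (strict < 0.6 removal)
  csum <- cumsum(colSums(base))
  cut <- which(csum >= 0.3 * sum(base))[1]   # drop the left ~30% of pixels
  s <- base; s[, 1:cut] <- 0
  r <- area_ratio_filter(s, lab)
  expect_equal(nrow(r), 1)
  expect_gte(r$ratio, 0.6)
  # centroid on background of the filtered image: skipped with warning
  ring <- base; ring[30:50, 30:50] <- 0                  # centroid falls in hole
  expect_warning(area_ratio_filter(ring, lab * 0), "background")
})

test_that("equivalent diameter follows the closed form and scales", {
  expect_equal(measure_diameter(pi * 100, 1), 20)
  expect_equal(measure_diameter(pi * 100, 0.5), 10)
  # planted disc of radius 10: rasterized diameter within 5%
  d <- disc_mask(40, 40, 20, 20, 10)
  expect_lt(abs(measure_diameter(sum(d), 1) - 20) / 20, 0.05)
  expect_error(measure_diameter(10, 0))
})

test_that("well-separated planted cells are recovered exactly", {
  g <- tiny_fov()
  cfg <- pheno_config(correction_model = unit_correction_model())
  res <- enumerate_fov(g$fov, data.frame(
    name = c("P4", "P6"), pattern = c("+--", "-+-"),
    stringsAsFactors = FALSE), cfg)
  expect_equal(unname(res$counts["P4"]), unname(g$truth$counts["P4"]))
  expect_equal(unname(res$counts["P6"]), unname(g$truth$counts["P6"]))
  # every record satisfies the type invariants
  expect_true(all(res$records$area >= 200 & res$records$area <= 2000))
  expect_true(all(res$records$eccentricity <= 0.8))

  # partition property: the 2^k pattern counts sum to the surviving nuclei
  pats <- expand.grid(a = c("+", "-"), b = c("+", "-"), c = c("+", "-"),
                      stringsAsFactors = FALSE)
  full <- data.frame(name = apply(pats, 1, paste, collapse = ""),
                     pattern = apply(pats, 1, paste, collapse = ""),
                     stringsAsFactors = FALSE)
  resf <- enumerate_fov(g$fov, full, cfg)
  expect_equal(sum(resf$counts), max(resf$segmented$filtered_labels))
})

test_that("missing channels are reported by name", {
  g <- tiny_fov()
  fov2 <- g$fov
  fov2$markers <- fov2$markers[1:2]
  expect_error(enumerate_phenotype(fov2, c("+", "-", "+")), "channel 3")
})

test_that("export writes counts, positions, overlays and padded thumbnails", {
  g <- tiny_fov()
  res <- enumerate_fov(g$fov, data.frame(
    name = c("P4", "P6"), pattern = c("+--", "-+-"),
    stringsAsFactors = FALSE),
    pheno_config(correction_model = unit_correction_model()))
  out <- file.path(tempdir(), "export_test")
  export_results(list(fovA = res), list(fovA = g$fov), out,
                 thumbnails = TRUE)
  counts <- read.csv(file.path(out, "counts.csv"))
  expect_equal(sum(counts$count), sum(res$counts))
  pos <- read.csv(file.path(out, "positions.csv"))
  expect_equal(nrow(pos), nrow(res$records))
  thumbs <- list.files(out, "cell[0-9]+\\.png$")
  expect_length(thumbs, nrow(res$records))
  expect_true(file.exists(file.path(out, "fovA_overlay.png")))
  # corner cell still yields a full-size thumbnail via mirrored padding
  th <- phenocount:::cell_thumbnail(g$fov$nucleus, 2, 2)
  expect_equal(dim(th), c(120, 120))
  unlink(out, recursive = TRUE)
})

test_that("pipeline configs round-trip through YAML", {
  skip_if_not_installed("yaml")
  cfg <- pheno_config(method = "otsu", clip_limit = 0.02, tolerance = 1)
  path <- tempfile(fileext = ".yml")
  write_pheno_config(cfg, path)
  back <- read_pheno_config(path)
  expect_equal(back$method, "otsu")
  expect_equal(back$clip_limit, 0.02)
  expect_equal(back$tolerance, 1)
  expect_s3_class(back, "pheno_config")
})
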