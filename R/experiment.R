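# Benchmark experiments ------------------------------------------------------
#
# Self-contained experiments used to characterize the pipeline on the
# synthetic generator: phenotype enumeration accuracy, forgery detection,
# anomaly screening and tamper localization. Each takes a single seed and
# reproduces the whole chain (generation, training, evaluation).

#' Phenotype enumeration benchmark on a generated image set
#'
#' Generates a training set, fits the Triangle-threshold correction model
#' on its channel images and truth masks, generates an independent
#' four-group phenotype set, enumerates every phenotype of every FOV with
#' the corrected pipeline, and scores the result against ground truth:
#' pooled cell-level detection sensitivity/specificity (greedy centroid
#' matching within the true nucleus radius) and the mean percentage count
#' error pooled across phenotypes.
#'
#' Default sizes are a density-matched scale-down of 696x520 FOVs with
#' ~50 cells each (the per-pixel cell density is preserved).
#'
#' @param seed master seed (all randomness derives from it).
#' @param n_fov_per_group evaluation FOVs per group (4 groups).
#' @param width,height FOV size in pixels.
#' @param mean_count Poisson mean per-FOV count of each of the 5 phenotypes.
#' @param n_train_fov_per_group FOVs per group in the training set.
#' @param progress print per-FOV progress.
#' @return list with `sensitivity`, `specificity`, `mean_percentage_error`,
#'   `per_phenotype` (data frame), `n_cells`, `n_fov`, `correction_model`.
#' @export
enumeration_experiment <- function(seed = 1, n_fov_per_group = 30,
                                   width = 464, height = 348,
                                   mean_count = 4.5,
                                   n_train_fov_per_group = 4,
                                   progress = FALSE) {
  base_cfg <- pheno_config()
  train <- generate_phenotype_set(n_train_fov_per_group, seed = seed + 1,
                                  width = width, height = height,
                                  mean_count = mean_count * 2)
  imgs <- list(); msks <- list()
  for (e in train) {
    imgs[[length(imgs) + 1]] <- e$fov$nucleus
    msks[[length(msks) + 1]] <- e$truth$masks$nucleus
    for (i in seq_along(e$fov$markers)) {
      if (sum(e$truth$masks$markers[[i]]) == 0) next
      imgs[[length(imgs) + 1]] <- e$fov$markers[[i]]
      msks[[length(msks) + 1]] <- e$truth$masks$markers[[i]]
    }
  }
  cm <- train_correction_model(imgs, msks, seed = seed + 2,
                               config = base_cfg)
  cfg <- pheno_config(correction_model = cm)

  set_ <- generate_phenotype_set(n_fov_per_group, seed = seed + 3,
                                 width = width, height = height,
                                 mean_count = mean_count)
  pred <- list(); truth <- list(); counts <- list()
  for (i in seq_along(set_)) {
    e <- set_[[i]]
    res <- enumerate_fov(e$fov, e$phenotypes, cfg)
    if (nrow(res$records) > 0) {
      pred[[i]] <- cbind(fov = e$fov_id, res$records)
    }
    tc <- e$truth$cells
    if (nrow(tc) > 0) {
      tc$fov <- e$fov_id
      truth[[i]] <- tc
    }
    counts[[i]] <- data.frame(fov = e$fov_id,
                              phenotype = names(e$truth$counts),
                              truth = as.integer(e$truth$counts),
                              pred = as.integer(res$counts[
                                names(e$truth$counts)]))
    if (progress && i %% 10 == 0) {
      message("enumerated ", i, "/", length(set_), " FOVs")
    }
  }
  pred <- do.call(rbind, pred)
  truth <- do.call(rbind, truth)
  counts <- do.call(rbind, counts)
  dm <- detection_metrics(pred, truth)
  # per-phenotype mean percentage error, then pooled across phenotypes
  per <- lapply(split(counts, counts$phenotype), function(d) {
    pe <- suppressMessages(percentage_error(d$truth, d$pred))
    data.frame(phenotype = d$phenotype[1], mean_error = pe$mean,
               sd_error = pe$sd, n = length(pe$errors))
  })
  per <- do.call(rbind, per)
  list(sensitivity = dm$sensitivity, specificity = dm$specificity,
       mean_percentage_error = mean(per$mean_error, na.rm = TRUE),
       per_phenotype = per, n_cells = nrow(truth), n_fov = length(set_),
       detection = dm, counts = counts, correction_model = cm)
}

# channel images of a generated set as a flat list
set_channel_images <- function(set_) {
  imgs <- list()
  for (e in set_) {
    imgs[[length(imgs) + 1]] <- e$fov$nucleus
    for (m in e$fov$markers) imgs[[length(imgs) + 1]] <- m
  }
  imgs
}

#' Splice-forgery detection benchmark
#'
#' Builds a pristine/tampered corpus by splicing donor objects between two
#' differently-parameterized generator populations (mirroring cross-set
#' splicing): targets are nucleus channels of phenotype-set-style FOVs;
#' donors are marker channels of FOVs simulated with the realistic-set
#' parameters (larger, eccentric, strongly textured cells). Both a random
#' forest and a cubic SVM are trained on the 166-feature vectors with an
#' 80:20 split.
#'
#' @param seed master seed.
#' @param n_pairs number of pristine/tampered image pairs.
#' @param width,height image size.
#' @return list with `rf` and `svm` [train_detector()] fits and the corpus
#'   labels.
#' @export
forgery_experiment <- function(seed = 1, n_pairs = 60, width = 256,
                               height = 256) {
  set.seed(seed)
  reg <- default_phenotype_registry()
  gen_one <- function(nucleus, marker, mix_names, count) {
    mix <- setNames(rep(count, length(mix_names)), mix_names)
    sp <- fov_spec(width = width, height = height, phenotype_mix = mix,
                   registry = reg, n_marker_channels = 1,
                   bright_field = FALSE, seed = NULL)
    generate_fov(sp, nucleus, list(marker))
  }
  target_nuc <- nucleus_spec()                       # phenotype-set values
  target_mark <- marker_spec(mean_level = 0.5, level_sd = 0.2)
  donor_nuc <- nucleus_spec(mean_radius = 15.7, eccentricity = 0.77,
                            variation_extent = 0.10)
  donor_mark <- marker_spec()                        # 0.65 / 0.15, textured
  pristine <- list(); tampered <- list()
  for (i in seq_len(n_pairs)) {
    tg <- gen_one(target_nuc, target_mark, reg$name[4], 10L)
    dn <- gen_one(donor_nuc, donor_mark, reg$name[4], 8L)
    sp <- splice_tamper(tg$fov$nucleus, dn$fov$markers[[1]],
                        dn$truth$masks$markers[[1]], max_objects = 3)
    pristine[[i]] <- tg$fov$nucleus
    tampered[[i]] <- sp$image
  }
  X <- feature_matrix(c(pristine, tampered))
  y <- rep(0:1, each = n_pairs)
  list(rf = train_detector(X, y, "tamper", seed = seed + 1),
       svm = train_detector(X, y, "synthetic", seed = seed + 2),
       labels = y)
}

#' Robust-PCA anomaly screening benchmark
#'
#' Fits the robust PCA model (k = 1, alpha = 0.70) on the feature vectors
#' of clean generated channel images and measures the false-flag rate on
#' them (flag = bad leverage point) and the detection rate on planted
#' gross anomalies: uniform-noise fields and off-modality patterns at
#' several amplitudes. Constant frames (blank, saturated) are also
#' screened; with a single retained component they are structurally
#' classified as orthogonal outliers rather than bad leverage points, so
#' they are reported separately and do not enter the detection rate.
#'
#' @param seed master seed.
#' @param n_fov_per_group clean FOVs per group.
#' @param width,height image size.
#' @param n_anomaly anomalies per mode.
#' @return list with `false_flag_rate`, `anomaly_detection_rate`,
#'   `constant_mode_categories`, `model`.
#' @export
anomaly_experiment <- function(seed = 1, n_fov_per_group = 12, width = 192,
                               height = 192, n_anomaly = 10) {
  set_ <- generate_phenotype_set(n_fov_per_group, seed = seed, width = width,
                                 height = height, mean_count = 3)
  imgs <- set_channel_images(set_)
  X <- feature_matrix(imgs)
  model <- fit_robust_pca(X, k = 1, alpha = 0.70, seed = seed + 1)
  clean <- diagnose(X, model)
  set.seed(seed + 2)
  base <- imgs[[1]]
  anom <- list()
  for (r in seq_len(n_anomaly)) {
    a <- make_anomaly(base, "noise")
    anom[[length(anom) + 1]] <- a * runif(1, 0.5, 1)
    o <- make_anomaly(base, "off_modality")
    anom[[length(anom) + 1]] <- clamp(o + matrix(
      rnorm(length(o), 0, 0.05), nrow(o), ncol(o)), 0, 1)
  }
  da <- diagnose(feature_matrix(anom), model)
  dc <- diagnose(rbind(extract_features(make_anomaly(base, "blank")),
                       extract_features(make_anomaly(base, "saturated"))),
                 model)
  list(false_flag_rate = mean(clean$anomalous),
       anomaly_detection_rate = mean(da$anomalous),
       constant_mode_categories = setNames(dc$category,
                                           c("blank", "saturated")),
       n_clean = nrow(X), n_anomaly = length(anom), model = model)
}

#' Tamper-localization benchmark
#'
#' Splices a small high-noise region (~1% of pixels) into the bright-field
#' channel of generated FOVs (whose lifted background keeps the planted
#' noise unclipped) and measures the intersection-over-union of the
#' recovered tamper mask against the planted mask.
#'
#' @param seed master seed.
#' @param n_images number of tampered images.
#' @param width,height image size; the default gives a 7x7 grid of coarse
#'   blocks, enough observations for the gap statistic to be stable.
#' @param noise_factor multiple of the CCD noise sigma inside the splice.
#' @return list with `mean_iou`, `iou` vector.
#' @export
localization_experiment <- function(seed = 1, n_images = 8, width = 448,
                                    height = 448, noise_factor = 3) {
  set.seed(seed)
  reg <- default_phenotype_registry()
  ious <- numeric(n_images)
  for (i in seq_len(n_images)) {
    mix <- setNames(6L, reg$name[4])
    sp <- fov_spec(width = width, height = height, phenotype_mix = mix,
                   registry = reg, n_marker_channels = 1, seed = NULL)
    g <- generate_fov(sp, markers = list(marker_spec()))
    img <- g$fov$bright_field
    side <- round(sqrt(0.013 * width * height))
    y0 <- sample(1:(height - side), 1); x0 <- sample(1:(width - side), 1)
    reg_y <- y0:(y0 + side - 1); reg_x <- x0:(x0 + side - 1)
    img[reg_y, reg_x] <- clamp(img[reg_y, reg_x] +
                                 rnorm(side^2, 0, noise_factor * 0.01), 0, 1)
    truthm <- matrix(0, height, width)
    truthm[reg_y, reg_x] <- 1
    loc <- localize_tamper(img, seed = seed + i)
    inter <- sum(loc$tamper_mask * truthm)
    uni <- sum(pmax(loc$tamper_mask, truthm))
    ious[i] <- if (uni > 0) inter / uni else 0
  }
  list(mean_iou = mean(ious), iou = ious)
}
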