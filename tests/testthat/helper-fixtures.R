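# shared fixtures, generated once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

# binary disc in an h x w image
disc_mask <- function(h, w, cy, cx, r) {
  m <- matrix(0, h, w)
  m[(row(m) - cy)^2 + (col(m) - cx)^2 <= r^2] <- 1
  m
}

# small well-separated two-phenotype FOV used across phenotyper tests
tiny_fov <- function() {
  fixture("tiny_fov", function() {
    reg <- default_phenotype_registry()
    # P4 = (+,-,-), P6 = (-,+,-) in the default registry ordering
    mix <- setNames(c(3L, 5L), c("P4", "P6"))
    spec <- fov_spec(width = 320, height = 320, phenotype_mix = mix,
                     registry = reg, n_marker_channels = 3,
                     ccd_noise_variance = 1e-4, seed = 421)
    generate_fov(spec, nucleus_spec(clustering_probability = 0))
  })
}

# a modest clean phenotype set shared by simgen / forensics tests
small_set <- function() {
  fixture("small_set", function() {
    generate_phenotype_set(n_fov_per_group = 2, seed = 31, width = 192,
                           height = 192, mean_count = 3)
  })
}

# correction model trained on generator fixtures (shared by the phenotyper
# tests; the full pipeline thresholds with the learned correction factor)
unit_correction_model <- function() {
  fixture("unit_correction_model", function() {
    ts <- generate_phenotype_set(n_fov_per_group = 4, seed = 99,
                                 width = 192, height = 192, mean_count = 4)
    imgs <- list(); msks <- list()
    for (e in ts) {
      imgs[[length(imgs) + 1]] <- e$fov$nucleus
      msks[[length(msks) + 1]] <- e$truth$masks$nucleus
      for (i in seq_along(e$fov$markers)) {
        if (sum(e$truth$masks$markers[[i]]) == 0) next
        imgs[[length(imgs) + 1]] <- e$fov$markers[[i]]
        msks[[length(msks) + 1]] <- e$truth$masks$markers[[i]]
      }
    }
    train_correction_model(imgs, msks, seed = 11, ntree = 150,
                           config = pheno_config())
  })
}

# feature matrix of the small set's channel images (clean corpus)
clean_features <- function() {
  fixture("clean_features", function() {
    imgs <- list()
    for (e in small_set()) {
      imgs[[length(imgs) + 1]] <- e$fov$nucleus
      for (m in e$fov$markers) imgs[[length(imgs) + 1]] <- m
    }
    feature_matrix(imgs)
  })
}
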