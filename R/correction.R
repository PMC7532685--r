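# Threshold correction model -------------------------------------------------
#
# The Triangle threshold is modulated by a learned multiplicative correction
# factor c (final threshold T = c * T_triangle). Training labels c* are
# obtained per fixture by a grid search (0.2..3.0 step 0.05) minimizing the
# pixelwise disagreement between the corrected binarization and the truth
# mask; a regressor then maps the 166-feature vector to c*.

CORRECTION_GRID <- seq(0.2, 3.0, by = 0.05)

# optimal correction factor for one (image, truth mask) fixture
optimal_correction <- function(img, truth_mask, grid = CORRECTION_GRID) {
  g <- gray8(img)
  traw <- threshold_image(g, "triangle")
  tm <- (to_gray(truth_mask) > 0) * 1
  err <- vapply(grid, function(cc) {
    m <- (g >= clamp(cc * traw, 0, 255)) * 1
    mean(m != tm)
  }, numeric(1))
  grid[which.min(err)]
}

#' Train the threshold-correction regressor
#'
#' Computes per-fixture optimal correction factors by grid search against
#' the truth masks, extracts the 166-dimensional feature vector of every
#' image, and fits a regressor (random forest by default) on an 80:20
#' train/test split.
#'
#' @param images list of grayscale images.
#' @param masks list of binary truth masks (same order/dimensions).
#' @param regressor regressor family; `"random_forest"` (default) or
#'   `"linear"`.
#' @param seed integer seed controlling the split and the forest.
#' @param grid candidate correction factors.
#' @param ntree forest size.
#' @param config optional [pheno_config()]; when supplied, every fixture
#'   image is preprocessed with its settings first, so that training
#'   matches the preprocessing used at enumeration time.
#' @return object of class `correction_model` with fields `model`,
#'   `regressor`, `grid_range`, `rmse`, `mae`, `baseline_mae` (always-1
#'   predictor on the test split), `n`, `seed`.
#' @export
train_correction_model <- function(images, masks,
                                   regressor = c("random_forest", "linear"),
                                   seed = 1, grid = CORRECTION_GRID,
                                   ntree = 300, config = NULL) {
  regressor <- match.arg(regressor)
  stopifnot(length(images) == length(masks))
  if (!is.null(config)) {
    images <- lapply(images, function(im) {
      preprocess_image(im, denoise = config$denoise,
                       enhance = config$enhance,
                       spatial_sigma = config$spatial_sigma,
                       range_sigma = config$range_sigma,
                       tiles = config$tiles, clip_limit = config$clip_limit)
    })
  }
  usable <- vapply(seq_along(images), function(j) {
    s <- sum(to_gray(masks[[j]]) > 0)
    s > 0 && s < length(masks[[j]])
  }, logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " degenerate fixture(s) (all background or all ",
            "foreground) excluded")
  }
  images <- images[usable]; masks <- masks[usable]
  if (length(images) < 50) {
    stop("need at least 50 usable fixtures, got ", length(images))
  }
  labels <- vapply(seq_along(images), function(j) {
    optimal_correction(images[[j]], masks[[j]], grid)
  }, numeric(1))
  X <- feature_matrix(images)
  set.seed(seed)
  n <- nrow(X)
  idx_tr <- sample(n, floor(0.8 * n))
  df <- data.frame(X, cstar = labels, check.names = TRUE)
  if (regressor == "random_forest") {
    # labels sit on a coarse grid; the few-unique-values warning is expected
    fit <- suppressWarnings(
      randomForest::randomForest(cstar ~ ., data = df[idx_tr, ],
                                 ntree = ntree))
  } else {
    fit <- stats::lm(cstar ~ ., data = df[idx_tr, ])
  }
  pred_te <- clamp(predict(fit, df[-idx_tr, ]), min(grid), max(grid))
  res <- pred_te - labels[-idx_tr]
  structure(list(
    model = fit,
    regressor = regressor,
    grid_range = range(grid),
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    baseline_mae = mean(abs(1 - labels[-idx_tr])),
    n = n, seed = seed,
    feature_names = colnames(df)[seq_len(ncol(X))]
  ), class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "Threshold-correction model (%s, n = %d)\n  test RMSE = %.3f, MAE = %.3f (always-1 baseline MAE = %.3f)\n",
    x$regressor, x$n, x$rmse, x$mae, x$baseline_mae))
  invisible(x)
}

#' Predict a correction factor from a feature vector
#'
#' @param features 166-length feature vector from [extract_features()] (or
#'   a matrix of such rows).
#' @param model fitted [train_correction_model()] object.
#' @return predicted factor(s), clipped to the training grid range.
#' @export
predict_correction_factor <- function(features, model) {
  if (!inherits(model, "correction_model")) stop("model is not fitted")
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  colnames(features) <- model$feature_names
  p <- predict(model$model, as.data.frame(features))
  clamp(as.numeric(p), model$grid_range[1], model$grid_range[2])
}

#' Corrected Triangle threshold for an image
#'
#' Computes the raw Triangle threshold and, when a correction model is
#' supplied, multiplies it by the predicted correction factor.
#'
#' @param img grayscale image.
#' @param model optional `correction_model`.
#' @param method thresholding method for the raw value.
#' @return a [threshold_decision()].
#' @export
corrected_threshold <- function(img, model = NULL, method = "triangle") {
  raw <- threshold_image(img, method)
  cc <- if (is.null(model)) 1 else
    predict_correction_factor(extract_features(img), model)
  threshold_decision(method, raw, cc)
}
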