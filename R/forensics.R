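# Image forensics ------------------------------------------------------------
#
# Quad-layer protection: (1) robust-PCA anomaly screening on the 166-feature
# vectors (bad leverage points = anomalies), (2) random-forest tamper
# classifier, (3) cubic-SVM synthetic-image classifier, (4) coarse-to-fine
# tamper localization from PCA-estimated block noise levels.

#' Fit a robust PCA anomaly model
#'
#' ROBPCA-style estimator: the feature matrix is robustly standardized
#' (median/MAD; zero-MAD columns dropped), reduced to the affine span of
#' the data, and the `h = floor(alpha * n)` points with smallest
#' projection-pursuit outlyingness (directions through random pairs of
#' points) define the robust center and loadings. Score distances are cut
#' at the chi-square 97.5% quantile with `k` degrees of freedom; orthogonal
#' distances at the Wilson-Hilferty normal approximation (robust
#' median/MAD version).
#'
#' @param X numeric matrix, one observation per row (e.g. from
#'   [feature_matrix()]).
#' @param k number of principal components to retain (default 1).
#' @param alpha lower bound of the uncontaminated proportion, in (0.5, 1\]
#'   (default 0.70).
#' @param ndir number of projection-pursuit directions.
#' @param seed seed for the direction sampling.
#' @param scale `"mad"` (default) robustly standardizes each column
#'   (median/MAD) before the fit; `"none"` analyzes the features on their
#'   native scales.
#' @return object of class `anomaly_model`.
#' @export
fit_robust_pca <- function(X, k = 1, alpha = 0.70, ndir = 250, seed = 1,
                           scale = c("mad", "none")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(X), k >= 1, alpha > 0.5, alpha <= 1)
  n <- nrow(X)
  if (n < max(10, k + 2)) stop("too few observations for robust PCA")
  med <- apply(X, 2, median)
  madv <- apply(X, 2, mad)
  if (max(madv) <= 1e-12) stop("degenerate variance: all features constant")
  if (scale == "none") {
    keep <- seq_len(ncol(X))
    med <- rep(0, ncol(X))
    madv <- rep(1, ncol(X))
  } else {
    keep <- which(madv > 1e-12)
  }
  if (length(keep) == 0) stop("degenerate variance: all features constant")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, med[keep]), 2, madv[keep],
              "/")
  ctr <- colMeans(Xs)
  Xc <- sweep(Xs, 2, ctr)
  sv <- svd(Xc, nu = 0)
  r <- sum(sv$d > max(sv$d) * 1e-9)
  if (r < k) stop("degenerate variance: data rank below k")
  V <- sv$v[, seq_len(r), drop = FALSE]
  Z <- Xc %*% V
  set.seed(seed)
  outl <- rep(0, n)
  for (d in seq_len(ndir)) {
    ij <- sample.int(n, 2)
    v <- Z[ij[1], ] - Z[ij[2], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    pr <- Z %*% (v / nv)
    s <- mad(pr)
    if (s < 1e-12) next
    outl <- pmax(outl, abs(pr - median(pr)) / s)
  }
  h <- max(floor(alpha * n), k + 2)
  H0 <- order(outl)[seq_len(min(h, n))]
  mu0 <- colMeans(Z[H0, , drop = FALSE])
  ev <- eigen(cov(Z[H0, , drop = FALSE]), symmetric = TRUE)
  kk <- min(k, sum(ev$values > 1e-12))
  if (kk < 1) stop("degenerate variance within the robust subset")
  P <- ev$vectors[, seq_len(kk), drop = FALSE]
  lambda <- ev$values[seq_len(kk)]
  model <- structure(list(
    k = kk, alpha = alpha, col_keep = keep, col_med = med[keep],
    col_mad = madv[keep], svd_center = ctr, V = V, center = mu0,
    loadings = P, eigenvalues = lambda,
    cutoff_sd = sqrt(qchisq(0.975, kk)), cutoff_od = NA_real_,
    n = n, seed = seed), class = "anomaly_model")
  dists <- robpca_distances(model, X)
  od23 <- dists$orthogonal_distance^(2 / 3)
  model$cutoff_od <- max((median(od23) + mad(od23) * qnorm(0.975))^(3 / 2),
                         1e-8)
  model$train_distances <- dists
  model
}

# score and orthogonal distances of rows of X under a fitted model
robpca_distances <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xs <- sweep(sweep(X[, model$col_keep, drop = FALSE], 2, model$col_med),
              2, model$col_mad, "/")
  Z <- sweep(Xs, 2, model$svd_center) %*% model$V
  Zc <- sweep(Z, 2, model$center)
  Ts <- Zc %*% model$loadings
  sd2 <- rowSums(sweep(Ts^2, 2, model$eigenvalues, "/"))
  resid <- Zc - Ts %*% t(model$loadings)
  data.frame(score_distance = sqrt(sd2),
             orthogonal_distance = sqrt(rowSums(resid^2)))
}

#' @export
print.anomaly_model <- function(x, ...) {
  cat(sprintf(
    "Robust PCA anomaly model: k = %d, alpha = %.2f, n = %d\n  cutoffs: score %.3f, orthogonal %.3f\n",
    x$k, x$alpha, x$n, x$cutoff_sd, x$cutoff_od))
  invisible(x)
}

#' Diagnose a feature vector against a robust PCA model
#'
#' Classifies the point by the 2x2 rule on (score distance, orthogonal
#' distance) vs the model cutoffs: `regular` (both small), `good_leverage`
#' (large score only), `orthogonal_outlier` (large orthogonal only),
#' `bad_leverage` (both large). Bad leverage points are flagged as
#' anomalies.
#'
#' @param features one feature vector (or matrix of rows).
#' @param model fitted [fit_robust_pca()] model.
#' @return data frame with `score_distance`, `orthogonal_distance`,
#'   `category`, `anomalous`.
#' @export
diagnose <- function(features, model) {
  if (!inherits(model, "anomaly_model")) stop("model is not fitted")
  d <- robpca_distances(model, if (is.null(dim(features)))
    matrix(features, nrow = 1) else features)
  big_sd <- d$score_distance > model$cutoff_sd
  big_od <- d$orthogonal_distance > model$cutoff_od
  d$category <- ifelse(big_sd & big_od, "bad_leverage",
                ifelse(big_sd, "good_leverage",
                ifelse(big_od, "orthogonal_outlier", "regular")))
  d$anomalous <- d$category == "bad_leverage"
  d
}

#' Train a tamper or synthetic-image detector
#'
#' Tamper detection uses a random forest; synthetic-image detection a
#' cubic-kernel SVM. Training uses a stratified 80:20 split with held-out
#' sensitivity/specificity/accuracy reported.
#'
#' @param X feature matrix (rows = images).
#' @param labels logical or 0/1 vector (TRUE = tampered / synthetic).
#' @param kind `"tamper"` or `"synthetic"`.
#' @param seed split/model seed.
#' @param ntree forest size (tamper kind).
#' @return object of class `image_detector` with fields `model`, `kind`,
#'   `sensitivity`, `specificity`, `accuracy`, `seed`.
#' @export
train_detector <- function(X, labels, kind = c("tamper", "synthetic"),
                           seed = 1, ntree = 300) {
  kind <- match.arg(kind)
  y <- factor(as.integer(as.logical(labels)), levels = c(0, 1))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  set.seed(seed)
  idx_tr <- unlist(lapply(levels(y), function(l) {
    i <- which(y == l)
    sample(i, floor(0.8 * length(i)))
  }))
  # constant features carry no information and break kernel scaling
  keep <- which(apply(X[idx_tr, , drop = FALSE], 2, sd) > 1e-12)
  X <- X[, keep, drop = FALSE]
  df <- data.frame(X, y = y, check.names = TRUE)
  fit <- if (kind == "tamper") {
    randomForest::randomForest(y ~ ., data = df[idx_tr, ], ntree = ntree)
  } else {
    e1071::svm(y ~ ., data = df[idx_tr, ], kernel = "polynomial",
               degree = 3, coef0 = 1, probability = FALSE, scale = TRUE)
  }
  pred <- predict(fit, df[-idx_tr, ])
  truth <- y[-idx_tr]
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
  structure(list(model = fit, kind = kind, feature_keep = keep,
                 feature_names = colnames(df)[seq_len(ncol(X))],
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(truth), seed = seed),
            class = "image_detector")
}

#' @export
print.image_detector <- function(x, ...) {
  cat(sprintf(
    "%s detector (%s): held-out sens %.3f, spec %.3f, acc %.3f\n",
    x$kind, class(x$model)[1], x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

predict_detector <- function(det, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- features[, det$feature_keep, drop = FALSE]
  colnames(features) <- det$feature_names
  as.integer(as.character(predict(det$model,
                                  as.data.frame(features)))) == 1
}

#' Run the full forensic screen on one image
#'
#' Extracts the image's feature vector once and applies the synthetic-image
#' classifier, the robust-PCA anomaly screen and the tamper classifier
#' (independent single-target flags). Tamper localization is run only when
#' the tamper flag is set and `localize = TRUE`.
#'
#' @param img grayscale image.
#' @param models list with elements `anomaly` ([fit_robust_pca()] model),
#'   `tamper` and `synthetic` ([train_detector()] fits).
#' @param localize attempt tamper localization when flagged.
#' @return object of class `forensics_verdict`: flags `synthetic`,
#'   `anomalous`, `tampered`, the two robust distances, and (optionally)
#'   `tamper_mask` / `tamper_box`.
#' @export
classify_image <- function(img, models, localize = FALSE) {
  stopifnot(all(c("anomaly", "tamper", "synthetic") %in% names(models)))
  f <- extract_features(img)
  fm <- matrix(f, nrow = 1)
  diag <- diagnose(fm, models$anomaly)
  verdict <- structure(list(
    synthetic = predict_detector(models$synthetic, fm),
    anomalous = diag$anomalous,
    tampered = predict_detector(models$tamper, fm),
    score_distance = diag$score_distance,
    orthogonal_distance = diag$orthogonal_distance,
    category = diag$category,
    tamper_mask = NULL, tamper_box = NULL), class = "forensics_verdict")
  if (localize && verdict$tampered) {
    loc <- localize_tamper(img)
    verdict$tamper_mask <- loc$tamper_mask
    verdict$tamper_box <- loc$tamper_box
  }
  verdict
}

#' @export
print.forensics_verdict <- function(x, ...) {
  cat(sprintf(
    "Forensics verdict: synthetic=%s anomalous=%s tampered=%s (SD %.2f, OD %.2f)\n",
    x$synthetic, x$anomalous, x$tampered, x$score_distance,
    x$orthogonal_distance))
  if (!is.null(x$tamper_box)) {
    cat(sprintf("  tamper box [x0,x1)x[y0,y1): [%d,%d)x[%d,%d)\n",
                x$tamper_box[1], x$tamper_box[2], x$tamper_box[3],
                x$tamper_box[4]))
  }
  invisible(x)
}

#' Write forensic verdicts to CSV
#'
#' @param verdicts named list of [classify_image()] results.
#' @param path CSV path.
#' @export
write_verdicts_csv <- function(verdicts, path) {
  rows <- lapply(names(verdicts), function(id) {
    v <- verdicts[[id]]
    box <- if (is.null(v$tamper_box)) rep(NA_integer_, 4) else v$tamper_box
    data.frame(image_id = id, synthetic = v$synthetic,
               anomalous = v$anomalous, tampered = v$tampered,
               score_distance = v$score_distance,
               orthogonal_distance = v$orthogonal_distance,
               box_x0 = box[1], box_x1 = box[2], box_y0 = box[3],
               box_y1 = box[4])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# PCA noise estimate of one block: median of the smallest quarter of the
# eigenvalue spectrum of sliding 7x7 patches. Image structure (including
# smooth texture) concentrates in the leading eigenvalues; the spectrum
# tail estimates the sensor noise floor.
block_noise_sigma <- function(block, patch = 7, max_patches = 600) {
  nr <- nrow(block); nc <- ncol(block)
  if (nr < patch || nc < patch) return(NA_real_)
  offs <- expand.grid(dy = 0:(patch - 1), dx = 0:(patch - 1))
  ys <- 1:(nr - patch + 1); xs <- 1:(nc - patch + 1)
  pos <- expand.grid(y = ys, x = xs)
  if (nrow(pos) > max_patches) {
    pos <- pos[seq(1, nrow(pos), length.out = max_patches), ]
  }
  M <- matrix(0, nrow(pos), patch * patch)
  for (j in seq_len(nrow(offs))) {
    M[, j] <- block[cbind(pos$y + offs$dy[j], pos$x + offs$dx[j])]
  }
  ev <- eigen(cov(M), symmetric = TRUE, only.values = TRUE)$values
  p <- length(ev)
  m <- max(floor(p / 4), 3)
  sqrt(max(median(ev[(p - m + 1):p]), 0))
}

#' Estimate per-block noise levels by patch PCA
#'
#' Segments the image into `block_size` x `block_size` blocks and, within
#' each, estimates the noise standard deviation from the low tail of the
#' eigenvalue spectrum of the covariance of sliding 7x7 patches.
#'
#' @param img grayscale image (any scale; estimates are on that scale).
#' @param block_size 64 (coarse) or 32 (fine).
#' @return object of class `block_noise_map`: `sigma` matrix of
#'   `ceil(H/bs) x ceil(W/bs)` noise levels plus block geometry.
#' @export
estimate_block_noise <- function(img, block_size = 64) {
  g <- to_gray(img)
  nr <- nrow(g); nc <- ncol(g)
  if (nr < block_size || nc < block_size) {
    stop("image smaller than the block size")
  }
  nby <- ceiling(nr / block_size); nbx <- ceiling(nc / block_size)
  sig <- matrix(NA_real_, nby, nbx)
  for (by in 1:nby) {
    for (bx in 1:nbx) {
      y0 <- (by - 1) * block_size + 1; y1 <- min(by * block_size, nr)
      x0 <- (bx - 1) * block_size + 1; x1 <- min(bx * block_size, nc)
      sig[by, bx] <- block_noise_sigma(g[y0:y1, x0:x1, drop = FALSE])
    }
  }
  structure(list(sigma = sig, block_size = block_size, height = nr,
                 width = nc), class = "block_noise_map")
}

# gap statistic for 1-D Ward clustering, uniform reference over the
# observed range, B references; returns the k in 1..kmax with largest gap
gap_choose_k <- function(x, kmax = 5, B = 50) {
  x <- x[is.finite(x)]
  kmax <- min(kmax, length(unique(x)))
  if (kmax <= 1) return(1)
  wss <- function(v, cl) {
    sum(tapply(v, cl, function(z) sum((z - mean(z))^2)))
  }
  ward_cut <- function(v, k) {
    cutree(hclust(dist(v), method = "ward.D2"), k)
  }
  logW <- vapply(1:kmax, function(k) {
    log(max(wss(x, ward_cut(x, k)), 1e-12))
  }, numeric(1))
  rng <- range(x)
  logWref <- matrix(0, B, kmax)
  for (b in 1:B) {
    xr <- runif(length(x), rng[1], rng[2])
    logWref[b, ] <- vapply(1:kmax, function(k) {
      log(max(wss(xr, ward_cut(xr, k)), 1e-12))
    }, numeric(1))
  }
  gap <- colMeans(logWref) - logW
  which.max(gap)
}

# silhouette-based choice of k in 2..kmax for 1-D Ward clustering
silhouette_choose_k <- function(x, kmax = 5) {
  x <- x[is.finite(x)]
  kmax <- min(kmax, length(unique(x)) - 1, length(x) - 1)
  if (kmax < 2) return(1)
  d <- dist(x)
  hc <- hclust(d, method = "ward.D2")
  sil <- vapply(2:kmax, function(k) {
    mean(cluster::silhouette(cutree(hc, k), d)[, "sil_width"])
  }, numeric(1))
  (2:kmax)[which.max(sil)]
}

#' Localize a tampered region from block noise levels
#'
#' Coarse-to-fine strategy: 64x64-block noise levels are Ward-clustered
#' with the cluster count (1-5) chosen by the gap statistic; if more than
#' one cluster is found, the class with the fewest pixels marks candidate
#' tampered blocks. 32x32 blocks restricted to those candidates plus a
#' one-block margin are re-clustered (cluster count by largest mean
#' silhouette), and the least-pixel fine class gives the tamper mask and
#' bounding box.
#'
#' @param img grayscale image, at least 64x64.
#' @param coarse,fine block sizes.
#' @param kmax maximum cluster count considered.
#' @param seed seed for the gap-statistic reference draws.
#' @return list with `k_coarse`, `k_fine`, `class_map` (coarse cluster
#'   assignment matrix), `tamper_mask` (binary image) and `tamper_box`
#'   (0-based half-open `c(x0, x1, y0, y1)`, `NULL` when nothing is
#'   flagged).
#' @export
localize_tamper <- function(img, coarse = 64, fine = 32, kmax = 5,
                            seed = 1) {
  g <- to_gray(img)
  nr <- nrow(g); nc <- ncol(g)
  if (nr < coarse || nc < coarse) stop("image smaller than 64x64")
  set.seed(seed)
  cmap <- estimate_block_noise(g, coarse)
  sig <- cmap$sigma
  vals <- as.vector(sig)
  kc <- gap_choose_k(vals, kmax)
  empty <- list(k_coarse = kc, k_fine = NA_integer_,
                class_map = matrix(1L, nrow(sig), ncol(sig)),
                tamper_mask = matrix(0, nr, nc), tamper_box = NULL)
  if (kc <= 1) return(empty)
  cl <- cutree(hclust(dist(vals), method = "ward.D2"), kc)
  clm <- matrix(cl, nrow(sig), ncol(sig))
  # pixels per class (edge blocks are smaller)
  bh <- function(by) min(coarse, nr - (by - 1) * coarse)
  bw <- function(bx) min(coarse, nc - (bx - 1) * coarse)
  px <- vapply(1:kc, function(k) {
    idx <- which(clm == k, arr.ind = TRUE)
    sum(vapply(seq_len(nrow(idx)),
               function(j) bh(idx[j, 1]) * bw(idx[j, 2]), numeric(1)))
  }, numeric(1))
  target <- which.min(px)
  cand <- clm == target
  # margin of one coarse block
  grow <- cand
  for (dy in -1:1) for (dx in -1:1) {
    sh <- matrix(FALSE, nrow(cand), ncol(cand))
    ys <- clamp((1:nrow(cand)) + dy, 1, nrow(cand))
    xs <- clamp((1:ncol(cand)) + dx, 1, ncol(cand))
    sh[] <- cand[ys, xs]
    grow <- grow | sh
  }
  # fine stage restricted to candidate region
  fmap <- estimate_block_noise(g, fine)
  fs <- fmap$sigma
  fb_in <- matrix(FALSE, nrow(fs), ncol(fs))
  for (by in seq_len(nrow(fs))) {
    for (bx in seq_len(ncol(fs))) {
      cy <- ceiling(((by - 1) * fine + 1) / coarse)
      cx <- ceiling(((bx - 1) * fine + 1) / coarse)
      fb_in[by, bx] <- grow[min(cy, nrow(grow)), min(cx, ncol(grow))]
    }
  }
  fvals <- fs[fb_in]
  kf <- if (sum(fb_in) >= 3) silhouette_choose_k(fvals, kmax) else 1
  if (kf <= 1) {
    # fine stage uninformative: fall back to the coarse candidate blocks
    fine_sel <- matrix(FALSE, nrow(fs), ncol(fs))
    for (by in seq_len(nrow(fs))) {
      for (bx in seq_len(ncol(fs))) {
        cy <- ceiling(((by - 1) * fine + 1) / coarse)
        cx <- ceiling(((bx - 1) * fine + 1) / coarse)
        fine_sel[by, bx] <- cand[min(cy, nrow(cand)), min(cx, ncol(cand))]
      }
    }
    sel <- which(fine_sel, arr.ind = TRUE)
  } else {
    fcl <- cutree(hclust(dist(fvals), method = "ward.D2"), kf)
    fpx <- vapply(1:kf, function(k) sum(fcl == k) * fine * fine, numeric(1))
    ft <- which.min(fpx)
    idx <- which(fb_in, arr.ind = TRUE)
    sel <- idx[fcl == ft, , drop = FALSE]
  }
  mask <- matrix(0, nr, nc)
  for (j in seq_len(nrow(sel))) {
    y0 <- (sel[j, 1] - 1) * fine + 1; y1 <- min(sel[j, 1] * fine, nr)
    x0 <- (sel[j, 2] - 1) * fine + 1; x1 <- min(sel[j, 2] * fine, nc)
    mask[y0:y1, x0:x1] <- 1
  }
  if (mean(mask) > 0.5) return(empty)   # least class must stay a minority
  box <- NULL
  if (sum(mask) > 0) {
    ys <- range(which(rowSums(mask) > 0)); xs <- range(which(colSums(mask) > 0))
    box <- c(x0 = xs[1] - 1L, x1 = xs[2], y0 = ys[1] - 1L, y1 = ys[2])
  }
  list(k_coarse = kc, k_fine = kf, class_map = clm, tamper_mask = mask,
       tamper_box = box)
}
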