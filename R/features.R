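# Feature extraction ---------------------------------------------------------
#
# The 166-dimensional descriptor: 7 whole-image histogram statistics,
# the same 7 statistics on a 3x3 block partition (63), and 4 moments of the
# magnitude response of a 24-filter Gabor bank (96).
#
# Normative formulas (on the normalized 256-bin histogram p(i), i = 0..255):
#   mean      = sum i p(i)
#   sd        = sqrt(sum (i - mean)^2 p(i))
#   skewness  = 3rd standardized moment (0 when sd = 0)
#   kurtosis  = 4th standardized moment (0 when sd = 0)
#   energy    = sum p(i)^2
#   entropy   = -sum p(i) log2 p(i), 0 log 0 := 0
#   smoothness = 1 - 1/(1 + sigma01^2), sigma01 = sd of intensities
#                rescaled to [0, 1]

GABOR_SCALES <- c(2.0, 2.5, 3.0, 3.5)       # wavelength, pixels per cycle
GABOR_ORIENTATIONS <- c(0, 60, 120, 180, 240, 300)  # degrees

#' Seven histogram statistics of a grayscale image
#'
#' @param img grayscale image.
#' @return named numeric vector: mean, sd, skewness, kurtosis, energy,
#'   entropy, smoothness.
#' @export
histogram_stats <- function(img) {
  h <- hist256(img)
  n <- sum(h)
  if (n == 0) stop("empty image")
  p <- h / n
  i <- 0:255
  mu <- sum(i * p)
  v <- sum((i - mu)^2 * p)
  s <- sqrt(v)
  if (s > 0) {
    skew <- sum(((i - mu) / s)^3 * p)
    kurt <- sum(((i - mu) / s)^4 * p)
  } else {
    skew <- 0
    kurt <- 0
  }
  energy <- sum(p^2)
  pp <- p[p > 0]
  entropy <- -sum(pp * log2(pp))
  s01 <- s / 255
  smoothness <- 1 - 1 / (1 + s01^2)
  c(mean = mu, sd = s, skewness = skew, kurtosis = kurt,
    energy = energy, entropy = entropy, smoothness = smoothness)
}

# block edges: boundary j at ceiling(j * extent / 3); earlier blocks absorb
# the remainder (width 10 -> 4, 3, 3)
block_edges <- function(extent) ceiling((0:3) * extent / 3)

#' Histogram statistics on a 3x3 block partition
#'
#' The image is split into 3x3 blocks (row-major order; earlier blocks
#' absorb remainder pixels when a dimension is not divisible by 3) and the
#' seven histogram statistics are computed per block.
#'
#' @param img grayscale image, at least 3x3.
#' @return named numeric vector of length 63.
#' @export
block_stats <- function(img) {
  g <- gray8(img)
  if (nrow(g) < 3 || ncol(g) < 3) stop("image must be at least 3x3")
  re <- block_edges(nrow(g))
  ce <- block_edges(ncol(g))
  out <- numeric(0)
  for (r in 1:3) {
    for (cc in 1:3) {
      blk <- g[(re[r] + 1):re[r + 1], (ce[cc] + 1):ce[cc + 1], drop = FALSE]
      st <- histogram_stats(blk)
      names(st) <- sprintf("b%d%d_%s", r, cc, names(st))
      out <- c(out, st)
    }
  }
  out
}

#' Build one Gabor kernel (quadrature pair)
#'
#' Wavelength is interpreted as pixels per cycle; the Gaussian envelope has
#' sigma = 0.56 * wavelength, aspect ratio 0.5, truncated at 3 sigma.
#'
#' @param wavelength wavelength in pixels.
#' @param theta_deg orientation in degrees.
#' @return list with `even` and `odd` kernel matrices.
#' @export
gabor_kernel <- function(wavelength, theta_deg) {
  sigma <- 0.56 * wavelength
  gamma <- 0.5
  hw <- ceiling(3 * sigma)
  xy <- -hw:hw
  th <- theta_deg * pi / 180
  # kernel x runs along image columns, y along rows
  Y <- matrix(xy, 2 * hw + 1, 2 * hw + 1)
  X <- t(Y)
  xr <- X * cos(th) + Y * sin(th)
  yr <- -X * sin(th) + Y * cos(th)
  env <- exp(-(xr^2 + (gamma * yr)^2) / (2 * sigma^2))
  list(even = env * cos(2 * pi * xr / wavelength),
       odd  = env * sin(2 * pi * xr / wavelength))
}

# cache of zero-padded, center-shifted kernel FFTs keyed by image dims
.gabor_cache <- new.env(parent = emptyenv())

gabor_kernel_ffts <- function(nr, nc) {
  key <- paste(nr, nc, sep = "x")
  if (!is.null(.gabor_cache[[key]])) return(.gabor_cache[[key]])
  out <- list()
  idx <- 0
  for (lam in GABOR_SCALES) {
    for (ori in GABOR_ORIENTATIONS) {
      idx <- idx + 1
      kk <- gabor_kernel(lam, ori)
      kc <- kk$even + 1i * kk$odd
      kdim <- nrow(kc)
      hw <- (kdim - 1) / 2
      pad <- matrix(0i, nr, nc)
      pad[1:kdim, 1:kdim] <- kc
      # shift so the kernel center sits at (1, 1) for circular convolution
      pad <- pad[c((hw + 1):nr, 1:hw), c((hw + 1):nc, 1:hw)]
      out[[idx]] <- fft(pad)
    }
  }
  .gabor_cache[[key]] <- out
  out
}

#' Gabor filter-bank features
#'
#' Applies the 24-filter bank (4 scales x 6 orientations) by circular FFT
#' convolution, takes the magnitude of the quadrature response and records
#' its mean, variance, skewness and kurtosis, in scale-major order.
#'
#' @param img grayscale image larger than the largest kernel (13x13).
#' @return named numeric vector of length 96.
#' @export
gabor_features <- function(img) {
  g <- gray8(img)
  hwmax <- ceiling(3 * 0.56 * max(GABOR_SCALES))
  if (nrow(g) < 2 * hwmax + 1 || ncol(g) < 2 * hwmax + 1) {
    stop("image smaller than the largest Gabor kernel")
  }
  Fimg <- fft(g)
  kf <- gabor_kernel_ffts(nrow(g), ncol(g))
  out <- numeric(0)
  idx <- 0
  for (lam in GABOR_SCALES) {
    for (ori in GABOR_ORIENTATIONS) {
      idx <- idx + 1
      # complex kernel (even + i*odd): one circular convolution yields both
      # quadrature responses
      resp <- fft(Fimg * kf[[idx]], inverse = TRUE) / length(g)
      v <- as.vector(Mod(resp))
      mu <- mean(v)
      d <- v - mu
      d2 <- d * d
      vv <- mean(d2)
      if (vv > 0) {
        sk <- mean(d2 * d) / vv^1.5
        ku <- mean(d2 * d2) / vv^2
      } else {
        sk <- 0; ku <- 0
      }
      st <- c(mu, vv, sk, ku)
      names(st) <- sprintf("gabor_s%.1f_o%03d_%s", lam, ori,
                           c("mean", "var", "skewness", "kurtosis"))
      out <- c(out, st)
    }
  }
  out
}

#' Extract the full 166-dimensional feature vector
#'
#' Concatenation of [histogram_stats()] (7), [block_stats()] (63) and
#' [gabor_features()] (96), in that order.
#'
#' @param img grayscale image (>= 3x3 and larger than the Gabor kernels).
#' @return named numeric vector of length 166 with attribute
#'   `layout_version`.
#' @export
extract_features <- function(img) {
  v <- c(histogram_stats(img), block_stats(img), gabor_features(img))
  stopifnot(length(v) == 166)
  attr(v, "layout_version") <- "hist7+block63+gabor96/v1"
  v
}

#' Feature matrix for a list of images
#'
#' @param imgs list of grayscale images.
#' @return numeric matrix, one row per image, 166 named columns.
#' @export
feature_matrix <- function(imgs) {
  rows <- lapply(imgs, function(im) {
    f <- extract_features(im)
    attributes(f)["layout_version"] <- NULL
    f
  })
  do.call(rbind, rows)
}

#' Write a feature matrix to CSV
#'
#' One row per image with the stable 166-column header.
#'
#' @param fm matrix from [feature_matrix()].
#' @param path output CSV path.
#' @param ids optional row identifiers (first column `image_id`).
#' @export
write_features_csv <- function(fm, path, ids = NULL) {
  df <- as.data.frame(fm)
  if (!is.null(ids)) df <- cbind(image_id = ids, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
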