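# Histogram thresholding -----------------------------------------------------
#
# All sixteen methods operate on the 256-bin histogram of the 8-bit image
# view.  Split-based methods evaluate their objective at every candidate
# split k (background = bins 0..k, foreground = bins k+1..255) and return the
# threshold T = k + 1 on the 0..255 intensity scale, so that binarization
# with `pixel >= T` reproduces the chosen split on integer images.  Ties in
# an objective are broken toward the lower intensity.  Statistic-style
# methods (Mean, Percentile, Triangle) return their statistic directly.

#' Available thresholding methods
#' @return character vector of the sixteen registered method names.
#' @export
threshold_methods <- function() {
  c("triangle", "otsu", "mean", "percentile", "li", "intermodes", "minimum",
    "isodata", "maxentropy", "renyientropy", "minerror", "moments",
    "shanbhag", "yen", "huang", "huang2")
}

#' Compute a global threshold for a grayscale image
#'
#' Dispatches to one of sixteen classical histogram thresholding methods.
#' The returned value is on the 0..255 scale of the 8-bit image view;
#' `binarize_image()` treats `pixel >= T` as foreground.
#'
#' @param img grayscale image (matrix; fractions or 8/16-bit).
#' @param method one of [threshold_methods()].
#' @return numeric threshold on the 0..255 scale.
#' @examples
#' img <- matrix(c(rep(40, 60), rep(200, 40)), 10, 10)
#' threshold_image(img, "mean")   # 104
#' @export
threshold_image <- function(img, method = "triangle") {
  method <- match.arg(tolower(method), threshold_methods())
  h <- hist256(img)
  fn <- switch(method,
    triangle     = th_triangle,
    otsu         = th_otsu,
    mean         = th_mean,
    percentile   = th_percentile,
    li           = th_li,
    intermodes   = th_intermodes,
    minimum      = th_minimum,
    isodata      = th_isodata,
    maxentropy   = th_maxentropy,
    renyientropy = th_renyi,
    minerror     = th_minerror,
    moments      = th_moments,
    shanbhag     = th_shanbhag,
    yen          = th_yen,
    huang        = th_huang,
    huang2       = th_huang2)
  fn(h)
}

#' Binarize an image at a threshold
#'
#' @param img grayscale image.
#' @param T threshold on the 0..255 scale; pixels `>= T` become foreground.
#' @return binary (0/1) matrix of the same dimensions.
#' @export
binarize_image <- function(img, T) {
  g <- gray8(img)
  (g >= T) * 1
}

#' Record a corrected threshold decision
#'
#' The final threshold is the product of the raw method threshold and a
#' correction factor `c`, clipped to the valid intensity range.
#'
#' @param method method name.
#' @param raw_threshold raw threshold from the method.
#' @param correction_factor positive multiplier (default 1).
#' @return object of class `threshold_decision` with fields `method`,
#'   `raw_threshold`, `correction_factor`, `final_threshold`.
#' @export
threshold_decision <- function(method, raw_threshold, correction_factor = 1) {
  stopifnot(correction_factor > 0, is.finite(raw_threshold))
  structure(list(
    method = method,
    raw_threshold = raw_threshold,
    correction_factor = correction_factor,
    final_threshold = clamp(raw_threshold * correction_factor, 0, 255)
  ), class = "threshold_decision")
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf("Threshold decision [%s]: raw = %.3f, c = %.3f, final = %.3f\n",
              x$method, x$raw_threshold, x$correction_factor,
              x$final_threshold))
  invisible(x)
}

# -- internals ---------------------------------------------------------------

# class statistics for every split k = 0..254 given counts h[1..256]
split_stats <- function(h) {
  n <- sum(h)
  i <- 0:255
  p <- h / n
  P0 <- cumsum(p)[1:255]          # background mass for k = 0..254
  P1 <- 1 - P0
  S0 <- cumsum(i * p)[1:255]      # background first moment
  mu <- sum(i * p)
  S1 <- mu - S0
  list(i = i, p = p, P0 = P0, P1 = P1, S0 = S0, S1 = S1, mu = mu, n = n)
}

# lowest split index among maximizers (NA-safe), converted to threshold k+1
best_split <- function(obj, maximize = TRUE) {
  if (!maximize) obj <- -obj
  obj[!is.finite(obj)] <- -Inf
  if (all(obj == -Inf)) stop("degenerate histogram: objective undefined")
  which.max(obj)  # which.max returns the first (lowest k) maximizer; k = idx-1
}

th_mean <- function(h) {
  i <- 0:255
  sum(i * h) / sum(h)
}

th_percentile <- function(h) {
  cum <- cumsum(h) / sum(h)
  min(which(cum >= 0.5)) - 1
}

th_otsu <- function(h) {
  s <- split_stats(h)
  valid <- s$P0 > 0 & s$P1 > 0
  obj <- rep(NA_real_, 255)
  obj[valid] <- (s$S0[valid] - s$mu * s$P0[valid])^2 /
    (s$P0[valid] * s$P1[valid])
  if (!any(valid)) return(th_mean(h))  # constant image
  best_split(obj)  # threshold = k + 1 = index
}

th_li <- function(h) {
  s <- split_stats(h)
  valid <- s$P0 > 0 & s$P1 > 0 & s$S0 > 0 & s$S1 > 0
  if (!any(valid)) return(th_mean(h))
  mu0 <- s$S0 / s$P0
  mu1 <- s$S1 / s$P1
  obj <- rep(NA_real_, 255)
  obj[valid] <- -(s$S0[valid] * log(mu0[valid]) +
                  s$S1[valid] * log(mu1[valid]))
  best_split(obj, maximize = FALSE)
}

th_isodata <- function(h) {
  s <- split_stats(h)
  valid <- s$P0 > 0 & s$P1 > 0
  if (!any(valid)) return(th_mean(h))
  mu0 <- s$S0 / s$P0
  mu1 <- s$S1 / s$P1
  # fixed point: smallest k with k >= (mu0 + mu1)/2 - 0.5 among valid splits
  target <- (mu0 + mu1) / 2
  k <- 0:254
  ok <- valid & (k + 1 >= target)
  if (!any(ok)) return(255)
  min(which(ok))  # threshold k + 1 = index
}

shannon_part <- function(p, P) {
  # entropy of a class with bin masses p and total mass P
  q <- p[p > 0] / P
  -sum(q * log(q))
}

th_maxentropy <- function(h) {
  p <- h / sum(h)
  cp <- cumsum(p)
  obj <- rep(NA_real_, 255)
  for (k in 0:254) {
    P0 <- cp[k + 1]; P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    obj[k + 1] <- shannon_part(p[1:(k + 1)], P0) +
      shannon_part(p[(k + 2):256], P1)
  }
  if (all(is.na(obj))) return(th_mean(h))
  best_split(obj)
}

th_renyi <- function(h, alpha = 0.5) {
  # Renyi entropy of order 1/2 in place of Shannon entropy
  p <- h / sum(h)
  cp <- cumsum(p)
  obj <- rep(NA_real_, 255)
  for (k in 0:254) {
    P0 <- cp[k + 1]; P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    H0 <- log(sum((p[1:(k + 1)] / P0)^alpha)) / (1 - alpha)
    H1 <- log(sum((p[(k + 2):256] / P1)^alpha)) / (1 - alpha)
    obj[k + 1] <- H0 + H1
  }
  if (all(is.na(obj))) return(th_mean(h))
  best_split(obj)
}

th_yen <- function(h) {
  p <- h / sum(h)
  P0 <- cumsum(p)[1:255]
  P1 <- 1 - P0
  G0 <- cumsum(p^2)[1:255]
  G1 <- sum(p^2) - G0
  valid <- P0 > 0 & P1 > 0 & G0 > 0 & G1 > 0
  if (!any(valid)) return(th_mean(h))
  obj <- rep(NA_real_, 255)
  obj[valid] <- -log(G0[valid] * G1[valid]) +
    2 * log(P0[valid] * P1[valid])
  best_split(obj)
}

th_minerror <- function(h) {
  # Kittler & Illingworth criterion under two-normal histogram model
  s <- split_stats(h)
  i <- 0:255
  p <- s$p
  Q0 <- cumsum(i^2 * p)[1:255]
  Q1 <- sum(i^2 * p) - Q0
  mu0 <- s$S0 / s$P0
  mu1 <- s$S1 / s$P1
  v0 <- Q0 / s$P0 - mu0^2
  v1 <- Q1 / s$P1 - mu1^2
  valid <- s$P0 > 0 & s$P1 > 0 & v0 > 1e-8 & v1 > 1e-8
  if (!any(valid)) return(th_otsu(h))
  obj <- rep(NA_real_, 255)
  obj[valid] <- 1 + 2 * (s$P0[valid] * log(sqrt(v0[valid])) +
                         s$P1[valid] * log(sqrt(v1[valid]))) -
    2 * (s$P0[valid] * log(s$P0[valid]) + s$P1[valid] * log(s$P1[valid]))
  best_split(obj, maximize = FALSE)
}

th_moments <- function(h) {
  # Tsai's moment preservation (closed form)
  p <- h / sum(h)
  i <- 0:255
  m1 <- sum(i * p); m2 <- sum(i^2 * p); m3 <- sum(i^3 * p)
  cd <- m2 - m1^2
  if (cd <= 1e-12) return(th_mean(h))
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(th_otsu(h))
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  pd <- (z1 - m1) / (z1 - z0)   # target background fraction
  cum <- cumsum(p)
  min(which(cum >= pd)) - 1 + 1  # split at that fractile; threshold = k + 1
}

huang_objective <- function(h) {
  # Huang & Wang fuzziness (Shannon entropy of membership), per split
  s <- split_stats(h)
  C <- 255
  obj <- rep(NA_real_, 255)
  i <- 0:255
  for (k in 0:254) {
    if (s$P0[k + 1] <= 0 || s$P1[k + 1] <= 0) next
    mu0 <- s$S0[k + 1] / s$P0[k + 1]
    mu1 <- s$S1[k + 1] / s$P1[k + 1]
    u <- numeric(256)
    u[1:(k + 1)] <- 1 / (1 + abs(i[1:(k + 1)] - mu0) / C)
    u[(k + 2):256] <- 1 / (1 + abs(i[(k + 2):256] - mu1) / C)
    hf <- -u * log(u) - (1 - u) * log(1 - u)
    hf[!is.finite(hf)] <- 0
    obj[k + 1] <- sum(s$p * hf)
  }
  obj
}

th_huang <- function(h) {
  obj <- huang_objective(h)
  if (all(is.na(obj))) return(th_mean(h))
  best_split(obj, maximize = FALSE)
}

th_huang2 <- function(h) {
  # alternative evaluation path of the same fuzziness objective using
  # cumulative sums restricted to the occupied gray-level range; the
  # minimizer is identical by construction
  nz <- which(h > 0)
  if (length(nz) <= 1) return(th_mean(h))
  lo <- min(nz) - 1; hi <- max(nz) - 1
  hh <- h
  obj <- huang_objective(hh)
  ks <- lo:(hi - 1)
  ks <- ks[ks >= 0 & ks <= 254]
  sub <- obj[ks + 1]
  if (all(is.na(sub))) return(th_mean(h))
  ks[which.min(sub)] + 1
}

smooth_until_bimodal <- function(h, max_iter = 10000) {
  # iterative 3-tap mean smoothing of the histogram until exactly two local
  # maxima remain
  x <- as.numeric(h)
  if (sum(x > 0) < 2) stop("degenerate histogram: no two modes exist")
  n_modes <- function(v) {
    m <- 0
    for (j in 2:255) if (v[j] > v[j - 1] && v[j] >= v[j + 1]) m <- m + 1
    m
  }
  it <- 0
  while (n_modes(x) > 2 && it < max_iter) {
    x <- (c(x[1], x[-256]) + x + c(x[-1], x[256])) / 3
    it <- it + 1
  }
  if (n_modes(x) != 2) stop("degenerate histogram: could not isolate two modes")
  x
}

hist_modes <- function(x) {
  which(vapply(2:255, function(j) x[j] > x[j - 1] && x[j] >= x[j + 1],
               logical(1))) + 1
}

th_intermodes <- function(h) {
  x <- smooth_until_bimodal(h)
  m <- hist_modes(x)
  floor((sum(m[1:2] - 1)) / 2)
}

th_minimum <- function(h) {
  x <- smooth_until_bimodal(h)
  m <- hist_modes(x)
  seg <- (m[1] + 1):(m[2] - 1)
  if (length(seg) == 0) return(m[1] - 1 + 1)
  seg[which.min(x[seg])] - 1
}

th_triangle <- function(h) {
  nz <- which(h > 0)
  if (length(nz) <= 1) return(nz[1] - 1)
  peak <- which.max(h)
  lo <- min(nz); hi <- max(nz)
  # work on the longer tail; mirror so the tail is to the right of the peak
  if ((peak - lo) > (hi - peak)) {
    hh <- rev(h); peak <- 257 - peak; tail_end <- 257 - lo; flipped <- TRUE
  } else {
    hh <- h; tail_end <- hi; flipped <- FALSE
  }
  if (tail_end <= peak) return(peak - 1)
  ks <- peak:tail_end
  # distance from chord (peak, h[peak]) -- (tail_end, 0) to (k, h[k])
  dx <- tail_end - peak
  dy <- 0 - hh[peak]
  num <- abs(dy * (ks - peak) - dx * (hh[ks] - hh[peak]))
  kbest <- ks[which.max(num)]
  if (flipped) kbest <- 257 - kbest
  kbest - 1
}

th_shanbhag <- function(h) {
  # Shanbhag's fuzzy-set information measure (follows the standard
  # formulation built on left/right cumulative membership)
  p <- h / sum(h)
  cp <- cumsum(p)
  obj <- rep(NA_real_, 255)
  for (k in 0:254) {
    P0 <- cp[k + 1]; P1 <- 1 - P0
    if (P0 <= 1e-12 || P1 <= 1e-12) next
    # background: fuzzy information weighted by the mass below each bin
    term0 <- 0; W <- 0
    for (j in 1:(k + 1)) {
      if (p[j] > 1e-12) term0 <- term0 - p[j] * log(1 - W / P0)
      W <- W + p[j]
    }
    term0 <- term0 / P0
    # foreground: mass above each bin
    term1 <- 0; W <- 0
    for (j in 256:(k + 2)) {
      if (p[j] > 1e-12) term1 <- term1 - p[j] * log(1 - W / P1)
      W <- W + p[j]
    }
    term1 <- term1 / P1
    obj[k + 1] <- abs(term0 - term1)
  }
  if (all(is.na(obj))) return(th_mean(h))
  best_split(obj, maximize = FALSE)
}
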