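# Preprocessing and segmentation --------------------------------------------

#' Edge-preserving bilateral denoising
#'
#' Classic bilateral filter: each pixel is replaced by a weighted mean of
#' its neighbourhood, with weights the product of a spatial Gaussian
#' (`spatial_sigma`, pixels) and a range Gaussian on intensity difference
#' (`range_sigma`, same units as the image). The window is truncated at
#' 2 spatial sigma.
#'
#' @param img grayscale image (any intensity scale; output on the same
#'   scale).
#' @param spatial_sigma spatial standard deviation in pixels (> 0).
#' @param range_sigma range standard deviation in intensity units (> 0);
#'   default 0.1 of the image dynamic range.
#' @return filtered matrix, same dimensions and range.
#' @export
denoise_bilateral <- function(img, spatial_sigma = 3,
                              range_sigma = NULL) {
  g <- to_gray(img)
  if (is.null(range_sigma)) {
    dr <- diff(range(g))
    range_sigma <- if (dr > 0) 0.1 * dr else 1
  }
  if (spatial_sigma <= 0 || range_sigma <= 0) {
    stop("bilateral filter sigmas must be positive")
  }
  bilateral_cpp(g, spatial_sigma, range_sigma)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Thin wrapper around `EBImage::clahe()` operating on the \[0,1\] view and
#' returning the result on the input's intensity scale.
#'
#' @param img grayscale image.
#' @param tiles number of tiles per side (default 8).
#' @param clip_limit normalized clip limit (default 0.01).
#' @return contrast-enhanced matrix on the 0..255 scale.
#' @export
clahe_enhance <- function(img, tiles = 8, clip_limit = 0.01) {
  if (tiles < 1 || clip_limit <= 0) stop("invalid CLAHE parameters")
  g <- gray8(img)
  if (nrow(g) < tiles || ncol(g) < tiles) {
    stop("image smaller than the CLAHE tile grid")
  }
  if (diff(range(g)) < 1e-12) return(g)   # constant image: nothing to equalize
  # EBImage clahe needs dimensions divisible by the tile grid: pad by
  # replication and crop back
  nr <- nrow(g); nc <- ncol(g)
  nr2 <- ceiling(nr / tiles) * tiles
  nc2 <- ceiling(nc / tiles) * tiles
  gp <- g[c(1:nr, rep(nr, nr2 - nr)), c(1:nc, rep(nc, nc2 - nc)),
          drop = FALSE]
  # EBImage clahe: limit is a multiple of the uniform bin content; output
  # is rescaled to the full intensity range (contrast expansion)
  out <- EBImage::clahe(gp / 255, nx = tiles, ny = tiles,
                        limit = clip_limit * 256, keep.range = FALSE)
  out <- matrix(as.numeric(out), nr2, nc2)[1:nr, 1:nc]
  matrix(pmin(pmax(out, 0), 1) * 255, nr, nc)
}

#' Default preprocessing chain
#'
#' Grayscale conversion, bilateral denoising and CLAHE, as used ahead of
#' thresholding.
#'
#' @param img input image (grayscale or RGB).
#' @param denoise,enhance logical switches.
#' @param spatial_sigma,range_sigma,tiles,clip_limit filter parameters.
#' @return preprocessed matrix on the 0..255 scale.
#' @export
preprocess_image <- function(img, denoise = TRUE, enhance = TRUE,
                             spatial_sigma = 3, range_sigma = NULL,
                             tiles = 8, clip_limit = 0.01) {
  g <- gray8(img)
  if (denoise) g <- denoise_bilateral(g, spatial_sigma, range_sigma)
  if (enhance) g <- clahe_enhance(g, tiles, clip_limit)
  g
}

#' Split touching foreground objects with the watershed transform
#'
#' Runs the watershed transform on the distance map of the binary mask so
#' that touching or overlapping cells are separated at distance-ridge
#' lines.
#'
#' @param mask binary (0/1) matrix.
#' @param tolerance,ext passed to `EBImage::watershed()`.
#' @return integer label matrix (0 = background).
#' @export
watershed_split <- function(mask, tolerance = 1, ext = 1) {
  m <- (to_gray(mask) > 0) * 1
  if (sum(m) == 0) return(matrix(0L, nrow(m), ncol(m)))
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  matrix(as.integer(lab), nrow(m), ncol(m))
}
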