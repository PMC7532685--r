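# Rule-based phenotyping core ------------------------------------------------
#
# Chain per FOV: binarize channels -> watershed the nucleus mask -> purge
# non-nucleic objects (area outside 200..2000 px or eccentricity > 0.8) ->
# build the combinatorial cytoplasmic mask for a phenotype pattern -> apply
# it to the nucleus mask -> region-growing area-ratio filter (< 0.6
# removed) -> blob detection = surviving objects are cells.

object_props <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  nlab <- max(labels)
  if (nlab == 0) {
    return(data.frame(label = integer(0), y = numeric(0), x = numeric(0),
                      area = numeric(0), eccentricity = numeric(0)))
  }
  # EBImage indexes dim1 as its x; our matrices are [row = y, col = x]
  mom <- EBImage::computeFeatures.moment(labels)
  shp <- EBImage::computeFeatures.shape(labels)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  if (is.null(dim(shp))) shp <- matrix(shp, nrow = 1,
                                       dimnames = list(NULL, names(shp)))
  data.frame(label = seq_len(nlab),
             y = mom[, "m.cx"], x = mom[, "m.cy"],
             area = shp[, "s.area"],
             eccentricity = mom[, "m.eccentricity"])
}

#' Remove non-nucleic objects from a labeled nucleus mask
#'
#' Objects with area < `min_area`, area > `max_area` or eccentricity >
#' `max_eccentricity` are removed and the remaining labels re-compacted.
#' Defaults follow the printed filtering rule (200, 2000 pixels, 0.8); the
#' bounds are magnification dependent and therefore exposed.
#'
#' @param labels integer label matrix (e.g. from [watershed_split()]).
#' @param min_area,max_area area bounds in pixels.
#' @param max_eccentricity eccentricity bound.
#' @return integer label matrix with surviving objects relabeled 1..n.
#' @export
filter_nucleus_objects <- function(labels, min_area = 200, max_area = 2000,
                                   max_eccentricity = 0.8) {
  props <- object_props(labels)
  if (nrow(props) == 0) return(matrix(0L, nrow(labels), ncol(labels)))
  bad <- props$label[props$area < min_area | props$area > max_area |
                       props$eccentricity > max_eccentricity]
  out <- labels
  if (length(bad) > 0) {
    out <- EBImage::rmObjects(matrix(as.integer(labels), nrow(labels),
                                     ncol(labels)), bad, reenumerate = TRUE)
  }
  matrix(as.integer(out), nrow(labels), ncol(labels))
}

#' Build a combinatorial cytoplasmic mask
#'
#' Multiplies the binary marker masks selected by the pattern, inverting
#' masks whose pattern entry is `"-"`; entries `"0"` are excluded from the
#' product. An empty effective pattern yields an all-ones mask.
#'
#' @param masks list of binary marker masks (same dimensions).
#' @param pattern character vector over the masks, entries `"+"`, `"-"` or
#'   `"0"`.
#' @return binary mask.
#' @export
build_cytoplasm_mask <- function(masks, pattern) {
  stopifnot(length(pattern) == length(masks))
  dims <- lapply(masks, dim)
  if (length(masks) > 1 &&
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("marker masks have mismatched dimensions")
  }
  if (length(masks) == 0) stop("no marker masks supplied")
  out <- matrix(1, nrow(masks[[1]]), ncol(masks[[1]]))
  for (i in seq_along(masks)) {
    if (pattern[i] == "0") next
    m <- (to_gray(masks[[i]]) > 0) * 1
    out <- out * if (pattern[i] == "+") m else 1 - m
  }
  out
}

#' Region-growing area-ratio filter
#'
#' For every object of the masked nucleus image, grows a region from its
#' centroid in both the masked image and the filtered nucleus labeling and
#' compares the two areas; objects with ratio (masked/filtered) below the
#' cutoff are removed. Objects whose centroid falls on background of the
#' filtered image are skipped with a warning (counted as removed).
#'
#' @param masked_mask binary mask = nucleus mask restricted to the
#'   cytoplasmic mask.
#' @param filtered_labels label matrix of the filtered nucleus image.
#' @param ratio_cutoff removal threshold (default 0.6; strict `<`).
#' @return data frame of surviving cells: `label` (filtered-nucleus
#'   label), `x`, `y`, `area`, `eccentricity`, `ratio`.
#' @export
area_ratio_filter <- function(masked_mask, filtered_labels,
                              ratio_cutoff = 0.6) {
  mm <- (to_gray(masked_mask) > 0) * 1
  mlab <- matrix(as.integer(EBImage::bwlabel(mm)), nrow(mm), ncol(mm))
  mprops <- object_props(mlab)
  fprops <- object_props(filtered_labels)
  keep <- list()
  skipped <- 0L
  for (j in seq_len(nrow(mprops))) {
    ry <- clamp(round(mprops$y[j]), 1, nrow(mm))
    rx <- clamp(round(mprops$x[j]), 1, ncol(mm))
    flab <- filtered_labels[ry, rx]
    if (flab == 0) { skipped <- skipped + 1L; next }
    fa <- fprops$area[fprops$label == flab]
    ratio <- mprops$area[j] / fa
    if (ratio < ratio_cutoff) next
    fr <- fprops[fprops$label == flab, ]
    keep[[length(keep) + 1]] <- data.frame(
      label = flab, x = fr$x, y = fr$y, area = fr$area,
      eccentricity = fr$eccentricity, ratio = ratio)
  }
  if (skipped > 0) {
    warning(skipped, " object(s) skipped: centroid on background of the ",
            "filtered nucleus image")
  }
  out <- if (length(keep) > 0) do.call(rbind, keep) else
    data.frame(label = integer(0), x = numeric(0), y = numeric(0),
               area = numeric(0), eccentricity = numeric(0),
               ratio = numeric(0))
  # one filtered nucleus cannot be claimed twice (ratios sum to <= 1), but
  # guard against pathological masks
  out[!duplicated(out$label), , drop = FALSE]
}

#' Pipeline configuration
#'
#' @param method thresholding method (default `"triangle"`).
#' @param correction_model optional [train_correction_model()] fit applied
#'   to the nucleus/marker thresholds.
#' @param denoise,enhance preprocessing switches (bilateral filter, CLAHE).
#' @param spatial_sigma,range_sigma bilateral filter parameters.
#' @param tiles,clip_limit CLAHE parameters.
#' @param min_area,max_area,max_eccentricity nucleus filter bounds.
#' @param min_marker_area marker-mask despeckle floor: binary marker-mask
#'   components smaller than this (in pixels, well below cell scale) are
#'   removed before the cytoplasmic masks are built.
#' @param ratio_cutoff area-ratio removal cutoff.
#' @param tolerance watershed tolerance (0.5 default: splits
#'   deeply-overlapped nucleus pairs more reliably than the transform's
#'   usual 1 while leaving single ellipses intact).
#' @return a `pheno_config` list.
#' @export
pheno_config <- function(method = "triangle", correction_model = NULL,
                         denoise = TRUE, enhance = TRUE,
                         spatial_sigma = 3, range_sigma = NULL,
                         tiles = 8, clip_limit = 0.01, min_area = 200,
                         max_area = 2000, max_eccentricity = 0.8,
                         min_marker_area = 50,
                         ratio_cutoff = 0.6, tolerance = 0.5) {
  structure(list(method = method, correction_model = correction_model,
                 denoise = denoise, enhance = enhance,
                 spatial_sigma = spatial_sigma, range_sigma = range_sigma,
                 tiles = tiles, clip_limit = clip_limit,
                 min_area = min_area,
                 max_area = max_area, max_eccentricity = max_eccentricity,
                 min_marker_area = min_marker_area,
                 ratio_cutoff = ratio_cutoff, tolerance = tolerance),
            class = "pheno_config")
}

# drop binary-mask components below a pixel floor
despeckle_mask <- function(mask, min_px) {
  if (min_px <= 1 || sum(mask) == 0) return(mask)
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  out <- (matrix(sizes[ifelse(lab == 0, NA, lab)],
                 nrow(lab), ncol(lab)) >= min_px)
  out[is.na(out)] <- FALSE
  out * 1
}

# binarize all channels of an FOV once; returns masks + filtered labels
segment_fov <- function(fov, config = pheno_config()) {
  binmask <- function(img) {
    g <- preprocess_image(img, denoise = config$denoise,
                          enhance = config$enhance,
                          spatial_sigma = config$spatial_sigma,
                          range_sigma = config$range_sigma,
                          tiles = config$tiles,
                          clip_limit = config$clip_limit)
    dec <- corrected_threshold(g, config$correction_model, config$method)
    binarize_image(g, dec$final_threshold)
  }
  nuc_mask <- binmask(fov$nucleus)
  # drop sub-minimum specks before the watershed: they could never pass the
  # area filter (watershed only splits components) and they dominate its cost
  lab0 <- matrix(as.integer(EBImage::bwlabel(nuc_mask)), nrow(nuc_mask),
                 ncol(nuc_mask))
  if (max(lab0) > 0) {
    sizes <- tabulate(lab0[lab0 > 0], nbins = max(lab0))
    nuc_mask <- (matrix(sizes[ifelse(lab0 == 0, NA, lab0)],
                        nrow(lab0), ncol(lab0)) >= config$min_area)
    nuc_mask[is.na(nuc_mask)] <- FALSE
    nuc_mask <- nuc_mask * 1
  }
  labels <- watershed_split(nuc_mask, tolerance = config$tolerance)
  filtered <- filter_nucleus_objects(labels, config$min_area,
                                     config$max_area,
                                     config$max_eccentricity)
  marker_masks <- lapply(fov$markers, function(img) {
    despeckle_mask(binmask(img), config$min_marker_area)
  })
  list(nucleus_mask = nuc_mask, filtered_labels = filtered,
       marker_masks = marker_masks)
}

#' Enumerate one phenotype in a field of view
#'
#' Runs the full rule-based chain for a single marker pattern and returns
#' one cell record per surviving blob.
#'
#' @param fov an `fov` list (fields `nucleus`, `markers`, `pixel_size`).
#' @param pattern character vector over the FOV's marker channels with
#'   entries `"+"`, `"-"` or `"0"`; e.g. `c("+", "-", "0")`. Length 0 (or
#'   all `"0"`) enumerates nuclei regardless of markers.
#' @param config a [pheno_config()].
#' @param segmented optional precomputed [segment_fov()] result (lets
#'   callers enumerate many phenotypes without re-binarizing).
#' @param phenotype label attached to the records.
#' @return list with `records` (data frame id, x, y, area, eccentricity,
#'   equivalent_diameter, phenotype), `count` and `labels` (overlay label
#'   matrix of the detected cells).
#' @export
enumerate_phenotype <- function(fov, pattern, config = pheno_config(),
                                segmented = NULL, phenotype = NA_character_) {
  if (length(pattern) > length(fov$markers)) {
    stop("pattern references marker channel ", length(pattern),
         " but the FOV has only ", length(fov$markers))
  }
  if (is.null(segmented)) segmented <- segment_fov(fov, config)
  filt <- segmented$filtered_labels
  if (length(pattern) == 0 || all(pattern == "0")) {
    cells <- object_props(filt)
    cells$ratio <- 1
  } else {
    cyto <- build_cytoplasm_mask(segmented$marker_masks[seq_along(pattern)],
                                 pattern)
    masked <- (filt > 0) * cyto
    cells <- suppressWarnings(
      area_ratio_filter(masked, filt, config$ratio_cutoff))
  }
  px <- if (is.null(fov$pixel_size)) 1 else fov$pixel_size
  rec <- data.frame(
    id = seq_len(nrow(cells)),
    x = cells$x, y = cells$y, area = cells$area,
    eccentricity = cells$eccentricity,
    equivalent_diameter = measure_diameter(cells$area, px),
    phenotype = rep(phenotype, nrow(cells)),
    stringsAsFactors = FALSE)
  overlay <- filt
  overlay[!(overlay %in% cells$label)] <- 0L
  list(records = rec, count = nrow(rec), labels = overlay)
}

#' Enumerate every phenotype of a registry in one FOV
#'
#' Binarizes the FOV once and applies [enumerate_phenotype()] for each
#' pattern.
#'
#' @param fov an `fov` list.
#' @param phenotypes data frame with columns `name` and `pattern` (string
#'   such as `"+-"` over the FOV's marker channels), as produced by
#'   [generate_phenotype_set()].
#' @param config a [pheno_config()].
#' @return list with `records` (all cells, with `phenotype` filled),
#'   `counts` (named integer vector) and `segmented`.
#' @export
enumerate_fov <- function(fov, phenotypes, config = pheno_config()) {
  seg <- segment_fov(fov, config)
  recs <- list(); counts <- integer(0)
  for (j in seq_len(nrow(phenotypes))) {
    pat <- strsplit(phenotypes$pattern[j], "")[[1]]
    r <- enumerate_phenotype(fov, pat, config, segmented = seg,
                             phenotype = phenotypes$name[j])
    recs[[j]] <- r$records
    counts[phenotypes$name[j]] <- r$count
  }
  list(records = do.call(rbind, recs), counts = counts, segmented = seg)
}

#' Equivalent diameter of a cell
#'
#' @param area object area in pixels (vectorized).
#' @param pixel_size physical pixel size in micrometres (> 0).
#' @return equivalent diameter `2 * sqrt(area / pi) * pixel_size`.
#' @export
measure_diameter <- function(area, pixel_size = 1) {
  stopifnot(pixel_size > 0)
  2 * sqrt(area / pi) * pixel_size
}

# 120x120 thumbnail centred on (x, y) with mirrored padding at the borders
cell_thumbnail <- function(img, x, y, size = 120) {
  nr <- nrow(img); nc <- ncol(img)
  half <- size %/% 2
  ridx <- round(y) + (-half):(half - 1) + 1
  cidx <- round(x) + (-half):(half - 1) + 1
  mirror <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    i <- ifelse(i > n, 2 * n - i, i)
    clamp(i, 1, n)
  }
  img[mirror(ridx, nr), mirror(cidx, nc), drop = FALSE]
}

#' Export enumeration results
#'
#' Writes the per-FOV count CSV, the per-cell position CSV, color-coded
#' overlay PNGs and (optionally) one ~120x120 thumbnail per detected cell
#' cropped from the nucleus channel around its centroid (mirror-padded at
#' image borders).
#'
#' @param results named list of [enumerate_fov()] outputs (names = FOV
#'   ids).
#' @param fovs named list of the corresponding `fov` objects (needed for
#'   thumbnails/overlays).
#' @param out_dir output directory.
#' @param thumbnails write per-cell thumbnails.
#' @return invisibly, the output directory.
#' @export
export_results <- function(results, fovs, out_dir, thumbnails = FALSE) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  counts <- list(); cells <- list()
  for (fid in names(results)) {
    res <- results[[fid]]
    counts[[fid]] <- data.frame(fov = fid, phenotype = names(res$counts),
                                count = as.integer(res$counts))
    if (nrow(res$records) > 0) {
      cells[[fid]] <- cbind(fov = fid, res$records)
    }
    lab <- res$segmented$filtered_labels
    col <- EBImage::colorLabels(lab)
    png::writePNG(EBImage::imageData(col),
                  file.path(out_dir, sprintf("%s_overlay.png", fid)))
    if (thumbnails && nrow(res$records) > 0) {
      for (j in seq_len(nrow(res$records))) {
        th <- cell_thumbnail(fovs[[fid]]$nucleus, res$records$x[j],
                             res$records$y[j])
        png::writePNG(clamp(th, 0, 1),
                      file.path(out_dir, sprintf("%s_%s_cell%03d.png", fid,
                                                 res$records$phenotype[j],
                                                 j)))
      }
    }
  }
  write.csv(do.call(rbind, counts), file.path(out_dir, "counts.csv"),
            row.names = FALSE)
  pos <- if (length(cells) > 0) do.call(rbind, cells) else
    data.frame(fov = character(0))
  write.csv(pos, file.path(out_dir, "positions.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Read / write a pipeline configuration file
#'
#' Serializes a [pheno_config()] (minus any fitted correction model) as a
#' small YAML file, so runs can be reproduced from a plain-text config.
#'
#' @param config a `pheno_config`.
#' @param path file path.
#' @return `read_pheno_config()` returns a `pheno_config`.
#' @export
write_pheno_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for config files")
  }
  x <- unclass(config)
  x$correction_model <- NULL
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pheno_config
#' @export
read_pheno_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required for config files")
  }
  x <- yaml::read_yaml(path)
  do.call(pheno_config, x)
}
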