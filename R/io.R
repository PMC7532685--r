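# File interfaces ------------------------------------------------------------
#
# Naming convention: {fovID}_{BF|NUC|C1|C2|C3}.tif (or .png). Ground truth
# is written as one per-cell CSV (fov, x, y, radius, phenotype) and one
# per-FOV count CSV; tamper masks as PNG.

channel_file_tags <- function(n_markers, bright_field = TRUE) {
  c(if (bright_field) "BF", "NUC",
    if (n_markers > 0) paste0("C", seq_len(n_markers)))
}

write_gray <- function(img, path, format = c("tiff", "png"), bits = 8L) {
  format <- match.arg(format)
  q <- clamp(img, 0, 1)
  if (format == "tiff") {
    tiff::writeTIFF(q, path, bits.per.sample = as.integer(bits))
  } else {
    png::writePNG(q, path)
  }
  invisible(path)
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else png::readPNG(path)
  to_gray(img)
}

#' Write a phenotype set (or list of FOVs) to disk
#'
#' Writes one image file per channel using the
#' `{fovID}_{BF|NUC|C1|C2|C3}` convention, a per-cell ground-truth CSV and
#' a per-FOV count CSV.
#'
#' @param set a `phenotype_set` (or any list of entries with `fov`,
#'   `truth`, `fov_id` fields).
#' @param dir output directory (created if missing).
#' @param format `"tiff"` (default) or `"png"`.
#' @param bits bit depth for TIFF output (8 default, 16 optional).
#' @return invisibly, the directory.
#' @export
write_fov_set <- function(set, dir, format = c("tiff", "png"), bits = 8L) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "png"
  cells <- list(); counts <- list()
  for (e in set) {
    fid <- if (!is.null(e$fov_id)) e$fov_id else
      sprintf("fov%04d", length(cells) + 1L)
    if (!is.null(e$fov$bright_field)) {
      write_gray(e$fov$bright_field,
                 file.path(dir, sprintf("%s_BF.%s", fid, ext)), format, bits)
    }
    write_gray(e$fov$nucleus,
               file.path(dir, sprintf("%s_NUC.%s", fid, ext)), format, bits)
    for (i in seq_along(e$fov$markers)) {
      write_gray(e$fov$markers[[i]],
                 file.path(dir, sprintf("%s_C%d.%s", fid, i, ext)),
                 format, bits)
    }
    cl <- e$truth$cells
    if (nrow(cl) > 0) cells[[fid]] <- cbind(fov = fid, cl)
    counts[[fid]] <- data.frame(fov = fid,
                                phenotype = names(e$truth$counts),
                                count = as.integer(e$truth$counts))
  }
  write.csv(do.call(rbind, cells), file.path(dir, "ground_truth_cells.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, counts), file.path(dir, "ground_truth_counts.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read one FOV from disk
#'
#' @param dir directory written by [write_fov_set()].
#' @param fov_id FOV identifier.
#' @param n_markers number of marker channels to read.
#' @param pixel_size physical pixel size attached to the result.
#' @return an `fov` list (intensities in \[0,1\]).
#' @export
read_fov <- function(dir, fov_id, n_markers = 3, pixel_size = 1) {
  find1 <- function(tag) {
    p <- list.files(dir, sprintf("^%s_%s\\.(tif|tiff|png)$", fov_id, tag),
                    full.names = TRUE)
    if (length(p) == 0) NULL else read_gray(p[1])
  }
  mk <- list()
  for (i in seq_len(n_markers)) {
    m <- find1(paste0("C", i))
    if (is.null(m)) break
    mk[[i]] <- m
  }
  nuc <- find1("NUC")
  if (is.null(nuc)) stop("nucleus channel not found for ", fov_id)
  structure(list(bright_field = find1("BF"), nucleus = nuc, markers = mk,
                 pixel_size = pixel_size), class = "fov")
}

#' Write a binary mask as PNG
#' @param mask 0/1 matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(clamp(to_gray(mask), 0, 1), path)
  invisible(path)
}
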