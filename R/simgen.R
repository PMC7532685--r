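# Synthetic fluorescent FOV generator ----------------------------------------
#
# SIMCEP/SimuCell-style simulation: elliptical nuclei (with jittered radius
# and eccentricity, optional clustering) inside larger elliptical cytoplasm
# regions whose marker intensity carries a multiplicative Perlin-style
# texture; additive Gaussian CCD noise on every channel.  All intensities
# are fractions in [0, 1] internally; writers quantize to 8-bit by default.

#' Nucleus population specification
#'
#' @param mean_radius mean nucleus radius in pixels (> 0).
#' @param eccentricity nucleus eccentricity in \[0, 1).
#' @param variation_extent fractional jitter applied to radius and
#'   eccentricity (uniform on +/- this fraction).
#' @param count_distribution numeric `c(mean, dispersion)` of cells per FOV
#'   (dispersion 0 = Poisson) used by samplers that draw counts.
#' @param clustering_probability probability that a cell is placed as the
#'   offspring of an already-placed cell (within 1.5 nucleus radii).
#' @param mean_level,level_sd fluorescence level of the nucleus stain
#'   (fraction of full scale).
#' @return a `nucleus_spec` list.
#' @export
nucleus_spec <- function(mean_radius = 13, eccentricity = 0.5,
                         variation_extent = 0.1,
                         count_distribution = c(mean = 50, dispersion = 0),
                         clustering_probability = 0.25,
                         mean_level = 0.7, level_sd = 0.1) {
  stopifnot(mean_radius > 0, eccentricity >= 0, eccentricity < 1,
            clustering_probability >= 0, clustering_probability <= 1,
            variation_extent >= 0)
  structure(list(mean_radius = mean_radius, eccentricity = eccentricity,
                 variation_extent = variation_extent,
                 count_distribution = count_distribution,
                 clustering_probability = clustering_probability,
                 mean_level = mean_level, level_sd = level_sd),
            class = "nucleus_spec")
}

#' Cytoplasm marker specification
#'
#' Defaults follow the realistic-simulation settings (marker level 0.65,
#' sd 0.15, multiplicative Perlin-style texture with amplitude 0.2, length
#' scale 6 px and falloff frequency 0.0025, cytoplasm radius 18,
#' eccentricity 0.5, variation 0.3).
#'
#' @param mean_level mean marker intensity (fraction in \[0,1\]).
#' @param level_sd marker intensity standard deviation.
#' @param texture list with `amplitude`, `length_scale`,
#'   `falloff_frequency`, `mode` ("fractal" = 1/f spectral noise, or
#'   "smooth" = Gaussian-smoothed white noise).
#' @param cell_radius cytoplasm mean radius in pixels.
#' @param cell_eccentricity cytoplasm eccentricity.
#' @param variation_extent fractional jitter on radius/eccentricity.
#' @return a `marker_spec` list.
#' @export
marker_spec <- function(mean_level = 0.65, level_sd = 0.15,
                        texture = list(amplitude = 0.2, length_scale = 6,
                                       falloff_frequency = 0.0025,
                                       mode = "fractal"),
                        cell_radius = 18, cell_eccentricity = 0.5,
                        variation_extent = 0.3) {
  stopifnot(mean_level >= 0, mean_level <= 1, level_sd >= 0,
            texture$amplitude >= 0, cell_radius > 0)
  structure(list(mean_level = mean_level, level_sd = level_sd,
                 texture = texture, cell_radius = cell_radius,
                 cell_eccentricity = cell_eccentricity,
                 variation_extent = variation_extent),
            class = "marker_spec")
}

#' Field-of-view specification
#'
#' @param width,height image dimensions in pixels.
#' @param phenotype_mix named integer vector: requested cell count per
#'   phenotype (names must appear in `registry`).
#' @param registry phenotype registry (see
#'   [default_phenotype_registry()]); rows define each phenotype's marker
#'   pattern.
#' @param n_marker_channels number of cytoplasm marker channels (0-3).
#' @param ccd_noise_variance variance of the additive Gaussian CCD noise
#'   (intensity fraction squared); 1e-4 by default.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param pixel_size physical pixel size in micrometres.
#' @param bright_field include a synthetic bright-field channel.
#' @return an `fov_spec` list.
#' @export
fov_spec <- function(width = 696, height = 520, phenotype_mix,
                     registry = default_phenotype_registry(),
                     n_marker_channels = 3, ccd_noise_variance = 1e-4,
                     seed = NULL, pixel_size = 1, bright_field = TRUE) {
  stopifnot(n_marker_channels %in% 0:3, all(phenotype_mix >= 0),
            ccd_noise_variance >= 0)
  if (is.null(names(phenotype_mix)) ||
      !all(names(phenotype_mix) %in% registry$name)) {
    stop("phenotype_mix must be named by registry phenotypes")
  }
  structure(list(width = width, height = height,
                 phenotype_mix = phenotype_mix, registry = registry,
                 n_marker_channels = n_marker_channels,
                 ccd_noise_variance = ccd_noise_variance, seed = seed,
                 pixel_size = pixel_size, bright_field = bright_field),
            class = "fov_spec")
}

#' Default registry of the twenty phenotypes
#'
#' A phenotype is a marker pattern over the three cytoplasm channels with
#' entries `"+"` (expressed), `"-"` (not expressed) or `"0"` (channel not
#' part of the phenotype's definition). The default registry contains every
#' pattern with at least one expressed marker (19) plus the nucleus-only
#' phenotype, for 20 classes in total; it can be replaced by any data frame
#' with columns `name`, `c1`, `c2`, `c3`.
#'
#' @return data frame with columns `name`, `c1`, `c2`, `c3`.
#' @export
default_phenotype_registry <- function() {
  g <- expand.grid(c1 = c("+", "-", "0"), c2 = c("+", "-", "0"),
                   c3 = c("+", "-", "0"), stringsAsFactors = FALSE)
  keep <- apply(g, 1, function(r) any(r == "+"))
  g <- g[keep, , drop = FALSE]
  # stable order: by number of defined channels (desc), then pattern
  # (locale-independent: rank entries explicitly)
  ndef <- rowSums(g != "0")
  key <- function(v) match(v, c("+", "-", "0"))
  g <- g[order(-ndef, key(g$c1), key(g$c2), key(g$c3)), ]
  g <- rbind(g, data.frame(c1 = "0", c2 = "0", c3 = "0"))
  g$name <- paste0("P", seq_len(nrow(g)))
  rownames(g) <- NULL
  g[, c("name", "c1", "c2", "c3")]
}

# realized +/- pattern over a set of present channels: "-" and "0" both
# realize as non-expressing
realized_pattern <- function(row, channels) {
  ent <- unlist(row[paste0("c", channels)], use.names = FALSE)
  paste(ifelse(ent == "+", "+", "-"), collapse = "")
}

# Perlin-style value noise field, standardized to mean 0 / sd 1.
# mode "fractal": spectral synthesis with 1/(f + falloff) amplitude and a
# high-frequency cutoff at 1/length_scale; mode "smooth": Gaussian-smoothed
# white noise with sigma = length_scale.
perlin_field <- function(nr, nc, length_scale = 6, falloff_frequency = 0.0025,
                         mode = c("fractal", "smooth")) {
  mode <- match.arg(mode)
  if (mode == "smooth") {
    z <- matrix(rnorm(nr * nc), nr, nc)
    f <- EBImage::gblur(z, sigma = length_scale)
  } else {
    z <- matrix(rnorm(nr * nc), nr, nc)
    Fz <- fft(z)
    fy <- pmin(0:(nr - 1), nr - (0:(nr - 1))) / nr
    fx <- pmin(0:(nc - 1), nc - (0:(nc - 1))) / nc
    fr <- sqrt(outer(fy^2, fx^2, `+`))
    amp <- ifelse(fr > 0 & fr <= 1 / length_scale,
                  1 / (fr + falloff_frequency), 0)
    f <- Re(fft(Fz * amp, inverse = TRUE)) / (nr * nc)
  }
  s <- sd(as.vector(f))
  if (s == 0) return(matrix(0, nr, nc))
  (f - mean(f)) / s
}

# draw a filled ellipse into img (max composition)
draw_ellipse <- function(img, cx, cy, a, b, theta, level) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(max(a, b))
  x0 <- max(1, floor(cx - r)); x1 <- min(nc, ceiling(cx + r))
  y0 <- max(1, floor(cy - r)); y1 <- min(nr, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys - cy, length(ys), length(xs))
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  inside <- (xr / a)^2 + (yr / b)^2 <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- pmax(sub[inside], level)
  img[ys, xs] <- sub
  img
}

# semi-axes of an ellipse with geometric-mean radius r and eccentricity e
ellipse_axes <- function(r, e) {
  q <- (1 - e^2)^(1 / 4)
  c(a = r / q, b = r * q)
}

jitter_frac <- function(x, extent) x * (1 + runif(length(x), -extent, extent))

#' Generate one synthetic field of view with ground truth
#'
#' Places the requested number of cells of each phenotype (rejection
#' sampling; a cell is clustered with probability
#' `nucleus$clustering_probability`, in which case it lands within 1.5
#' nucleus radii of an already-placed cell), rasterizes the nucleus channel
#' and one cytoplasm channel per marker, applies multiplicative
#' Perlin-style texture to the marker intensities and adds Gaussian CCD
#' noise.
#'
#' @param spec an [fov_spec()].
#' @param nucleus a [nucleus_spec()].
#' @param markers list of [marker_spec()], length `spec$n_marker_channels`.
#' @param max_retries placement retries per cell before a placement-failure
#'   error is raised.
#' @return list with `fov` (fields `bright_field`, `nucleus`, `markers`,
#'   `pixel_size`; intensities in \[0,1\]) and `truth` (fields `cells`
#'   data frame x/y/radius/phenotype, `counts`, `tamper_mask = NULL`, and
#'   `masks`: the pre-noise binary nucleus and per-marker masks, as the
#'   reference simulators provide).
#' @export
generate_fov <- function(spec, nucleus = nucleus_spec(),
                         markers = replicate(spec$n_marker_channels,
                                             marker_spec(),
                                             simplify = FALSE),
                         max_retries = 200) {
  stopifnot(inherits(spec, "fov_spec"), inherits(nucleus, "nucleus_spec"))
  if (length(markers) != spec$n_marker_channels) {
    stop("markers must have length n_marker_channels")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  w <- spec$width; h <- spec$height
  mix <- spec$phenotype_mix
  reg <- spec$registry

  # cell table
  phen <- rep(names(mix), times = mix)
  n <- length(phen)
  if (n > 0) phen <- sample(phen)   # interleave phenotypes before placement
  r_nuc <- jitter_frac(rep(nucleus$mean_radius, n), nucleus$variation_extent)
  e_nuc <- clamp(jitter_frac(rep(nucleus$eccentricity, n),
                             nucleus$variation_extent), 0, 0.95)
  th <- runif(n, 0, pi)

  # placement
  cx <- numeric(n); cy <- numeric(n)
  amax <- vapply(seq_len(n),
                 function(j) ellipse_axes(r_nuc[j], e_nuc[j])["a"],
                 numeric(1))
  for (j in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      if (j > 1 && runif(1) < nucleus$clustering_probability) {
        # clustered: land next to a parent, from moderately overlapping
        # (0.8x the touching distance) to just separated (1.5x)
        par <- sample(j - 1, 1)
        d <- runif(1, 0.8, 1.5) * (r_nuc[par] + r_nuc[j])
        ang <- runif(1, 0, 2 * pi)
        px <- cx[par] + d * cos(ang)
        py <- cy[par] + d * sin(ang)
        if (px < amax[j] + 1 || px > w - amax[j] ||
            py < amax[j] + 1 || py > h - amax[j]) next
        cx[j] <- px; cy[j] <- py; placed <- TRUE; break
      } else {
        px <- runif(1, amax[j] + 1, w - amax[j])
        py <- runif(1, amax[j] + 1, h - amax[j])
        if (j > 1) {
          dd <- sqrt((cx[1:(j - 1)] - px)^2 + (cy[1:(j - 1)] - py)^2)
          if (any(dd < 1.05 * (amax[1:(j - 1)] + amax[j]))) next
        }
        cx[j] <- px; cy[j] <- py; placed <- TRUE; break
      }
    }
    if (!placed) {
      stop("placement failure: could not place cell ", j, " of ", n,
           " within the retry budget")
    }
  }

  # nucleus channel (and its binary truth mask, recorded pre-noise)
  nuc_img <- matrix(0, h, w)
  nuc_mask <- matrix(0, h, w)
  lev_nuc <- clamp(rnorm(n, nucleus$mean_level, nucleus$level_sd), 0.05, 1)
  for (j in seq_len(n)) {
    ax <- ellipse_axes(r_nuc[j], e_nuc[j])
    nuc_img <- draw_ellipse(nuc_img, cx[j], cy[j], ax["a"], ax["b"], th[j],
                            lev_nuc[j])
    nuc_mask <- draw_ellipse(nuc_mask, cx[j], cy[j], ax["a"], ax["b"],
                             th[j], 1)
  }
  tex <- perlin_field(h, w, 6, 0.0025)
  nuc_img <- clamp(nuc_img * (1 + 0.2 * tex), 0, 1)

  # one cytoplasm per cell, shared by all marker channels (geometry from the
  # first marker spec), jittered and grown if necessary so it contains the
  # cell's nucleus
  cyto_ax <- matrix(0, n, 2)
  if (spec$n_marker_channels > 0 && n > 0) {
    ms1 <- markers[[1]]
    for (j in seq_len(n)) {
      rc <- jitter_frac(ms1$cell_radius, ms1$variation_extent)
      ec <- clamp(jitter_frac(ms1$cell_eccentricity, ms1$variation_extent),
                  0, 0.95)
      ax <- ellipse_axes(rc, ec)
      axn <- ellipse_axes(r_nuc[j], e_nuc[j])
      scale_up <- max(1, 1.05 * axn["a"] / ax["a"], 1.05 * axn["b"] / ax["b"])
      cyto_ax[j, ] <- ax * scale_up
    }
  }

  # a cell expresses channel i iff its registry pattern has "+" there
  # ("-" and "0" are both non-expressing)
  marker_imgs <- list()
  marker_masks <- list()
  any_cyto <- matrix(0, h, w)
  for (i in seq_len(spec$n_marker_channels)) {
    ms <- markers[[i]]
    img <- matrix(0, h, w)
    msk <- matrix(0, h, w)
    for (j in seq_len(n)) {
      pat <- reg[reg$name == phen[j], paste0("c", i)]
      if (identical(pat, "+")) {
        lev <- clamp(rnorm(1, ms$mean_level, ms$level_sd),
                     max(0, ms$mean_level - 3 * ms$level_sd),
                     min(1, ms$mean_level + 3 * ms$level_sd))
        img <- draw_ellipse(img, cx[j], cy[j], cyto_ax[j, 1], cyto_ax[j, 2],
                            th[j], lev)
        msk <- draw_ellipse(msk, cx[j], cy[j], cyto_ax[j, 1], cyto_ax[j, 2],
                            th[j], 1)
      }
      if (i == 1) {
        any_cyto <- draw_ellipse(any_cyto, cx[j], cy[j], cyto_ax[j, 1],
                                 cyto_ax[j, 2], th[j], 1)
      }
    }
    tx <- ms$texture
    fld <- perlin_field(h, w, tx$length_scale, tx$falloff_frequency,
                        if (is.null(tx$mode)) "fractal" else tx$mode)
    img <- clamp(img * (1 + tx$amplitude * fld), 0, 1)
    marker_imgs[[i]] <- img
    marker_masks[[i]] <- msk
  }

  bf <- NULL
  if (isTRUE(spec$bright_field)) {
    bf <- clamp(0.85 - 0.08 * any_cyto - 0.05 * (nuc_img > 0), 0, 1)
  }

  # CCD noise
  addn <- function(im) clamp(im + rnorm(length(im), 0,
                                        sqrt(spec$ccd_noise_variance)),
                             0, 1)
  nuc_img <- addn(nuc_img)
  marker_imgs <- lapply(marker_imgs, addn)
  if (!is.null(bf)) bf <- addn(bf)

  counts <- setNames(integer(length(mix)), names(mix))
  if (n > 0) {
    tb <- table(phen)
    counts[names(tb)] <- as.integer(tb)
  }
  cells <- data.frame(x = cx, y = cy, radius = r_nuc,
                      phenotype = if (n > 0) phen else character(0),
                      stringsAsFactors = FALSE)
  list(
    fov = structure(list(bright_field = bf, nucleus = nuc_img,
                         markers = marker_imgs,
                         pixel_size = spec$pixel_size), class = "fov"),
    truth = list(cells = cells, counts = counts, tamper_mask = NULL,
                 masks = list(nucleus = nuc_mask, markers = marker_masks))
  )
}

#' Generate the four-group phenotype image set
#'
#' Reproduces the structure of the synthetic phenotype set: four groups,
#' each containing `n_fov_per_group` FOVs of 5 randomly selected phenotypes
#' with random per-FOV counts. The groups are a random partition of the
#' 20-phenotype registry into four sets of five, re-drawn until every
#' group's realized marker patterns are pairwise distinct (so ground truth
#' stays recoverable by the rule-based enumerator). With
#' `n_fov_per_group = 100` the set contains 400 FOVs and 2000 images
#' (1 bright field + 1 nucleus + up to 3 markers each).
#'
#' @param n_fov_per_group FOVs per group (>= 1).
#' @param seed integer seed.
#' @param width,height image size (defaults 696 x 520).
#' @param mean_count Poisson mean of the per-FOV count of each phenotype.
#' @param registry phenotype registry.
#' @param nucleus nucleus population (defaults: radius 13, eccentricity
#'   0.5, variation 0.1, clustering 25%).
#' @param marker marker template (phenotype-set values: level 0.5, sd 0.2,
#'   Perlin texture; cytoplasm radius 18, eccentricity 0.5, variation 0.3).
#' @param ccd_noise_variance CCD noise variance (1e-4).
#' @return list of FOV entries (class `phenotype_set`), each with fields
#'   `fov`, `truth`, `group`, `fov_id`, `channels` (marker channel indices
#'   present) and `phenotypes` (data frame name/pattern over the present
#'   channels).
#' @export
generate_phenotype_set <- function(n_fov_per_group = 100, seed = 1,
                                   width = 696, height = 520,
                                   mean_count = 10,
                                   registry = default_phenotype_registry(),
                                   nucleus = nucleus_spec(),
                                   marker = marker_spec(mean_level = 0.5,
                                                        level_sd = 0.2),
                                   ccd_noise_variance = 1e-4) {
  stopifnot(n_fov_per_group >= 1, nrow(registry) >= 20)
  set.seed(seed)
  # propose partitions that spread each realized-pattern equivalence class
  # (patterns identical once "0" realizes as "-") over distinct groups, then
  # verify against the per-group channel layout
  propose_groups <- function() {
    full <- vapply(1:20, function(j)
      realized_pattern(registry[j, ], 1:3), character(1))
    perm <- sample(registry$name[1:20])
    classes <- split(perm, full[match(perm, registry$name)])
    classes <- classes[order(-lengths(classes), names(classes),
                             method = "radix")]
    cap <- rep(5L, 4)
    assign <- setNames(integer(20), registry$name[1:20])
    for (cl in classes) {
      open <- order(-cap + runif(4) * 0.1)
      gsel <- head(open[cap[open] > 0], length(cl))
      if (length(gsel) < length(cl)) {
        gsel <- c(gsel, sample(which(cap > 0), length(cl) - length(gsel),
                               replace = TRUE))
      }
      for (i in seq_along(cl)) {
        g <- gsel[i]
        if (cap[g] == 0) g <- which.max(cap)
        assign[cl[i]] <- g
        cap[g] <- cap[g] - 1L
      }
    }
    split(names(assign), assign)
  }
  groups <- NULL
  for (try in 1:1000) {
    cand <- propose_groups()
    ok <- all(vapply(cand, function(g) {
      rows <- registry[match(g, registry$name), ]
      ch <- which(vapply(1:3, function(i) any(rows[[paste0("c", i)]] == "+"),
                         logical(1)))
      pats <- vapply(seq_len(nrow(rows)),
                     function(j) realized_pattern(rows[j, ], ch),
                     character(1))
      !anyDuplicated(pats)
    }, logical(1)))
    if (ok) { groups <- cand; break }
  }
  if (is.null(groups)) stop("could not partition phenotypes into groups")

  out <- list()
  id <- 0L
  for (g in 1:4) {
    rows <- registry[match(groups[[g]], registry$name), ]
    ch <- which(vapply(1:3, function(i) any(rows[[paste0("c", i)]] == "+"),
                       logical(1)))
    # registry restricted to the FOV's channel layout: channel slot k of the
    # FOV is original channel ch[k]
    sub <- data.frame(name = rows$name, stringsAsFactors = FALSE)
    for (k in seq_along(ch)) sub[[paste0("c", k)]] <- rows[[paste0("c", ch[k])]]
    for (k in seq_len(3 - length(ch))) {
      sub[[paste0("c", length(ch) + k)]] <- "0"
    }
    pats <- vapply(seq_len(nrow(rows)),
                   function(j) realized_pattern(rows[j, ], ch), character(1))
    for (f in seq_len(n_fov_per_group)) {
      id <- id + 1L
      mix <- setNames(rpois(5, mean_count), sub$name)
      sp <- fov_spec(width = width, height = height, phenotype_mix = mix,
                     registry = sub, n_marker_channels = length(ch),
                     ccd_noise_variance = ccd_noise_variance, seed = NULL)
      gen <- generate_fov(sp, nucleus,
                          replicate(length(ch), marker, simplify = FALSE))
      out[[id]] <- list(fov = gen$fov, truth = gen$truth, group = g,
                        fov_id = sprintf("fov%04d", id),
                        channels = ch,
                        phenotypes = data.frame(name = sub$name,
                                                pattern = pats,
                                                stringsAsFactors = FALSE),
                        registry = sub)
    }
  }
  structure(out, class = "phenotype_set", groups = groups, seed = seed)
}

#' Splice objects from a donor image into a target (forgery simulation)
#'
#' Selects 1..`max_objects` connected components of `donor_mask` uniformly
#' at random and pastes the corresponding donor pixels at uniformly random
#' in-bounds positions of the target.
#'
#' @param target,donor single-channel images on the same intensity scale.
#' @param donor_mask binary mask of donor objects (same size as `donor`).
#' @param max_objects maximum number of objects to paste (>= 1).
#' @param seed optional seed.
#' @return list with `image` (tampered target) and `record` (fields
#'   `n_objects_pasted`, `tamper_mask`, `tampered_pixel_fraction`).
#' @export
splice_tamper <- function(target, donor, donor_mask, max_objects = 3,
                          seed = NULL) {
  if (max_objects < 1) stop("max_objects must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tg <- to_gray(target); dn <- to_gray(donor)
  dm <- (to_gray(donor_mask) > 0) * 1
  lab <- EBImage::bwlabel(dm)
  ncomp <- max(lab)
  if (ncomp < 1) stop("donor_mask has no connected components")
  npaste <- sample.int(max_objects, 1)
  picks <- sample.int(ncomp, npaste, replace = npaste > ncomp)
  out <- tg
  mask <- matrix(0, nrow(tg), ncol(tg))
  for (comp in picks) {
    sel <- lab == comp
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    oh <- diff(rows) + 1; ow <- diff(cols) + 1
    if (oh > nrow(tg) || ow > ncol(tg)) next
    obj <- sel[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    src <- dn[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    r0 <- sample.int(nrow(tg) - oh + 1, 1)
    c0 <- sample.int(ncol(tg) - ow + 1, 1)
    tgt <- out[r0:(r0 + oh - 1), c0:(c0 + ow - 1), drop = FALSE]
    tgt[obj] <- src[obj]
    out[r0:(r0 + oh - 1), c0:(c0 + ow - 1)] <- tgt
    msk <- mask[r0:(r0 + oh - 1), c0:(c0 + ow - 1), drop = FALSE]
    msk[obj] <- 1
    mask[r0:(r0 + oh - 1), c0:(c0 + ow - 1)] <- msk
  }
  list(image = out,
       record = list(n_objects_pasted = npaste, tamper_mask = mask,
                     tampered_pixel_fraction = mean(mask)))
}

#' Mirror augmentation
#'
#' @param image 2-D image.
#' @return list of 4 images: original, horizontal flip, vertical flip and
#'   the combination of both.
#' @export
augment_mirror <- function(image) {
  m <- to_gray(image)
  list(original = m,
       horizontal = m[, rev(seq_len(ncol(m))), drop = FALSE],
       vertical = m[rev(seq_len(nrow(m))), , drop = FALSE],
       both = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE])
}

#' Construct an anomalous test image
#'
#' Produces images far outside the fluorescent-image feature distribution,
#' for exercising the anomaly-screening layer. Modes: `blank` (all zero),
#' `saturated` (all pixels at full scale), `noise` (uniform white noise),
#' `off_modality` (high-contrast checkerboard-plus-gradient pattern unlike
#' any fluorescence image).
#'
#' @param base image providing dimensions and intensity scale.
#' @param mode one of `"blank"`, `"saturated"`, `"noise"`,
#'   `"off_modality"`.
#' @param seed optional seed for the noise mode.
#' @return matrix of the same dimensions and scale as `base`.
#' @export
make_anomaly <- function(base, mode = c("blank", "saturated", "noise",
                                        "off_modality"),
                         seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  b <- to_gray(base)
  nr <- nrow(b); nc <- ncol(b)
  mx <- if (max(b) <= 1) 1 else if (max(b) > 255) 65535 else 255
  switch(mode,
    blank = matrix(0, nr, nc),
    saturated = matrix(mx, nr, nc),
    noise = matrix(runif(nr * nc, 0, mx), nr, nc),
    off_modality = {
      sq <- 16
      chk <- (((row(b) - 1) %/% sq + (col(b) - 1) %/% sq) %% 2)
      grad <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
      (0.7 * chk + 0.3 * grad) * mx
    })
}
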