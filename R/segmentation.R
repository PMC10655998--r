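#' Block-mean downsampling
#'
#' Averages non-overlapping `factor x factor` blocks, emulating analysis at
#' a lower nominal magnification. Trailing rows/columns that do not fill a
#' block are dropped (with a warning).
#'
#' @param x numeric matrix or `[rows, cols, k]` array.
#' @param factor positive integer block size; 1 returns the input.
#' @return The downsampled matrix/array.
#' @export
block_downsample <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(x)
  if (length(dim(x)) == 3) {
    out <- lapply(seq_len(dim(x)[3]),
                  function(ch) block_downsample(x[, , ch], factor))
    return(array(unlist(out), c(dim(out[[1]]), length(out))))
  }
  nr <- nrow(x); nc <- ncol(x)
  kr <- nr %/% factor; kc <- nc %/% factor
  if (kr * factor != nr || kc * factor != nc) {
    warning("raster not divisible by block factor; trailing pixels dropped")
    x <- x[seq_len(kr * factor), seq_len(kc * factor), drop = FALSE]
  }
  # average rows then columns via dim-folding
  dim(x) <- c(factor, kr, kc * factor)
  x <- colMeans(x)                      # kr x (kc*factor)
  x <- matrix(x, kr, kc * factor)
  x <- t(x)
  dim(x) <- c(factor, kc, kr)
  x <- colMeans(x)                      # kc x kr
  t(matrix(x, kc, kr))
}

#' Minimum-channel brightness raster
#'
#' Grey-scale representation used for tissue detection: the per-pixel
#' minimum (darkest value) across the R, G and B layers.
#'
#' @param slide an [rgb_slide()], or a `[rows, cols, 3]` numeric array.
#' @return A numeric matrix in `[0, 255]`.
#' @export
min_channel_brightness <- function(slide) {
  px <- if (inherits(slide, "rgb_slide")) slide$pixels else slide
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("expected a 3-channel raster")
  pmin(px[, , 1], px[, , 2], px[, , 3])
}

#' Detect tissue by dynamic brightness thresholding
#'
#' The threshold is the 95th percentile of the grey raster (the value
#' separating the brightest 5% of the area from the rest) adjusted by -10
#' grey levels, clamped to `[0, 255]`; pixels strictly below it are tissue.
#'
#' @param grey numeric matrix in `[0, 255]` (min-channel brightness).
#' @param params a [segmentation_params()].
#' @return An object of class `tissue_mask`: logical `mask` (TRUE = tissue)
#'   and `threshold_used`.
#' @export
detect_tissue <- function(grey, params = segmentation_params()) {
  if (any(grey < 0 | grey > 255)) stop("grey values must lie in [0, 255]")
  thr <- unname(quantile(grey, params$tissue_percentile / 100, type = 7)) +
    params$tissue_offset
  thr <- min(max(thr, 0), 255)
  structure(list(mask = grey < thr, threshold_used = thr),
            class = "tissue_mask")
}

#' Classify brown staining into none / light / dark
#'
#' A pixel belongs to the brown area when its brown density exceeds
#' `brown_min_au` (strict) and its Brown+ve density exceeds
#' `brown_pos_min_au` (strict); brown-area pixels at or above `dark_min_au`
#' are dark, the remainder light. Pixels outside the tissue mask, when one
#' is supplied, are forced to none.
#'
#' @param maps a [stain_maps()].
#' @param params a [segmentation_params()].
#' @param tissue optional logical matrix on the same grid (TRUE = tissue).
#' @return An object of class `brown_class_mask`: integer matrix `labels`
#'   (0 none, 1 light, 2 dark) plus the grid calibration.
#' @export
classify_brown <- function(maps, params = segmentation_params(),
                           tissue = NULL) {
  stopifnot(inherits(maps, "stain_maps"))
  lab <- matrix(0L, nrow(maps$brown_au), ncol(maps$brown_au))
  brown <- maps$brown_au > params$brown_min_au &
    maps$brown_pos_au > params$brown_pos_min_au
  if (!is.null(tissue)) {
    if (!identical(dim(tissue), dim(lab)))
      stop("tissue mask grid does not match the stain maps")
    brown <- brown & tissue
  }
  lab[brown] <- 1L
  lab[brown & maps$brown_au >= params$dark_min_au] <- 2L
  structure(list(labels = lab, mpp = maps$mpp, downsample = maps$downsample),
            class = "brown_class_mask")
}

#' Grow plaque candidates from dark seeds
#'
#' Connected components of dark pixels act as seeds; every light component
#' adjacent to a seed is attached to it, and a light component touching
#' several seeds merges them into a single candidate. Light components with
#' no adjacent seed are discarded. Object statistics (areas in um^2, mean
#' and population SD of brown density, elliptic fit, centroid) are computed
#' on the final pixel sets.
#'
#' @param classes a [classify_brown()] result.
#' @param maps the [stain_maps()] the classes were derived from.
#' @param params a [segmentation_params()].
#' @return A list of candidate objects; each carries `id`, `pixels`
#'   (matrix of row/col indices on the class grid), `n_px`, `area_um2`,
#'   `dark_area_um2`, `mean_brown_au`, `sd_brown_au`, `elliptic_fit` and
#'   `centroid` (0-based x/y in scan-resolution pixels).
#' @export
grow_candidates <- function(classes, maps, params = segmentation_params()) {
  stopifnot(inherits(classes, "brown_class_mask"))
  lab <- cpp_grow_candidates(classes$labels == 2L, classes$labels == 1L,
                             as.integer(params$connectivity))
  ids <- which(lab > 0)
  if (length(ids) == 0) return(list())
  ds <- classes$downsample
  px_area <- (classes$mpp * ds)^2
  rr <- (ids - 1L) %% nrow(lab) + 1L
  cc <- (ids - 1L) %/% nrow(lab) + 1L
  cand_id <- lab[ids]
  dark <- classes$labels[ids] == 2L
  brown <- maps$brown_au[ids]
  ord <- order(cand_id)
  rr <- rr[ord]; cc <- cc[ord]; dark <- dark[ord]; brown <- brown[ord]
  cand_id <- cand_id[ord]
  bounds <- c(0, cumsum(tabulate(cand_id)))
  lapply(seq_len(max(cand_id)), function(k) {
    sel <- (bounds[k] + 1):bounds[k + 1]
    pix <- cbind(row = rr[sel], col = cc[sel])
    n <- nrow(pix)
    m <- mean(brown[sel])
    # centroid mapped back to 0-based scan-grid coordinates
    cx <- (mean(pix[, "col"]) - 1) * ds + (ds - 1) / 2
    cy <- (mean(pix[, "row"]) - 1) * ds + (ds - 1) / 2
    list(id = k,
         pixels = pix,
         n_px = n,
         area_um2 = n * px_area,
         dark_area_um2 = sum(dark[sel]) * px_area,
         mean_brown_au = m,
         sd_brown_au = sqrt(mean((brown[sel] - m)^2)),
         elliptic_fit = elliptic_fit(pix),
         centroid = c(x = cx, y = cy))
  })
}

#' Elliptic fit score of a pixel set
#'
#' Fits the ellipse sharing the object's centroid, second-moment orientation
#' and axis ratio, scaled to the object's pixel count, and returns the
#' intersection-over-union between the object and the rasterised ellipse.
#' A single pixel scores 1 by convention; degenerate (collinear) sets of
#' more than one pixel score 0.
#'
#' @param pixels two-column matrix of row/col pixel indices.
#' @return A score in `[0, 1]`.
#' @export
elliptic_fit <- function(pixels) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (n == 0) stop("empty pixel set")
  if (n == 1) return(1)
  y <- pixels[, 1]; x <- pixels[, 2]
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2); syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  if (l2 <= 1e-9) return(0)  # collinear: no finite-axis-ratio ellipse
  # semi-axes with the object's axis ratio, scaled so the ellipse area = n
  s <- sqrt(n / (pi * sqrt(l1 * l2)))
  a <- s * sqrt(l1); b <- s * sqrt(l2)
  u <- ev$vectors[, 1]
  r <- ceiling(a) + 1L
  gx <- floor(mx - r):ceiling(mx + r)
  gy <- floor(my - r):ceiling(my + r)
  pg <- expand.grid(x = gx, y = gy)
  dx <- pg$x - mx; dy <- pg$y - my
  t1 <- (dx * u[1] + dy * u[2]) / a
  t2 <- (-dx * u[2] + dy * u[1]) / b
  inside <- t1 * t1 + t2 * t2 <= 1
  key_e <- (pg$x[inside]) * 1e6 + pg$y[inside]
  key_o <- x * 1e6 + y
  inter <- length(intersect(key_e, key_o))
  inter / (length(key_e) + n - inter)
}

# the five removal predicates; returns a character vector of violated rules
candidate_flags <- function(cand, params) {
  flags <- character(0)
  if (cand$area_um2 < params$min_area_um2)
    flags <- c(flags, "min_area")
  if (cand$dark_area_um2 < params$min_dark_area_um2)
    flags <- c(flags, "min_dark_area")
  if (cand$mean_brown_au > params$artifact_intensity_min_au &&
      cand$sd_brown_au < params$artifact_sd_max_au)
    flags <- c(flags, "uniform_dark")
  if (cand$area_um2 < params$small_area_um2 &&
      cand$elliptic_fit < params$elliptic_fit_min)
    flags <- c(flags, "non_elliptical")
  if (cand$area_um2 > params$small_area_um2 &&
      cand$dark_area_um2 / cand$area_um2 > params$dark_fraction_max)
    flags <- c(flags, "dark_fraction")
  flags
}

#' Apply the five plaque-removal rules
#'
#' A candidate is removed when any rule fires: (`min_area`) area below
#' 10 um^2; (`min_dark_area`) dark brown area below 1.5 um^2;
#' (`uniform_dark`) mean brown density above 0.5 au with SD below 0.25 au;
#' (`non_elliptical`) area below 40 um^2 with elliptic fit below the
#' configured minimum; (`dark_fraction`) area above 40 um^2 with more than
#' 70% dark brown area. An object of exactly 40 um^2 is subject to neither
#' of the last two rules.
#'
#' @param cands list of candidates from [grow_candidates()].
#' @param params a [segmentation_params()].
#' @return A list with `plaques` (accepted candidates, `removal_flags`
#'   empty) and `rejected` (each with its violated rules in
#'   `removal_flags`).
#' @export
filter_candidates <- function(cands, params = segmentation_params()) {
  flags <- lapply(cands, candidate_flags, params = params)
  keep <- lengths(flags) == 0
  plaques <- Map(function(c, f) { c$removal_flags <- f; c },
                 cands[keep], flags[keep])
  rejected <- Map(function(c, f) { c$removal_flags <- f; c },
                  cands[!keep], flags[!keep])
  list(plaques = unname(plaques), rejected = unname(rejected))
}

# nearest-neighbour upsampling of a logical/numeric matrix by integer factor
upsample_nn <- function(m, factor) {
  factor <- as.integer(factor)
  if (factor == 1) return(m)
  m[rep(seq_len(nrow(m)), each = factor),
    rep(seq_len(ncol(m)), each = factor), drop = FALSE]
}

#' Run the full plaque segmentation pipeline on a slide
#'
#' Tissue detection runs on the raster block-averaged to the tissue working
#' magnification (x10 by default), stain detection on the stain working
#' magnification (x20); the tissue mask is upsampled (nearest-neighbour) to
#' the stain grid and stain classes outside tissue are forced to none.
#'
#' @param slide an [rgb_slide()].
#' @param params a [segmentation_params()].
#' @param ref a [stain_reference()].
#' @return An object of class `segmentation` with elements `tissue`
#'   (x10-grid [detect_tissue()] result), `tissue_stain` (tissue mask on the
#'   stain grid), `maps`, `classes`, `candidates`, `plaques`, `rejected`,
#'   and the factors/calibration used.
#' @export
segment_slide <- function(slide, params = segmentation_params(),
                          ref = stain_reference()) {
  stopifnot(inherits(slide, "rgb_slide"))
  f_tissue <- max(1L, as.integer(round(slide$scan_magnification /
                                         params$tissue_scale_mag)))
  f_stain <- max(1L, as.integer(round(slide$scan_magnification /
                                        params$stain_scale_mag)))
  if (f_tissue %% f_stain != 0)
    stop("tissue block factor must be a multiple of the stain block factor")

  px_t <- block_downsample(slide$pixels, f_tissue)
  tissue <- detect_tissue(min_channel_brightness(px_t), params)

  px_s <- block_downsample(slide$pixels, f_stain)
  slide_s <- rgb_slide(round(px_s), mpp = slide$mpp * f_stain,
                       i0 = slide$i0,
                       scan_magnification = slide$scan_magnification)
  # keep unrounded intensities for the density transform
  dens <- array(0, dim(px_s))
  for (ch in 1:3)
    dens[, , ch] <- -log(pmin(pmax(px_s[, , ch], 1), slide$i0[ch]) /
                           slide$i0[ch])
  maps <- unmix_stains(dens, ref, mpp = slide$mpp, downsample = f_stain)

  tissue_stain <- upsample_nn(tissue$mask, f_tissue %/% f_stain)
  # guard: crop to the stain grid if the division dropped trailing blocks
  tissue_stain <- tissue_stain[seq_len(nrow(maps$brown_au)),
                               seq_len(ncol(maps$brown_au)), drop = FALSE]

  classes <- classify_brown(maps, params, tissue = tissue_stain)
  cands <- grow_candidates(classes, maps, params)
  filt <- filter_candidates(cands, params)
  structure(list(tissue = tissue,
                 tissue_stain = tissue_stain,
                 maps = maps,
                 classes = classes,
                 candidates = cands,
                 plaques = filt$plaques,
                 rejected = filt$rejected,
                 params = params,
                 mpp = slide$mpp,
                 f_tissue = f_tissue,
                 f_stain = f_stain),
            class = "segmentation")
}

#' Tabulate segmented objects
#'
#' @param seg a [segment_slide()] result, or a plain list of candidates.
#' @return A data frame with one row per object: id, centroid, areas, stain
#'   statistics, elliptic fit, acceptance and flags.
#' @export
object_table <- function(seg) {
  objs <- if (inherits(seg, "segmentation"))
    c(seg$plaques, seg$rejected) else seg
  if (length(objs) == 0)
    return(data.frame(id = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area_um2 = numeric(0),
                      dark_area_um2 = numeric(0), mean_brown_au = numeric(0),
                      sd_brown_au = numeric(0), elliptic_fit = numeric(0),
                      accepted = logical(0), flags = character(0)))
  df <- do.call(rbind, lapply(objs, function(o) {
    data.frame(id = o$id,
               centroid_x = o$centroid[["x"]],
               centroid_y = o$centroid[["y"]],
               area_um2 = o$area_um2,
               dark_area_um2 = o$dark_area_um2,
               mean_brown_au = o$mean_brown_au,
               sd_brown_au = o$sd_brown_au,
               elliptic_fit = o$elliptic_fit,
               accepted = length(o$removal_flags %||% character(0)) == 0,
               flags = paste(o$removal_flags %||% character(0),
                             collapse = ";"))
  }))
  df[order(df$id), , drop = FALSE]
}
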