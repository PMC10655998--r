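#' Construct a calibrated RGB slide
#'
#' @param pixels integer array `[rows, cols, 3]` with values in 0..255;
#'   row-major raster, origin top-left, x increasing to the right (columns)
#'   and y downward (rows).
#' @param mpp microns per pixel of the raster (> 0).
#' @param i0 per-channel background (glass) reference intensity, in (0, 255].
#' @param scan_magnification nominal objective magnification of the scan.
#' @return An object of class `rgb_slide`.
#' @export
rgb_slide <- function(pixels, mpp, i0 = c(255, 255, 255),
                      scan_magnification = 40) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop("pixels must be a [rows, cols, 3] array")
  if (any(pixels < 0 | pixels > 255) || any(!is.finite(pixels)))
    stop("channel values must lie in [0, 255]")
  if (!is.numeric(mpp) || length(mpp) != 1 || !is.finite(mpp) || mpp <= 0)
    stop("mpp must be a positive scalar")
  if (length(i0) == 1) i0 <- rep(i0, 3)
  if (length(i0) != 3 || any(i0 <= 0) || any(i0 > 255))
    stop("i0 must be a per-channel value in (0, 255]")
  pixels <- array(as.integer(round(pixels)), dim(pixels))  # strip reader attrs
  structure(list(pixels = pixels, mpp = mpp, i0 = as.numeric(i0),
                 scan_magnification = scan_magnification),
            class = "rgb_slide")
}

#' @export
print.rgb_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_slide> %d x %d px, %.4g um/px (x%g scan)\n",
              d[2], d[1], x$mpp, x$scan_magnification))
  invisible(x)
}

png_header_info <- function(path) {
  hdr <- readBin(path, "raw", 26)
  list(bit_depth = as.integer(hdr[25]), color_type = as.integer(hdr[26]))
}

#' Read an 8-bit RGB brightfield image
#'
#' Reads a TIFF or PNG slide image and attaches its pixel calibration.
#' Only 3-channel 8-bit images are accepted; greyscale, paletted, alpha or
#' deeper-bit-depth files raise an error rather than being coerced.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param mpp microns per pixel of the image.
#' @param i0 per-channel glass reference intensity (defaults to 255).
#' @param scan_magnification nominal objective magnification.
#' @return An [rgb_slide()].
#' @export
read_slide <- function(path, mpp, i0 = c(255, 255, 255),
                       scan_magnification = 40) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    imgs <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    img <- imgs[[1]]
    bits <- attr(img, "bits.per.sample") %||% 8L
    if (!identical(as.integer(bits), 8L))
      stop("unsupported bit depth: ", bits, " (8-bit required)")
  } else if (ext == "png") {
    hdr <- png_header_info(path)
    if (hdr$bit_depth != 8L)
      stop("unsupported bit depth: ", hdr$bit_depth, " (8-bit required)")
    if (hdr$color_type != 2L)
      stop("unsupported PNG colour type: ", hdr$color_type,
           " (8-bit RGB truecolour required)")
    img <- png::readPNG(path)
  } else {
    stop("unsupported image format: .", ext, " (TIFF or PNG required)")
  }
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("wrong channel count: expected 3 channels, got ",
         if (length(dim(img)) == 2) 1 else dim(img)[3])
  px <- round(img * 255)
  rgb_slide(px, mpp = mpp, i0 = i0, scan_magnification = scan_magnification)
}

#' Write a slide as an 8-bit TIFF or PNG
#'
#' @param slide an [rgb_slide()].
#' @param path output path; format chosen from the extension.
#' @return The path, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "rgb_slide"))
  img <- slide$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Construct a named region polygon
#'
#' @param name region label.
#' @param polygon numeric matrix with columns x, y of polygon vertices in
#'   0-based pixel coordinates (x right, y down, vertices at pixel centres);
#'   the closing vertex may be repeated or omitted.
#' @return An object of class `region`.
#' @export
region <- function(name, polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2) stop("polygon must have two columns (x, y)")
  n <- nrow(polygon)
  if (n >= 2 && all(polygon[1, ] == polygon[n, ]))
    polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3) stop("polygon needs at least 3 distinct vertices")
  if (polygon_self_intersects(polygon))
    stop("polygon is self-intersecting: ", name)
  if (abs(polygon_area(polygon)) <= 0)
    stop("polygon has zero area: ", name)
  structure(list(name = as.character(name), polygon = polygon),
            class = "region")
}

# shoelace (signed) area in squared pixel units
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polygon_self_intersects <- function(p) {
  n <- nrow(p)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (segments_cross(p[idx[i, 1], ], p[idx[i, 2], ],
                         p[idx[j, 1], ], p[idx[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

#' Read region annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each with a `name`
#' property. Only the exterior ring is used. Duplicate names are suffixed
#' deterministically with `#2`, `#3`, ... in feature order.
#'
#' @param path path to a GeoJSON file.
#' @return A list of [region()] objects.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  if (length(feats) == 0) stop("no features in ", path)
  names_raw <- character(length(feats))
  regions <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    g <- f$geometry
    if (!identical(g$type, "Polygon"))
      stop("unsupported geometry type: ", g$type %||% "missing",
           " (only Polygon is accepted)")
    nm <- f$properties$name
    if (is.null(nm)) stop("feature ", i, " lacks a 'name' property")
    ring <- g$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(v) as.numeric(v[1:2])))
    names_raw[i] <- as.character(nm)
    regions[[i]] <- region(nm, poly)
  }
  # deterministic de-duplication in feature order
  seen <- table(character(0))
  for (i in seq_along(regions)) {
    nm <- names_raw[i]
    k <- sum(names_raw[seq_len(i)] == nm)
    if (k > 1) regions[[i]]$name <- paste0(nm, "#", k)
  }
  regions
}

#' Write region annotations to GeoJSON
#'
#' @param regions list of [region()] objects.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_regions <- function(regions, path) {
  feats <- lapply(regions, function(r) {
    ring <- lapply(seq_len(nrow(r$polygon)), function(i) as.list(r$polygon[i, ]))
    ring[[length(ring) + 1]] <- as.list(r$polygon[1, ])  # close the ring
    list(type = "Feature",
         properties = list(name = r$name),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-region plaque burden reports to CSV
#'
#' @param reports a data frame of region reports (one row per region, as
#'   returned by [quantify_region()] / [quantify_section()]), or a list of
#'   such single-row data frames.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_report <- function(reports, path) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (length(reports) == 0) stop("no reports to write")
  df <- do.call(rbind, reports)
  cols <- c("region", "tissue_area_um2", "plaque_count", "plaque_area_um2",
            "plaque_coverage_pct", "brown_coverage_pct")
  if (!all(cols %in% names(df))) stop("malformed region report")
  df <- df[, cols]
  for (col in setdiff(cols, c("region", "plaque_count")))
    df[[col]] <- signif(df[[col]], 6)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a plate-reader table
#'
#' CSV schema: `row,col,role,analyte,replicate_group,nominal_conc,signal`
#' with `role` one of standard/blank/sample. Standards must carry a nominal
#' concentration.
#'
#' @param path CSV path.
#' @return A validated data frame of wells.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "role", "analyte", "replicate_group",
            "nominal_conc", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate table lacks columns: ",
                         paste(miss, collapse = ", "))
  validate_wells(df)
}

validate_wells <- function(df) {
  if (!all(df$role %in% c("standard", "blank", "sample")))
    stop("well role must be standard, blank or sample")
  std <- df$role == "standard"
  if (any(std & (is.na(df$nominal_conc) | df$nominal_conc < 0)))
    stop("standards must carry a non-negative nominal_conc")
  if (any(!is.finite(df$signal) | df$signal < 0))
    stop("signals must be finite and non-negative")
  if (any(is.na(df$replicate_group) | df$replicate_group == ""))
    stop("replicate_group must be non-empty")
  df
}
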