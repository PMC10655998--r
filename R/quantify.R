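#' Point-in-polygon test (boundary counts as inside)
#'
#' Even-odd (ray casting) rule with an explicit boundary check, vectorised
#' over points.
#'
#' @param px,py point coordinates.
#' @param poly two-column vertex matrix (x, y), not necessarily closed.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n >= 2 && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1
  }
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  eps <- 1e-9
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xe[i]; y2 <- ye[i]
    # on-segment test
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
    on <- abs(cross) <= eps * max(1, sqrt(seg_len2)) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    boundary <- boundary | on
    # crossing test (half-open rule avoids double-counting vertices)
    crosses <- ((y1 > py) != (y2 > py))
    xi <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
    inside <- xor(inside, crosses & !is.na(xi) & px < xi)
  }
  inside | boundary
}

# logical mask of raster pixels whose centres fall inside the polygon;
# the raster may be a block-downsampled grid (ds = block factor), with the
# polygon in 0-based scan-grid pixel coordinates
region_pixel_mask <- function(poly, nrow, ncol, ds = 1) {
  cx <- (seq_len(ncol) - 1) * ds + (ds - 1) / 2
  cy <- (seq_len(nrow) - 1) * ds + (ds - 1) / 2
  pts <- expand.grid(y = cy, x = cx)  # column-major like the raster
  matrix(point_in_polygon(pts$x, pts$y, poly), nrow, ncol)
}

region_report_row <- function(name, tissue_px, plaque_count, plaque_area,
                              brown_px, px_area) {
  tissue_area <- tissue_px * px_area
  data.frame(region = name,
             tissue_area_um2 = tissue_area,
             plaque_count = plaque_count,
             plaque_area_um2 = plaque_area,
             plaque_coverage_pct = if (tissue_area > 0)
               min(100, 100 * plaque_area / tissue_area) else 0,
             brown_coverage_pct = if (tissue_px > 0)
               100 * brown_px / tissue_px else 0,
             stringsAsFactors = FALSE)
}

#' Quantify plaque burden within an annotated region
#'
#' A plaque belongs to the region when its centroid lies inside the polygon
#' (boundary counts as inside); the full area of every counted plaque is
#' summed. Coverage denominators are the tissue area inside the polygon,
#' not the polygon area, so glass does not dilute the burden.
#'
#' @param plaques list of accepted plaques (from [segment_slide()] or
#'   [filter_candidates()]).
#' @param classes a [classify_brown()] result on the stain grid.
#' @param tissue logical tissue mask on the same grid.
#' @param region a [region()] with its polygon in 0-based scan-grid pixel
#'   coordinates.
#' @return A one-row data frame: `region`, `tissue_area_um2`,
#'   `plaque_count`, `plaque_area_um2`, `plaque_coverage_pct`,
#'   `brown_coverage_pct`.
#' @export
quantify_region <- function(plaques, classes, tissue, region) {
  stopifnot(inherits(classes, "brown_class_mask"), inherits(region, "region"))
  if (!identical(dim(tissue), dim(classes$labels)))
    stop("tissue mask grid does not match the class raster")
  ds <- classes$downsample
  nr <- nrow(classes$labels); nc <- ncol(classes$labels)
  rmask <- region_pixel_mask(region$polygon, nr, nc, ds)
  if (!any(rmask)) {
    # region may still be valid if tiny; fully outside the raster is an error
    bb_ok <- any(region$polygon[, 1] >= 0 & region$polygon[, 1] <= nc * ds &
                   region$polygon[, 2] >= 0 & region$polygon[, 2] <= nr * ds)
    if (!bb_ok) stop("region polygon lies outside the raster: ", region$name)
  }
  inside <- if (length(plaques))
    point_in_polygon(vapply(plaques, function(p) p$centroid[["x"]], 0),
                     vapply(plaques, function(p) p$centroid[["y"]], 0),
                     region$polygon) else logical(0)
  plaque_area <- sum(vapply(plaques[inside], function(p) p$area_um2, 0))
  px_area <- (classes$mpp * ds)^2
  region_report_row(region$name,
                    tissue_px = sum(tissue & rmask),
                    plaque_count = sum(inside),
                    plaque_area = plaque_area,
                    brown_px = sum(classes$labels > 0 & tissue & rmask),
                    px_area = px_area)
}

#' Quantify plaque burden over the whole section
#'
#' Equivalent to [quantify_region()] with a region covering the full
#' raster.
#'
#' @inheritParams quantify_region
#' @param name label for the report row.
#' @return A one-row data frame (see [quantify_region()]).
#' @export
quantify_section <- function(plaques, classes, tissue, name = "section") {
  stopifnot(inherits(classes, "brown_class_mask"))
  if (!identical(dim(tissue), dim(classes$labels)))
    stop("tissue mask grid does not match the class raster")
  px_area <- (classes$mpp * classes$downsample)^2
  region_report_row(name,
                    tissue_px = sum(tissue),
                    plaque_count = length(plaques),
                    plaque_area = sum(vapply(plaques,
                                             function(p) p$area_um2, 0)),
                    brown_px = sum(classes$labels > 0 & tissue),
                    px_area = px_area)
}

#' Per-region and whole-section burden report for a segmentation
#'
#' @param seg a [segment_slide()] result.
#' @param regions optional list of [region()] annotations.
#' @param section_name label for the whole-section row.
#' @return A data frame with one row per region plus one section row.
#' @export
quantify_slide <- function(seg, regions = NULL, section_name = "section") {
  stopifnot(inherits(seg, "segmentation"))
  rows <- lapply(regions %||% list(), function(r)
    quantify_region(seg$plaques, seg$classes, seg$tissue_stain, r))
  rows[[length(rows) + 1]] <- quantify_section(seg$plaques, seg$classes,
                                               seg$tissue_stain,
                                               name = section_name)
  do.call(rbind, rows)
}
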