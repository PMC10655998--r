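#' Convert RGB intensities to per-channel optical density
#'
#' Beer-Lambert transform underlying the density component of the
#' hue-saturation-density colour model for transmitted-light microscopy:
#' `D_ch = -ln(I_ch / i0_ch)`, with intensities clipped to `[1, i0]` first
#' so the density is finite and non-negative everywhere.
#'
#' @param slide an [rgb_slide()].
#' @return A numeric array `[rows, cols, 3]` of densities (au, natural log).
#' @export
rgb_to_density <- function(slide) {
  stopifnot(inherits(slide, "rgb_slide"))
  d <- dim(slide$pixels)
  out <- array(0, d)
  for (ch in 1:3) {
    i <- pmin(pmax(slide$pixels[, , ch], 1), slide$i0[ch])
    out[, , ch] <- -log(i / slide$i0[ch])
  }
  out
}

#' Unmix a density raster into brown (DAB) and blue (hematoxylin) maps
#'
#' Per-pixel least-squares decomposition of the 3-channel optical-density
#' vector onto the two stain reference directions. Negative coefficients are
#' clamped to zero; the Brown+ve raster (brown minus blue) is computed after
#' clamping, so `brown_pos_au == brown_au - blue_au` holds exactly.
#'
#' @param density `[rows, cols, 3]` density array from [rgb_to_density()].
#' @param ref a [stain_reference()].
#' @param mpp microns per pixel of the scan-resolution grid.
#' @param downsample block-averaging factor already applied to this raster
#'   relative to the scan grid (1 = native resolution).
#' @return An object of class `stain_maps` with matrices `brown_au`,
#'   `blue_au`, `brown_pos_au` and fields `mpp`, `downsample`.
#' @export
unmix_stains <- function(density, ref, mpp = 1, downsample = 1) {
  stopifnot(inherits(ref, "stain_reference"))
  if (length(dim(density)) != 3 || dim(density)[3] != 3)
    stop("density must be a [rows, cols, 3] array")
  a <- cbind(ref$brown_od, ref$blue_od)       # 3 x 2
  pinv <- solve(crossprod(a), t(a))           # 2 x 3
  d <- dim(density)
  n <- d[1] * d[2]
  dm <- rbind(as.vector(density[, , 1]),
              as.vector(density[, , 2]),
              as.vector(density[, , 3]))      # 3 x n
  coef <- pinv %*% dm                         # 2 x n
  brown <- matrix(pmax(coef[1, ], 0), d[1], d[2])
  blue <- matrix(pmax(coef[2, ], 0), d[1], d[2])
  stain_maps(brown, blue, mpp = mpp, downsample = downsample)
}

#' Assemble stain maps
#'
#' @param brown_au,blue_au non-negative density matrices of equal shape.
#' @param mpp microns per pixel of the scan grid.
#' @param downsample block factor of this raster relative to the scan grid.
#' @return An object of class `stain_maps`; `brown_pos_au` is derived as
#'   `brown_au - blue_au`.
#' @export
stain_maps <- function(brown_au, blue_au, mpp = 1, downsample = 1) {
  if (!identical(dim(brown_au), dim(blue_au)))
    stop("brown and blue rasters must share dimensions")
  if (any(brown_au < 0) || any(blue_au < 0))
    stop("stain densities must be non-negative")
  structure(list(brown_au = brown_au,
                 blue_au = blue_au,
                 brown_pos_au = brown_au - blue_au,
                 mpp = mpp,
                 downsample = downsample),
            class = "stain_maps")
}

#' @export
print.stain_maps <- function(x, ...) {
  d <- dim(x$brown_au)
  cat(sprintf(
    "<stain_maps> %d x %d px at %.4g um/px (block factor %d)\n",
    d[2], d[1], x$mpp * x$downsample, as.integer(x$downsample)))
  invisible(x)
}

# effective microns per pixel of a (possibly downsampled) raster
mpp_eff <- function(maps) maps$mpp * maps$downsample
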