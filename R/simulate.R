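# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# mask of pixels whose centres (in microns) fall inside a micron polygon
um_pixel_mask <- function(poly_um, nrow, ncol, mpp) {
  cx <- (seq_len(ncol) - 0.5) * mpp
  cy <- (seq_len(nrow) - 0.5) * mpp
  pts <- expand.grid(y = cy, x = cx)
  matrix(point_in_polygon(pts$x, pts$y, poly_um), nrow, ncol)
}

#' Specify a synthetic brightfield section
#'
#' Describes a transmitted-light slide for [simulate_slide()]: glass
#' background, a hematoxylin-tinted tissue polygon, DAB-stained plaques
#' (dark circular core inside a lighter, optionally wobbled halo) and
#' rule-violating artifact objects. All geometry is in microns (x right,
#' y down, origin at the top-left image corner); densities are natural-log
#' optical densities (au).
#'
#' @param width_px,height_px raster size in scan-resolution pixels.
#' @param mpp microns per pixel of the scan.
#' @param tissue_polygon two-column micron matrix; default an inset
#'   rectangle leaving a glass margin.
#' @param plaques data frame with columns `x_um`, `y_um`, `core_radius_um`,
#'   `halo_radius_um`, `core_brown_au`, `halo_brown_au` and optionally
#'   `wobble_amp`, `wobble_lobes`, `wobble_phase` (low-order radial wobble
#'   of the halo outline).
#' @param artifacts data frame with columns `type` (one of "speck",
#'   "pale_blob", "uniform_blob", "line", "dense_blob"), `x_um`, `y_um` and
#'   optionally `angle` (line orientation: "h" or "v"). Each type is built
#'   to violate exactly one removal rule (min_area, min_dark_area,
#'   uniform_dark, non_elliptical, dark_fraction respectively).
#' @param hematoxylin_au blue counterstain density over tissue.
#' @param noise_sd_au additive per-channel Gaussian density noise SD.
#' @param glass_jitter integer grey-level jitter amplitude on glass.
#' @param scan_magnification nominal objective of the emulated scan.
#' @param seed RNG seed used by [simulate_slide()].
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(width_px, height_px, mpp = 0.5,
                       tissue_polygon = NULL,
                       plaques = NULL, artifacts = NULL,
                       hematoxylin_au = 0.08, noise_sd_au = 0,
                       glass_jitter = 1, scan_magnification = 40,
                       seed = 1) {
  if (is.null(tissue_polygon)) {
    mx <- 0.06 * width_px * mpp; my <- 0.06 * height_px * mpp
    tissue_polygon <- cbind(
      x = c(mx, width_px * mpp - mx, width_px * mpp - mx, mx),
      y = c(my, my, height_px * mpp - my, height_px * mpp - my))
  }
  plaques <- plaques %||%
    data.frame(x_um = numeric(0), y_um = numeric(0),
               core_radius_um = numeric(0), halo_radius_um = numeric(0),
               core_brown_au = numeric(0), halo_brown_au = numeric(0))
  artifacts <- artifacts %||%
    data.frame(type = character(0), x_um = numeric(0), y_um = numeric(0))
  if (nrow(plaques)) {
    if (is.null(plaques$wobble_amp)) plaques$wobble_amp <- 0
    if (is.null(plaques$wobble_lobes)) plaques$wobble_lobes <- 3
    if (is.null(plaques$wobble_phase)) plaques$wobble_phase <- 0
    if (any(plaques$halo_radius_um < plaques$core_radius_um))
      stop("halo_radius_um must be at least core_radius_um")
    if (any(plaques$core_brown_au < 0 | plaques$halo_brown_au < 0))
      stop("densities must be non-negative")
  }
  if (nrow(artifacts)) {
    ok <- artifacts$type %in% names(artifact_rule)
    if (!all(ok)) stop("unknown artifact type: ",
                       paste(unique(artifacts$type[!ok]), collapse = ", "))
    if (is.null(artifacts$angle)) artifacts$angle <- "h"
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 mpp = mpp, tissue_polygon = tissue_polygon,
                 plaques = plaques, artifacts = artifacts,
                 hematoxylin_au = hematoxylin_au,
                 noise_sd_au = noise_sd_au,
                 glass_jitter = as.integer(glass_jitter),
                 scan_magnification = scan_magnification,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

# Artifact block patterns. Artifacts are drawn in aligned 2x2-scan-pixel
# blocks so that analysis at half resolution sees crisp objects; each
# pattern is a matrix of brown densities (au), 0 = untouched.
artifact_pattern <- function(type, angle = "h") {
  disc <- function(r) {
    d <- 2 * ceiling(r) + 1
    ctr <- ceiling(r) + 1
    m <- matrix(0, d, d)
    for (i in seq_len(d)) for (j in seq_len(d))
      if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- 1
    m
  }
  m <- switch(type,
    speck = {        # < 10 um^2 but dark-cored, compact: rule min_area
      m <- matrix(0.36, 3, 3); m[2, 1:2] <- 0.8; m
    },
    pale_blob = {    # >= 10 um^2, one dark block only: rule min_dark_area
      m <- disc(2.75) * 0.36; m[ceiling(2.75) + 1, ceiling(2.75) + 1] <- 0.8; m
    },
    uniform_blob = { # mid-size, uniformly dark: rule uniform_dark
      disc(3.0) * 0.8
    },
    line = {         # thin 30 um streak with a dark middle: non_elliptical
      m <- matrix(0.36, 1, 30); m[1, 15:16] <- 0.8; m
    },
    dense_blob = {   # > 40 um^2, > 70% dark, mottled core: dark_fraction
      outer <- disc(4.5); inner <- disc(4.2)
      d <- nrow(outer); di <- nrow(inner)
      pad <- (d - di) / 2
      core <- matrix(0, d, d)
      core[(pad + 1):(pad + di), (pad + 1):(pad + di)] <- inner
      chk <- outer(seq_len(d), seq_len(d), function(i, j) (i + j) %% 2)
      m <- outer * 0.36
      m[core == 1] <- ifelse(chk[core == 1] == 1, 1.35, 0.55)
      m
    },
    stop("unknown artifact type: ", type))
  if (type == "line" && angle == "v") m <- t(m)
  m
}

artifact_rule <- c(speck = "min_area",
                   pale_blob = "min_dark_area",
                   uniform_blob = "uniform_dark",
                   line = "non_elliptical",
                   dense_blob = "dark_fraction")

#' Render a synthetic slide with ground truth
#'
#' Composes per-pixel optical density (hematoxylin over tissue plus the
#' local DAB load, plus optional Gaussian density noise), converts it to
#' transmitted intensity via the Beer-Lambert relation
#' `I = i0 * exp(-D)`, and quantises to 8 bits. Glass outside the tissue
#' polygon sits at the reference intensity with +-1 grey-level jitter.
#' Deterministic for a fixed seed.
#'
#' @param spec a [slide_spec()].
#' @param ref a [stain_reference()] giving the per-channel stain colours.
#' @param seed RNG seed (defaults to the spec's).
#' @param keep_density keep the planted density rasters in the truth object
#'   (set FALSE for large sections to save memory).
#' @return A list with `slide` (an [rgb_slide()]) and `truth` (class
#'   `slide_truth`): per-plaque footprints/areas, per-artifact intended
#'   removal rule, and (optionally) the planted density rasters `brown_au`,
#'   `blue_au`.
#' @export
simulate_slide <- function(spec, ref = stain_reference(), seed = spec$seed,
                           keep_density = TRUE) {
  stopifnot(inherits(spec, "slide_spec"))
  h <- spec$height_px; w <- spec$width_px; mpp <- spec$mpp
  tissue <- um_pixel_mask(spec$tissue_polygon, h, w, mpp)
  brown <- matrix(0, h, w)

  clip_idx <- function(v, n) v[v >= 1 & v <= n]
  truth_plaques <- NULL
  pl <- spec$plaques
  if (nrow(pl)) {
    rows <- vector("list", nrow(pl))
    for (k in seq_len(nrow(pl))) {
      p <- pl[k, ]
      rmax <- p$halo_radius_um * (1 + abs(p$wobble_amp))
      ci <- clip_idx(floor((p$y_um - rmax) / mpp):ceiling((p$y_um + rmax) / mpp + 1), h)
      cj <- clip_idx(floor((p$x_um - rmax) / mpp):ceiling((p$x_um + rmax) / mpp + 1), w)
      yy <- (ci - 0.5) * mpp - p$y_um
      xx <- (cj - 0.5) * mpp - p$x_um
      dy <- matrix(yy, length(ci), length(cj))
      dx <- matrix(xx, length(ci), length(cj), byrow = TRUE)
      dist <- sqrt(dx^2 + dy^2)
      theta <- atan2(dy, dx)
      rb <- p$halo_radius_um *
        (1 + p$wobble_amp * cos(p$wobble_lobes * theta + p$wobble_phase))
      # anti-aliased footprints: edge pixels carry density in proportion to
      # their coverage (linear ramp over one pixel width), so downstream
      # block averaging sees a continuous, unbiased boundary
      cov_halo <- pmin(pmax((rb - dist) / mpp + 0.5, 0), 1)
      cov_core <- pmin(pmax((p$core_radius_um - dist) / mpp + 0.5, 0), 1)
      sub <- brown[ci, cj]
      sub <- pmax(sub, p$halo_brown_au * cov_halo)
      sub <- pmax(sub, p$core_brown_au * cov_core)
      brown[ci, cj] <- sub
      if (!all(tissue[ci, cj][cov_halo > 0]))
        stop("plaque ", k, " extends outside the tissue polygon")
      rows[[k]] <- data.frame(id = k, x_um = p$x_um, y_um = p$y_um,
                              x_px = p$x_um / mpp - 0.5,
                              y_px = p$y_um / mpp - 0.5,
                              core_radius_um = p$core_radius_um,
                              halo_radius_um = p$halo_radius_um,
                              footprint_px = sum(cov_halo),
                              area_um2 = sum(cov_halo) * mpp^2)
    }
    truth_plaques <- do.call(rbind, rows)
  }

  truth_artifacts <- NULL
  ar <- spec$artifacts
  if (nrow(ar)) {
    rows <- vector("list", nrow(ar))
    for (k in seq_len(nrow(ar))) {
      a <- ar[k, ]
      pat <- artifact_pattern(a$type, a$angle)
      # anchor the block pattern on the even-pixel grid to survive the
      # 2x block averaging of stain detection without edge blur
      bi <- 2 * round(a$y_um / mpp / 2)
      bj <- 2 * round(a$x_um / mpp / 2)
      # top-left corner on the even-pixel grid (1-based rows bi+1, bi+2, ...)
      ci <- bi + seq_len(2 * nrow(pat))
      cj <- bj + seq_len(2 * ncol(pat))
      if (any(ci < 1 | ci > h) || any(cj < 1 | cj > w))
        stop("artifact ", k, " extends outside the raster")
      big <- pat[rep(seq_len(nrow(pat)), each = 2),
                 rep(seq_len(ncol(pat)), each = 2), drop = FALSE]
      sub <- brown[ci, cj]
      brown[ci, cj] <- pmax(sub, big)
      if (!all(tissue[ci, cj][big > 0]))
        stop("artifact ", k, " extends outside the tissue polygon")
      rows[[k]] <- data.frame(id = k, type = a$type,
                              rule = unname(artifact_rule[a$type]),
                              x_um = a$x_um, y_um = a$y_um,
                              x_px = bj - 1, y_px = bi - 1,
                              area_um2 = sum(big > 0) * mpp^2)
    }
    truth_artifacts <- do.call(rbind, rows)
  }

  blue <- spec$hematoxylin_au * tissue
  i0 <- c(255, 255, 255)
  px <- array(0L, c(h, w, 3))
  with_seed(seed, {
    glass_j <- if (spec$glass_jitter > 0)
      matrix(sample(seq(-spec$glass_jitter, spec$glass_jitter),
                    h * w, replace = TRUE), h, w) else matrix(0L, h, w)
    for (ch in 1:3) {
      d <- brown * ref$brown_od[ch] + blue * ref$blue_od[ch]
      if (spec$noise_sd_au > 0)
        d <- pmax(d + matrix(rnorm(h * w, 0, spec$noise_sd_au), h, w), 0)
      i <- round(i0[ch] * exp(-d))
      i[!tissue] <- i0[ch] + glass_j[!tissue]
      px[, , ch] <- pmin(pmax(i, 0L), 255L)
    }
  })
  slide <- rgb_slide(px, mpp = mpp, i0 = i0,
                     scan_magnification = spec$scan_magnification)
  truth <- structure(list(plaques = truth_plaques,
                          artifacts = truth_artifacts,
                          brown_au = if (keep_density) brown,
                          blue_au = if (keep_density) blue,
                          tissue = if (keep_density) tissue,
                          spec = spec),
                     class = "slide_truth")
  list(slide = slide, truth = truth)
}

#' Canonical validation section: 200 plaques and 50 artifacts
#'
#' A 4000 x 4000 px section at 0.5 um/px with 200 detectable plaques
#' (varied radii and halo wobble) and 50 artifacts (10 of each of the five
#' rule-violating types) placed on a jittered grid inside the tissue
#' polygon, rendered noiselessly. Regenerated from code; deterministic per
#' seed.
#'
#' @param n_plaques,n_artifacts object counts.
#' @param width_px,height_px,mpp raster geometry.
#' @param noise_sd_au density noise (0 = the canonical noiseless fixture).
#' @param seed placement/render seed.
#' @return A [slide_spec()].
#' @export
clean_section_spec <- function(n_plaques = 200, n_artifacts = 50,
                               width_px = 4000, height_px = 4000,
                               mpp = 0.5, noise_sd_au = 0, seed = 1) {
  w_um <- width_px * mpp; h_um <- height_px * mpp
  margin <- 0.06 * min(w_um, h_um)
  inner <- margin + 40
  cell <- 80
  nx <- floor((w_um - 2 * inner) / cell)
  ny <- floor((h_um - 2 * inner) / cell)
  if (nx * ny < n_plaques + n_artifacts)
    stop("section too small for the requested object count")
  with_seed(seed, {
    cells <- sample(nx * ny, n_plaques + n_artifacts)
    cx <- inner + ((cells - 1) %% nx + 0.5) * cell +
      runif(length(cells), -15, 15)
    cy <- inner + ((cells - 1) %/% nx + 0.5) * cell +
      runif(length(cells), -15, 15)
    pk <- seq_len(n_plaques)
    plaques <- data.frame(
      x_um = cx[pk], y_um = cy[pk],
      core_radius_um = runif(n_plaques, 2, 2.8),
      halo_radius_um = runif(n_plaques, 7, 11),
      core_brown_au = 0.8, halo_brown_au = 0.40,
      wobble_amp = runif(n_plaques, 0, 0.08),
      wobble_lobes = sample(3:5, n_plaques, replace = TRUE),
      wobble_phase = runif(n_plaques, 0, 2 * pi))
    types <- rep(names(artifact_rule), length.out = n_artifacts)
    artifacts <- data.frame(
      type = types,
      x_um = cx[n_plaques + seq_len(n_artifacts)],
      y_um = cy[n_plaques + seq_len(n_artifacts)],
      angle = sample(c("h", "v"), n_artifacts, replace = TRUE))
  })
  slide_spec(width_px, height_px, mpp = mpp,
             plaques = plaques, artifacts = artifacts,
             noise_sd_au = noise_sd_au, seed = seed)
}

#' Empty control section
#'
#' Tissue and glass only; segmentation of its rendering must produce no
#' candidate objects.
#'
#' @param width_px,height_px,mpp raster geometry.
#' @param seed render seed.
#' @return A [slide_spec()].
#' @export
null_section_spec <- function(width_px = 800, height_px = 800, mpp = 0.5,
                              seed = 1) {
  slide_spec(width_px, height_px, mpp = mpp, seed = seed)
}

#' Constructed boundary-case candidate objects
#'
#' Candidate statistics sitting exactly on the removal-rule boundaries:
#' area exactly 10 and 40 um^2, dark area exactly 1.5 um^2, dark fraction
#' exactly 0.70, mean/SD exactly at 0.5/0.25 au. Used to pin the printed
#' inequality directions (strict "smaller than 10", "less than 1.5",
#' ">0.5 & <0.25", strict "less/greater than 40", strict ">70%").
#'
#' @return A list of candidate-like objects with a `expect_flags` field
#'   naming the rules that must fire (empty = must be accepted).
#' @export
boundary_case_candidates <- function() {
  mk <- function(area, dark, mean_b, sd_b, fit, expect) {
    list(id = NA_integer_, pixels = cbind(row = 1L, col = 1L),
         n_px = as.integer(area), area_um2 = area, dark_area_um2 = dark,
         mean_brown_au = mean_b, sd_brown_au = sd_b, elliptic_fit = fit,
         centroid = c(x = 0, y = 0), expect_flags = expect)
  }
  list(
    mk(10, 5, 0.4, 0.2, 0.9, character(0)),     # area exactly 10: kept
    mk(9.99, 5, 0.4, 0.2, 0.9, "min_area"),
    mk(20, 1.5, 0.4, 0.2, 0.9, character(0)),   # dark exactly 1.5: kept
    mk(20, 1.49, 0.4, 0.2, 0.9, "min_dark_area"),
    mk(40, 10, 0.4, 0.2, 0.1, character(0)),    # 40 um^2: neither d nor e
    mk(40, 39, 0.4, 0.3, 0.9, character(0)),
    mk(41, 28.7, 0.4, 0.3, 0.9, character(0)),  # fraction exactly 0.70
    mk(41, 29.11, 0.4, 0.3, 0.9, "dark_fraction"),
    mk(39.9, 10, 0.4, 0.3, 0.64, "non_elliptical"),
    mk(30, 10, 0.5, 0.1, 0.9, character(0)),    # mean exactly 0.5: kept
    mk(30, 10, 0.51, 0.25, 0.9, character(0)),  # SD exactly 0.25: kept
    mk(30, 10, 0.51, 0.24, 0.9, "uniform_dark"))
}

#' Specify a synthetic immunoassay plate
#'
#' Twelve-point duplicate serial-dilution standard curve with blanks and
#' samples, under multiplicative signal noise, matching the layout of a
#' plate-based oligomer immunoassay.
#'
#' @param a,b,c,d true 4PL parameters (zero-dose asymptote, slope,
#'   inflection, saturating asymptote).
#' @param top_conc highest standard concentration.
#' @param dilution_factor serial dilution step (> 1).
#' @param n_points number of standard concentrations.
#' @param n_replicates replicate wells per standard (duplicate by default).
#' @param n_blanks number of blank wells.
#' @param sample_concs named numeric vector of true sample concentrations
#'   (each loaded in `n_replicates` wells).
#' @param noise_cv_pct multiplicative noise CV in percent.
#' @param seed RNG seed for [simulate_plate()].
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(a = 100, b = 1.2, c = 50, d = 10000,
                       top_conc = 2500, dilution_factor = 3,
                       n_points = 12, n_replicates = 2, n_blanks = 4,
                       sample_concs = NULL, noise_cv_pct = 1, seed = 1) {
  stopifnot(dilution_factor > 1, n_points >= 2, noise_cv_pct >= 0)
  structure(list(a = a, b = b, c = c, d = d, top_conc = top_conc,
                 dilution_factor = dilution_factor, n_points = n_points,
                 n_replicates = n_replicates, n_blanks = n_blanks,
                 sample_concs = sample_concs, noise_cv_pct = noise_cv_pct,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

#' Render a synthetic plate
#'
#' Signals are `4PL(true conc) * (1 + eps)` with
#' `eps ~ Normal(0, cv/100)` truncated at -0.99; blanks sit at the
#' zero-dose asymptote with the same noise. Deterministic per seed.
#'
#' @param spec a [plate_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return A list with `wells` (a plate data frame as read by
#'   [read_plate()]) and `truth` (the spec, holding the true parameters and
#'   concentrations).
#' @export
simulate_plate <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "plate_spec"))
  concs <- spec$top_conc / spec$dilution_factor^(seq_len(spec$n_points) - 1)
  std <- data.frame(
    role = "standard",
    nominal_conc = rep(concs, each = spec$n_replicates),
    replicate_group = rep(sprintf("std_%02d", seq_len(spec$n_points)),
                          each = spec$n_replicates))
  blank <- data.frame(role = "blank", nominal_conc = NA_real_,
                      replicate_group = rep("blank", spec$n_blanks))
  smp <- if (length(spec$sample_concs))
    data.frame(role = "sample", nominal_conc = NA_real_,
               replicate_group = rep(names(spec$sample_concs),
                                     each = spec$n_replicates))
  else NULL
  wells <- rbind(std, blank, smp)
  true_conc <- c(rep(concs, each = spec$n_replicates),
                 rep(0, spec$n_blanks),
                 if (length(spec$sample_concs))
                   rep(unname(spec$sample_concs),
                       each = spec$n_replicates))
  mu <- ifelse(true_conc > 0,
               four_pl(true_conc, spec$a, spec$b, spec$c, spec$d),
               spec$a)
  with_seed(seed, {
    eps <- pmax(rnorm(nrow(wells), 0, spec$noise_cv_pct / 100), -0.99)
    wells$signal <- mu * (1 + eps)
  })
  n <- nrow(wells)
  wells$row <- LETTERS[(seq_len(n) - 1) %/% 12 + 1]
  wells$col <- (seq_len(n) - 1) %% 12 + 1
  wells$analyte <- "analyte"
  wells$true_conc <- true_conc
  wells <- wells[, c("row", "col", "role", "analyte", "replicate_group",
                     "nominal_conc", "signal", "true_conc")]
  list(wells = validate_wells(wells), truth = spec)
}

#' Render grouped measurements with known medians
#'
#' Draws per-group samples whose population median equals the requested
#' median: lognormal (`exp(Normal(log median, spread))`, spread = SD on the
#' log scale) or normal (`Normal(median, spread)`). Emulates per-genotype
#' measurement tables with small n.
#'
#' @param medians named numeric vector of group medians.
#' @param spread per-group spread (recycled); log-scale SD for lognormal.
#' @param n per-group sample size (recycled).
#' @param family "lognormal" or "normal".
#' @param seed RNG seed.
#' @return A [group_table()].
#' @export
simulate_groups <- function(medians, spread, n,
                            family = c("lognormal", "normal"), seed = 1) {
  family <- match.arg(family)
  if (is.null(names(medians))) stop("medians must be named by group")
  k <- length(medians)
  spread <- rep(spread, length.out = k)
  n <- rep(n, length.out = k)
  stopifnot(all(n >= 1), all(spread >= 0))
  with_seed(seed, {
    out <- lapply(seq_len(k), function(i) {
      if (family == "lognormal") {
        if (medians[i] <= 0) stop("lognormal medians must be positive")
        exp(rnorm(n[i], log(medians[i]), spread[i]))
      } else rnorm(n[i], medians[i], spread[i])
    })
  })
  group_table(setNames(out, names(medians)))
}
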