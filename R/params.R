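#' Segmentation parameters
#'
#' Container for every tunable threshold of the plaque segmentation pipeline.
#' Defaults are the published rule set: tissue is separated from glass at the
#' 95th brightness centile minus 10 grey levels (256-level scale), brown
#' staining above 0.15 au with Brown+ve above 0.1 au is retained, dark brown
#' starts at 0.5 au (inclusive), and candidate objects are removed when they
#' are smaller than 10 um^2, contain less than 1.5 um^2 of dark brown, are
#' uniformly dark (mean > 0.5 au with SD < 0.25 au), are small (< 40 um^2)
#' and non-elliptical, or are large (> 40 um^2) with more than 70% dark brown
#' area.
#'
#' @param tissue_percentile brightness percentile for the tissue threshold.
#' @param tissue_offset additive adjustment to the threshold, in grey levels.
#' @param tissue_scale_mag nominal magnification at which tissue detection
#'   runs (the raster is block-averaged from the scan magnification).
#' @param stain_scale_mag nominal magnification for stain detection.
#' @param brown_min_au minimum brown density (strict) for any brown class.
#' @param brown_pos_min_au minimum Brown+ve density (strict) for any brown
#'   class.
#' @param dark_min_au density at and above which brown counts as dark.
#' @param min_area_um2 rule (a): objects smaller than this are removed.
#' @param min_dark_area_um2 rule (b): minimum dark brown area.
#' @param artifact_intensity_min_au rule (c): mean brown density above which
#'   a low-variance object is treated as an artifact.
#' @param artifact_sd_max_au rule (c): brown density SD below which it is.
#' @param small_area_um2 boundary between the small-object shape rule (d)
#'   and the large-object dark-fraction rule (e).
#' @param dark_fraction_max rule (e): maximum tolerated dark brown fraction
#'   for large objects.
#' @param elliptic_fit_min rule (d): minimum elliptic fit score.
#' @param connectivity pixel connectivity (4 or 8) used for components and
#'   region growing.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(tissue_percentile = 95,
                                tissue_offset = -10,
                                tissue_scale_mag = 10,
                                stain_scale_mag = 20,
                                brown_min_au = 0.15,
                                brown_pos_min_au = 0.1,
                                dark_min_au = 0.5,
                                min_area_um2 = 10,
                                min_dark_area_um2 = 1.5,
                                artifact_intensity_min_au = 0.5,
                                artifact_sd_max_au = 0.25,
                                small_area_um2 = 40,
                                dark_fraction_max = 0.70,
                                elliptic_fit_min = 0.65,
                                connectivity = 8) {
  p <- list(tissue_percentile = tissue_percentile,
            tissue_offset = tissue_offset,
            tissue_scale_mag = tissue_scale_mag,
            stain_scale_mag = stain_scale_mag,
            brown_min_au = brown_min_au,
            brown_pos_min_au = brown_pos_min_au,
            dark_min_au = dark_min_au,
            min_area_um2 = min_area_um2,
            min_dark_area_um2 = min_dark_area_um2,
            artifact_intensity_min_au = artifact_intensity_min_au,
            artifact_sd_max_au = artifact_sd_max_au,
            small_area_um2 = small_area_um2,
            dark_fraction_max = dark_fraction_max,
            elliptic_fit_min = elliptic_fit_min,
            connectivity = connectivity)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num) || !all(is.finite(unlist(p))))
    stop("all segmentation parameters must be finite numerics")
  if (p$dark_fraction_max <= 0 || p$dark_fraction_max > 1)
    stop("dark_fraction_max must lie in (0, 1]")
  if (p$brown_min_au >= p$dark_min_au)
    stop("brown_min_au must be below dark_min_au")
  if (!p$connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8")
  if (p$tissue_percentile <= 0 || p$tissue_percentile >= 100)
    stop("tissue_percentile must lie in (0, 100)")
  structure(p, class = "segmentation_params")
}

#' Immunoassay quality-control parameters
#'
#' Thresholds for assay limit determination. The limit of detection is the
#' blank mean plus `lod_sd_multiplier` blank SDs (back-interpolated to
#' concentration); set `lod_add_blank_mean = FALSE` for the bare
#' multiplier-times-SD signal threshold. The lower limit of quantification
#' is the lowest standard whose back-interpolation lies within
#' `[lloq_backinterp_low_pct, lloq_backinterp_high_pct]` percent of nominal,
#' whose replicate CV is at most `lloq_cv_max_pct`, and whose mean signal
#' exceeds the blank mean by `blank_sd_multiplier` blank SDs.
#'
#' @param lod_sd_multiplier blank-SD multiplier for the detection limit.
#' @param lloq_backinterp_low_pct,lloq_backinterp_high_pct accepted
#'   back-interpolation window, in percent of nominal concentration.
#' @param lloq_cv_max_pct maximum replicate coefficient of variation (%).
#' @param blank_sd_multiplier blank-SD multiplier for the blank-separation
#'   clause.
#' @param curve_model calibration curve family ("4PL"; "5PL" reserved).
#' @param weighting least-squares weighting: "none", "1/y" or "1/y^2".
#' @param lod_add_blank_mean add the blank mean to the LOD signal threshold.
#' @return An object of class `assay_qc_params`.
#' @export
assay_qc_params <- function(lod_sd_multiplier = 2.5,
                            lloq_backinterp_low_pct = 80,
                            lloq_backinterp_high_pct = 120,
                            lloq_cv_max_pct = 20,
                            blank_sd_multiplier = 9,
                            curve_model = "4PL",
                            weighting = c("none", "1/y", "1/y^2"),
                            lod_add_blank_mean = TRUE) {
  weighting <- match.arg(weighting)
  curve_model <- match.arg(curve_model, c("4PL"))
  if (lod_sd_multiplier <= 0 || blank_sd_multiplier <= 0)
    stop("SD multipliers must be positive")
  if (!(lloq_backinterp_low_pct < 100 && 100 < lloq_backinterp_high_pct))
    stop("back-interpolation window must bracket 100%")
  structure(list(lod_sd_multiplier = lod_sd_multiplier,
                 lloq_backinterp_low_pct = lloq_backinterp_low_pct,
                 lloq_backinterp_high_pct = lloq_backinterp_high_pct,
                 lloq_cv_max_pct = lloq_cv_max_pct,
                 blank_sd_multiplier = blank_sd_multiplier,
                 curve_model = curve_model,
                 weighting = weighting,
                 lod_add_blank_mean = lod_add_blank_mean),
            class = "assay_qc_params")
}

#' Stain reference vectors
#'
#' Per-channel optical-density direction of each chromogen, used for the
#' two-stain unmixing. Defaults are widely used DAB and hematoxylin
#' absorbance vectors; both are normalised to unit Euclidean length.
#'
#' @param brown_od length-3 non-negative OD vector for DAB (R, G, B).
#' @param blue_od length-3 non-negative OD vector for hematoxylin.
#' @return An object of class `stain_reference` with unit-norm vectors.
#' @export
stain_reference <- function(brown_od = c(0.269, 0.568, 0.778),
                            blue_od = c(0.650, 0.704, 0.286)) {
  check_vec <- function(v, what) {
    if (length(v) != 3 || !is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop(what, " must be a non-negative finite length-3 vector")
    n <- sqrt(sum(v^2))
    if (n == 0) stop(what, " must be non-zero")
    v / n
  }
  brown <- check_vec(brown_od, "brown_od")
  blue <- check_vec(blue_od, "blue_od")
  # linear independence: reject (near-)parallel references
  if (sqrt(sum(cross3(brown, blue)^2)) < 1e-6)
    stop("stain reference vectors are degenerate (parallel)")
  structure(list(brown_od = brown, blue_od = blue), class = "stain_reference")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Read pipeline parameters from a YAML configuration file
#'
#' Reads a file with optional top-level sections `segmentation`, `assay` and
#' `stain`, each holding overrides for [segmentation_params()],
#' [assay_qc_params()] and [stain_reference()] respectively. Absent keys keep
#' their defaults.
#'
#' @param path path to a YAML file.
#' @return A list with elements `segmentation`, `assay` and `stain`.
#' @export
params_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  build <- function(fun, over) do.call(fun, as.list(over %||% list()))
  list(segmentation = build(segmentation_params, cfg$segmentation),
       assay = build(assay_qc_params, cfg$assay),
       stain = build(stain_reference, cfg$stain))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
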