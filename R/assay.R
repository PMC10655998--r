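#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x / c)^b)` to standard
#' wells, where `a` is the response as concentration approaches zero, `d`
#' the response at saturating concentration, `c` the inflection
#' concentration and `b` the slope. Initialisation is deterministic from
#' the data (a = smallest per-concentration mean signal, d = largest,
#' c = geometric mid concentration, b = 1); optional `1/y` or `1/y^2`
#' weighting uses the observed signals. Non-monotone per-concentration mean
#' signals (beyond 5% of the signal range) are flagged with a warning and
#' `monotone_ok = FALSE` rather than silently fitted.
#'
#' @param standards data frame of standard wells with columns
#'   `nominal_conc` (> 0) and `signal`; at least 5 distinct concentrations.
#' @param params an [assay_qc_params()].
#' @return An object of class `curve_fit` with the parameters, residual sum
#'   of squares, a `converged` flag and `monotone_ok`.
#' @export
fit_curve <- function(standards, params = assay_qc_params()) {
  std <- standards
  if (!is.null(standards$role))
    std <- standards[standards$role == "standard", , drop = FALSE]
  if (any(!is.finite(std$signal))) stop("standard signals must be finite")
  if (any(std$nominal_conc <= 0))
    stop("standard concentrations must be positive for curve fitting")
  concs <- sort(unique(std$nominal_conc))
  if (length(concs) < 5)
    stop("need at least 5 distinct standard concentrations, got ",
         length(concs))
  means <- vapply(concs, function(cc)
    mean(std$signal[std$nominal_conc == cc]), 0)

  dm <- diff(means)
  tol <- 0.05 * diff(range(means))
  # non-monotone = the per-concentration means both rise and fall by more
  # than the tolerance somewhere along the dilution series
  monotone_ok <- !(any(dm > tol) && any(dm < -tol))
  if (!monotone_ok)
    warning("standard mean signals are not monotone in concentration")

  start <- list(a = min(means), d = max(means),
                c = exp(mean(log(range(concs)))), b = 1)
  w <- switch(params$weighting,
              "none" = rep(1, nrow(std)),
              "1/y" = 1 / pmax(std$signal, .Machine$double.eps),
              "1/y^2" = 1 / pmax(std$signal, .Machine$double.eps)^2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ d + (a - d) / (1 + (nominal_conc / c)^b),
      data = std, start = start, weights = w,
      lower = c(a = -Inf, d = -Inf, c = .Machine$double.eps, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      warning("curve fit failed: ", conditionMessage(e))
      NULL
    })
  cf <- if (is.null(fit)) start else as.list(coef(fit))
  res <- std$signal - four_pl(std$nominal_conc, cf$a, cf$b, cf$c, cf$d)
  structure(list(model = params$curve_model,
                 a = cf$a, b = cf$b, c = cf$c, d = cf$d,
                 weighting = params$weighting,
                 rss = sum(res^2),
                 converged = !is.null(fit) && isTRUE(fit$convInfo$isConv),
                 monotone_ok = monotone_ok,
                 conc_range = range(concs)),
            class = "curve_fit")
}

#' Evaluate a four-parameter logistic curve
#'
#' @param x concentration(s).
#' @param a,b,c,d 4PL parameters (zero-dose asymptote, slope, inflection,
#'   saturating asymptote).
#' @return Signal value(s).
#' @export
four_pl <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)

#' @export
predict.curve_fit <- function(object, x, ...) {
  four_pl(x, object$a, object$b, object$c, object$d)
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf(
    "<curve_fit 4PL> a=%.4g b=%.4g c=%.4g d=%.4g (rss %.4g%s%s)\n",
    x$a, x$b, x$c, x$d, x$rss,
    if (x$converged) "" else ", NOT converged",
    if (x$monotone_ok) "" else ", non-monotone standards"))
  invisible(x)
}

#' Back-interpolate concentrations from signals
#'
#' Closed-form 4PL inverse `x = c * ((a - d) / (y - d) - 1)^(1/b)`. Signals
#' at or beyond the asymptotes are censored ("below" / "above" range)
#' rather than extrapolated.
#'
#' @param fit a converged [fit_curve()] result.
#' @param signal numeric vector of signals.
#' @return Data frame with columns `signal`, `conc` (NA when censored) and
#'   `censor` ("ok", "below", "above").
#' @export
back_interpolate <- function(fit, signal) {
  stopifnot(inherits(fit, "curve_fit"))
  if (!fit$converged) stop("curve fit did not converge")
  lo <- min(fit$a, fit$d); hi <- max(fit$a, fit$d)
  increasing <- fit$d >= fit$a  # signal rises with concentration
  censor <- rep("ok", length(signal))
  censor[signal <= lo] <- if (increasing) "below" else "above"
  censor[signal >= hi] <- if (increasing) "above" else "below"
  conc <- rep(NA_real_, length(signal))
  ok <- censor == "ok"
  y <- signal[ok]
  conc[ok] <- fit$c * ((fit$a - fit$d) / (y - fit$d) - 1)^(1 / fit$b)
  data.frame(signal = signal, conc = conc, censor = censor,
             stringsAsFactors = FALSE)
}

#' Limit of detection from blank wells
#'
#' The signal threshold is the blank mean plus `lod_sd_multiplier` sample
#' SDs of the blank signals (or the bare multiple of the SD when
#' `lod_add_blank_mean` is FALSE), back-interpolated to concentration. A
#' threshold at or below the curve's lower range is censored at
#' concentration 0.
#'
#' @param blanks data frame of blank wells (column `signal`; at least 2).
#' @param fit a converged [fit_curve()] result.
#' @param params an [assay_qc_params()].
#' @return List with `threshold_signal`, `lod_conc` and `censored`.
#' @export
compute_lod <- function(blanks, fit, params = assay_qc_params()) {
  sig <- blanks$signal %||% blanks
  if (length(sig) < 2) stop("need at least 2 blank wells")
  thr <- params$lod_sd_multiplier * sd(sig) +
    if (params$lod_add_blank_mean) mean(sig) else 0
  bi <- back_interpolate(fit, thr)
  censored <- bi$censor != "ok"
  list(threshold_signal = thr,
       lod_conc = if (bi$censor == "below") 0 else bi$conc,
       censored = censored)
}

#' Assay limits: LOD and LLOQ with the per-standard QC table
#'
#' For each standard concentration the replicate mean signal, CV% and
#' back-interpolation% are computed; a standard passes when its
#' back-interpolation lies within the configured window (100 +/- 20% by
#' default), its CV is at most 20%, and its mean signal exceeds the blank
#' mean by 9 blank SDs. The LLOQ is the lowest passing standard
#' concentration (NA when none pass).
#'
#' @param standards data frame of standard wells (`nominal_conc`,
#'   `signal`).
#' @param blanks data frame of blank wells.
#' @param fit a converged [fit_curve()] result.
#' @param params an [assay_qc_params()].
#' @return An object of class `assay_limits`: `lod_conc`,
#'   `lod_threshold_signal`, `lloq_conc`, and `per_standard` (one row per
#'   concentration with the QC quantities and a `passes` flag).
#' @export
compute_lloq <- function(standards, blanks, fit,
                         params = assay_qc_params()) {
  stopifnot(inherits(fit, "curve_fit"))
  std <- if (!is.null(standards$role))
    standards[standards$role == "standard", , drop = FALSE] else standards
  bsig <- blanks$signal %||% blanks
  lod <- compute_lod(blanks, fit, params)
  blank_gate <- mean(bsig) + params$blank_sd_multiplier * sd(bsig)

  concs <- sort(unique(std$nominal_conc))
  per <- do.call(rbind, lapply(concs, function(cc) {
    s <- std$signal[std$nominal_conc == cc]
    m <- mean(s)
    cv <- if (length(s) > 1) 100 * sd(s) / m else NA_real_
    bi <- back_interpolate(fit, m)
    bip <- if (bi$censor == "ok") 100 * bi$conc / cc else NA_real_
    passes <- !is.na(bip) &&
      bip >= params$lloq_backinterp_low_pct &&
      bip <= params$lloq_backinterp_high_pct &&
      !is.na(cv) && cv <= params$lloq_cv_max_pct &&
      m > blank_gate
    data.frame(nominal_conc = cc, mean_signal = m, cv_pct = cv,
               backinterp_pct = bip, passes = passes)
  }))
  lloq <- if (any(per$passes)) min(per$nominal_conc[per$passes]) else NA_real_
  structure(list(lod_conc = lod$lod_conc,
                 lod_threshold_signal = lod$threshold_signal,
                 blank_gate_signal = blank_gate,
                 lloq_conc = lloq,
                 per_standard = per),
            class = "assay_limits")
}

#' Quantify sample wells against a fitted standard curve
#'
#' Replicate wells (grouped by `replicate_group`) are averaged, the mean
#' signal back-interpolated, multiplied by the dilution factor and
#' optionally divided by a tissue normaliser (e.g. mg of wet tissue, for
#' ng/mg reporting). Wells whose mean signal falls below the LOD signal
#' threshold are flagged `<LOD`, concentrations below the LLOQ are flagged
#' `<LLOQ`, and signals beyond the curve range are censored; censored wells
#' never receive a numeric estimate.
#'
#' @param samples data frame of sample wells (`replicate_group`, `signal`).
#' @param fit a converged [fit_curve()] result.
#' @param limits an [compute_lloq()] result (optional; omit for no
#'   LOD/LLOQ censoring).
#' @param dilution multiplicative dilution factor applied to concentrations.
#' @param tissue_norm optional scalar divisor (tissue mass).
#' @return Data frame with one row per replicate group: `sample`,
#'   `mean_signal`, `conc` (NA when censored) and `status` ("ok", "<LOD",
#'   "<LLOQ", "below_range", "above_range").
#' @export
quantify_samples <- function(samples, fit, limits = NULL, dilution = 1,
                             tissue_norm = NULL) {
  stopifnot(inherits(fit, "curve_fit"))
  smp <- if (!is.null(samples$role))
    samples[samples$role == "sample", , drop = FALSE] else samples
  groups <- unique(smp$replicate_group)
  rows <- lapply(groups, function(g) {
    m <- mean(smp$signal[smp$replicate_group == g])
    bi <- back_interpolate(fit, m)
    status <- switch(bi$censor, below = "below_range",
                     above = "above_range", "ok")
    conc <- bi$conc
    if (!is.null(limits)) {
      if (m < limits$lod_threshold_signal) {
        status <- "<LOD"; conc <- NA_real_
      } else if (status == "ok" && !is.na(limits$lloq_conc) &&
                 conc < limits$lloq_conc) {
        status <- "<LLOQ"; conc <- NA_real_
      }
    }
    if (status %in% c("below_range", "above_range")) conc <- NA_real_
    if (!is.na(conc)) {
      conc <- conc * dilution
      if (!is.null(tissue_norm)) conc <- conc / tissue_norm
    }
    data.frame(sample = g, mean_signal = m, conc = conc, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
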