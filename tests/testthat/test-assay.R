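noiseless_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pl <- simulate_plate(plate_spec(noise_cv_pct = 0, seed = 2))
      cache <<- list(wells = pl$wells, fit = fit_curve(pl$wells))
    }
    cache
  }
})

test_that("noiseless twelve-point duplicates recover the true 4PL exactly", {
  nf <- noiseless_fit()
  fit <- nf$fit
  true <- plate_spec()
  expect_true(fit$converged)
  expect_lt(abs(fit$a / true$a - 1), 1e-3)
  expect_lt(abs(fit$b / true$b - 1), 1e-3)
  expect_lt(abs(fit$c / true$c - 1), 1e-3)
  expect_lt(abs(fit$d / true$d - 1), 1e-3)
})

test_that("the curve midpoint back-interpolates to the inflection", {
  fit <- noiseless_fit()$fit
  mid <- (fit$a + fit$d) / 2
  expect_equal(back_interpolate(fit, mid)$conc, fit$c, tolerance = 1e-9)
})

test_that("forward-then-inverse evaluation is the identity on the range", {
  fit <- noiseless_fit()$fit
  xs <- exp(seq(log(2), log(2000), length.out = 40))
  ys <- predict(fit, xs)
  back <- back_interpolate(fit, ys)
  expect_true(all(back$censor == "ok"))
  expect_lt(max(abs(back$conc / xs - 1)), 1e-8)
})

test_that("signals beyond the asymptotes are censored, never extrapolated", {
  fit <- noiseless_fit()$fit
  out <- back_interpolate(fit, c(fit$a - 5, fit$d + 5, fit$d))
  expect_equal(out$censor, c("below", "above", "above"))
  expect_true(all(is.na(out$conc)))
})

test_that("LOD arithmetic: blanks {10,12,14} give threshold signal 17", {
  # sample SD of {10,12,14} is 2, so mean + 2.5 SD = 17
  pl <- simulate_plate(plate_spec(a = 5, noise_cv_pct = 0, seed = 2))
  fit <- fit_curve(pl$wells)
  blanks <- data.frame(signal = c(10, 12, 14))
  lod <- compute_lod(blanks, fit)
  expect_equal(lod$threshold_signal, 17)
  expect_false(lod$censored)
  expect_equal(predict(fit, lod$lod_conc), 17, tolerance = 1e-6)
  # literal reading without the blank-mean term
  lod2 <- compute_lod(blanks, fit, assay_qc_params(lod_add_blank_mean = FALSE))
  expect_equal(lod2$threshold_signal, 5)
  # degenerate: identical blanks collapse the threshold onto their mean
  lod3 <- compute_lod(data.frame(signal = c(20, 20)), fit)
  expect_equal(lod3$threshold_signal, 20)
})

test_that("LLOQ is the lowest standard passing all three clauses", {
  nf <- noiseless_fit()
  wells <- nf$wells
  std <- wells[wells$role == "standard", ]
  blanks <- wells[wells$role == "blank", ]
  concs <- sort(unique(std$nominal_conc))
  # corrupt all but the three highest standards: +30% shifts the mean
  # signal so back-interpolation leaves the 80-120% window
  low <- std$nominal_conc %in% head(concs, length(concs) - 3)
  std$signal[low] <- std$signal[low] * 1.3
  lim <- compute_lloq(std, blanks, nf$fit)
  expect_equal(sum(lim$per_standard$passes), 3)
  expect_equal(lim$lloq_conc, concs[length(concs) - 2])
  expect_true(lim$lod_conc <= lim$lloq_conc)

  # duplicates at 30% CV fail the CV clause everywhere
  std2 <- wells[wells$role == "standard", ]
  flip <- rep(c(1.35, 0.65), length.out = nrow(std2))
  std2$signal <- std2$signal * flip
  lim2 <- compute_lloq(std2, blanks, nf$fit)
  expect_true(all(lim2$per_standard$cv_pct > 20))
  expect_true(is.na(lim2$lloq_conc))
})

test_that("sample quantification censors one way and scales with dilution", {
  nf <- noiseless_fit()
  std <- nf$wells[nf$wells$role == "standard", ]
  blanks <- nf$wells[nf$wells$role == "blank", ]
  lim <- compute_lloq(std, blanks, nf$fit)
  conc8 <- sort(unique(std$nominal_conc))[8]
  samples <- data.frame(
    role = "sample",
    replicate_group = c("hi", "hi", "lo", "lo", "dead", "dead"),
    signal = c(rep(mean(std$signal[std$nominal_conc == conc8]), 2),
               rep(blanks$signal[1] * 0.999, 2),
               rep(predict(nf$fit, conc8), 2)))
  out <- quantify_samples(samples, nf$fit, lim, dilution = 10)
  hi <- out[out$sample == "hi", ]
  expect_equal(hi$status, "ok")
  expect_equal(hi$conc, conc8 * 10, tolerance = 1e-6)
  lo <- out[out$sample == "lo", ]
  expect_equal(lo$status, "<LOD")
  expect_true(is.na(lo$conc))
  # with a tissue normaliser the reported level is conc * dilution / mass
  out2 <- quantify_samples(samples, nf$fit, lim, dilution = 10,
                           tissue_norm = 4)
  expect_equal(out2$conc[out2$sample == "hi"], conc8 * 10 / 4,
               tolerance = 1e-6)
})

test_that("simulated samples at 2% noise are recovered within 5% median error", {
  true_concs <- setNames(exp(runif(8, log(5), log(1500))),
                         paste0("s", 1:8))
  set.seed(31)
  pl <- simulate_plate(plate_spec(noise_cv_pct = 2,
                                  sample_concs = true_concs, seed = 31))
  fit <- fit_curve(pl$wells)
  out <- quantify_samples(pl$wells, fit)
  err <- abs(out$conc[match(names(true_concs), out$sample)] /
               true_concs - 1)
  expect_lt(median(err), 0.05)
})

test_that("LOD does not exceed LLOQ across noisy plates", {
  for (s in 1:10) {
    pl <- simulate_plate(plate_spec(noise_cv_pct = 3, seed = s))
    fit <- fit_curve(pl$wells)
    lim <- compute_lloq(pl$wells[pl$wells$role == "standard", ],
                        pl$wells[pl$wells$role == "blank", ], fit)
    if (!is.na(lim$lloq_conc) && lim$lod_conc > 0)
      expect_lte(lim$lod_conc, lim$lloq_conc)
  }
})

test_that("degenerate standard designs are refused or flagged", {
  pl <- simulate_plate(plate_spec(n_points = 4, noise_cv_pct = 0, seed = 1))
  expect_error(fit_curve(pl$wells), "5 distinct")
  good <- simulate_plate(plate_spec(noise_cv_pct = 0, seed = 1))$wells
  std <- good[good$role == "standard", ]
  # invert the top half of the curve: clearly non-monotone
  hi <- std$nominal_conc > 100
  std$signal[hi] <- max(std$signal) - std$signal[hi] + min(std$signal)
  expect_warning(f <- fit_curve(std), "not monotone")
  expect_false(f$monotone_ok)
})
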