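#!/usr/bin/env Rscript
# Standard-curve calibration on a simulated twelve-point duplicate plate:
# 4PL fit, LOD/LLOQ determination and back-interpolation of unknown
# samples with known true concentrations.

suppressPackageStartupMessages(library(plaquetools))
dir.create("results", showWarnings = FALSE)

true_samples <- c(hom_appps1_12m = 900, hom_appps1_6m = 80,
                  hom_j20_12m = 250, hom_wt = 3, hom_blank_like = 0.5)
spec <- plate_spec(noise_cv_pct = 2, sample_concs = true_samples, seed = 42)
plate <- simulate_plate(spec)
write.csv(plate$wells, "results/plate_wells.csv", row.names = FALSE)

qc <- assay_qc_params(weighting = "1/y^2")
fit <- fit_curve(plate$wells, qc)
print(fit)
write.csv(data.frame(param = c("a", "b", "c", "d"),
                     fitted = c(fit$a, fit$b, fit$c, fit$d),
                     true = c(spec$a, spec$b, spec$c, spec$d)),
          "results/assay_fit.csv", row.names = FALSE)

std <- plate$wells[plate$wells$role == "standard", ]
blanks <- plate$wells[plate$wells$role == "blank", ]
limits <- compute_lloq(std, blanks, fit, qc)
cat(sprintf("LOD %.3g (signal threshold %.1f); LLOQ %.3g\n",
            limits$lod_conc, limits$lod_threshold_signal, limits$lloq_conc))
write.csv(limits$per_standard, "results/assay_limits.csv", row.names = FALSE)

samples <- quantify_samples(plate$wells, fit, limits)
samples$true_conc <- true_samples[samples$sample]
print(samples, row.names = FALSE)
write.csv(samples, "results/assay_samples.csv", row.names = FALSE)
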