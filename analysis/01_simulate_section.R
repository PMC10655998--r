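#!/usr/bin/env Rscript
# Render the canonical validation section: 200 detectable plaques and 50
# rule-violating artifacts on a 4000 x 4000 px slide at 0.5 um/px, plus
# quadrant region annotations. The slide image goes to scratch/ (large,
# regenerable); the ground-truth tables and regions go to results/.

suppressPackageStartupMessages(library(plaquetools))

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

spec <- clean_section_spec(seed = 7)
sim <- simulate_slide(spec, keep_density = FALSE)

write_slide(sim$slide, "scratch/clean_section.tif")

# quadrant regions in 0-based scan-pixel coordinates
w <- spec$width_px - 0.5
quad <- function(name, x0, x1, y0, y1)
  region(name, cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
half <- spec$width_px / 2 - 0.55
regions <- list(quad("q_nw", -0.5, half, -0.5, half),
                quad("q_ne", half, w, -0.5, half),
                quad("q_sw", -0.5, half, half, w),
                quad("q_se", half, w, half, w))
write_regions(regions, "results/clean_section_regions.geojson")

write.csv(sim$truth$plaques, "results/clean_section_truth_plaques.csv",
          row.names = FALSE)
write.csv(sim$truth$artifacts, "results/clean_section_truth_artifacts.csv",
          row.names = FALSE)

cat(sprintf("rendered %d x %d px section: %d plaques (%.0f um^2 planted), %d artifacts\n",
            spec$width_px, spec$height_px,
            nrow(sim$truth$plaques), sum(sim$truth$plaques$area_um2),
            nrow(sim$truth$artifacts)))
cat("slide -> scratch/clean_section.tif; truth + regions -> results/\n")
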