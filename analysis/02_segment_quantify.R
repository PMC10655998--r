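#!/usr/bin/env Rscript
# Segment the rendered section and quantify plaque burden per region and
# for the whole section, then check the result against the planted truth.
# Requires 01_simulate_section.R to have run.

suppressPackageStartupMessages(library(plaquetools))

slide <- read_slide("scratch/clean_section.tif", mpp = 0.5)
regions <- read_regions("results/clean_section_regions.geojson")
truth_plaques <- read.csv("results/clean_section_truth_plaques.csv")
truth_artifacts <- read.csv("results/clean_section_truth_artifacts.csv")

seg <- segment_slide(slide)
cat(sprintf("tissue threshold %.1f; %d candidates -> %d plaques, %d rejected\n",
            seg$tissue$threshold_used, length(seg$candidates),
            length(seg$plaques), length(seg$rejected)))

objects <- object_table(seg)
write.csv(objects, "results/clean_section_objects.csv", row.names = FALSE)

report <- quantify_slide(seg, regions)
write_report(report, "results/clean_section_report.csv")
print(report, row.names = FALSE)

# recovery against ground truth
tot_meas <- sum(objects$area_um2[objects$accepted])
tot_true <- sum(truth_plaques$area_um2)
cat(sprintf("plaque count: %d measured vs %d planted\n",
            sum(objects$accepted), nrow(truth_plaques)))
cat(sprintf("plaque area: %.0f vs %.0f um^2 (%+.2f%%)\n",
            tot_meas, tot_true, 100 * (tot_meas / tot_true - 1)))
rej <- objects[!objects$accepted, ]
near <- vapply(seq_len(nrow(rej)), function(i)
  which.min((truth_artifacts$x_px - rej$centroid_x[i])^2 +
              (truth_artifacts$y_px - rej$centroid_y[i])^2), 0L)
cat(sprintf("artifacts rejected with the intended rule: %d / %d\n",
            sum(rej$flags == truth_artifacts$rule[near]), nrow(rej)))
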