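test_that("slide rendering is a pure function of spec and seed", {
  pl <- data.frame(x_um = 60, y_um = 60, core_radius_um = 3,
                   halo_radius_um = 9, core_brown_au = 0.8,
                   halo_brown_au = 0.4)
  sp <- slide_spec(240, 240, mpp = 0.5, plaques = pl, noise_sd_au = 0.02,
                   seed = 5)
  a <- simulate_slide(sp)
  b <- simulate_slide(sp)
  expect_identical(a$slide$pixels, b$slide$pixels)
  c <- simulate_slide(sp, seed = 6)
  expect_false(identical(a$slide$pixels, c$slide$pixels))
})

test_that("a null section segments to zero candidates", {
  sim <- simulate_slide(null_section_spec(width_px = 400, height_px = 400))
  seg <- segment_slide(sim$slide)
  expect_length(seg$candidates, 0)
  rep <- quantify_section(seg$plaques, seg$classes, seg$tissue_stain)
  expect_equal(rep$plaque_count, 0)
  expect_equal(rep$brown_coverage_pct, 0)
  expect_gt(rep$tissue_area_um2, 0)
})

test_that("a single canonical plaque is detected once at its true size", {
  pl <- data.frame(x_um = 100, y_um = 100, core_radius_um = 5,
                   halo_radius_um = 10, core_brown_au = 0.8,
                   halo_brown_au = 0.3)
  sim <- simulate_slide(slide_spec(400, 400, mpp = 0.5, plaques = pl,
                                   seed = 7))
  seg <- segment_slide(sim$slide)
  expect_length(seg$plaques, 1)
  expect_lt(abs(seg$plaques[[1]]$area_um2 / (pi * 100) - 1), 0.1)
  expect_equal(seg$plaques[[1]]$centroid[["x"]], 199.5, tolerance = 1)
})

test_that("plaques outside the tissue polygon are refused", {
  pl <- data.frame(x_um = 5, y_um = 5, core_radius_um = 2,
                   halo_radius_um = 6, core_brown_au = 0.8,
                   halo_brown_au = 0.4)
  expect_error(simulate_slide(slide_spec(200, 200, mpp = 0.5, plaques = pl)),
               "tissue polygon")
})

test_that("each artifact type is rejected by exactly its designed rule", {
  ar <- data.frame(type = c("speck", "pale_blob", "uniform_blob", "line",
                            "dense_blob"),
                   x_um = c(50, 150, 250, 150, 250),
                   y_um = c(50, 50, 50, 150, 150), angle = "h")
  sim <- simulate_slide(slide_spec(640, 640, mpp = 0.5, artifacts = ar,
                                   seed = 3))
  seg <- segment_slide(sim$slide)
  expect_length(seg$plaques, 0)
  expect_length(seg$rejected, 5)
  tab <- object_table(seg)
  idx <- match_artifacts(tab, sim$truth$artifacts)
  expect_equal(tab$flags, sim$truth$artifacts$rule[idx])
})

test_that("continuous planted densities survive render-side bookkeeping", {
  pl <- data.frame(x_um = 60, y_um = 60, core_radius_um = 3,
                   halo_radius_um = 9, core_brown_au = 0.8,
                   halo_brown_au = 0.4)
  sp <- slide_spec(240, 240, mpp = 0.5, plaques = pl, seed = 5)
  sim <- simulate_slide(sp)
  # interior of the core carries exactly the core density; glass none
  cx <- round(60 / 0.5); cy <- round(60 / 0.5)
  expect_equal(sim$truth$brown_au[cy, cx], 0.8)
  expect_equal(sim$truth$brown_au[5, 5], 0)
  expect_false(sim$truth$tissue[5, 5])
  # fractional footprint: between the inscribed and circumscribed discs
  fp <- sim$truth$plaques$footprint_px
  r_px <- 9 / 0.5
  expect_gt(fp, pi * (r_px - 1)^2)
  expect_lt(fp, pi * (r_px + 1)^2)
})

test_that("plates render on the true curve and keep the duplicate layout", {
  spec <- plate_spec(noise_cv_pct = 0, sample_concs = c(q = 40), seed = 9)
  pl <- simulate_plate(spec)
  std <- pl$wells[pl$wells$role == "standard", ]
  expect_equal(nrow(std), 24)  # twelve points in duplicate
  expect_equal(std$signal,
               four_pl(std$nominal_conc, spec$a, spec$b, spec$c, spec$d))
  expect_true(all(table(std$replicate_group) == 2))
  expect_true(all(tapply(std$nominal_conc, std$replicate_group,
                         function(v) length(unique(v))) == 1))
  blanks <- pl$wells$signal[pl$wells$role == "blank"]
  expect_true(all(blanks == spec$a))
  # noisy render differs from the curve but is seed-stable
  n1 <- simulate_plate(plate_spec(noise_cv_pct = 5, seed = 4))
  n2 <- simulate_plate(plate_spec(noise_cv_pct = 5, seed = 4))
  expect_identical(n1$wells$signal, n2$wells$signal)
})

test_that("group generation hits the requested medians", {
  g0 <- simulate_groups(c(a = 10, b = 1000), spread = 0, n = 5, seed = 2)
  expect_equal(unclass(g0), list(a = rep(10, 5), b = rep(1000, 5)),
               ignore_attr = TRUE)
  big <- simulate_groups(c(a = 50), spread = 0.6, n = 1e4, seed = 3)
  expect_lt(abs(median(big$a) / 50 - 1), 0.02)
  norm <- simulate_groups(c(a = -2), spread = 1, n = 1e4,
                          family = "normal", seed = 3)
  expect_lt(abs(median(norm$a) - (-2)), 0.05)
})

test_that("ten-fold separated medians are reliably detected", {
  hits <- 0
  for (s in 1:60) {
    g <- simulate_groups(c(lo = 20, hi = 200), spread = 0.5, n = 8,
                         seed = 1000 + s)
    kd <- kruskal_dunn(g, list(c("lo", "hi")))
    if (kd$pairwise$p_adjusted < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)
})
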