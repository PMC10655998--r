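# small synthetic section shared across quantification tests
local_section <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(17)
      xs <- rep(seq(60, 340, by = 70), times = 5)
      ys <- rep(seq(60, 340, by = 70), each = 5)
      keep <- sample(length(xs), 12)
      pl <- data.frame(x_um = xs[keep], y_um = ys[keep],
                       core_radius_um = 2.5,
                       halo_radius_um = runif(12, 7, 11),
                       core_brown_au = 0.8, halo_brown_au = 0.4)
      sp <- slide_spec(800, 800, mpp = 0.5, plaques = pl, seed = 9)
      sim <- simulate_slide(sp)
      cache <<- list(sim = sim, seg = segment_slide(sim$slide))
    }
    cache
  }
})

test_that("planted plaques are counted once with area near ground truth", {
  cs <- local_section()
  seg <- cs$seg
  expect_length(seg$plaques, nrow(cs$sim$truth$plaques))
  tot <- sum(vapply(seg$plaques, function(p) p$area_um2, 0))
  expect_lt(abs(tot / sum(cs$sim$truth$plaques$area_um2) - 1), 0.02)
})

test_that("a region with no plaques reports zero everywhere that matters", {
  cs <- local_section()
  # 10x10 um corner of glass: inside raster, no tissue, no plaques
  r <- region("corner", cbind(x = c(1, 18, 18, 1), y = c(1, 1, 18, 18)))
  rep <- quantify_region(cs$seg$plaques, cs$seg$classes,
                         cs$seg$tissue_stain, r)
  expect_equal(rep$plaque_count, 0)
  expect_equal(rep$plaque_coverage_pct, 0)
  expect_equal(rep$brown_coverage_pct, 0)
})

test_that("section totals equal sums over an exhaustive region partition", {
  cs <- local_section()
  seg <- cs$seg
  w <- 800 - 0.5  # full raster in 0-based pixel coordinates
  quad <- function(name, x0, x1, y0, y1)
    region(name, cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)))
  # half-open split: shared edges belong to the left/top region only if a
  # centroid lies exactly on them, which the jittered layout avoids
  regs <- list(quad("q1", -0.5, 399.8, -0.5, 399.8),
               quad("q2", 399.8, w, -0.5, 399.8),
               quad("q3", -0.5, 399.8, 399.8, w),
               quad("q4", 399.8, w, 399.8, w))
  per <- lapply(regs, function(r)
    quantify_region(seg$plaques, seg$classes, seg$tissue_stain, r))
  per <- do.call(rbind, per)
  whole <- quantify_section(seg$plaques, seg$classes, seg$tissue_stain)
  expect_equal(sum(per$plaque_count), whole$plaque_count)
  expect_equal(sum(per$plaque_area_um2), whole$plaque_area_um2,
               tolerance = 1e-9)
  expect_equal(sum(per$tissue_area_um2), whole$tissue_area_um2,
               tolerance = 1e-9)
})

test_that("a centroid on the polygon boundary is counted as inside", {
  cls <- structure(list(labels = matrix(0L, 20, 20), mpp = 1,
                        downsample = 1), class = "brown_class_mask")
  tissue <- matrix(TRUE, 20, 20)
  pl <- make_candidate(50, 10, 0.4, 0.3, 0.9)
  pl$centroid <- c(x = 10, y = 5)   # exactly on the region's left edge
  r <- region("edge", cbind(x = c(10, 15, 15, 10), y = c(0, 0, 10, 10)))
  rep <- quantify_region(list(pl), cls, tissue, r)
  expect_equal(rep$plaque_count, 1)
  expect_equal(rep$plaque_area_um2, 50)
})

test_that("a region fully outside the raster raises an error", {
  cls <- structure(list(labels = matrix(0L, 10, 10), mpp = 1,
                        downsample = 1), class = "brown_class_mask")
  r <- region("far", cbind(x = c(100, 110, 110, 100), y = c(100, 100, 110, 110)))
  expect_error(quantify_region(list(), cls, matrix(TRUE, 10, 10), r),
               "outside the raster")
})

test_that("coverage percentages are invariant to a matched rescale", {
  pl <- data.frame(x_um = c(60, 130), y_um = c(70, 120),
                   core_radius_um = 2.5, halo_radius_um = 8,
                   core_brown_au = 0.8, halo_brown_au = 0.4)
  sp1 <- slide_spec(400, 400, mpp = 0.5, plaques = pl, seed = 4)
  pl2 <- pl
  pl2[c("x_um", "y_um", "core_radius_um", "halo_radius_um")] <-
    pl[c("x_um", "y_um", "core_radius_um", "halo_radius_um")] * 2
  sp2 <- slide_spec(400, 400, mpp = 1.0, plaques = pl2,
                    tissue_polygon = sp1$tissue_polygon * 2, seed = 4)
  s1 <- segment_slide(simulate_slide(sp1)$slide)
  s2 <- segment_slide(simulate_slide(sp2)$slide)
  r1 <- quantify_section(s1$plaques, s1$classes, s1$tissue_stain)
  r2 <- quantify_section(s2$plaques, s2$classes, s2$tissue_stain)
  # identical pixel content at twice the calibration: percentages equal,
  # areas scale by 4
  expect_equal(r1$plaque_coverage_pct, r2$plaque_coverage_pct,
               tolerance = 1e-9)
  expect_equal(r1$brown_coverage_pct, r2$brown_coverage_pct,
               tolerance = 1e-9)
  expect_equal(4 * r1$plaque_area_um2, r2$plaque_area_um2, tolerance = 1e-9)
})
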