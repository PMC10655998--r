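test_that("min-channel brightness equals the elementwise minimum", {
  set.seed(11)
  px <- array(sample(0:255, 20 * 15 * 3, replace = TRUE), c(20, 15, 3))
  got <- min_channel_brightness(px)
  expect_identical(got, pmin(px[, , 1], pmin(px[, , 2], px[, , 3])))
  achro <- array(rep(matrix(7L, 4, 4), 3), c(4, 4, 3))
  expect_true(all(min_channel_brightness(achro) == 7L))
  expect_equal(min_channel_brightness(array(c(200, 150, 250), c(1, 1, 3)))[1],
               150)
})

test_that("tissue threshold is the 95th centile minus 10", {
  uniform <- matrix(250, 20, 20)
  t1 <- detect_tissue(uniform)
  expect_equal(t1$threshold_used, 240)
  expect_false(any(t1$mask))

  bimodal <- matrix(250, 20, 20)
  dark <- sample(400, 40)  # exactly 10% of pixels
  bimodal[dark] <- 100
  t2 <- detect_tissue(bimodal)
  expect_equal(t2$threshold_used, 240)
  expect_equal(sort(which(t2$mask)), sort(dark))
})

test_that("brown classification honours the printed threshold boundaries", {
  vals <- rbind(c(0.20, 0.15),   # light
                c(0.60, 0.30),   # dark
                c(0.50, 0.30),   # exactly 0.5: dark (inclusive)
                c(0.20, 0.05),   # Brown+ve too low: none
                c(0.15, 0.14),   # exactly 0.15: none (strict)
                c(0.20, 0.10))   # Brown+ve exactly 0.1: none (strict)
  brown <- matrix(vals[, 1], nrow = 1)
  blue <- matrix(vals[, 1] - vals[, 2], nrow = 1)
  cls <- classify_brown(stain_maps(brown, blue))
  expect_equal(as.vector(cls$labels), c(1L, 2L, 2L, 0L, 0L, 0L))
})

test_that("tissue masking forces non-tissue pixels to class none", {
  brown <- matrix(0.6, 2, 2)
  blue <- matrix(0.1, 2, 2)
  tissue <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  cls <- classify_brown(stain_maps(brown, blue), tissue = tissue)
  expect_equal(cls$labels == 0L, !tissue)
})

test_that("dark seeds grow through connected light areas and merge", {
  lab <- matrix(0L, 9, 9)
  lab[4:6, 4:6] <- 1L          # light ring ...
  lab[5, 5] <- 2L              # ... around one dark pixel
  cls <- structure(list(labels = lab, mpp = 1, downsample = 1),
                   class = "brown_class_mask")
  maps <- stain_maps(matrix(0.3, 9, 9), matrix(0, 9, 9))
  cands <- grow_candidates(cls, maps)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$n_px, 9L)
  expect_equal(cands[[1]]$dark_area_um2, 1)

  # isolated dark blob without light: candidate equals the blob
  lab2 <- matrix(0L, 9, 9); lab2[2:3, 2:3] <- 2L
  cls2 <- structure(list(labels = lab2, mpp = 1, downsample = 1),
                    class = "brown_class_mask")
  c2 <- grow_candidates(cls2, maps)
  expect_length(c2, 1)
  expect_equal(c2[[1]]$n_px, 4L)

  # two dark blobs bridged by one light path merge into one candidate;
  # an unattached light blob is discarded
  lab3 <- matrix(0L, 9, 9)
  lab3[5, 2] <- 2L; lab3[5, 8] <- 2L; lab3[5, 3:7] <- 1L
  lab3[1, 1] <- 1L
  cls3 <- structure(list(labels = lab3, mpp = 1, downsample = 1),
                    class = "brown_class_mask")
  c3 <- grow_candidates(cls3, maps)
  expect_length(c3, 1)
  expect_equal(c3[[1]]$n_px, 7L)
})

test_that("region growing matches a graph-based oracle on random masks", {
  set.seed(23)
  for (conn in c(8L, 4L)) {
    for (rep in 1:5) {
      dark <- matrix(runif(20 * 20) < 0.08, 20, 20)
      light <- matrix(runif(20 * 20) < 0.25, 20, 20) & !dark
      cls <- structure(list(labels = matrix(0L, 20, 20), mpp = 1,
                            downsample = 1), class = "brown_class_mask")
      cls$labels[light] <- 1L
      cls$labels[dark] <- 2L
      maps <- stain_maps(matrix(0.3, 20, 20), matrix(0, 20, 20))
      p <- segmentation_params(connectivity = conn)
      cands <- grow_candidates(cls, maps, p)
      got <- lapply(cands, function(cd)
        sort((cd$pixels[, "col"] - 1L) * 20L + cd$pixels[, "row"]))
      want <- oracle_grow(dark, light, conn)
      key <- function(l) paste(vapply(l, paste, "", collapse = ","))
      expect_setequal(key(got), key(want))
    }
  }
})

test_that("elliptic fit scores disks high, lines zero, single pixels one", {
  disk <- which(outer((-12:12)^2, (-12:12)^2, "+") <= 100, arr.ind = TRUE)
  expect_gte(elliptic_fit(disk), 0.9)
  line <- cbind(row = rep(1L, 40), col = 1:40)
  expect_lt(elliptic_fit(line), 0.65)
  expect_equal(elliptic_fit(cbind(row = 3L, col = 5L)), 1)
  square <- as.matrix(expand.grid(row = 1:9, col = 1:9))
  expect_gte(elliptic_fit(square), 0.65)  # compact shapes pass the rule
})

test_that("the five removal rules fire exactly as printed", {
  p <- segmentation_params()
  cases <- list(
    list(make_candidate(9, 5, 0.4, 0.3, 0.9), "min_area"),
    list(make_candidate(25, 1.0, 0.4, 0.3, 0.9), "min_dark_area"),
    list(make_candidate(30, 10, 0.6, 0.10, 0.9), "uniform_dark"),
    list(make_candidate(30, 10, 0.4, 0.3, 0.5), "non_elliptical"),
    list(make_candidate(50, 40, 0.4, 0.3, 0.9), "dark_fraction"))
  for (cs in cases) {
    out <- filter_candidates(list(cs[[1]]), p)
    expect_length(out$plaques, 0)
    expect_equal(out$rejected[[1]]$removal_flags, cs[[2]])
  }
  ok <- make_candidate(60, 20, 0.4, 0.3, 0.9)
  out <- filter_candidates(list(ok), p)
  expect_length(out$plaques, 1)
  expect_length(out$plaques[[1]]$removal_flags, 0)
})

test_that("randomized candidates match the rule-by-rule oracle exactly", {
  set.seed(99)
  p <- segmentation_params()
  n <- 1000
  cands <- lapply(seq_len(n), function(i) {
    area <- runif(1, 1, 120)
    make_candidate(area, runif(1, 0, area), runif(1, 0.1, 1.2),
                   runif(1, 0, 0.6), runif(1, 0, 1), id = i)
  })
  out <- filter_candidates(cands, p)
  got <- character(n)
  for (o in c(out$plaques, out$rejected))
    got[o$id] <- paste(sort(o$removal_flags), collapse = ";")
  want <- vapply(cands, function(cd)
    paste(sort(oracle_removal_flags(cd$area_um2, cd$dark_area_um2,
                                    cd$mean_brown_au, cd$sd_brown_au,
                                    cd$elliptic_fit, p)), collapse = ";"),
    "")
  expect_identical(got, want)
})

test_that("boundary-valued objects fall on the printed side of each rule", {
  p <- segmentation_params()
  for (bc in boundary_case_candidates()) {
    out <- filter_candidates(list(bc), p)
    got <- if (length(out$rejected)) out$rejected[[1]]$removal_flags
      else character(0)
    expect_equal(sort(got), sort(bc$expect_flags),
                 info = sprintf("area=%g dark=%g", bc$area_um2,
                                bc$dark_area_um2))
  }
})

test_that("filtering accepted plaques again removes nothing", {
  set.seed(5)
  cands <- lapply(1:200, function(i) {
    area <- runif(1, 1, 120)
    make_candidate(area, runif(1, 0, area), runif(1, 0.1, 1.2),
                   runif(1, 0, 0.6), runif(1, 0, 1), id = i)
  })
  p <- segmentation_params()
  once <- filter_candidates(cands, p)
  twice <- filter_candidates(once$plaques, p)
  expect_length(twice$rejected, 0)
  expect_length(twice$plaques, length(once$plaques))
})

test_that("candidates partition the non-background pixels without overlap", {
  set.seed(31)
  dark <- matrix(runif(30 * 30) < 0.1, 30, 30)
  light <- matrix(runif(30 * 30) < 0.3, 30, 30) & !dark
  cls <- structure(list(labels = matrix(0L, 30, 30), mpp = 1,
                        downsample = 1), class = "brown_class_mask")
  cls$labels[light] <- 1L
  cls$labels[dark] <- 2L
  maps <- stain_maps(matrix(0.3, 30, 30), matrix(0, 30, 30))
  cands <- grow_candidates(cls, maps)
  all_px <- do.call(rbind, lapply(cands, function(cd) cd$pixels))
  keys <- (all_px[, "col"] - 1L) * 30L + all_px[, "row"]
  expect_false(any(duplicated(keys)))               # no overlap
  expect_true(all(cls$labels[cbind(all_px)] > 0L))  # subset of non-none
  # every dark pixel is claimed by exactly one candidate
  expect_equal(sum(cls$labels[cbind(all_px)] == 2L), sum(dark))
})
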