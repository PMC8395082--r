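square_roi <- function(lo, hi) {
  roi_polygon(cbind(x = c(lo, hi, hi, lo), y = c(lo, lo, hi, hi)))
}

test_that("ROI polygons validate vertex count and self-intersection", {
  expect_error(roi_polygon(cbind(0:1, 0:1)), ">= 3 vertices")
  bowtie <- cbind(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  expect_error(roi_polygon(bowtie), "self-intersecting")
  r <- square_roi(-0.5, 9.5)
  expect_s3_class(r, "roi_polygon")
  # explicit closing vertex is tolerated
  r2 <- roi_polygon(cbind(x = c(0, 5, 5, 0, 0), y = c(0, 0, 5, 5, 0)))
  expect_equal(nrow(r2$vertices), 4)
})

test_that("ROI CSV round trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(-0.5, 19.5, 19.5, -0.5),
                       y = c(-0.5, -0.5, 19.5, 19.5)), f,
            row.names = FALSE)
  r <- read_roi_csv(f)
  expect_equal(r$vertices[, "x"], c(-0.5, 19.5, 19.5, -0.5))
})

test_that("per-dot quantification normalizes total intensity by dot count", {
  obj <- data.frame(total_intensity = rep(100, 4))
  q <- quantify_dots(obj)
  expect_equal(q$n_dots, 4)
  expect_equal(q$intensity_per_dot, 100)
  expect_equal(quantify_dots(
    data.frame(total_intensity = c(50, 150)))$intensity_per_dot, 100)
  q0 <- quantify_dots(obj[0, , drop = FALSE])
  expect_equal(q0$n_dots, 0)
  expect_true(is.na(q0$intensity_per_dot))
})

test_that("per-dot intensity recovers a planted 2:1 amplitude ratio", {
  det_one <- function(amp, seed) {
    sim <- simulate_movie(simulation_config(
      image_size = 128, n_frames = 1, n_spots = 10, n_pairs = 0,
      amplitude = amp, min_separation_px = 14, seed = seed))
    img <- get_frame(sim$movie, "A", 1)
    pp <- subtract_background(
      gaussian_blur(img, 0.1, 0.125), 10)
    obj <- filter_circularity(
      measure_objects(segment_dots(pp, 25), pp, 0.125), 0.1)
    quantify_dots(obj)$intensity_per_dot
  }
  # threshold segmentation clips dim tails more than bright ones, so
  # the recovered ratio sits slightly above the planted 2.0
  ratio <- det_one(300, 41) / det_one(150, 42)
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.4)
})

test_that("PM band of a square outline has the closed-form eroded area", {
  # 40 x 40 px cell, band 12 px: interior (40-24)^2 survives
  roi <- square_roi(-0.5, 39.5)
  img <- matrix(0, 40, 40)
  img[13:28, 13:28] <- 1  # the 16x16 interior beyond the band
  ps <- 0.125
  v <- quantify_pm_band(img, roi, band_um = 12 * ps, pixel_size = ps)
  expect_equal(v, 0)  # interior signal excluded from the band
  ones <- matrix(1, 40, 40)
  v1 <- quantify_pm_band(ones, roi, band_um = 12 * ps, pixel_size = ps)
  # uniform image: per-area value is 1/ps^2 regardless of band size
  expect_equal(v1, 1 / ps^2)
  # band area itself: total intensity / value = area -> 1344 px^2
  expect_equal(sum(ones) * 0 + (40^2 - 16^2) * ps^2,
               sum(ones[dtctrack:::dist_to_polygon_boundary(
                 rep(0:39, each = 40), rep(0:39, 40), roi) <= 12]) * ps^2)
})

test_that("a bright rim dominates the band read-out as the band narrows", {
  ps <- 0.125
  roi <- square_roi(-0.5, 29.5)
  img <- matrix(10, 30, 30)
  img[c(1, 30), ] <- 200; img[, c(1, 30)] <- 200  # 1-px bright rim
  wide <- quantify_pm_band(img, roi, band_um = 10 * ps, pixel_size = ps)
  narrow <- quantify_pm_band(img, roi, band_um = 1 * ps, pixel_size = ps)
  expect_gt(narrow, wide)
  expect_lt(wide, 200 / ps^2)
  expect_gt(narrow, 0.9 * 200 / ps^2)
})

test_that("band wider than the inradius degrades to the whole ROI with a warning", {
  ps <- 0.125
  roi <- square_roi(-0.5, 19.5)
  set.seed(51)
  img <- matrix(runif(400, 0, 50), 20, 20)
  expect_warning(v <- quantify_pm_band(img, roi, band_um = 30 * ps,
                                       pixel_size = ps), "inradius")
  expect_equal(v, quantify_roi_per_area(img, roi, ps))
})

test_that("ROI per-area intensity is intensive", {
  ps <- 0.2
  img <- matrix(3, 30, 30)
  small <- square_roi(4.5, 14.5)
  large <- square_roi(0.5, 28.5)
  expect_equal(quantify_roi_per_area(img, small, ps), 3 / ps^2)
  expect_equal(quantify_roi_per_area(img, large, ps), 3 / ps^2)
  degenerate <- roi_polygon(cbind(x = c(100, 101, 101), y = c(100, 100, 101)))
  expect_error(quantify_roi_per_area(img, degenerate, ps), "zero-area")
})
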