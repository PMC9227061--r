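test_that("slide calibration recovers the pixel size", {
  set.seed(1)
  sl <- gen_calibration_slide(spacing_px = 20, division_um = 10)
  cal <- calibrate(sl$image, sl$division_um)
  expect_equal(cal$um_per_px, 0.5, tolerance = 0.02)

  sl2 <- gen_calibration_slide(spacing_px = 10, division_um = 10)
  expect_equal(calibrate(sl2$image, 10)$um_per_px, 1, tolerance = 0.02)

  # a 5 degree slide rotation is absorbed by the projection angle search
  sl3 <- gen_calibration_slide(spacing_px = 20, division_um = 10,
                               angle_deg = 5)
  expect_equal(calibrate(sl3$image, 10)$um_per_px, 0.5, tolerance = 0.02)

  # featureless image: no graduations to calibrate on
  set.seed(2)
  blank <- matrix(200 + rnorm(100 * 100), 100, 100)
  expect_error(calibrate(blank, 10), "calibration error")
})

test_that("calibrations rescale by the vertical resolution ratio", {
  cal <- calibration(0.5, image_size = c(1920, 1080))
  expect_equal(rescale_calibration(cal, c(1280, 720))$um_per_px, 0.75)
  expect_equal(rescale_calibration(cal, c(1920, 1080))$um_per_px, 0.5)
  expect_equal(rescale_calibration(calibration(1, c(1920, 1080)),
                                   c(960, 540))$um_per_px, 2)
})

test_that("segmentation binarizes dark cells and closes gaps", {
  # uniform bright image: nothing below threshold
  bright <- matrix(220, 64, 64)
  expect_equal(sum(segment(bright, segmentation_params(gray_threshold = 100))),
               0)

  # one dark disk becomes one component containing the disk
  img <- matrix(220, 64, 64)
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, `+`))
  img[d <= 10] <- 40
  mask <- segment(img, segmentation_params(gray_threshold = 128))
  expect_true(all(mask[d <= 9] == 1))
  expect_equal(max(EBImage::bwlabel(mask)), 1)

  # two disks 2 px apart fuse under two closing passes with a 5 px brush
  img2 <- matrix(220, 64, 64)
  d1 <- sqrt(outer((1:64 - 32)^2, (1:64 - 20)^2, `+`))
  d2 <- sqrt(outer((1:64 - 32)^2, (1:64 - 42)^2, `+`))
  img2[d1 <= 10 | d2 <= 10] <- 40
  p2 <- segmentation_params(gray_threshold = 128, erosion_iterations = 2,
                            erosion_kernel = 5)
  expect_equal(max(EBImage::bwlabel(segment(img2, p2))), 1)
  # without closing they stay separate
  p0 <- segmentation_params(gray_threshold = 128, erosion_iterations = 0)
  expect_equal(max(EBImage::bwlabel(segment(img2, p0))), 2)
})

test_that("detect_cells filters by area and measures boxes in um", {
  mask <- matrix(0L, 80, 120)
  centers <- list(c(20, 20), c(40, 60), c(60, 100))
  for (ct in centers) {
    d <- sqrt(outer((1:80 - ct[1])^2, (1:120 - ct[2])^2, `+`))
    mask[d <= 8] <- 1L  # area ~ 200 px^2
  }
  cal <- calibration(0.5, image_size = c(120, 80))
  det <- detect_cells(mask, cal, min_area = 50)
  expect_equal(nrow(det$records), 3)
  expect_equal(attr(det$annotated, "n_cells"), 3)
  expect_equal(det$records$width_um, rep(17 * 0.5, 3))  # 2r+1 px boxes
  expect_equal(det$records$centroid_x_px, c(20, 60, 100), tolerance = 1e-6)
  expect_equal(nrow(detect_cells(mask, cal, min_area = 300)$records), 0)
})

test_that("detection count and sizes match simulator ground truth", {
  set.seed(3)
  mg <- gen_micrograph(n_cells = 25)
  res <- analyze_image(mg$image, mg$cal)
  expect_equal(res$n_cells, 25)
  # match detections to truth by nearest centroid
  truth <- mg$truth
  for (i in seq_len(nrow(res$records))) {
    j <- which.min((truth$x_px - res$records$centroid_x_px[i])^2 +
                     (truth$y_px - res$records$centroid_y_px[i])^2)
    expect_lt(abs(res$records$width_um[i] - truth$diameter_um[j]),
              1 * mg$cal$um_per_px + 1e-9)
    expect_lt(abs(res$records$height_um[i] - truth$diameter_um[j]),
              1 * mg$cal$um_per_px + 1e-9)
  }
  # determinism: same image, same records
  expect_identical(res$records, analyze_image(mg$image, mg$cal)$records)
})

test_that("raising min_area never increases the detection count", {
  set.seed(4)
  mg <- gen_micrograph(n_cells = 15)
  mask <- segment(mg$image)
  counts <- vapply(c(0, 20, 50, 150, 400, 1200), function(a)
    nrow(detect_cells(mask, mg$cal, min_area = a)$records), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("measurement CSV round-trips", {
  set.seed(5)
  mg <- gen_micrograph(n_cells = 6)
  res <- analyze_image(mg$image, mg$cal)
  f <- withr::local_tempfile(fileext = ".csv")
  export_measurements(res$records, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 6)
  expect_equal(back$width_um, res$records$width_um)
  expect_equal(back$id, res$records$id)

  # empty records give a header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_measurements(res$records[0, ], f2)
  expect_length(readLines(f2), 1)
  expect_match(readLines(f2)[1], "id.*width_um")
})
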