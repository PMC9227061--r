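test_that("well addressing matches the two-plate holder convention", {
  lay <- plate_layout()  # two 12-well plates
  fmt <- lay$format

  # origin well sits at the A1 offset
  p00 <- well_to_stage(lay, c(0, 0))
  expect_equal(c(p00$x_mm, p00$y_mm), c(fmt$a1_offset_x, fmt$a1_offset_y))

  # (2,3) is the bottom-right well of plate 1: max column/row of plate 1
  p23 <- well_to_stage(lay, c(2, 3))
  expect_equal(p23$x_mm, fmt$a1_offset_x + 2 * fmt$well_pitch)
  expect_equal(p23$y_mm, fmt$a1_offset_y + 3 * fmt$well_pitch)

  # (3,0) is the top-left well of plate 2: shifted by plate width + gap
  p30 <- well_to_stage(lay, c(3, 0))
  expect_equal(p30$x_mm,
               fmt$a1_offset_x + fmt$plate_width + lay$plate_gap)
  expect_equal(p30$y_mm, fmt$a1_offset_y)
  expect_gt(p30$x_mm, p23$x_mm)
})

test_that("pitch arithmetic gives the expected well-to-well deltas", {
  fmt <- plate_format(12, well_pitch = 26, well_diameter = 22)
  lay <- plate_layout(format = fmt)
  d <- well_to_stage(lay, c(1, 2))
  o <- well_to_stage(lay, c(0, 0))
  expect_equal(c(d$x_mm - o$x_mm, d$y_mm - o$y_mm), c(26, 52))
})

test_that("enumerate_wells covers both plates in row-major order", {
  expect_equal(nrow(enumerate_wells(plate_layout())), 24)
  expect_equal(nrow(enumerate_wells(
    plate_layout(plate_format(96), n_plates = 1))), 96)

  lay24 <- plate_layout(plate_format(24))
  w <- enumerate_wells(lay24)
  expect_equal(nrow(w), 48)
  expect_equal(unlist(w[1, ]), c(x = 0, y = 0))
  expect_equal(unlist(w[nrow(w), ]),
               c(x = 2 * lay24$format$n_cols - 1,
                 y = lay24$format$n_rows - 1))
  # row-major: x varies fastest within a plate
  expect_equal(w$x[1:3], c(0, 1, 2))
  expect_equal(w$y[1:3], c(0, 0, 0))
})

test_that("well mapping is injective with nearest-centre round trip", {
  for (wells in c(12, 24, 96)) {
    lay <- plate_layout(plate_format(wells), n_plates = 2)
    pos <- well_to_stage(lay, enumerate_wells(lay))
    dmat <- as.matrix(dist(pos[, c("x_mm", "y_mm")]))
    # nearest centre to each well's own coordinate is itself ...
    expect_equal(unname(apply(dmat, 1, which.min)), seq_len(nrow(pos)))
    # ... and the closest other well centre is exactly one pitch away
    diag(dmat) <- Inf
    expect_equal(min(dmat), lay$format$well_pitch, tolerance = 1e-9)
  }
})

test_that("global offsets shift every well by exactly that offset", {
  set.seed(101)
  base <- plate_layout()
  for (i in 1:5) {
    off <- runif(2, -5, 15)
    shifted <- plate_layout(global_offset_x = off[1],
                            global_offset_y = off[2])
    a <- well_to_stage(base, enumerate_wells(base))
    b <- well_to_stage(shifted, enumerate_wells(shifted))
    expect_equal(b$x_mm, a$x_mm + off[1])
    expect_equal(b$y_mm, a$y_mm + off[2])
  }
})

test_that("out-of-range addresses raise errors naming the axis", {
  lay <- plate_layout()
  expect_error(well_to_stage(lay, c(6, 0)), "x axis")
  expect_error(well_to_stage(lay, c(0, 4)), "y axis")
  expect_error(well_to_stage(lay, c(-1, 0)), "x axis")
})

test_that("custom positions generated from the formula agree with it", {
  lay <- plate_layout()
  wells <- enumerate_wells(lay)
  pos <- well_to_stage(lay, wells)
  custom <- data.frame(x = pos$x, y = pos$y, x_mm = pos$x_mm,
                       y_mm = pos$y_mm)
  lay2 <- plate_layout(custom_positions = custom)
  pos2 <- well_to_stage(lay2, wells)
  expect_equal(pos2$x_mm, pos$x_mm)
  expect_equal(pos2$y_mm, pos$y_mm)

  # incomplete table is rejected
  expect_error(plate_layout(custom_positions = custom[-1, ]),
               "cover every addressable well")
})

test_that("layout JSON files round-trip", {
  lay <- plate_layout(plate_format(24), global_offset_x = 2.5,
                      plate_gap = 12)
  f <- withr::local_tempfile(fileext = ".json")
  write_plate_layout(lay, f)
  lay2 <- read_plate_layout(f)
  w <- enumerate_wells(lay)
  expect_equal(well_to_stage(lay2, w), well_to_stage(lay, w))

  # custom-position files work too
  pos <- well_to_stage(lay, w)
  lay3 <- plate_layout(plate_format(24),
                       custom_positions = data.frame(
                         x = pos$x, y = pos$y, x_mm = pos$x_mm,
                         y_mm = pos$y_mm))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_plate_layout(lay3, f2)
  expect_equal(well_to_stage(read_plate_layout(f2), w)$x_mm, pos$x_mm)
})

test_that("tip positions are the camera position plus the tool offset", {
  lay <- plate_layout()
  w <- enumerate_wells(lay)
  expect_equal(tip_position_for_well(lay, w, c(0, 0)),
               well_to_stage(lay, w))
  t1 <- tip_position_for_well(lay, c(0, 0), c(30, 0))
  c1 <- well_to_stage(lay, c(0, 0))
  expect_equal(t1$x_mm, c1$x_mm + 30)
  # offsets pushing the stage outside the bed are range errors
  expect_error(tip_position_for_well(lay, c(0, 0), c(-30, 0)),
               "working surface")
  expect_error(tip_position_for_well(lay, c(5, 0), c(210, 0)),
               "working surface")
})
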