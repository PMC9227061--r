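test_that("static scenes track at (near) zero speed", {
  set.seed(1)
  v <- gen_motility_video(n_cells = 4, speed_um_s = 0, duration = 0.5)
  tr <- track_cell(v$frames, c(v$truth$x_px[1], v$truth$y_px[1]), v$cal)
  expect_false(tr$terminated_early)
  expect_lt(tr$mean_speed_um_s, 1)
})

test_that("a 1 px/frame cell reads 15 um/s at 30 fps and 0.5 um/px", {
  set.seed(2)
  v <- gen_motility_video(n_cells = 1, speed_um_s = 15, duration = 1)
  tr <- track_cell(v$frames, c(v$truth$x_px[1], v$truth$y_px[1]), v$cal,
                   fps = 30)
  expect_equal(tr$mean_speed_um_s, 15, tolerance = 0.05)
})

test_that("tracked speed is within 10% of truth from 5 to 100 um/s", {
  set.seed(3)
  for (sp in c(5, 20, 50, 100)) {
    v <- gen_motility_video(n_cells = 3, speed_um_s = sp, duration = 0.5)
    tr <- track_cell(v$frames, c(v$truth$x_px[1], v$truth$y_px[1]),
                     v$cal, fps = 30)
    expect_gt(tr$n_frames_tracked, 3)
    expect_lt(abs(tr$mean_speed_um_s - v$truth$speed_um_s[1]),
              0.1 * v$truth$speed_um_s[1])
  }
})

test_that("a circular trajectory is recovered to within 10% path length", {
  set.seed(4)
  rnd <- render_model(image_size = c(160, 160), pixel_size = 0.5,
                      noise_sd = 1)
  mk_cell <- function(x, y) data.frame(
    x_um = x, y_um = y, z_um = 2950, radius_um = 5,
    vx_um_s = 0, vy_um_s = 0, r = 60, g = 120, b = 50)
  radius_um <- 20; fps <- 30; n <- 40
  th <- 2 * pi * (0:(n - 1)) / n  # one full revolution
  frames <- lapply(th, function(a)
    render_frame(scene(mk_cell(40 + radius_um * cos(a),
                               40 + radius_um * sin(a)),
                       fov_um = c(80, 80), photoresponse = NULL),
                 rnd))
  seed_pt <- c((40 + radius_um) / 0.5 + 0.5, 40 / 0.5 + 0.5)
  tr <- track_cell(frames, seed_pt, calibration(0.5), fps = fps)
  expect_false(tr$terminated_early)
  steps <- sqrt(diff(tr$points$x_px)^2 + diff(tr$points$y_px)^2) * 0.5
  true_len <- 2 * pi * radius_um * (n - 1) / n
  expect_equal(sum(steps), true_len, tolerance = 0.1)
})

test_that("a featureless seed fails the flow immediately", {
  flat <- replicate(3, matrix(150, 96, 96), simplify = FALSE)
  tr <- track_cell(flat, c(48, 48), calibration(0.5))
  expect_true(tr$terminated_early)
  expect_equal(tr$n_frames_tracked, 1)
})

test_that("dense flow recovers global translation and stillness", {
  set.seed(5)
  base <- matrix(runif(128 * 128, 0, 255), 128, 128)
  base <- platescope:::smooth121(platescope:::smooth121(base))
  still <- flow_field(list(base, base), calibration(0.5), fps = 30)
  f0 <- still$fields[[1]]
  expect_lt(mean(sqrt(f0$u^2 + f0$v^2)[f0$ok]), 0.02)

  shifted <- matrix(0, 128, 128)
  shifted[, 3:128] <- base[, 1:126]; shifted[, 1:2] <- base[, 1:2]
  ff <- flow_field(list(base, shifted), calibration(0.5), fps = 30)
  f <- ff$fields[[1]]
  expect_equal(mean(sqrt(f$u^2 + f$v^2)[f$ok]), 2, tolerance = 0.1)
  expect_equal(ff$dominant_direction, 0, tolerance = 0.1)
})

test_that("reported speeds scale with calibration but not frame rate", {
  set.seed(6)
  v30 <- gen_motility_video(n_cells = 4, speed_um_s = 20, duration = 0.5,
                            fps = 30)
  ff1 <- flow_field(v30$frames, v30$cal, fps = 30)
  ff2 <- flow_field(v30$frames, calibration(1.0), fps = 30)
  expect_equal(ff2$mean_speed_um_s / ff1$mean_speed_um_s, 2,
               tolerance = 1e-6)

  # same physical motion filmed at double the frame rate: same um/s
  set.seed(6)
  v60 <- gen_motility_video(n_cells = 4, speed_um_s = 20, duration = 0.5,
                            fps = 60)
  tr30 <- track_cell(v30$frames, c(v30$truth$x_px[1], v30$truth$y_px[1]),
                     v30$cal, fps = 30)
  tr60 <- track_cell(v60$frames, c(v60$truth$x_px[1], v60$truth$y_px[1]),
                     v60$cal, fps = 60)
  expect_equal(tr30$mean_speed_um_s, tr60$mean_speed_um_s,
               tolerance = 0.1)
})

test_that("speed time series is flat under red light, decaying under white", {
  set.seed(7)
  pr <- list(trigger = c("b", "w"), tau = 60)
  red0 <- gen_motility_video(n_cells = 5, speed_um_s = c(15, 25),
                             duration = 0.4, light = "red",
                             photoresponse = pr, t0 = 0)
  set.seed(7)
  red300 <- gen_motility_video(n_cells = 5, speed_um_s = c(15, 25),
                               duration = 0.4, light = "red",
                               photoresponse = pr, t0 = 300)
  s0 <- flow_field(red0$frames, red0$cal)$mean_speed_um_s
  s300 <- flow_field(red300$frames, red300$cal)$mean_speed_um_s
  expect_equal(s300, s0, tolerance = 0.15)

  set.seed(7)
  wh300 <- gen_motility_video(n_cells = 5, speed_um_s = c(15, 25),
                              duration = 0.4, light = "white",
                              photoresponse = pr, t0 = 300)
  sw <- flow_field(wh300$frames, wh300$cal)$mean_speed_um_s
  expect_lt(sw, 0.05 * s0)

  # windowed series under white light decays toward arrest
  set.seed(8)
  wh <- gen_motility_video(n_cells = 5, speed_um_s = c(15, 25),
                           duration = 2, light = "white",
                           image_size = c(128, 128),
                           photoresponse = list(trigger = "w", tau = 0.6))
  ts <- speed_timeseries(wh$frames, wh$cal, fps = 30, window = 0.5)
  expect_true(all(diff(ts$mean_speed_um_s) < 0.5))  # no rebound
  expect_lt(ts$mean_speed_um_s[nrow(ts)], 0.2 * ts$mean_speed_um_s[1])
  # and a static scene stays flat at ~0
  set.seed(9)
  st <- gen_motility_video(n_cells = 4, speed_um_s = 0, duration = 1)
  ts2 <- speed_timeseries(st$frames, st$cal, fps = 30, window = 0.5)
  expect_true(all(ts2$mean_speed_um_s < 1))
})

test_that("track CSV export keeps the per-step speeds", {
  set.seed(10)
  v <- gen_motility_video(n_cells = 2, speed_um_s = 20, duration = 0.3)
  tr <- track_cell(v$frames, c(v$truth$x_px[1], v$truth$y_px[1]), v$cal)
  f <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tr, f)
  back <- read.csv(f)
  expect_equal(names(back), c("t_s", "x_px", "y_px", "speed_um_s"))
  expect_equal(nrow(back), tr$n_frames_tracked)
  expect_true(is.na(back$speed_um_s[1]))
})
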