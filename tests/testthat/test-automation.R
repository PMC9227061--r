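test_that("the printed demo scripts validate with broadcasting", {
  s4 <- validate_script(maxthroughput_path())
  expect_s3_class(s4, "automation_script")
  expect_equal(nrow(s4$pos), 24)
  expect_equal(s4$volume, rep(1, 24))  # [1] broadcasts to every well
  expect_equal(nrow(s4$light), 24)
  expect_true(all(s4$light[, "w"] == 255))
  expect_false(s4$trash)

  s3 <- validate_script(demoseq_path())
  expect_equal(s3$name, "DemoSeq")
  expect_equal(s3$volume, c(1, 2, 3))
  expect_equal(s3$delay, c(30, 60, 0))
  expect_equal(s3$light[, "r"], c(255, 0, 0), ignore_attr = TRUE)
  expect_true(s3$trash && s3$sampling && s3$capture)
})

test_that("invalid scripts fail naming the missing or malformed key", {
  base <- jsonlite::fromJSON(demoseq_path(), simplifyVector = FALSE)
  expect_error(validate_script(base[setdiff(names(base), "name")]),
               '"name"')
  expect_error(validate_script(base[setdiff(names(base), "pos")]),
               '"pos"')
  expect_error(validate_script(base[setdiff(names(base), "volume")]),
               '"volume"')
  bad_len <- base; bad_len$volume <- list(1, 2)
  expect_error(validate_script(bad_len), '"volume".*length')
  bad_light <- base; bad_light$light <- list(list(1, 2, 3))
  expect_error(validate_script(bad_light), "r, g, b, w")
  extra <- base; extra$frobnicate <- 1
  expect_warning(validate_script(extra), "frobnicate")
  neg <- base; neg$delay <- list(-1, 0, 0)
  expect_error(validate_script(neg), "delay")
})

test_that("normalization is idempotent and delay defaults to zero", {
  s <- validate_script(demoseq_path())
  expect_equal(validate_script(s), s)
  nodelay <- validate_script('{"name":"a","pos":[[0,0],[1,0]]}')
  expect_equal(nodelay$delay, c(0, 0))
})

test_that("runtime estimates respect the scripted delays", {
  lay <- plate_layout()
  tm <- timing_model()
  est3 <- estimate_runtime(demoseq_path(), lay, tm)
  expect_gte(est3, 90)  # the scripted delays alone sum to 90 s

  # with free moves and zeroed action constants only the delays remain
  tm0 <- timing_model(move_speed_xy = 1e9, move_speed_z = 1e9, home_s = 0,
                      purge_s = 0, pump_s_per_ml = 0, settle_s = 0,
                      autofocus_s = 0, capture_s = 0, park_z_s = 0)
  only_delays <- validate_script(
    '{"name":"d","pos":[[0,0],[1,0],[2,0]],"delay":[5,7,9]}')
  expect_equal(estimate_runtime(only_delays, lay, tm0), 21,
               tolerance = 1e-6)
})

test_that("executing the three-well demo produces the printed images", {
  set.seed(1)
  scn <- small_scene()
  dev <- virtual_device(scn, small_render(), seed = 2, settle_s = 0.1)
  lay <- plate_layout()
  out <- withr::local_tempdir()
  rep <- execute_script(demoseq_path(), dev, lay, out_dir = out)
  expect_equal(rep$images,
               c("DemoSeqX0Y0.png", "DemoSeqX2Y3.png", "DemoSeqX3Y0.png"))
  expect_setequal(list.files(out), rep$images)
  expect_length(rep$dispensed, 3)
  expect_equal(rep$dispensed, c(1, 2, 3), tolerance = 0.2)
  # scripted delays are part of the elapsed time
  expect_gte(rep$elapsed, 90)
  # all LEDs off and device parked afterwards
  expect_equal(unname(dev$leds), c(0, 0, 0, 0))
  expect_equal(device_position(dev), c(x = 220, y = 220, z = 240))
})

test_that("a no-op script cycles lights but captures nothing", {
  dev <- virtual_device(seed = 3)  # no scene needed: no capture
  lay <- plate_layout()
  rep <- execute_script('{"name":"idle","pos":[[0,0],[1,1]],"light":[[0,255,0,0]]}',
                        dev, lay)
  expect_length(rep$images, 0)
  expect_gt(rep$elapsed, 0)
  expect_true(all(is.na(rep$wells$dispensed_ml)))
  expect_equal(unname(dev$leds), c(0, 0, 0, 0))
})

test_that("execution is deterministic for a fixed device seed", {
  set.seed(4)
  scn <- small_scene()
  lay <- plate_layout()
  run <- function() {
    dev <- virtual_device(scn, small_render(), seed = 9, settle_s = 0.1)
    r <- execute_script(demoseq_path(), dev, lay)
    r[c("elapsed", "images", "dispensed")]
  }
  expect_identical(run(), run())
})

test_that("safe position is idempotent and inside the working volume", {
  dev <- virtual_device(seed = 5)
  device_home(dev)
  safe_position(dev)
  p1 <- device_position(dev)
  safe_position(dev)
  expect_equal(device_position(dev), p1)
  expect_true(all(p1 >= 0 & p1 <= c(220, 220, 240)))
})

test_that("simulated runtime matches the estimate under a matched model", {
  set.seed(6)
  scn <- small_scene()
  lay <- plate_layout()
  dev <- virtual_device(scn, small_render(), seed = 10, settle_s = 0.2)
  tm <- timing_model_for_device(dev)
  est <- estimate_runtime(maxthroughput_path(), lay, tm)
  rep <- execute_script(maxthroughput_path(), dev, lay)
  expect_equal(length(rep$images), 24)
  expect_gte(rep$elapsed / est, 0.9)
  expect_lte(rep$elapsed / est, 1.1)
})

test_that("the action log serializes as JSON lines", {
  dev <- virtual_device(seed = 7)
  device_home(dev)
  device_move_to(dev, x = 50)
  device_set_light(dev, c(0, 0, 0, 255))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_run_log(dev, f)
  lines <- readLines(f)
  expect_length(lines, 3)
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_equal(vapply(parsed, `[[`, character(1), "action"),
               c("home", "move", "led"))
})
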