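#' Peristaltic pump model
#'
#' Positive-displacement pump with multiplicative Gaussian volume error:
#' a requested volume V is dispensed as V * (1 + e), e ~ N(0,
#' `relative_error_sd`). The default 3.5% relative error reproduces the
#' characterization of the 3D-printed pump at 1 mL.
#'
#' @param flow_rate mL/s.
#' @param relative_error_sd relative volume error (sd), dimensionless.
#' @param purge_volume volume pushed through when purging the circuit, mL.
#' @return object of class `pump_model`.
#' @export
pump_model <- function(flow_rate = 0.2, relative_error_sd = 0.035,
                       purge_volume = 1) {
  stopifnot(flow_rate > 0, relative_error_sd >= 0, purge_volume >= 0)
  structure(list(flow_rate = flow_rate,
                 relative_error_sd = relative_error_sd,
                 purge_volume = purge_volume), class = "pump_model")
}

#' Simulate dispensed volumes
#'
#' Draws from the pump's error model using the current RNG stream.
#'
#' @param pump a [pump_model()].
#' @param volume requested volume(s), mL; must be positive.
#' @return actually dispensed volume(s), mL.
#' @export
dispense_volume <- function(pump, volume) {
  if (any(volume <= 0)) stop("dispense volume must be positive")
  volume * (1 + stats::rnorm(length(volume), 0, pump$relative_error_sd))
}

#' Virtual imaging station
#'
#' Simulates the full hardware behind the device contract the automation
#' engine drives: a 3-axis Cartesian stage (220 x 220 x 240 mm working
#' volume) with Gaussian homing repeatability error applied once per homing
#' event, a peristaltic pump, per-well RGBW LEDs, and a camera rendering
#' the synthetic [scene()] through a [render_model()]. All stochastic
#' behaviour (homing noise, pump error, pixel noise) comes from one
#' device-private RNG stream seeded at construction, so identical seeds
#' give bit-identical runs. The device keeps an internal clock advanced by
#' realistic action durations.
#'
#' @param scn a [scene()] (may be `NULL` for liquid-handling-only runs).
#' @param render a [render_model()].
#' @param pump a [pump_model()].
#' @param seed integer seed for the device RNG stream.
#' @param homing_noise_sd_um per-axis homing error sd `c(x, y, z)` in µm
#'   (defaults from the measured homing repeatability: 37/14/9 µm).
#' @param axis_speed_xy,axis_speed_z stage speeds, mm/s.
#' @param settle_s settle delay between a Y move and a capture, s.
#' @param capture_s camera exposure + readout time, s.
#' @return an environment of class `virtual_device`.
#' @export
virtual_device <- function(scn = NULL, render = render_model(),
                           pump = pump_model(), seed = 1,
                           homing_noise_sd_um = c(37, 14, 9),
                           axis_speed_xy = 50, axis_speed_z = 5,
                           settle_s = 1, capture_s = 0.2) {
  dev <- new.env(parent = emptyenv())
  dev$scene <- scn
  dev$render <- render
  dev$pump <- pump
  dev$seed <- seed
  dev$rng_state <- NULL
  dev$homing_noise_sd_um <- homing_noise_sd_um
  dev$axis_speed_xy <- axis_speed_xy
  dev$axis_speed_z <- axis_speed_z
  dev$settle_s <- settle_s
  dev$capture_s <- capture_s
  dev$pos <- c(x = 0, y = 0, z = 0)        # nominal, mm
  dev$origin_error <- c(x = 0, y = 0, z = 0)  # from last homing, mm
  dev$homed <- FALSE
  dev$leds <- as_leds(c(0, 0, 0, 0))
  dev$light_since <- 0                      # clock time the LEDs last changed
  dev$clock <- 0
  dev$log <- list()
  class(dev) <- "virtual_device"
  dev
}

working_volume <- c(x = 220, y = 220, z = 240)

# run expr (a function of no arguments) under the device's private RNG
# stream, leaving the global stream untouched
with_device_rng <- function(dev, fn) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    dev$rng_state <- get(".Random.seed", envir = genv)
    if (is.null(old)) rm(".Random.seed", envir = genv)
    else assign(".Random.seed", old, envir = genv)
  })
  if (is.null(dev$rng_state)) set.seed(dev$seed)
  else assign(".Random.seed", dev$rng_state, envir = genv)
  fn()
}

log_action <- function(dev, action, ...) {
  dev$log[[length(dev$log) + 1]] <-
    list(t = dev$clock, action = action, ...)
  invisible(dev)
}

#' Home the stage
#'
#' Drives all axes to their end stops. The nominal position becomes
#' (0, 0, 0); the true position deviates by a per-axis Gaussian draw with
#' the configured homing repeatability sd, applied once per homing event
#' (subsequent moves are exact relative to this origin).
#'
#' @param dev a [virtual_device()].
#' @return the device, invisibly.
#' @export
device_home <- function(dev) {
  err_um <- with_device_rng(dev, function()
    stats::rnorm(3, 0, dev$homing_noise_sd_um))
  dev$origin_error <- c(x = err_um[1], y = err_um[2], z = err_um[3]) / 1000
  dev$pos <- c(x = 0, y = 0, z = 0)
  dev$homed <- TRUE
  dev$clock <- dev$clock + 5
  log_action(dev, "home", origin_error_mm = unname(dev$origin_error))
  invisible(dev)
}

#' Move the stage
#'
#' Absolute move; omitted axes keep their position. Duration is distance /
#' axis speed (XY and Z move concurrently). Positions are exact — noise
#' enters only at homing.
#'
#' @param dev a [virtual_device()].
#' @param x,y,z target coordinates, mm.
#' @return move duration in s, invisibly.
#' @export
device_move_to <- function(dev, x = NULL, y = NULL, z = NULL) {
  target <- dev$pos
  if (!is.null(x)) target["x"] <- x
  if (!is.null(y)) target["y"] <- y
  if (!is.null(z)) target["z"] <- z
  for (ax in c("x", "y", "z"))
    if (target[ax] < 0 || target[ax] > working_volume[ax])
      stop(sprintf("move target %s=%.2f mm outside the working volume [0, %d] on the %s axis",
                   ax, target[ax], working_volume[ax], ax))
  d_xy <- sqrt(sum((target[c("x", "y")] - dev$pos[c("x", "y")])^2))
  d_z <- abs(target["z"] - dev$pos["z"])
  duration <- unname(max(d_xy / dev$axis_speed_xy, d_z / dev$axis_speed_z))
  dev$pos <- target
  dev$clock <- dev$clock + duration
  log_action(dev, "move", target = unname(target), duration = duration)
  invisible(duration)
}

#' Nominal and true stage position
#'
#' The true position includes the residual origin error of the last homing.
#'
#' @param dev a [virtual_device()].
#' @return named numeric `c(x, y, z)` in mm.
#' @export
device_position <- function(dev) dev$pos

#' @rdname device_position
#' @export
device_true_position <- function(dev) dev$pos + dev$origin_error

#' Set the well illumination
#'
#' @param dev a [virtual_device()].
#' @param leds RGBW vector `c(r, g, b, w)`, 0..255.
#' @return the device, invisibly.
#' @export
device_set_light <- function(dev, leds) {
  leds <- as_leds(leds)
  if (any(leds != dev$leds)) dev$light_since <- dev$clock
  dev$leds <- leds
  log_action(dev, "led", leds = unname(leds))
  invisible(dev)
}

#' Dispense through the pump
#'
#' @param dev a [virtual_device()].
#' @param volume requested volume, mL (> 0).
#' @param purge purge the circuit first (pushes `purge_volume` through).
#' @return actually dispensed volume, mL.
#' @export
device_dispense <- function(dev, volume, purge = FALSE) {
  if (volume <= 0) stop("dispense volume must be positive")
  actual <- with_device_rng(dev, function()
    dispense_volume(dev$pump, volume))
  dur <- volume / dev$pump$flow_rate +
    if (purge) dev$pump$purge_volume / dev$pump$flow_rate else 0
  dev$clock <- dev$clock + dur
  log_action(dev, "pump", requested = volume, dispensed = actual,
             purge = purge)
  actual
}

#' Wait (advance the device clock)
#'
#' @param dev a [virtual_device()].
#' @param seconds delay, s.
#' @return the device, invisibly.
#' @export
device_wait <- function(dev, seconds) {
  stopifnot(seconds >= 0)
  dev$clock <- dev$clock + seconds
  log_action(dev, "wait", seconds = seconds)
  invisible(dev)
}

# scene time used for kinematics: time since the current illumination was
# applied (the photoresponse integrates exposure to the present light)
device_scene_time <- function(dev) dev$clock - dev$light_since

#' Capture a frame with the virtual camera
#'
#' Renders the scene at the camera's true height (homing error included)
#' under the current LEDs, advancing the clock by the exposure time.
#'
#' @param dev a [virtual_device()].
#' @return h x w x 3 array, 0..255.
#' @export
device_capture <- function(dev) {
  if (is.null(dev$scene)) stop("device has no scene to image")
  z <- unname(device_true_position(dev)["z"])
  t <- device_scene_time(dev)
  img <- with_device_rng(dev, function()
    render_frame(dev$scene, dev$render, z = z, leds = dev$leds, t = t))
  dev$clock <- dev$clock + dev$capture_s
  log_action(dev, "capture", z = z, t = t)
  img
}

#' Capture a video with the virtual camera
#'
#' @param dev a [virtual_device()].
#' @param duration s.
#' @param fps frames per second.
#' @return list of frames (h x w x 3 arrays).
#' @export
device_capture_video <- function(dev, duration, fps = 30) {
  if (is.null(dev$scene)) stop("device has no scene to image")
  z <- unname(device_true_position(dev)["z"])
  t0 <- device_scene_time(dev)
  frames <- with_device_rng(dev, function()
    capture_video(dev$scene, dev$render, z = z, leds = dev$leds,
                  duration = duration, fps = fps, t0 = t0))
  dev$clock <- dev$clock + duration
  log_action(dev, "video", duration = duration, fps = fps)
  frames
}

#' Ground truth as the camera currently sees it
#'
#' [scene_truth()] evaluated at the device's current scene time and
#' illumination — true pixel-frame positions, sizes and speeds of every
#' cell at the moment a capture started.
#'
#' @param dev a [virtual_device()].
#' @return data.frame, see [scene_truth()].
#' @export
device_scene_truth <- function(dev) {
  if (is.null(dev$scene)) stop("device has no scene")
  scene_truth(dev$scene, dev$render, t = device_scene_time(dev),
              leds = dev$leds)
}

#' Elapsed simulated time
#'
#' @param dev a [virtual_device()].
#' @return seconds since construction.
#' @export
device_elapsed <- function(dev) dev$clock

#' @export
print.virtual_device <- function(x, ...) {
  cat(sprintf("<virtual_device> pos (%.1f, %.1f, %.1f) mm%s, leds [%s], t = %.1f s\n",
              x$pos["x"], x$pos["y"], x$pos["z"],
              if (x$homed) " (homed)" else "",
              paste(x$leds, collapse = ","), x$clock))
  invisible(x)
}
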