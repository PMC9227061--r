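#' Validate and normalize an automation script
#'
#' Automation scripts are JSON objects with keys `name` (sequence name),
#' `pos` (list of `[x, y]` well addresses), and optionally `sampling`,
#' `volume` (mL, required when sampling), `capture`, `light` (list of
#' `[r, g, b, w]`, 0..255), `delay` (s, wait after each well), `trash`
#' (purge the circuit before each dispense). Singleton `volume`, `light`
#' and `delay` lists broadcast to every well; any other length must equal
#' the number of wells. Missing required keys raise an error naming the
#' key; unknown keys raise a warning. Normalization is idempotent.
#'
#' @param x a file path, a JSON string, a list, or an already-normalized
#'   `automation_script`.
#' @return object of class `automation_script` with `pos` a data.frame
#'   (x, y), `volume`/`delay` numeric vectors and `light` an n x 4 matrix,
#'   all of length/rows = number of wells.
#' @export
validate_script <- function(x) {
  if (inherits(x, "automation_script")) x <- unclass(x)
  if (is.character(x) && length(x) == 1) {
    x <- if (file.exists(x)) jsonlite::fromJSON(x, simplifyVector = FALSE)
    else jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  if (!is.list(x)) stop("script must be a JSON object")
  known <- c("name", "pos", "sampling", "volume", "capture", "light",
             "delay", "trash")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    warning("ignoring unknown script key(s): ",
            paste(unknown, collapse = ", "))
  if (is.null(x$name) || !nzchar(as.character(x$name)[1]))
    stop("invalid script: missing required property \"name\"")
  if (is.null(x$pos) || !length(x$pos))
    stop("invalid script: missing required property \"pos\"")
  pos <- x$pos
  if (is.data.frame(pos)) pos <- pos[, c("x", "y")]
  else {
    if (is.matrix(pos)) pos <- lapply(seq_len(nrow(pos)), function(i) pos[i, ])
    if (!all(vapply(pos, length, integer(1)) == 2))
      stop("invalid script: every \"pos\" entry must be a pair [x, y]")
    pos <- data.frame(x = vapply(pos, function(p) as.integer(p[[1]]),
                                 integer(1)),
                      y = vapply(pos, function(p) as.integer(p[[2]]),
                                 integer(1)))
  }
  n <- nrow(pos)
  sampling <- isTRUE(x$sampling)
  capture <- isTRUE(x$capture)
  trash <- isTRUE(x$trash)
  broadcast <- function(v, what, len1_ok = TRUE) {
    if (length(v) == 1 && len1_ok) v <- rep(v, n)
    if (length(v) != n)
      stop(sprintf("invalid script: \"%s\" must have length 1 or %d, got %d",
                   what, n, length(v)))
    v
  }
  volume <- NULL
  if (sampling) {
    if (is.null(x$volume))
      stop("invalid script: missing required property \"volume\" (sampling is true)")
    volume <- broadcast(as.numeric(unlist(x$volume)), "volume")
    if (any(volume <= 0)) stop("invalid script: volumes must be positive")
  } else if (!is.null(x$volume)) {
    volume <- broadcast(as.numeric(unlist(x$volume)), "volume")
  }
  light <- x$light
  if (is.null(light)) light <- list(c(0, 0, 0, 0))
  if (is.matrix(light)) light <- lapply(seq_len(nrow(light)),
                                        function(i) light[i, ])
  if (is.numeric(light) && length(light) == 4) light <- list(light)
  if (!all(vapply(light, length, integer(1)) == 4))
    stop("invalid script: every \"light\" entry must be [r, g, b, w]")
  if (length(light) == 1) light <- rep(light, n)
  if (length(light) != n)
    stop(sprintf("invalid script: \"light\" must have length 1 or %d, got %d",
                 n, length(light)))
  light <- do.call(rbind, lapply(light, as.numeric))
  colnames(light) <- c("r", "g", "b", "w")
  if (any(light < 0 | light > 255))
    stop("invalid script: light channels must be in [0, 255]")
  delay <- if (is.null(x$delay)) 0 else as.numeric(unlist(x$delay))
  delay <- broadcast(delay, "delay")
  if (any(delay < 0)) stop("invalid script: delays must be >= 0")
  structure(list(name = as.character(x$name)[1], pos = pos,
                 sampling = sampling, volume = volume, capture = capture,
                 light = light, delay = delay, trash = trash),
            class = "automation_script")
}

#' @export
print.automation_script <- function(x, ...) {
  cat(sprintf("<automation_script> \"%s\": %d wells%s%s%s\n", x$name,
              nrow(x$pos),
              if (x$sampling) ", sampling" else "",
              if (x$capture) ", capture" else "",
              if (x$trash) ", purge" else ""))
  invisible(x)
}

#' Per-action timing constants
#'
#' Durations used by the runtime estimator. The defaults mirror the
#' virtual device's own constants so that estimates match simulated runs;
#' [timing_model_for_device()] derives them from a device instance
#' (measuring one autofocus on a clone).
#'
#' @param move_speed_xy,move_speed_z stage speeds, mm/s.
#' @param home_s homing duration, s.
#' @param purge_s circuit purge duration, s.
#' @param pump_s_per_ml pumping time per mL, s.
#' @param settle_s liquid settle delay before capture, s.
#' @param autofocus_s duration of one full autofocus sweep, s.
#' @param capture_s one image capture, s.
#' @param park_z_s raising the camera to its parked height at the end of a
#'   run, s (z travel dominates parking: the full 228 mm at 5 mm/s).
#' @return object of class `timing_model`.
#' @export
timing_model <- function(move_speed_xy = 50, move_speed_z = 5, home_s = 5,
                         purge_s = 5, pump_s_per_ml = 5, settle_s = 1,
                         autofocus_s = 4.5, capture_s = 0.2,
                         park_z_s = 45.6) {
  vals <- c(move_speed_xy, move_speed_z, home_s, purge_s, pump_s_per_ml,
            settle_s, autofocus_s, capture_s, park_z_s)
  stopifnot(all(vals >= 0), move_speed_xy > 0, move_speed_z > 0)
  structure(list(move_speed_xy = move_speed_xy, move_speed_z = move_speed_z,
                 home_s = home_s, purge_s = purge_s,
                 pump_s_per_ml = pump_s_per_ml, settle_s = settle_s,
                 autofocus_s = autofocus_s, capture_s = capture_s,
                 park_z_s = park_z_s),
            class = "timing_model")
}

clone_device <- function(dev) {
  d2 <- new.env(parent = emptyenv())
  for (nm in ls(dev, all.names = TRUE)) assign(nm, get(nm, envir = dev),
                                               envir = d2)
  class(d2) <- class(dev)
  d2
}

#' @rdname timing_model
#' @param dev a [virtual_device()].
#' @param focus_par a [focus_params()] (the sweep the executor will run).
#' @export
timing_model_for_device <- function(dev, focus_par = focus_params()) {
  focus_z <- dev$render$focal_offset
  af <- if (is.null(dev$scene)) 4.5 else {
    probe <- clone_device(dev)
    # start the probe sweep from the working focus height, as every
    # steady-state well does, so the one-off approach move is not charged
    # to each autofocus
    device_move_to(probe, z = focus_z)
    t0 <- device_elapsed(probe)
    device_autofocus(probe, params = focus_par)
    device_elapsed(probe) - t0
  }
  timing_model(move_speed_xy = dev$axis_speed_xy,
               move_speed_z = dev$axis_speed_z, home_s = 5,
               purge_s = dev$pump$purge_volume / dev$pump$flow_rate,
               pump_s_per_ml = 1 / dev$pump$flow_rate,
               settle_s = dev$settle_s, autofocus_s = af,
               capture_s = dev$capture_s,
               park_z_s = (unname(working_volume["z"]) - focus_z) /
                 dev$axis_speed_z)
}

# XY travel plan shared by the estimator and (implicitly) the executor:
# from the previous position, via the tip position when sampling, to the
# camera position over the well
script_waypoints <- function(script, layout, tool_offset = c(30, 0)) {
  cam <- well_to_stage(layout, script$pos)
  tip <- if (script$sampling)
    tip_position_for_well(layout, script$pos, tool_offset) else NULL
  list(cam = cam, tip = tip)
}

#' Estimate a script's runtime
#'
#' Sums, over wells, the XY travel (via the pipette tip when sampling),
#' purge and pump times, the settle delay, the autofocus sweep and capture
#' when capturing, and the scripted delay; plus homing at the start and
#' parking at the safe position at the end. Always at least the sum of the
#' scripted delays.
#'
#' @param script script (anything [validate_script()] accepts).
#' @param layout a [plate_layout()].
#' @param timing a [timing_model()].
#' @param tool_offset camera-to-tip offset, mm.
#' @return estimated duration, s.
#' @export
estimate_runtime <- function(script, layout, timing = timing_model(),
                             tool_offset = c(30, 0)) {
  script <- validate_script(script)
  wp <- script_waypoints(script, layout, tool_offset)
  pos <- c(0, 0)  # after homing
  total <- timing$home_s
  for (i in seq_len(nrow(script$pos))) {
    if (script$sampling) {
      tp <- c(wp$tip$x_mm[i], wp$tip$y_mm[i])
      total <- total + sqrt(sum((tp - pos)^2)) / timing$move_speed_xy
      pos <- tp
      if (script$trash) total <- total + timing$purge_s
      total <- total + script$volume[i] * timing$pump_s_per_ml
    }
    cp <- c(wp$cam$x_mm[i], wp$cam$y_mm[i])
    total <- total + sqrt(sum((cp - pos)^2)) / timing$move_speed_xy
    pos <- cp
    total <- total + timing$settle_s
    if (script$capture)
      total <- total + timing$autofocus_s + timing$capture_s
    total <- total + script$delay[i]
  }
  # parking: xy to the far corner and z to full height move concurrently
  safe <- working_volume[c("x", "y")]
  total <- total + max(sqrt(sum((safe - pos)^2)) / timing$move_speed_xy,
                       timing$park_z_s)
  max(total, sum(script$delay))
}

#' Park the device in its safe position
#'
#' Camera to the upper-right corner at full height, bed advanced toward
#' the user, giving free access to the plates. Idempotent.
#'
#' @param dev a [virtual_device()].
#' @return the device, invisibly.
#' @export
safe_position <- function(dev) {
  device_move_to(dev, x = unname(working_volume["x"]),
                 y = unname(working_volume["y"]),
                 z = unname(working_volume["z"]))
  invisible(dev)
}

#' Execute an automation script on a device
#'
#' For each well in order: set that well's light, move the pipette tip
#' over the well, purge and dispense when sampling, move the camera over
#' the well, wait for the liquid to settle, autofocus and capture when
#' capturing (images named `<name>X<x>Y<y>.png` with the raw 0-based well
#' indices), then wait the scripted delay. Afterwards all LEDs are turned
#' off, the device is parked at the safe position, and a run report with
#' the elapsed (simulated) time is returned.
#'
#' @param script script (anything [validate_script()] accepts).
#' @param dev a [virtual_device()].
#' @param layout a [plate_layout()].
#' @param out_dir directory for captured images (`NULL`: keep in memory).
#' @param tool_offset camera-to-tip offset, mm.
#' @param focus_par a [focus_params()] for the per-well autofocus.
#' @param run_autofocus set `FALSE` to capture at the current height.
#' @return object of class `run_report`: list with `elapsed` (s), `images`
#'   (file names), `frames` (when `out_dir` is `NULL`), `dispensed` (mL),
#'   `wells` (per-well log data.frame).
#' @export
execute_script <- function(script, dev, layout, out_dir = NULL,
                           tool_offset = c(30, 0),
                           focus_par = focus_params(),
                           run_autofocus = TRUE) {
  script <- validate_script(script)
  if (!dev$homed) device_home(dev)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  t0 <- device_elapsed(dev)
  wp <- script_waypoints(script, layout, tool_offset)
  images <- character(0)
  frames <- list()
  dispensed <- numeric(0)
  wells <- list()
  for (i in seq_len(nrow(script$pos))) {
    addr <- script$pos[i, ]
    device_set_light(dev, script$light[i, ])
    vol <- NA_real_
    if (script$sampling) {
      device_move_to(dev, x = wp$tip$x_mm[i], y = wp$tip$y_mm[i])
      vol <- device_dispense(dev, script$volume[i], purge = script$trash)
      dispensed <- c(dispensed, vol)
    }
    device_move_to(dev, x = wp$cam$x_mm[i], y = wp$cam$y_mm[i])
    device_wait(dev, dev$settle_s)
    img_name <- NA_character_
    if (script$capture) {
      if (run_autofocus && !is.null(dev$scene))
        device_autofocus(dev, params = focus_par)
      img <- device_capture(dev)
      img_name <- sprintf("%sX%dY%d.png", script$name, addr$x, addr$y)
      if (!is.null(out_dir)) write_image(img, file.path(out_dir, img_name))
      else frames[[img_name]] <- img
      images <- c(images, img_name)
    }
    device_wait(dev, script$delay[i])
    wells[[i]] <- data.frame(x = addr$x, y = addr$y, dispensed_ml = vol,
                             image = img_name,
                             t_done = device_elapsed(dev) - t0)
  }
  device_set_light(dev, c(0, 0, 0, 0))
  safe_position(dev)
  structure(list(elapsed = device_elapsed(dev) - t0, images = images,
                 frames = frames, dispensed = dispensed,
                 wells = do.call(rbind, wells), out_dir = out_dir,
                 name = script$name), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> \"%s\": %d wells, %d images, %.1f s simulated\n",
              x$name, nrow(x$wells), length(x$images), x$elapsed))
  invisible(x)
}

#' Write a device action log as JSON lines
#'
#' One JSON object per action with its simulated timestamp.
#'
#' @param dev a [virtual_device()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(dev, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (entry in dev$log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  invisible(path)
}
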