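#' Synthetic test fixtures with ground truth
#'
#' Every input the analysis modules consume can be generated here with a
#' known ground truth: graduated calibration slides, micrographs with
#' known cell counts and sizes, focus stacks with a known sharpness peak,
#' and motility videos with known speeds. Generation is seeded and
#' bit-reproducible; [make_fixture()] materializes a fixture on disk (PNG
#' frames plus a JSON truth sidecar), while the `gen_*` functions return
#' the same objects in memory for tests.
#'
#' @param kind one of `"calibration_slide"`, `"micrograph"`,
#'   `"focus_stack"`, `"motility_video"`, `"photoresponse_video"`.
#' @param seed integer RNG seed.
#' @param ... kind-specific parameters passed to the matching `gen_*`.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, seed = 1, ...) {
  kinds <- c("calibration_slide", "micrograph", "focus_stack",
             "motility_video", "photoresponse_video")
  if (!kind %in% kinds)
    stop("unknown fixture kind: ", kind, " (known: ",
         paste(kinds, collapse = ", "), ")")
  structure(list(kind = kind, seed = seed, params = list(...)),
            class = "fixture_spec")
}

#' Synthetic graduated calibration slide
#'
#' Dark parallel graduation lines, `spacing_px` apart, on a bright
#' background, optionally rotated.
#'
#' @param spacing_px distance between adjacent graduations, px.
#' @param division_um physical distance the spacing represents, µm.
#' @param size `c(w, h)` px.
#' @param angle_deg rotation of the graduations from vertical.
#' @param line_width_px graduation stroke width.
#' @param noise_sd pixel noise, gray levels.
#' @return list with `image` (matrix), `division_um`, `spacing_px`,
#'   `um_per_px` (ground truth).
#' @export
gen_calibration_slide <- function(spacing_px = 20, division_um = 10,
                                  size = c(480, 360), angle_deg = 0,
                                  line_width_px = 2, noise_sd = 2) {
  w <- size[1]; h <- size[2]
  a <- angle_deg * pi / 180
  u <- outer(seq_len(h) * sin(a), seq_len(w) * cos(a), `+`)
  d <- abs(((u + spacing_px / 2) %% spacing_px) - spacing_px / 2)
  img <- 230 - 190 * stats::plogis((line_width_px / 2 - d) / 0.5)
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  list(image = clip255(img), division_um = division_um,
       spacing_px = spacing_px, um_per_px = division_um / spacing_px)
}

#' Synthetic in-focus micrograph with known cells
#'
#' A static single-layer scene of non-overlapping cells rendered at its
#' focus height.
#'
#' @param n_cells number of cells.
#' @param diameter_um diameter range, µm.
#' @param pixel_size µm/px.
#' @param image_size `c(w, h)` px.
#' @param noise_sd camera noise, gray levels.
#' @param leds illumination.
#' @return list with `image` (RGB array), `truth` (data.frame from
#'   [scene_truth()]), `scene`, `render`, `cal` (matching [calibration()]).
#' @export
gen_micrograph <- function(n_cells = 25, diameter_um = c(5, 12),
                           pixel_size = 0.5, image_size = c(256, 256),
                           noise_sd = 2, leds = c(0, 0, 0, 255)) {
  render <- render_model(image_size = image_size, pixel_size = pixel_size,
                         noise_sd = noise_sd)
  scn <- make_scene(n_cells = n_cells, diameter_um = diameter_um,
                    speed_um_s = c(0, 0), photoresponse = NULL,
                    fov_um = image_size * pixel_size)
  z <- focus_height_for_depth(render, scn, scn$cells$z_um[1])
  img <- render_frame(scn, render, z = z, leds = leds)
  list(image = img, truth = scene_truth(scn, render), scene = scn,
       render = render,
       cal = calibration(pixel_size, image_size = image_size))
}

#' Synthetic focus stack
#'
#' A capture-at-height closure over a single-layer scene whose sharpness
#' is unimodal in the camera height, peaking at the layer's focus height.
#'
#' @param peak_offset_mm where the true focus peak sits relative to the
#'   render model's `focal_offset` (0 = liquid surface in focus).
#' @param n_cells,image_size,pixel_size,noise_sd scene/render parameters.
#' @return list with `capture_at` (function(height_mm) -> image),
#'   `true_peak` (mm), `scene`, `render`.
#' @export
gen_focus_stack <- function(peak_offset_mm = 0, n_cells = 8,
                            image_size = c(128, 128), pixel_size = 0.5,
                            noise_sd = 1) {
  render <- render_model(image_size = image_size, pixel_size = pixel_size,
                         noise_sd = noise_sd,
                         focal_offset = 12 + peak_offset_mm)
  scn <- make_scene(n_cells = n_cells, speed_um_s = c(0, 0),
                    photoresponse = NULL,
                    fov_um = image_size * pixel_size)
  list(capture_at = function(h) render_frame(scn, render, z = h),
       true_peak = focus_height_for_depth(render, scn, scn$cells$z_um[1]),
       scene = scn, render = render)
}

#' Synthetic motility video
#'
#' Cells moving at known speeds, filmed at `fps` for `duration` seconds.
#'
#' @param n_cells number of cells.
#' @param speed_um_s speed range (or a single common speed), µm/s.
#' @param duration,fps video length (s) and frame rate (Hz).
#' @param light illumination color name (`"red"`, `"white"`, `"blue"`) or
#'   an RGBW vector.
#' @param photoresponse see [scene()]; `NULL` disables the light response.
#' @param t0 scene time of the first frame, s.
#' @param image_size,pixel_size,noise_sd render parameters.
#' @return list with `frames`, `truth` (at the first frame), `scene`,
#'   `render`, `cal`, `fps`.
#' @export
gen_motility_video <- function(n_cells = 10, speed_um_s = c(10, 30),
                               duration = 1, fps = 30, light = "red",
                               photoresponse = NULL, t0 = 0,
                               image_size = c(192, 192), pixel_size = 0.5,
                               noise_sd = 1) {
  leds <- if (is.character(light))
    switch(light, red = c(255, 0, 0, 0), blue = c(0, 0, 255, 0),
           white = c(0, 0, 0, 255), stop("unknown light color: ", light))
  else light
  if (length(speed_um_s) == 1) speed_um_s <- rep(speed_um_s, 2)
  render <- render_model(image_size = image_size, pixel_size = pixel_size,
                         noise_sd = noise_sd)
  scn <- make_scene(n_cells = n_cells, speed_um_s = speed_um_s,
                    photoresponse = photoresponse,
                    fov_um = image_size * pixel_size)
  frames <- capture_video(scn, render, leds = leds, duration = duration,
                          fps = fps, t0 = t0)
  list(frames = frames, truth = scene_truth(scn, render, t = t0,
                                            leds = leds),
       scene = scn, render = render,
       cal = calibration(pixel_size, image_size = image_size), fps = fps)
}

#' Materialize a fixture on disk
#'
#' Writes the fixture's PNG image(s) and a `truth.json` sidecar holding
#' the generating parameters and ground truth (counts, sizes, positions,
#' speeds, focus peak, as applicable). Regenerating with the same spec
#' yields identical bytes.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisible list of written paths.
#' @export
make_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(spec$seed)
  p <- spec$params
  paths <- character(0)
  truth <- list(kind = spec$kind, seed = spec$seed)
  if (spec$kind == "calibration_slide") {
    fx <- do.call(gen_calibration_slide, p)
    paths <- file.path(out_dir, "slide.png")
    write_image(fx$image, paths)
    truth$um_per_px <- fx$um_per_px
    truth$division_um <- fx$division_um
    truth$spacing_px <- fx$spacing_px
  } else if (spec$kind == "micrograph") {
    fx <- do.call(gen_micrograph, p)
    paths <- file.path(out_dir, "micrograph.png")
    write_image(fx$image, paths)
    truth$n_cells <- nrow(fx$truth)
    truth$cells <- fx$truth
    truth$um_per_px <- fx$cal$um_per_px
  } else if (spec$kind == "focus_stack") {
    fx <- do.call(gen_focus_stack, p)
    heights <- p$heights %||% (fx$true_peak + seq(-0.5, 0.5, by = 0.05))
    paths <- vapply(seq_along(heights), function(i) {
      f <- file.path(out_dir, sprintf("stack_%03d.png", i))
      write_image(fx$capture_at(heights[i]), f)
      f
    }, character(1))
    truth$heights_mm <- heights
    truth$true_peak_mm <- fx$true_peak
  } else if (spec$kind %in% c("motility_video", "photoresponse_video")) {
    if (spec$kind == "photoresponse_video" && is.null(p$photoresponse))
      p$photoresponse <- list(trigger = c("b", "w"), tau = 60)
    fx <- do.call(gen_motility_video, p)
    paths <- vapply(seq_along(fx$frames), function(i) {
      f <- file.path(out_dir, sprintf("frame_%04d.png", i))
      write_image(fx$frames[[i]], f)
      f
    }, character(1))
    truth$n_cells <- nrow(fx$truth)
    truth$cells <- fx$truth
    truth$fps <- fx$fps
    truth$um_per_px <- fx$cal$um_per_px
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(paths = paths, truth = truth_path))
}
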