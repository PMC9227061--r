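#' Virtual camera optics
#'
#' Maps the synthetic scene to 8-bit bright-field frames. Each cell is a
#' dark disk whose edge softness grows linearly with the camera's defocus
#' distance; the liquid's top layer is globally sharpest because deeper
#' cells carry an extra depth-penalty blur (the instrument is set up to
#' image the upper layer of the liquid, where the image is sharpest).
#'
#' @param image_size `c(w, h)` in px.
#' @param pixel_size µm per px (2.8 mm lens at 1080p-equivalent: 0.5).
#' @param focal_offset camera z (mm) at which the liquid surface
#'   (z = column_depth) is in focus.
#' @param blur_scale blur growth, px of edge softness per mm of defocus.
#' @param depth_penalty extra blur, px per mm of cell depth below the
#'   liquid surface.
#' @param base_sigma edge softness of a perfectly focused cell, px.
#' @param noise_sd camera noise, gray levels (added to all channels).
#' @param cell_contrast how much darker than background an in-focus cell
#'   centre is, gray levels, before color modulation.
#' @return object of class `render_model`.
#' @export
render_model <- function(image_size = c(256, 256), pixel_size = 0.5,
                         focal_offset = 12, blur_scale = 8,
                         depth_penalty = 3, base_sigma = 0.9,
                         noise_sd = 2, cell_contrast = 140) {
  stopifnot(blur_scale > 0, pixel_size > 0, all(image_size >= 8))
  structure(list(image_size = as.integer(image_size),
                 pixel_size = pixel_size, focal_offset = focal_offset,
                 blur_scale = blur_scale, depth_penalty = depth_penalty,
                 base_sigma = base_sigma, noise_sd = noise_sd,
                 cell_contrast = cell_contrast),
            class = "render_model")
}

as_leds <- function(leds) {
  if (is.null(leds)) leds <- c(0, 0, 0, 0)
  leds <- as.numeric(leds)
  stopifnot(length(leds) == 4)
  if (any(leds < 0 | leds > 255)) stop("LED channels must be in [0, 255]")
  names(leds) <- c("r", "g", "b", "w")
  leds
}

# per-channel background gray level for a given LED state; a dim ambient
# floor keeps unlit frames renderable
led_background <- function(leds) {
  leds <- as_leds(leds)
  chan <- pmin(leds[c("r", "g", "b")] + leds["w"], 255)
  30 + 170 * chan / 255
}

#' Camera z height at which a cell is in focus
#'
#' @param render a [render_model()].
#' @param scn a [scene()].
#' @param z_um cell height above the well bottom, µm.
#' @return camera z in mm.
#' @export
focus_height_for_depth <- function(render, scn, z_um) {
  render$focal_offset - (scn$column_depth_um - z_um) / 1000
}

#' Render one bright-field frame
#'
#' @param scn a [scene()].
#' @param render a [render_model()].
#' @param z camera height, mm (scalar or a list with `$z`).
#' @param leds RGBW vector `c(r, g, b, w)`, 0..255.
#' @param t scene time, s (illumination assumed constant since t = 0).
#' @return h x w x 3 array, 0..255. Uses the current RNG stream for pixel
#'   noise.
#' @export
render_frame <- function(scn, render, z = NULL, leds = c(0, 0, 0, 255),
                         t = 0) {
  if (is.list(z)) z <- z$z
  if (is.null(z)) z <- render$focal_offset
  w <- render$image_size[1]; h <- render$image_size[2]
  leds <- as_leds(leds)
  bg <- led_background(leds)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]

  cells <- cells_at_time(scn, t, leds)
  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      cx <- cells$x_um[i] / render$pixel_size + 0.5  # 1-based px centre
      cy <- cells$y_um[i] / render$pixel_size + 0.5
      R <- cells$radius_um[i] / render$pixel_size
      depth_mm <- (scn$column_depth_um - cells$z_um[i]) / 1000
      defocus <- abs(z - focus_height_for_depth(render, scn, cells$z_um[i]))
      sigma <- render$base_sigma + render$blur_scale * defocus +
        render$depth_penalty * depth_mm
      s <- 0.55 * sigma  # logistic edge scale tracking the blur
      win <- ceiling(R + 6 * s + 2)
      r0 <- max(1, floor(cy - win)); r1 <- min(h, ceiling(cy + win))
      c0 <- max(1, floor(cx - win)); c1 <- min(w, ceiling(cx + win))
      if (r0 > r1 || c0 > c1) next  # cell outside the frame
      rows <- r0:r1; cols <- c0:c1
      d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
      mask <- stats::plogis((R - d) / s)
      # defocus also washes out contrast so far-out-of-focus cells fade
      amp <- render$cell_contrast / (1 + 0.6 * (sigma - render$base_sigma))
      col_rgb <- c(cells$r[i], cells$g[i], cells$b[i]) / 255
      for (ch in 1:3) {
        target <- bg[ch] - amp * (0.35 + 0.65 * (1 - col_rgb[ch]))
        img[rows, cols, ch] <- img[rows, cols, ch] +
          mask * (target - img[rows, cols, ch])
      }
    }
  }
  if (render$noise_sd > 0) {
    noise <- matrix(stats::rnorm(h * w, 0, render$noise_sd), h, w)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
  }
  clip255(img)
}

#' Render a frame sequence
#'
#' `ceiling(duration * fps)` frames with the scene advanced by 1/fps
#' between frames, illumination held constant.
#'
#' @inheritParams render_frame
#' @param duration seconds of video.
#' @param fps frame rate, Hz.
#' @param t0 scene time of the first frame, s.
#' @return list of h x w x 3 arrays.
#' @export
capture_video <- function(scn, render, z = NULL, leds = c(0, 0, 0, 255),
                          duration = 1, fps = 30, t0 = 0) {
  stopifnot(fps > 0)
  n <- ceiling(duration * fps)
  lapply(seq_len(n) - 1L, function(k)
    render_frame(scn, render, z = z, leds = leds, t = t0 + k / fps))
}
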