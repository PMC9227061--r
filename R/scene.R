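#' Synthetic liquid scene
#'
#' Ground-truth world imaged by the virtual camera: motile cells suspended
#' in a liquid column inside one well. Scene coordinates are micrometres
#' with (0, 0) at the top-left corner of the camera field of view; z runs
#' from 0 (well bottom) to `column_depth_um` (liquid surface). Cells drift
#' with constant velocity; while any photoresponse trigger channel is lit
#' their speed decays exponentially with time constant `tau` (flagellar
#' adhesion under blue/white light; red light leaves motion untouched).
#'
#' @param cells data.frame with columns `x_um`, `y_um`, `z_um`,
#'   `radius_um`, `vx_um_s`, `vy_um_s`, `r`, `g`, `b` (0..255 base color).
#' @param column_depth_um liquid column height, µm.
#' @param fov_um field-of-view extent `c(w, h)` in µm (cells wrap
#'   toroidally inside it so they never leave the frame).
#' @param photoresponse list with `trigger` (subset of `c("b", "w")`) and
#'   `tau` (s); `NULL` disables the light response.
#' @return object of class `scene`.
#' @export
scene <- function(cells, column_depth_um = 3000, fov_um = c(128, 128),
                  photoresponse = list(trigger = c("b", "w"), tau = 60)) {
  stopifnot(all(cells$radius_um > 0),
            all(cells$z_um >= 0 & cells$z_um <= column_depth_um))
  structure(list(cells = cells, column_depth_um = column_depth_um,
                 fov_um = fov_um, photoresponse = photoresponse),
            class = "scene")
}

#' Generate a random scene of motile cells
#'
#' Cells are placed uniformly in the field of view with a minimum
#' centre-to-centre separation (rejection sampling), at a common or random
#' depth, with uniformly distributed diameters and speeds in the given
#' ranges and uniform random heading. Defaults emulate a *C. reinhardtii*
#' culture (diameters 5-12 µm).
#'
#' @param n_cells number of cells.
#' @param diameter_um range `c(lo, hi)` of cell diameters, µm.
#' @param speed_um_s range of cell speeds, µm/s (use `c(0, 0)` for a static
#'   scene).
#' @param depth_um depth(s) of the cells: a single value places all cells
#'   in one layer; a range samples uniformly.
#' @param column_depth_um,fov_um,photoresponse see [scene()].
#' @param min_separation_um minimum centre distance between cells; default
#'   1.2 x the maximum diameter keeps cells non-overlapping.
#' @param margin_um keep-out border inside the field of view.
#' @return a [scene()].
#' @export
make_scene <- function(n_cells = 25, diameter_um = c(5, 12),
                       speed_um_s = c(10, 30), depth_um = 2950,
                       column_depth_um = 3000, fov_um = c(128, 128),
                       photoresponse = list(trigger = c("b", "w"), tau = 60),
                       min_separation_um = NULL, margin_um = NULL) {
  rad <- runif(n_cells, diameter_um[1] / 2, diameter_um[2] / 2)
  margin_um <- margin_um %||% (max(diameter_um) / 2 + 4)
  min_sep <- min_separation_um %||% (1.2 * max(diameter_um))
  xs <- ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_cells) {
    px <- runif(1, margin_um, fov_um[1] - margin_um)
    py <- runif(1, margin_um, fov_um[2] - margin_um)
    if (!length(xs) || min(sqrt((xs - px)^2 + (ys - py)^2)) >= min_sep) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
    tries <- tries + 1
    if (tries > 20000 * n_cells)
      stop("could not place ", n_cells, " cells with the requested separation")
  }
  sp <- runif(n_cells, speed_um_s[1], speed_um_s[2])
  th <- runif(n_cells, 0, 2 * pi)
  z <- if (length(depth_um) == 1) rep(depth_um, n_cells)
       else runif(n_cells, depth_um[1], depth_um[2])
  cells <- data.frame(
    x_um = xs, y_um = ys, z_um = z, radius_um = rad,
    vx_um_s = sp * cos(th), vy_um_s = sp * sin(th),
    r = round(runif(n_cells, 40, 90)),
    g = round(runif(n_cells, 90, 150)),
    b = round(runif(n_cells, 30, 70))
  )
  scene(cells, column_depth_um = column_depth_um, fov_um = fov_um,
        photoresponse = photoresponse)
}

photoresponse_active <- function(scn, leds) {
  pr <- scn$photoresponse
  if (is.null(pr)) return(FALSE)
  leds <- as_leds(leds)
  any(leds[pr$trigger] > 0)
}

#' Cell positions and speeds at a time point
#'
#' Advances the scene kinematics to time `t` under constant illumination
#' `leds` since t = 0. Under a lit trigger channel the displacement is the
#' closed-form integral of the exponentially decaying speed,
#' v * tau * (1 - exp(-t/tau)), and the instantaneous speed carries the
#' factor exp(-t/tau). Positions wrap toroidally inside the field of view.
#'
#' @param scn a [scene()].
#' @param t time, s.
#' @param leds RGBW vector `c(r, g, b, w)`.
#' @return data.frame of cells with updated `x_um`, `y_um` and an added
#'   `speed_um_s` (instantaneous ground-truth speed).
#' @export
cells_at_time <- function(scn, t, leds = c(0, 0, 0, 0)) {
  cells <- scn$cells
  if (photoresponse_active(scn, leds)) {
    tau <- scn$photoresponse$tau
    eff_t <- tau * (1 - exp(-t / tau))
    fac <- exp(-t / tau)
  } else {
    eff_t <- t
    fac <- 1
  }
  cells$x_um <- (cells$x_um + cells$vx_um_s * eff_t) %% scn$fov_um[1]
  cells$y_um <- (cells$y_um + cells$vy_um_s * eff_t) %% scn$fov_um[2]
  cells$speed_um_s <- sqrt(cells$vx_um_s^2 + cells$vy_um_s^2) * fac
  cells
}

#' Ground truth of a scene as seen by a render model
#'
#' @param scn a [scene()].
#' @param render a [render_model()].
#' @param t time, s.
#' @param leds RGBW vector.
#' @return data.frame with true pixel-frame centroids (`x_px`, `y_px`,
#'   1-based pixel centres), diameters in µm and px, and speeds in µm/s.
#' @export
scene_truth <- function(scn, render, t = 0, leds = c(0, 0, 0, 0)) {
  cells <- cells_at_time(scn, t, leds)
  data.frame(
    id = seq_len(nrow(cells)),
    x_px = cells$x_um / render$pixel_size + 0.5,
    y_px = cells$y_um / render$pixel_size + 0.5,
    diameter_um = 2 * cells$radius_um,
    diameter_px = 2 * cells$radius_um / render$pixel_size,
    z_um = cells$z_um,
    speed_um_s = cells$speed_um_s
  )
}
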