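#' Image sharpness: variance of the Laplacian
#'
#' The focus measure used throughout: the image is converted to grayscale,
#' convolved with the 3x3 discrete Laplacian, and the variance of the
#' response is returned. Zero for a constant image; invariant to adding a
#' constant gray level; larger for sharper edges.
#'
#' @param img grayscale matrix or RGB array, 0..255.
#' @return nonnegative scalar.
#' @export
sharpness <- function(img) {
  if (length(img) == 0) stop("cannot measure sharpness of an empty image")
  g <- to_gray(img)
  resp <- laplacian_response(g)
  stats::var(as.vector(resp)) * (length(resp) - 1) / length(resp)
}

#' Autofocus search parameters
#'
#' Defaults encode the two-phase procedure: start 0.5 mm above the
#' theoretical focus, descend 10 times by 0.1 mm scoring each height
#' (coarse phase, 1 mm total displacement), recentre 0.05 mm above the
#' coarse optimum and descend 10 times by 0.01 mm (fine phase). 20
#' sharpness evaluations in total.
#'
#' @param start_above mm above the theoretical focus to start.
#' @param coarse_step,coarse_n coarse descent step (mm) and count.
#' @param fine_recenter mm above the coarse optimum to restart.
#' @param fine_step,fine_n fine descent step (mm) and count.
#' @return object of class `focus_params`.
#' @export
focus_params <- function(start_above = 0.5, coarse_step = 0.1,
                         coarse_n = 10, fine_recenter = 0.05,
                         fine_step = 0.01, fine_n = 10) {
  stopifnot(start_above > 0, coarse_step > 0, coarse_n > 0,
            fine_recenter > 0, fine_step > 0, fine_n > 0,
            fine_step < coarse_step,
            coarse_n * coarse_step >= 2 * fine_recenter)
  structure(list(start_above = start_above, coarse_step = coarse_step,
                 coarse_n = as.integer(coarse_n),
                 fine_recenter = fine_recenter, fine_step = fine_step,
                 fine_n = as.integer(fine_n)), class = "focus_params")
}

# argmax with ties broken toward the highest camera position
argmax_highest <- function(heights, scores) {
  best <- which(scores == max(scores))
  heights[best[which.max(heights[best])]]
}

#' Two-phase coarse-to-fine autofocus
#'
#' Phase 1 starts `start_above` mm above the theoretical focus and descends
#' `coarse_n` times by `coarse_step`, scoring the image at each height with
#' [sharpness()]. Phase 2 restarts `fine_recenter` mm above the coarse
#' argmax and descends `fine_n` times by `fine_step`. The chosen height is
#' the global argmax over all evaluations; ties go to the highest camera
#' position (preferring the upper liquid layer). Exactly
#' `coarse_n + fine_n` captures are made regardless of image content.
#'
#' @param capture_at function(height_mm) returning an image.
#' @param theoretical_focus expected focus height, mm (e.g. from
#'   [focus_from_volume()]).
#' @param params a [focus_params()].
#' @param z_range heights are clamped to this interval (stage travel), mm.
#' @return object of class `focus_sweep`: list with `evaluations`
#'   (data.frame height, sharpness, phase), `best_height`, `n_evaluations`.
#' @export
autofocus <- function(capture_at, theoretical_focus,
                      params = focus_params(), z_range = c(0, 240)) {
  clamp <- function(z) pmin(pmax(z, z_range[1]), z_range[2])
  score_at <- function(h, phase) {
    img <- tryCatch(capture_at(h), error = function(e)
      stop(sprintf("capture failed at height %.3f mm: %s", h,
                   conditionMessage(e)), call. = FALSE))
    data.frame(height = h, sharpness = sharpness(img), phase = phase)
  }
  start <- theoretical_focus + params$start_above
  coarse_h <- clamp(start - seq_len(params$coarse_n) * params$coarse_step)
  ev <- do.call(rbind, lapply(coarse_h, score_at, phase = "coarse"))
  coarse_best <- argmax_highest(ev$height, ev$sharpness)
  fine_start <- clamp(coarse_best + params$fine_recenter)
  fine_h <- clamp(fine_start - seq_len(params$fine_n) * params$fine_step)
  ev <- rbind(ev, do.call(rbind, lapply(fine_h, score_at, phase = "fine")))
  structure(list(
    evaluations = ev,
    best_height = argmax_highest(ev$height, ev$sharpness),
    n_evaluations = nrow(ev),
    theoretical_focus = theoretical_focus
  ), class = "focus_sweep")
}

#' Theoretical focus height from the sample volume
#'
#' The robot knows the dispensed volume; the liquid column height is
#' volume / well cross-section and the camera focuses on the column top.
#'
#' @param volume_ml sample volume, mL.
#' @param well_diameter_mm well diameter, mm.
#' @param bottom_focus_z camera height at which the well bottom is in
#'   focus, mm.
#' @return camera height focusing the liquid surface, mm.
#' @export
focus_from_volume <- function(volume_ml, well_diameter_mm,
                              bottom_focus_z = 0) {
  stopifnot(volume_ml > 0, well_diameter_mm > 0)
  column_mm <- volume_ml * 1000 / (pi * (well_diameter_mm / 2)^2)
  bottom_focus_z + column_mm
}

#' Run the autofocus on a virtual device
#'
#' Wires [autofocus()] to a [virtual_device()]: each evaluation moves the
#' stage in z and captures a frame, then the stage is sent to the chosen
#' height.
#'
#' @param dev a [virtual_device()].
#' @param theoretical_focus expected focus height, mm; defaults to the
#'   scene's liquid-surface focus height.
#' @param params a [focus_params()].
#' @return a `focus_sweep`.
#' @export
device_autofocus <- function(dev, theoretical_focus = NULL,
                             params = focus_params()) {
  if (is.null(theoretical_focus))
    theoretical_focus <- dev$render$focal_offset
  sweep <- autofocus(function(h) {
    device_move_to(dev, z = h)
    device_capture(dev)
  }, theoretical_focus, params,
  z_range = c(0, unname(working_volume["z"])))
  device_move_to(dev, z = sweep$best_height)
  sweep
}

#' @export
print.focus_sweep <- function(x, ...) {
  cat(sprintf("<focus_sweep> %d evaluations, best height %.3f mm (theoretical %.3f mm)\n",
              x$n_evaluations, x$best_height, x$theoretical_focus))
  invisible(x)
}
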