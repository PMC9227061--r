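#' Track a single cell through a video
#'
#' Propagates a user-supplied seed point frame to frame with pyramidal
#' Lucas-Kanade optical flow, with a forward-backward consistency check:
#' the point is also tracked backwards and the track terminates early
#' (flagged) when the round trip misses by more than `fb_threshold` px or
#' the flow is untrackable. Speeds are converted to µm/s through the
#' calibration and frame rate.
#'
#' @param frames list of frames (grayscale matrices or RGB arrays, 0..255).
#' @param seed starting point `c(x, y)`, 1-based px in frame 1.
#' @param cal a [calibration()].
#' @param fps frame rate, Hz.
#' @param win LK window half-size, px.
#' @param levels pyramid levels.
#' @param fb_threshold forward-backward error tolerance, px.
#' @return object of class `cell_track`: list with `points` (data.frame
#'   t_s, x_px, y_px, speed_um_s), `mean_speed_um_s` (mean per-step
#'   speed), `net_speed_um_s` (net displacement / elapsed time),
#'   `terminated_early`, `n_frames_tracked`.
#' @export
track_cell <- function(frames, seed, cal, fps = 30, win = 7, levels = 3,
                       fb_threshold = 1) {
  stopifnot(length(frames) >= 2, fps > 0)
  gs <- lapply(frames, to_gray)
  pyrs <- lapply(gs, build_pyramid, levels = levels)
  p <- as.numeric(seed)
  pts <- data.frame(t_s = 0, x_px = p[1], y_px = p[2],
                    speed_um_s = NA_real_)
  terminated <- FALSE
  for (k in seq_len(length(gs) - 1)) {
    fwd <- lk_flow_pyr(pyrs[[k]], pyrs[[k + 1]], p, win = win)
    if (!fwd$ok) { terminated <- TRUE; break }
    q <- p + fwd$d
    bwd <- lk_flow_pyr(pyrs[[k + 1]], pyrs[[k]], q, win = win)
    if (!bwd$ok || sqrt(sum((fwd$d + bwd$d)^2)) > fb_threshold) {
      terminated <- TRUE; break
    }
    step_um_s <- sqrt(sum(fwd$d^2)) * cal$um_per_px * fps
    pts <- rbind(pts, data.frame(t_s = k / fps, x_px = q[1], y_px = q[2],
                                 speed_um_s = step_um_s))
    p <- q
  }
  steps <- pts$speed_um_s[-1]
  net <- if (nrow(pts) > 1) {
    sqrt((pts$x_px[nrow(pts)] - pts$x_px[1])^2 +
           (pts$y_px[nrow(pts)] - pts$y_px[1])^2) *
      cal$um_per_px / pts$t_s[nrow(pts)]
  } else NA_real_
  structure(list(points = pts,
                 mean_speed_um_s = if (length(steps)) mean(steps) else NA_real_,
                 net_speed_um_s = net,
                 terminated_early = terminated,
                 n_frames_tracked = nrow(pts)), class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> %d frames%s, mean speed %.2f um/s (net %.2f um/s)\n",
              x$n_frames_tracked,
              if (x$terminated_early) " (terminated early)" else "",
              x$mean_speed_um_s, x$net_speed_um_s))
  invisible(x)
}

#' Write a track as CSV
#'
#' Columns t_s, x_px, y_px, speed_um_s (per-step; empty for the seed row).
#'
#' @param track a `cell_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(track$points, path, row.names = FALSE)
  invisible(path)
}

#' Whole-field motion between consecutive frames
#'
#' Lucas-Kanade flow evaluated on a regular grid of stride `stride` px for
#' every consecutive frame pair; grid points whose neighbourhood carries no
#' texture (uniform background) or whose forward-backward round trip is
#' inconsistent (occlusions, cells leaving the field) are dropped from the
#' summary. The per-pair mean speed is the mean flow magnitude over the
#' surviving points, converted to µm/s.
#'
#' @param frames list of >= 2 frames.
#' @param cal a [calibration()].
#' @param fps frame rate, Hz.
#' @param stride grid spacing, px.
#' @param win LK window half-size, px.
#' @param levels pyramid levels.
#' @param fb_threshold forward-backward error tolerance, px.
#' @return object of class `flow_field`: list with `fields` (one
#'   data.frame x, y, u, v, ok per frame pair), `summary` (data.frame t_s,
#'   mean_speed_um_s, n_points), `mean_speed_um_s`, `dominant_direction`
#'   (radians, atan2 of the total displacement).
#' @export
flow_field <- function(frames, cal, fps = 30, stride = 16, win = 7,
                       levels = 3, fb_threshold = 1) {
  stopifnot(length(frames) >= 2)
  gs <- lapply(frames, to_gray)
  pyrs <- lapply(gs, build_pyramid, levels = levels)
  h <- nrow(gs[[1]]); w <- ncol(gs[[1]])
  xs <- seq(max(win + 2, stride %/% 2), w - win - 2, by = stride)
  ys <- seq(max(win + 2, stride %/% 2), h - win - 2, by = stride)
  grid <- expand.grid(x = xs, y = ys)
  fields <- vector("list", length(gs) - 1)
  summ <- data.frame(t_s = numeric(), mean_speed_um_s = numeric(),
                     n_points = integer())
  tot_u <- 0; tot_v <- 0
  for (k in seq_len(length(gs) - 1)) {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      p <- c(grid$x[i], grid$y[i])
      fwd <- lk_flow_pyr(pyrs[[k]], pyrs[[k + 1]], p, win = win)
      if (fwd$ok) {
        bwd <- lk_flow_pyr(pyrs[[k + 1]], pyrs[[k]], p + fwd$d, win = win)
        fwd$ok <- bwd$ok &&
          sqrt(sum((fwd$d + bwd$d)^2)) <= fb_threshold
      }
      fwd
    })
    f <- data.frame(x = grid$x, y = grid$y,
                    u = vapply(res, function(r) r$d[1], numeric(1)),
                    v = vapply(res, function(r) r$d[2], numeric(1)),
                    ok = vapply(res, function(r) r$ok, logical(1)))
    fields[[k]] <- f
    okf <- f[f$ok, , drop = FALSE]
    sp <- if (nrow(okf)) mean(sqrt(okf$u^2 + okf$v^2)) *
      cal$um_per_px * fps else 0
    tot_u <- tot_u + sum(okf$u); tot_v <- tot_v + sum(okf$v)
    summ <- rbind(summ, data.frame(t_s = (k - 0.5) / fps,
                                   mean_speed_um_s = sp,
                                   n_points = nrow(okf)))
  }
  structure(list(fields = fields, summary = summ,
                 mean_speed_um_s = mean(summ$mean_speed_um_s),
                 dominant_direction = atan2(tot_v, tot_u)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d frame pairs, mean speed %.2f um/s\n",
              length(x$fields), x$mean_speed_um_s))
  invisible(x)
}

#' Windowed mean speed over a video
#'
#' Dense-flow speeds of consecutive frame pairs averaged in consecutive
#' time windows — the curve used to watch motility arrest or a speed ramp.
#'
#' @param frames list of frames.
#' @param cal a [calibration()].
#' @param fps frame rate, Hz.
#' @param window window length, s (>= 2/fps).
#' @param ... passed to [flow_field()].
#' @return data.frame with `t_s` (window centre) and `mean_speed_um_s`.
#' @export
speed_timeseries <- function(frames, cal, fps = 30, window = 1, ...) {
  stopifnot(window >= 2 / fps)
  ff <- flow_field(frames, cal, fps = fps, ...)
  s <- ff$summary
  bin <- floor(s$t_s / window)
  out <- do.call(rbind, lapply(split(s, bin), function(d)
    data.frame(t_s = mean(d$t_s),
               mean_speed_um_s = mean(d$mean_speed_um_s))))
  rownames(out) <- NULL
  out
}

#' Burn a flow field into a frame as green vectors
#'
#' Vector length is proportional to the flow magnitude (scaled by
#' `scale`), mirroring the live overlay of the whole-field analysis.
#'
#' @param frame RGB array or grayscale matrix.
#' @param field one element of `flow_field()$fields`.
#' @param scale px of line per px/frame of flow.
#' @return RGB array with the overlay.
#' @export
draw_flow_overlay <- function(frame, field, scale = 5) {
  img <- if (length(dim(frame)) == 3) frame else
    array(rep(frame, 3), dim = c(nrow(frame), ncol(frame), 3))
  h <- dim(img)[1]; w <- dim(img)[2]
  f <- field[field$ok, , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    n <- max(2, ceiling(scale * sqrt(f$u[i]^2 + f$v[i]^2)))
    tt <- seq(0, 1, length.out = n)
    cx <- round(f$x[i] + tt * scale * f$u[i])
    cy <- round(f$y[i] + tt * scale * f$v[i])
    keep <- cx >= 1 & cx <= w & cy >= 1 & cy <= h
    img[cbind(cy[keep], cx[keep], 1)] <- 0
    img[cbind(cy[keep], cx[keep], 2)] <- 255
    img[cbind(cy[keep], cx[keep], 3)] <- 0
  }
  img
}
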