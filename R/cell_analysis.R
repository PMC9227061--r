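#' Pixel-size calibration
#'
#' Conversion between image pixels and physical micrometres for a given
#' lens and camera resolution. The 2.8 mm lens at 1920 x 1080 calibrates to
#' 0.5 µm/px; rescaling to 720p gives 0.75 µm/px.
#'
#' @param um_per_px micrometres per pixel.
#' @param image_size `c(w, h)` px the calibration was made at.
#' @param lens_focal_length mm, informational.
#' @return object of class `calibration`.
#' @export
calibration <- function(um_per_px, image_size = c(1920, 1080),
                        lens_focal_length = NA_real_) {
  stopifnot(um_per_px > 0)
  structure(list(um_per_px = um_per_px, image_size = as.integer(image_size),
                 lens_focal_length = lens_focal_length),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4g um/px at %d x %d\n", x$um_per_px,
              x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Calibrate from a graduated reference slide
#'
#' Estimates µm/px from an image of a calibration slide with parallel
#' graduation lines of known spacing. The mean-intensity profile is
#' projected perpendicular to the lines (the projection angle is chosen to
#' maximize profile contrast, tolerating a slightly rotated slide), dark
#' graduations are located as profile minima, and the median spacing of
#' adjacent graduations converts the known division into µm/px.
#'
#' @param slide_image image of the slide (matrix or RGB array, 0..255).
#' @param division_um physical distance between adjacent graduations, µm.
#' @param angle_range_deg search range for the line angle, degrees.
#' @param lens_focal_length stored in the result, informational.
#' @return a [calibration()].
#' @export
calibrate <- function(slide_image, division_um,
                      angle_range_deg = c(-10, 10),
                      lens_focal_length = NA_real_) {
  g <- to_gray(slide_image)
  h <- nrow(g); w <- ncol(g)
  rr <- as.vector(row(g)); cc <- as.vector(col(g)); v <- as.vector(g)
  profile_at <- function(a_deg) {
    a <- a_deg * pi / 180
    u <- cc * cos(a) + rr * sin(a)
    b <- as.integer(round(u - min(u))) + 1L
    cnt <- tabulate(b)
    s <- rowsum(v, b)
    keep <- cnt >= 0.5 * max(cnt)  # drop sparse corner bins
    list(profile = (s / cnt)[keep], ok = keep)
  }
  angles <- seq(angle_range_deg[1], angle_range_deg[2], by = 0.5)
  contrast <- vapply(angles, function(a) stats::var(profile_at(a)$profile),
                     numeric(1))
  best_a <- angles[which.max(contrast)]
  p <- profile_at(best_a)$profile
  # graduations are dark: find runs where the dip exceeds half the range
  q <- max(p) - p
  thr <- 0.5 * max(q)
  above <- q > thr
  edges <- diff(c(FALSE, above, FALSE))
  starts <- which(edges == 1); ends <- which(edges == -1) - 1
  centers <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    sum(seg * q[seg]) / sum(q[seg])
  }, numeric(1))
  if (max(q) < 20)
    stop("calibration error: no graduations with sufficient contrast")
  if (length(centers) < 2)
    stop("calibration error: fewer than 2 graduations detected")
  spacing <- stats::median(diff(centers))
  calibration(division_um / spacing, image_size = c(w, h),
              lens_focal_length = lens_focal_length)
}

#' Rescale a calibration to a new camera resolution
#'
#' With the same lens and sensor, halving the vertical resolution doubles
#' the pixel size: um_per_px scales by old_height / new_height.
#'
#' @param cal a [calibration()].
#' @param new_size `c(w, h)` px.
#' @return a [calibration()] at the new resolution.
#' @export
rescale_calibration <- function(cal, new_size) {
  new_size <- as.integer(new_size)
  calibration(cal$um_per_px * cal$image_size[2] / new_size[2],
              image_size = new_size,
              lens_focal_length = cal$lens_focal_length)
}

#' Segmentation parameters
#'
#' @param gray_threshold binarization threshold 0..255; `NULL` selects it
#'   per image by Otsu's method.
#' @param erosion_iterations morphological passes applied to the binary
#'   mask to connect nearby pixels and close the cells.
#' @param erosion_kernel structuring-element side, px (odd).
#' @param min_area smallest contour area kept, px^2.
#' @param morph `"close"` (closing: connects and fills without biasing
#'   sizes) or `"dilate"` (net foreground growth).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(gray_threshold = NULL,
                                erosion_iterations = 1,
                                erosion_kernel = 3, min_area = 50,
                                morph = c("close", "dilate")) {
  if (!is.null(gray_threshold))
    stopifnot(gray_threshold >= 0, gray_threshold <= 255)
  stopifnot(erosion_iterations >= 0, min_area >= 0,
            erosion_kernel %% 2 == 1)
  structure(list(gray_threshold = gray_threshold,
                 erosion_iterations = as.integer(erosion_iterations),
                 erosion_kernel = as.integer(erosion_kernel),
                 min_area = min_area, morph = match.arg(morph)),
            class = "segmentation_params")
}

#' Binarize a micrograph
#'
#' Grayscale conversion, inverted binary threshold (bright-field cells are
#' darker than background, so pixels below the threshold become foreground
#' 255 and the rest 0), then `erosion_iterations` morphological passes to
#' connect nearby foreground pixels and close the cells.
#'
#' @param img image, 0..255.
#' @param params a [segmentation_params()].
#' @return binary integer matrix (1 = foreground cell, 0 = background).
#' @export
segment <- function(img, params = segmentation_params()) {
  g <- to_gray(img)
  thr <- params$gray_threshold
  if (is.null(thr)) thr <- EBImage::otsu(g / 255, range = c(0, 1)) * 255
  mask <- matrix(as.numeric(g < thr), nrow(g), ncol(g))
  if (params$erosion_iterations > 0 && any(mask > 0)) {
    brush <- EBImage::makeBrush(params$erosion_kernel, shape = "box")
    op <- if (params$morph == "close") EBImage::closing else EBImage::dilate
    for (i in seq_len(params$erosion_iterations)) mask <- op(mask, brush)
  }
  structure(matrix(as.integer(mask > 0), nrow(g), ncol(g)),
            gray_threshold = thr)
}

#' Detect and measure cells in a binary mask
#'
#' Connected components of the mask are extracted; components smaller than
#' `min_area` px^2 (dust, artifacts) are discarded; each survivor is
#' measured by its axis-aligned bounding box and centroid, converted to
#' micrometres through the calibration, with the mean RGB color sampled
#' under the component when the original image is supplied. When the
#' original image is given the box edges are localized to sub-pixel
#' precision by interpolating the gray profile at the binarization
#' threshold, which removes the ~1 px bias of raw pixel counts. An annotated
#' copy of the input (bounding boxes burned in, detection count in the
#' `"n_cells"` attribute) accompanies the records.
#'
#' @param mask binary matrix from [segment()].
#' @param cal a [calibration()].
#' @param min_area px^2 below which a component is discarded.
#' @param img optional original image for color measurement/annotation.
#' @return list with `records` (data.frame: id, centroid_x_px,
#'   centroid_y_px, width_um, height_um, area_px, area_um2, r, g, b) and
#'   `annotated` (RGB array).
#' @export
detect_cells <- function(mask, cal, min_area = 50, img = NULL) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  empty <- data.frame(id = integer(), centroid_x_px = numeric(),
                      centroid_y_px = numeric(), width_um = numeric(),
                      height_um = numeric(), area_px = numeric(),
                      area_um2 = numeric(), r = numeric(), g = numeric(),
                      b = numeric())
  base_img <- if (!is.null(img) && length(dim(img)) == 3) img else {
    gm <- if (is.null(img)) mask * 255 else to_gray(img)
    array(rep(gm, 3), dim = c(nrow(mask), ncol(mask), 3))
  }
  if (n == 0)
    return(list(records = empty, annotated = structure(base_img,
                                                       n_cells = 0L)))
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- as.vector(tapply(rows, labs, length))
  keep <- which(area >= min_area)
  if (!length(keep))
    return(list(records = empty, annotated = structure(base_img,
                                                       n_cells = 0L)))
  agg <- function(v, f) as.vector(tapply(v, labs, f))[keep]
  rmin <- agg(rows, min); rmax <- agg(rows, max)
  cmin <- agg(cols, min); cmax <- agg(cols, max)
  upp <- cal$um_per_px

  # sub-pixel bounding-box extents: where the original grayscale and the
  # binarization threshold are known, the true edge position is found by
  # linear interpolation of the gray profile across the outermost
  # foreground pixels (removing the ~1 px quantization of pixel counts);
  # otherwise the box spans the outer pixel edges
  gray <- if (!is.null(img)) to_gray(img) else NULL
  thr <- attr(mask, "gray_threshold")
  edge_off <- function(g_in, g_out) {
    ok <- g_out > g_in & g_in < thr & g_out >= thr
    if (!any(ok)) return(0.5)
    mean(pmin(pmax((thr - g_in[ok]) / (g_out[ok] - g_in[ok]), 0), 1))
  }
  width_px <- cmax - cmin + 1
  height_px <- rmax - rmin + 1
  if (!is.null(gray) && !is.null(thr)) {
    h <- nrow(mask); w <- ncol(mask)
    for (i in seq_along(keep)) {
      sel <- labs == keep[i]
      rr <- rows[sel]; cc <- cols[sel]
      right <- if (cmax[i] < w)
        edge_off(gray[cbind(rr[cc == cmax[i]], cmax[i])],
                 gray[cbind(rr[cc == cmax[i]], cmax[i] + 1)]) else 0.5
      left <- if (cmin[i] > 1)
        edge_off(gray[cbind(rr[cc == cmin[i]], cmin[i])],
                 gray[cbind(rr[cc == cmin[i]], cmin[i] - 1)]) else 0.5
      bottom <- if (rmax[i] < h)
        edge_off(gray[cbind(rmax[i], cc[rr == rmax[i]])],
                 gray[cbind(rmax[i] + 1, cc[rr == rmax[i]])]) else 0.5
      top <- if (rmin[i] > 1)
        edge_off(gray[cbind(rmin[i], cc[rr == rmin[i]])],
                 gray[cbind(rmin[i] - 1, cc[rr == rmin[i]])]) else 0.5
      width_px[i] <- (cmax[i] - cmin[i]) + left + right
      height_px[i] <- (rmax[i] - rmin[i]) + top + bottom
    }
  }
  mean_chan <- function(ch) {
    if (length(dim(base_img)) != 3) return(rep(NA_real_, length(keep)))
    m <- base_img[, , ch]
    as.vector(tapply(m[idx], labs, mean))[keep]
  }
  records <- data.frame(
    id = seq_along(keep),
    centroid_x_px = agg(cols, mean),
    centroid_y_px = agg(rows, mean),
    width_um = width_px * upp,
    height_um = height_px * upp,
    area_px = area[keep],
    area_um2 = area[keep] * upp^2,
    r = round(mean_chan(1), 1),
    g = round(mean_chan(2), 1),
    b = round(mean_chan(3), 1)
  )
  ann <- base_img
  for (i in seq_along(keep)) {
    r0 <- max(1, rmin[i] - 1); r1 <- min(nrow(mask), rmax[i] + 1)
    c0 <- max(1, cmin[i] - 1); c1 <- min(ncol(mask), cmax[i] + 1)
    ann[c(r0, r1), c0:c1, 1] <- 0; ann[c(r0, r1), c0:c1, 2] <- 255
    ann[c(r0, r1), c0:c1, 3] <- 0
    ann[r0:r1, c(c0, c1), 1] <- 0; ann[r0:r1, c(c0, c1), 2] <- 255
    ann[r0:r1, c(c0, c1), 3] <- 0
  }
  list(records = records, annotated = structure(ann,
                                                n_cells = nrow(records)))
}

#' Export cell measurements to CSV
#'
#' One row per cell ordered by id, with a header; columns id,
#' centroid_x_px, centroid_y_px, width_um, height_um, area_um2, r, g, b.
#'
#' @param records data.frame from [detect_cells()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_measurements <- function(records, path) {
  cols <- c("id", "centroid_x_px", "centroid_y_px", "width_um",
            "height_um", "area_um2", "r", "g", "b")
  out <- records[order(records$id), intersect(cols, names(records)),
                 drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Full micrograph analysis
#'
#' [segment()] then [detect_cells()], optionally writing the CSV and the
#' annotated image.
#'
#' @param img image, 0..255.
#' @param cal a [calibration()].
#' @param params a [segmentation_params()].
#' @param out_csv,out_image optional output paths.
#' @return list with `records`, `annotated`, `mask`, `n_cells`.
#' @export
analyze_image <- function(img, cal, params = segmentation_params(),
                          out_csv = NULL, out_image = NULL) {
  mask <- segment(img, params)
  det <- detect_cells(mask, cal, min_area = params$min_area, img = img)
  if (!is.null(out_csv)) export_measurements(det$records, out_csv)
  if (!is.null(out_image)) write_image(det$annotated, out_image)
  list(records = det$records, annotated = det$annotated, mask = mask,
       n_cells = nrow(det$records))
}
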