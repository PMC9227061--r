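#' Plate format geometry
#'
#' Describes the physical geometry of one multiwell plate held in portrait
#' orientation on the two-plate holder (short plate edge along the stage X
#' axis, long edge along Y). Defaults follow the ANSI/SLAS microplate
#' footprint (127.76 x 85.48 mm) with the standard well pitches; A1 offsets
#' default to centering the well grid on the plate footprint. All lengths
#' are millimetres.
#'
#' @param wells_per_plate 12, 24 or 96.
#' @param n_cols,n_rows wells per plate along X resp. Y; defaults per format
#'   (12-well: 3 x 4, 24-well: 4 x 6, 96-well: 8 x 12, portrait).
#' @param well_pitch centre-to-centre well spacing in mm (SLAS: 26.01, 19.3,
#'   9.0 for 12/24/96 wells).
#' @param a1_offset_x,a1_offset_y centre of well (0,0) relative to the plate
#'   origin (its top-left corner on the holder), mm.
#' @param well_diameter well diameter in mm.
#' @param plate_width plate extent along X (SLAS short side, 85.48 mm).
#' @return An object of class `plate_format`.
#' @export
plate_format <- function(wells_per_plate = 12, n_cols = NULL, n_rows = NULL,
                         well_pitch = NULL, a1_offset_x = NULL,
                         a1_offset_y = NULL, well_diameter = NULL,
                         plate_width = 85.48) {
  std <- switch(as.character(wells_per_plate),
    "12" = list(n_cols = 3L, n_rows = 4L, pitch = 26.01, diam = 22.1),
    "24" = list(n_cols = 4L, n_rows = 6L, pitch = 19.30, diam = 15.6),
    "96" = list(n_cols = 8L, n_rows = 12L, pitch = 9.00, diam = 6.35),
    stop("unsupported plate format: ", wells_per_plate,
         " wells (supported: 12, 24, 96)")
  )
  n_cols <- as.integer(n_cols %||% std$n_cols)
  n_rows <- as.integer(n_rows %||% std$n_rows)
  well_pitch <- well_pitch %||% std$pitch
  well_diameter <- well_diameter %||% std$diam
  plate_length <- 127.76  # SLAS long side, along Y
  a1_offset_x <- a1_offset_x %||% ((plate_width - (n_cols - 1) * well_pitch) / 2)
  a1_offset_y <- a1_offset_y %||% ((plate_length - (n_rows - 1) * well_pitch) / 2)
  if (n_cols * n_rows != wells_per_plate)
    stop("n_cols * n_rows must equal wells_per_plate")
  if (!(well_pitch > well_diameter && well_diameter > 0))
    stop("well_pitch must exceed well_diameter, and well_diameter must be > 0")
  structure(list(
    wells_per_plate = as.integer(wells_per_plate),
    n_cols = n_cols, n_rows = n_rows,
    well_pitch = well_pitch,
    a1_offset_x = a1_offset_x, a1_offset_y = a1_offset_y,
    well_diameter = well_diameter,
    plate_width = plate_width
  ), class = "plate_format")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holder layout: plates on the stage
#'
#' Positions `n_plates` plates side by side along X on the holder. Well
#' addresses use a single 0-based column index `x` continuing across plates
#' (columns 0..n_cols-1 on plate 1, n_cols..2*n_cols-1 on plate 2) and a
#' 0-based row index `y`; (0,0) is the top-left well of plate 1. A custom
#' position table overrides the pitch arithmetic entirely.
#'
#' @param format a [plate_format()].
#' @param n_plates number of plates on the holder (default 2).
#' @param global_offset_x,global_offset_y manual offset in mm added to every
#'   stage coordinate (to compensate support misplacement).
#' @param plate_gap gap between adjacent plate footprints along X, mm.
#' @param custom_positions optional data.frame with columns `x`, `y`
#'   (0-based well address) and `x_mm`, `y_mm` (stage coordinates); when
#'   given it must cover every addressable well.
#' @param working_surface stage working area (x, y) in mm; coordinates are
#'   validated against it.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(format = plate_format(12), n_plates = 2,
                         global_offset_x = 0, global_offset_y = 0,
                         plate_gap = 10, custom_positions = NULL,
                         working_surface = c(220, 220)) {
  layout <- structure(list(
    format = format, n_plates = as.integer(n_plates),
    global_offset_x = global_offset_x, global_offset_y = global_offset_y,
    plate_gap = plate_gap, custom_positions = custom_positions,
    working_surface = working_surface
  ), class = "plate_layout")
  if (!is.null(custom_positions)) {
    need <- c("x", "y", "x_mm", "y_mm")
    if (!all(need %in% names(custom_positions)))
      stop("custom_positions needs columns x, y, x_mm, y_mm")
    all_wells <- enumerate_wells(layout)
    key <- function(d) paste(d$x, d$y)
    if (!all(key(all_wells) %in% key(custom_positions)))
      stop("custom_positions must cover every addressable well")
  }
  pos <- well_to_stage(layout, enumerate_wells(layout))
  if (any(pos$x_mm < 0 | pos$x_mm > working_surface[1] |
          pos$y_mm < 0 | pos$y_mm > working_surface[2]))
    stop("layout places wells outside the working surface")
  layout
}

check_address <- function(layout, x, y) {
  fmt <- layout$format
  nx <- layout$n_plates * fmt$n_cols
  bad_x <- x < 0 | x >= nx
  bad_y <- y < 0 | y >= fmt$n_rows
  if (any(bad_x))
    stop(sprintf("well address x=%d out of range [0, %d] on the x axis",
                 x[which(bad_x)[1]], nx - 1L))
  if (any(bad_y))
    stop(sprintf("well address y=%d out of range [0, %d] on the y axis",
                 y[which(bad_y)[1]], fmt$n_rows - 1L))
  invisible(TRUE)
}

#' Stage coordinates of a well centre
#'
#' Maps one or more well addresses to camera stage coordinates. With a
#' custom position table the stored coordinates (plus the global offset)
#' are returned; otherwise the A1 offset plus pitch arithmetic, with plate
#' k shifted along X by k * (plate_width + plate_gap).
#'
#' @param layout a [plate_layout()].
#' @param addr a length-2 vector `c(x, y)` or a data.frame with columns
#'   `x`, `y` (0-based addresses).
#' @return data.frame with columns `x`, `y`, `x_mm`, `y_mm`.
#' @export
well_to_stage <- function(layout, addr) {
  if (!is.data.frame(addr))
    addr <- data.frame(x = addr[1], y = addr[2])
  addr$x <- as.integer(addr$x); addr$y <- as.integer(addr$y)
  check_address(layout, addr$x, addr$y)
  fmt <- layout$format
  if (!is.null(layout$custom_positions)) {
    cp <- layout$custom_positions
    i <- match(paste(addr$x, addr$y), paste(cp$x, cp$y))
    out <- data.frame(x = addr$x, y = addr$y,
                      x_mm = cp$x_mm[i] + layout$global_offset_x,
                      y_mm = cp$y_mm[i] + layout$global_offset_y)
    return(out)
  }
  plate <- addr$x %/% fmt$n_cols
  col <- addr$x %% fmt$n_cols
  x_mm <- layout$global_offset_x + fmt$a1_offset_x + col * fmt$well_pitch +
    plate * (fmt$plate_width + layout$plate_gap)
  y_mm <- layout$global_offset_y + fmt$a1_offset_y + addr$y * fmt$well_pitch
  data.frame(x = addr$x, y = addr$y, x_mm = x_mm, y_mm = y_mm)
}

#' Enumerate every addressable well
#'
#' Row-major order within each plate ((0,0), (1,0), ..., then row 1, ...),
#' plate 1 before plate 2.
#'
#' @param layout a [plate_layout()].
#' @return data.frame with 0-based columns `x`, `y`,
#'   `n_plates * wells_per_plate` rows.
#' @export
enumerate_wells <- function(layout) {
  fmt <- layout$format
  out <- do.call(rbind, lapply(seq_len(layout$n_plates) - 1L, function(p) {
    g <- expand.grid(col = seq_len(fmt$n_cols) - 1L,
                     y = seq_len(fmt$n_rows) - 1L)
    data.frame(x = g$col + p * fmt$n_cols, y = g$y)
  }))
  rownames(out) <- NULL
  out
}

#' Stage coordinates placing the pipette tip over a well
#'
#' The micropipette tip sits in a fixed holder next to the camera; to centre
#' the tip over a well the stage is sent to the camera coordinate shifted by
#' the camera-to-tip offset.
#'
#' @param layout a [plate_layout()].
#' @param addr well address (vector or data.frame, see [well_to_stage()]).
#' @param tool_offset `c(dx, dy)` in mm from camera centre to tip.
#' @return data.frame as [well_to_stage()].
#' @export
tip_position_for_well <- function(layout, addr, tool_offset = c(30, 0)) {
  pos <- well_to_stage(layout, addr)
  pos$x_mm <- pos$x_mm + tool_offset[1]
  pos$y_mm <- pos$y_mm + tool_offset[2]
  ws <- layout$working_surface
  if (any(pos$x_mm < 0 | pos$x_mm > ws[1]))
    stop("tip position outside working surface on the x axis")
  if (any(pos$y_mm < 0 | pos$y_mm > ws[2]))
    stop("tip position outside working surface on the y axis")
  pos
}

#' Read or write a plate layout as JSON
#'
#' The file holds either `{"format": {...}, "n_plates": ..., "offsets":
#' [dx, dy], "plate_gap": ...}` or `{"custom_positions": [[x_idx, y_idx,
#' x_mm, y_mm], ...]}` (optionally alongside a format block, used then only
#' for addressing bounds).
#'
#' @param path JSON file path.
#' @return [plate_layout()] for `read_plate_layout`; `path`, invisibly, for
#'   `write_plate_layout`.
#' @export
read_plate_layout <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fmt <- if (is.null(j$format)) plate_format(12) else
    do.call(plate_format, as.list(j$format))
  cp <- NULL
  if (!is.null(j$custom_positions)) {
    m <- j$custom_positions
    if (is.list(m)) m <- do.call(rbind, m)
    cp <- data.frame(x = as.integer(m[, 1]), y = as.integer(m[, 2]),
                     x_mm = m[, 3], y_mm = m[, 4])
  }
  off <- j$offsets %||% c(0, 0)
  plate_layout(format = fmt, n_plates = j$n_plates %||% 2,
               global_offset_x = off[1], global_offset_y = off[2],
               plate_gap = j$plate_gap %||% 10, custom_positions = cp)
}

#' @rdname read_plate_layout
#' @param layout a [plate_layout()] to serialize.
#' @export
write_plate_layout <- function(layout, path) {
  fmt <- layout$format
  j <- list(
    format = fmt[c("wells_per_plate", "n_cols", "n_rows", "well_pitch",
                   "a1_offset_x", "a1_offset_y", "well_diameter",
                   "plate_width")],
    n_plates = layout$n_plates,
    offsets = c(layout$global_offset_x, layout$global_offset_y),
    plate_gap = layout$plate_gap
  )
  if (!is.null(layout$custom_positions)) {
    cp <- layout$custom_positions
    j$custom_positions <- unname(as.matrix(cp[, c("x", "y", "x_mm", "y_mm")]))
  }
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.plate_layout <- function(x, ...) {
  fmt <- x$format
  cat(sprintf("<plate_layout> %d x %d-well plate(s), %d x %d grid, pitch %.2f mm\n",
              x$n_plates, fmt$wells_per_plate, fmt$n_cols, fmt$n_rows,
              fmt$well_pitch))
  cat(sprintf("  global offset (%.2f, %.2f) mm, plate gap %.1f mm%s\n",
              x$global_offset_x, x$global_offset_y, x$plate_gap,
              if (!is.null(x$custom_positions)) ", custom positions" else ""))
  invisible(x)
}
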