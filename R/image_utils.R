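#' Image conventions and helpers
#'
#' Images are numeric matrices (grayscale) or h x w x 3 arrays (RGB) on the
#' 8-bit scale 0..255; row = image y, column = image x. `to_gray` applies
#' the standard Rec.601 luma weighting.
#'
#' @param img matrix or h x w x 3 array, 0..255.
#' @return numeric matrix, 0..255.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  stop("expected a matrix or an h x w x 3 array")
}

#' Discrete Laplacian response
#'
#' 3x3 five-point Laplacian of a grayscale image; the one-pixel border is
#' dropped (no padding assumption).
#'
#' @param gray numeric matrix.
#' @return numeric matrix, dimensions reduced by 2.
#' @export
laplacian_response <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3 || w < 3) stop("image too small for a 3x3 Laplacian")
  c0 <- gray[2:(h - 1), 2:(w - 1)]
  gray[1:(h - 2), 2:(w - 1)] + gray[3:h, 2:(w - 1)] +
    gray[2:(h - 1), 1:(w - 2)] + gray[2:(h - 1), 3:w] - 4 * c0
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Read and write 8-bit PNG images
#'
#' Thin wrappers around the png package converting between the package's
#' 0..255 convention and PNG's 0..1.
#'
#' @param img image (matrix or h x w x 3 array, 0..255).
#' @param path file path.
#' @return `read_image`: image on the 0..255 scale; `write_image`: `path`,
#'   invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(clip255(img) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3]  # drop alpha
  x * 255
}

# bilinear sampling of a matrix at fractional (row, col) positions;
# positions outside the support are clamped to the border
bilinear_sample <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  r <- pmin(pmax(r, 1), h); c <- pmin(pmax(c, 1), w)
  r0 <- pmin(floor(r), h - 1); c0 <- pmin(floor(c), w - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}
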