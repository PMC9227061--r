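# Pyramidal Lucas-Kanade optical flow, pure R.
#
# Images are grayscale matrices (row = y, col = x), positions are (x, y)
# in 1-based pixel coordinates. No R package provides optical flow, so the
# classic iterative LK estimator with a coarse-to-fine image pyramid is
# implemented here directly.

smooth121 <- function(g) {
  h <- nrow(g); w <- ncol(g)
  # separable [1,2,1]/4 with replicated borders
  gv <- (g[c(1, 1:(h - 1)), ] + 2 * g + g[c(2:h, h), ]) / 4
  (gv[, c(1, 1:(w - 1))] + 2 * gv + gv[, c(2:w, w)]) / 4
}

build_pyramid <- function(g, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- g
  for (l in seq_len(levels - 1)) {
    s <- smooth121(pyr[[l]])
    pyr[[l + 1]] <- s[seq(1, nrow(s), 2), seq(1, ncol(s), 2), drop = FALSE]
  }
  pyr
}

# one-level iterative LK at point p = c(x, y), initial displacement d.
# ok requires an invertible structure tensor AND enough gradient energy in
# the window (min_texture, squared gray levels per px) so that pure sensor
# noise does not pass as trackable texture.
lk_refine <- function(I1, I2, p, d = c(0, 0), win = 7, iters = 20,
                      min_det = 1e-4, min_texture = 0) {
  o <- -win:win
  if (p[1] - win - 1 < 1 || p[1] + win + 1 > ncol(I1) ||
      p[2] - win - 1 < 1 || p[2] + win + 1 > nrow(I1))
    return(list(d = d, ok = FALSE))
  gx <- p[1] + o; gy <- p[2] + o
  cc <- rep(gx, each = length(gy)); rr <- rep(gy, length(gx))
  s1 <- bilinear_sample(I1, rr, cc)
  ix <- (bilinear_sample(I1, rr, cc + 1) -
           bilinear_sample(I1, rr, cc - 1)) / 2
  iy <- (bilinear_sample(I1, rr + 1, cc) -
           bilinear_sample(I1, rr - 1, cc)) / 2
  energy <- sum(ix * ix + iy * iy)
  G <- matrix(c(sum(ix * ix), sum(ix * iy), sum(ix * iy), sum(iy * iy)),
              2, 2)
  if (det(G) < min_det * length(ix) ||
      energy < min_texture * length(ix))
    return(list(d = d, ok = FALSE))
  Ginv <- solve(G)
  for (k in seq_len(iters)) {
    it <- bilinear_sample(I2, rr + d[2], cc + d[1]) - s1
    delta <- -Ginv %*% c(sum(ix * it), sum(iy * it))
    d <- d + as.vector(delta)
    if (max(abs(delta)) < 0.005) break
  }
  list(d = d, ok = TRUE)
}

# flow of one point between two prebuilt pyramids
lk_flow_pyr <- function(pyr1, pyr2, p, win = 7, min_texture = 9) {
  levels <- length(pyr1)
  d <- c(0, 0); ok <- FALSE
  for (l in levels:1) {
    scale <- 2^(l - 1)
    pl <- (p - 1) / scale + 1
    d <- d * 2
    res <- lk_refine(pyr1[[l]], pyr2[[l]], pl, d = d, win = win,
                     min_texture = if (l == 1) min_texture else 0)
    if (l == 1) ok <- res$ok
    if (res$ok) d <- res$d
  }
  list(d = d, ok = ok)
}

#' Sparse optical flow for one point
#'
#' Pyramidal iterative Lucas-Kanade displacement of a single point between
#' two grayscale frames. A point is reported untrackable (`ok = FALSE`)
#' when its window leaves the image, its structure tensor is degenerate,
#' or the window's gradient energy is below `min_texture` (so uniform
#' background with mere sensor noise does not track).
#'
#' @param I1,I2 grayscale matrices (0..255).
#' @param p point `c(x, y)` in 1-based pixel coordinates in `I1`.
#' @param win window half-size, px.
#' @param levels pyramid levels.
#' @param min_texture minimum mean squared gradient (gray/px)^2.
#' @return list with `d` (displacement `c(dx, dy)` in px) and `ok`.
#' @export
lk_point_flow <- function(I1, I2, p, win = 7, levels = 3,
                          min_texture = 9) {
  lk_flow_pyr(build_pyramid(I1, levels), build_pyramid(I2, levels),
              as.numeric(p), win = win, min_texture = min_texture)
}
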