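# Contrast-limited adaptive histogram equalization, applied to the luminance
# channel of the LAB representation only, so chroma (and therefore stain hue)
# is untouched. Standard algorithm: per-tile 256-bin clipped histograms with
# uniform excess redistribution and bilinear inter-tile interpolation of the
# per-tile lookup tables; the LUT uses the midpoint CDF convention so a flat
# histogram is (within a level) a fixed point.

clahe_tile_lut <- function(hist, clip_limit) {
  n <- sum(hist)
  limit <- max(1, clip_limit * n / 256)
  excess <- sum(pmax(hist - limit, 0))
  h <- pmin(hist, limit) + excess / 256
  cdf <- cumsum(h)
  mid <- cdf - h / 2
  pmin(pmax(round(mid / n * 255), 0), 255)
}

#' Apply CLAHE to the luminance channel
#'
#' Converts the image to CIELAB, equalizes only L with contrast-limited tile
#' histograms and bilinear inter-tile interpolation, and converts back. A and
#' B channels pass through unchanged (up to color-space round-trip rounding).
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param cfg a [preprocess_config()].
#' @return image of the same shape in \[0, 255\].
#' @export
apply_clahe <- function(img, cfg = preprocess_config()) {
  assert_image(img)
  lab <- rgb_to_lab(img)
  L <- lab[, , 1]
  H <- nrow(L); W <- ncol(L)
  rows <- cfg$tile_grid[1]; cols <- cfg$tile_grid[2]
  if (H < rows || W < cols) {
    message("image smaller than the tile grid; falling back to one global tile")
    rows <- 1L; cols <- 1L
  }
  Lq <- pmin(pmax(round(L * 255 / 100), 0), 255)

  rb <- floor(seq(0, H, length.out = rows + 1))
  cb <- floor(seq(0, W, length.out = cols + 1))
  luts <- array(0L, dim = c(rows, cols, 256))
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      tile <- Lq[(rb[r] + 1):rb[r + 1], (cb[cc] + 1):cb[cc + 1]]
      hist <- tabulate(tile + 1L, nbins = 256L)
      luts[r, cc, ] <- clahe_tile_lut(hist, cfg$clip_limit)
    }
  }

  centers_r <- (rb[-length(rb)] + rb[-1] + 1) / 2
  centers_c <- (cb[-length(cb)] + cb[-1] + 1) / 2
  y <- seq_len(H); x <- seq_len(W)
  r1 <- pmin(pmax(findInterval(y, centers_r), 1L), rows)
  c1 <- pmin(pmax(findInterval(x, centers_c), 1L), cols)
  r2 <- pmin(r1 + 1L, rows); c2 <- pmin(c1 + 1L, cols)
  wy <- ifelse(r2 > r1, (y - centers_r[r1]) / (centers_r[r2] - centers_r[r1]), 0)
  wy <- pmin(pmax(wy, 0), 1)
  wx <- ifelse(c2 > c1, (x - centers_c[c1]) / (centers_c[c2] - centers_c[c1]), 0)
  wx <- pmin(pmax(wx, 0), 1)

  v <- as.vector(Lq) + 1L
  R1 <- rep(r1, times = W); R2 <- rep(r2, times = W)
  WY <- rep(wy, times = W)
  C1 <- rep(c1, each = H); C2 <- rep(c2, each = H)
  WX <- rep(wx, each = H)
  out <- (1 - WY) * (1 - WX) * luts[cbind(R1, C1, v)] +
    (1 - WY) * WX * luts[cbind(R1, C2, v)] +
    WY * (1 - WX) * luts[cbind(R2, C1, v)] +
    WY * WX * luts[cbind(R2, C2, v)]

  lab[, , 1] <- matrix(out, H, W) * 100 / 255
  lab_to_rgb(lab)
}
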