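# Color-space conversions. sRGB <-> CIELAB goes through grDevices::convertColor
# (D65 observer); HSV is implemented directly so per-channel shifts stay
# vectorized over whole images.

rgb_to_lab <- function(img) {
  d <- dim(img)
  m <- matrix(img, ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

lab_to_rgb <- function(lab) {
  d <- dim(lab)
  m <- matrix(lab, ncol = 3L)
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  clip255(array(rgb, dim = d) * 255)
}

# Vectorized RGB (0..255) -> HSV with h in degrees [0, 360), s, v in [0, 1].
rgb_to_hsv_mat <- function(img) {
  m <- matrix(img, ncol = 3L) / 255
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  ir <- nz & mx == r
  ig <- nz & !ir & mx == g
  ib <- nz & !ir & !ig
  h[ir] <- ((g[ir] - b[ir]) / d[ir]) %% 6
  h[ig] <- (b[ig] - r[ig]) / d[ig] + 2
  h[ib] <- (r[ib] - g[ib]) / d[ib] + 4
  h <- h * 60
  s <- ifelse(mx > 0, d / mx, 0)
  cbind(h = h, s = s, v = mx)
}

hsv_to_rgb_img <- function(hsv, dims) {
  h <- (hsv[, 1] %% 360) / 60
  s <- pmin(pmax(hsv[, 2], 0), 1)
  v <- pmin(pmax(hsv[, 3], 0), 1)
  c_ <- v * s
  x <- c_ * (1 - abs(h %% 2 - 1))
  m <- v - c_
  sector <- floor(h) %% 6
  r <- g <- b <- numeric(length(h))
  idx <- function(k) sector == k
  r[idx(0)] <- c_[idx(0)]; g[idx(0)] <- x[idx(0)]
  r[idx(1)] <- x[idx(1)]; g[idx(1)] <- c_[idx(1)]
  g[idx(2)] <- c_[idx(2)]; b[idx(2)] <- x[idx(2)]
  g[idx(3)] <- x[idx(3)]; b[idx(3)] <- c_[idx(3)]
  r[idx(4)] <- x[idx(4)]; b[idx(4)] <- c_[idx(4)]
  r[idx(5)] <- c_[idx(5)]; b[idx(5)] <- x[idx(5)]
  out <- cbind(r + m, g + m, b + m) * 255
  clip255(array(out, dim = dims))
}
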