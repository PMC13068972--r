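# Four-stage stain/color normalization pipeline:
#   CLAHE (LAB) -> CDF histogram matching -> Shades-of-Gray -> Macenko.
# All stages operate on H x W x 3 arrays in [0, 255] and are deterministic.

#' Preprocessing pipeline configuration
#'
#' @param clip_limit CLAHE contrast ceiling.
#' @param tile_grid CLAHE tile grid `(rows, cols)`.
#' @param minkowski_p Shades-of-Gray exponent (p = 1 is gray-world).
#' @param I0 maximum transmitted light intensity for optical density.
#' @param beta optical-density background threshold.
#' @param epsilon numerical-stability constant on the \[0,1\] intensity scale.
#' @param concentration_percentile robust stain-concentration maximum
#'   percentile.
#' @param mode Macenko coupling: `"literal"` normalizes by the image's own
#'   percentile; `"reference"` additionally rescales to reference statistics.
#' @param basis_mode stain-vector extraction: `"literal"` returns the raw
#'   top-2 right singular vectors; `"percentile"` the angle-percentile
#'   extreme directions of the original Macenko method.
#' @param fg_rule background exclusion: `"mean"` keeps pixels whose mean
#'   optical density exceeds `beta` (the total-OD convention, robust for
#'   stains with a near-zero channel); `"all"` requires every channel to
#'   exceed `beta`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(clip_limit = 3.0, tile_grid = c(8, 8),
                              minkowski_p = 6, I0 = 240, beta = 0.15,
                              epsilon = 1e-6, concentration_percentile = 99,
                              mode = c("literal", "reference"),
                              basis_mode = c("percentile", "literal"),
                              fg_rule = c("mean", "all")) {
  stopifnot(clip_limit > 0, all(tile_grid >= 1), length(tile_grid) == 2,
            minkowski_p >= 1, I0 > 0, beta > 0, beta < I0, epsilon > 0,
            concentration_percentile > 0, concentration_percentile <= 100)
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 minkowski_p = minkowski_p, I0 = I0, beta = beta,
                 epsilon = epsilon,
                 concentration_percentile = concentration_percentile,
                 mode = match.arg(mode), basis_mode = match.arg(basis_mode),
                 fg_rule = match.arg(fg_rule)),
            class = "preprocess_config")
}

# ---- histogram matching -----------------------------------------------------

channel_cdf <- function(channel) {
  h <- tabulate(pmin(pmax(round(channel), 0), 255) + 1L, nbins = 256L)
  cumsum(h) / sum(h)
}

#' Reference statistics for normalization
#'
#' Computes from a reference image everything the pipeline needs to couple
#' other images to it: per-channel intensity CDFs, the reference stain basis,
#' and the robust (percentile) concentration maxima.
#'
#' @param img reference image, H x W x 3 in \[0, 255\].
#' @param cfg a [preprocess_config()].
#' @return object of class `reference_stats`.
#' @export
build_reference_stats <- function(img, cfg = preprocess_config()) {
  assert_image(img)
  cdfs <- sapply(1:3, function(k) channel_cdf(img[, , k]))  # 256 x 3
  basis <- estimate_stain_basis(compute_od(img, cfg), cfg)
  conc <- stain_concentrations(img, basis, cfg)
  structure(list(rgb_cdfs = cdfs, stain_basis_ref = basis,
                 robust_max_ref = conc$robust_max),
            class = "reference_stats")
}

#' Histogram-match an image to reference CDFs
#'
#' Per RGB channel, maps each intensity i to the smallest reference level j
#' whose CDF reaches the source CDF at i; the mapping is monotone and drives
#' the squared CDF distance to the reference down.
#'
#' @param src source image.
#' @param ref_stats a [build_reference_stats()] object (only `rgb_cdfs` used).
#' @return matched image.
#' @export
match_histogram <- function(src, ref_stats) {
  assert_image(src)
  if (length(src) == 0) stop_gwovit("empty image", "invalid_image")
  out <- src
  for (k in 1:3) {
    ch <- pmin(pmax(round(src[, , k]), 0), 255)
    cdf_src <- channel_cdf(ch)
    cdf_ref <- ref_stats$rgb_cdfs[, k]
    # smallest j with cdf_ref[j] >= cdf_src[i]  (0-based levels)
    lut <- findInterval(cdf_src - 1e-12, cdf_ref) # counts of cdf_ref < target
    lut <- pmin(lut, 255L)
    out[, , k] <- matrix(lut[ch + 1L], nrow(ch), ncol(ch))
  }
  out
}

# ---- shades of gray ---------------------------------------------------------

#' Estimate the scene illuminant by Minkowski norm
#'
#' Returns, per channel, `(mean(I^p))^(1/p)`; p = 1 is the per-channel mean
#' (gray-world) and large p approaches the channel maximum (white-patch).
#'
#' @param img H x W x 3 image in \[0, 255\].
#' @param p Minkowski exponent, >= 1.
#' @return numeric length-3 illuminant estimate.
#' @export
estimate_illuminant <- function(img, p = 6) {
  assert_image(img)
  stopifnot(p >= 1)
  sapply(1:3, function(k) mean((img[, , k] / 255)^p)^(1 / p) * 255)
}

#' Shades-of-Gray color constancy correction
#'
#' Divides each channel by its Minkowski-norm illuminant estimate and
#' re-anchors to the mean of the three estimates, so the corrected image's
#' channel illuminants are equal: the average scene reflectance is mapped to
#' neutral gray.
#'
#' @inheritParams estimate_illuminant
#' @return corrected image, clipped to \[0, 255\].
#' @export
shades_of_gray <- function(img, p = 6) {
  e <- estimate_illuminant(img, p)
  if (any(e == 0))
    stop_gwovit("degenerate image: a channel is identically zero",
                "zero_illuminant")
  gains <- mean(e) / e
  clip255(sweep(img, 3, gains, "*"))
}

# ---- Macenko ----------------------------------------------------------------

#' Optical density of an image
#'
#' Element-wise `-log((I + eps) / I0)`; values brighter than I0 clamp to 0.
#'
#' @param img H x W x 3 image.
#' @param cfg a [preprocess_config()].
#' @return object of class `od_matrix`: list with `values` (N x 3 matrix) and
#'   `source_shape`.
#' @export
compute_od <- function(img, cfg = preprocess_config()) {
  assert_image(img)
  eps <- cfg$epsilon * 255
  od <- -log((matrix(img, ncol = 3L) + eps) / cfg$I0)
  od[od < 0] <- 0
  structure(list(values = od, source_shape = dim(img)[1:2]), class = "od_matrix")
}

normalize_stain_column <- function(v) {
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}

#' Estimate the hematoxylin/eosin stain basis
#'
#' Foreground pixels (optical density above `beta` in all three channels)
#' enter a singular value decomposition. In `"literal"` basis mode the top-2
#' right singular vectors themselves are returned (sign-corrected,
#' nonnegative-clamped, unit-normalized); in `"percentile"` mode the
#' angle-percentile extreme directions of the foreground pixels within the
#' top-2 singular plane are returned (the original Macenko rule), which can
#' recover non-orthogonal stain vectors. Columns are ordered so hematoxylin
#' has the larger red-channel component.
#'
#' @param od an [compute_od()] result.
#' @param cfg a [preprocess_config()].
#' @param alpha angle percentile (percent) for `"percentile"` mode.
#' @return 3 x 2 matrix of class `stain_basis`.
#' @export
foreground_mask <- function(od_values, cfg) {
  if (cfg$fg_rule == "all") rowSums(od_values > cfg$beta) == 3L
  else rowMeans(od_values) > cfg$beta
}

estimate_stain_basis <- function(od, cfg = preprocess_config(), alpha = 1) {
  stopifnot(inherits(od, "od_matrix"))
  fg <- od$values[foreground_mask(od$values, cfg), , drop = FALSE]
  if (nrow(fg) < 2)
    stop_gwovit("background-only image: no foreground pixels above beta",
                "background_only")
  sv <- svd(fg, nu = 0)
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop_gwovit("single-stain / rank-deficient image", "rank_deficient")
  V2 <- sv$v[, 1:2, drop = FALSE]
  if (cfg$basis_mode == "literal") {
    cols <- apply(V2, 2, normalize_stain_column)
  } else {
    # project foreground onto the singular plane, take extreme directions
    V2 <- apply(V2, 2, function(v) if (sum(v) < 0) -v else v)
    proj <- fg %*% V2
    phi <- atan2(proj[, 2], proj[, 1])
    q <- stats::quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
    cols <- cbind(V2 %*% c(cos(q[1]), sin(q[1])),
                  V2 %*% c(cos(q[2]), sin(q[2])))
    cols <- apply(cols, 2, normalize_stain_column)
  }
  if (cols[1, 1] < cols[1, 2]) cols <- cols[, 2:1]
  structure(cols, class = c("stain_basis", "matrix"))
}

# Least-squares stain concentrations against a 3x2 basis, negatives clamped,
# with the robust percentile maximum computed over foreground pixels.
stain_concentrations <- function(img, basis, cfg) {
  od <- compute_od(img, cfg)
  C <- solve(crossprod(basis), t(basis) %*% t(od$values))  # 2 x N
  C[C < 0] <- 0
  fg <- foreground_mask(od$values, cfg)
  robust <- if (any(fg)) {
    apply(C[, fg, drop = FALSE], 1, stats::quantile,
          probs = cfg$concentration_percentile / 100, names = FALSE)
  } else c(1, 1)
  robust[robust <= 0] <- 1
  list(values = C, robust_max = robust, source_shape = od$source_shape)
}

#' Macenko stain normalization
#'
#' Decomposes the image into stain concentrations against its estimated
#' basis, rescales the concentrations, and reconstructs through Beer-Lambert.
#' In `"literal"` mode each stain row is divided by its own percentile
#' maximum; in `"reference"` mode it is additionally multiplied by the
#' reference robust maxima and reconstructed with the reference stain basis,
#' coupling the image to a canonical staining appearance.
#'
#' @param img H x W x 3 image in \[0, 255\].
#' @param cfg a [preprocess_config()].
#' @param ref optional [build_reference_stats()]; required in reference mode.
#' @return normalized image.
#' @export
macenko_normalize <- function(img, cfg = preprocess_config(), ref = NULL) {
  assert_image(img)
  mode <- cfg$mode
  if (mode == "reference" && is.null(ref))
    stop_gwovit("reference mode requires reference stats", "missing_reference")
  basis <- estimate_stain_basis(compute_od(img, cfg), cfg)
  conc <- stain_concentrations(img, basis, cfg)
  Cn <- conc$values / conc$robust_max
  if (mode == "reference") {
    Cn <- Cn * ref$robust_max_ref
    basis <- ref$stain_basis_ref
  }
  trans <- cfg$I0 * exp(-(unclass(basis) %*% Cn))
  clip255(array(t(trans), dim = c(conc$source_shape, 3L)))
}

# ---- composed pipeline ------------------------------------------------------

#' Full four-stage preprocessing pipeline
#'
#' Applies, in order: CLAHE on luminance, histogram matching to the reference
#' CDFs, Shades-of-Gray with the configured Minkowski exponent, and Macenko
#' stain normalization. Deterministic; a per-stage summary (channel means) is
#' attached as the `"stage_log"` attribute.
#'
#' @param img input image.
#' @param cfg a [preprocess_config()].
#' @param ref a [build_reference_stats()] object.
#' @return normalized image with a `stage_log` attribute.
#' @export
preprocess <- function(img, cfg = preprocess_config(), ref) {
  stages <- list(
    clahe = function(x) apply_clahe(x, cfg),
    histmatch = function(x) match_histogram(x, ref),
    shades_of_gray = function(x) shades_of_gray(x, cfg$minkowski_p),
    macenko = function(x) macenko_normalize(x, cfg,
                                            ref = if (cfg$mode == "reference") ref)
  )
  log <- data.frame(stage = character(), mean_r = numeric(),
                    mean_g = numeric(), mean_b = numeric())
  out <- img
  for (nm in names(stages)) {
    out <- tryCatch(stages[[nm]](out), gwovit_error = function(e) {
      stop_gwovit(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
                  "stage_error")
    })
    log[nrow(log) + 1L, ] <- list(nm, mean(out[, , 1]), mean(out[, , 2]),
                                  mean(out[, , 3]))
  }
  attr(out, "stage_log") <- log
  out
}

#' Preprocess a batch of image files
#'
#' Runs [preprocess()] over files, writing outputs under `out_dir` (same
#' relative paths). With `skip_on_error = TRUE` a failing image keeps its last
#' successful stage's output and is flagged in the returned report instead of
#' aborting the batch.
#'
#' @param paths image paths relative to `in_dir`.
#' @param in_dir,out_dir input and output roots.
#' @param cfg a [preprocess_config()].
#' @param ref a [build_reference_stats()] object.
#' @param skip_on_error write partial output and continue on stage failures.
#' @return data.frame with columns path, status, message.
#' @export
preprocess_batch <- function(paths, in_dir, out_dir, cfg = preprocess_config(),
                             ref, skip_on_error = FALSE) {
  report <- data.frame(path = paths, status = "ok", message = "",
                       stringsAsFactors = FALSE)
  for (i in seq_along(paths)) {
    img <- read_image(file.path(in_dir, paths[i]))
    res <- tryCatch(preprocess(img, cfg, ref), gwovit_error = function(e) e)
    if (inherits(res, "condition")) {
      if (!skip_on_error) stop(res)
      # re-run stage by stage, keeping the last success
      out <- img
      for (f in list(function(x) apply_clahe(x, cfg),
                     function(x) match_histogram(x, ref),
                     function(x) shades_of_gray(x, cfg$minkowski_p))) {
        nxt <- tryCatch(f(out), gwovit_error = function(e) NULL)
        if (is.null(nxt)) break
        out <- nxt
      }
      report$status[i] <- "flagged"
      report$message[i] <- conditionMessage(res)
      res <- out
    }
    write_image(res, file.path(out_dir, paths[i]))
  }
  report
}

#' Pick a canonical reference image from a batch
#'
#' Chooses the image whose channel means are closest (L2) to the batch-median
#' channel means, a cheap proxy for "typical staining appearance".
#'
#' @param paths image paths.
#' @param in_dir root directory.
#' @return the selected path.
#' @export
pick_reference_image <- function(paths, in_dir = ".") {
  means <- t(vapply(paths, function(p) {
    img <- read_image(file.path(in_dir, p))
    c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]))
  }, numeric(3)))
  med <- apply(means, 2, stats::median)
  paths[which.min(rowSums(sweep(means, 2, med)^2))]
}
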