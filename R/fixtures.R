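# Synthetic BreakHis-like fixture generator.
#
# Images are formed in optical-density space from a two-stain Beer-Lambert
# model: nuclei are hematoxylin-rich ellipses, stroma is a smooth eosin-rich
# texture, and the transmitted intensity is I = I0 * exp(-B %*% C) for a 3x2
# stain basis B and 2xN concentration field C. Per-image channel gains and
# contrast jitter then corrupt the render so that every normalization stage in
# the preprocessing pipeline has a defect to correct, while the ground-truth
# basis, gains and nuclei counts are recorded for closed-loop tests.

#' Default hematoxylin/eosin stain basis
#'
#' A fixed 3 x 2 matrix of unit-norm optical-density directions taken from
#' standard H&E conventions: the hematoxylin-like column absorbs strongly in
#' the red channel, the eosin-like column almost exclusively in green.
#'
#' @return 3 x 2 numeric matrix; column 1 is hematoxylin, column 2 eosin.
#' @examples
#' B <- default_stain_basis()
#' colSums(B^2) # both 1
#' @export
default_stain_basis <- function() {
  B <- cbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  sweep(B, 2, sqrt(colSums(B^2)), "/")
}

#' Fixture generator configuration
#'
#' @param images_per_class_per_mag images to render per class and
#'   magnification (>= 1).
#' @param magnifications subset of `c(40, 100, 200, 400)`.
#' @param image_size square image side in pixels (>= 32).
#' @param stain_basis_true 3 x 2 unit-column, nonnegative stain basis.
#' @param stain_jitter_deg max angular perturbation of each basis column, in
#'   degrees.
#' @param illumination_gain_range per-channel multiplicative gain interval,
#'   a sub-interval of (0, 2].
#' @param contrast_jitter_range interval of contrast slopes around 1.
#' @param nuclei_density named vector `c(benign = ..., malignant = ...)`:
#'   mean nucleus count at 40X.
#' @param nuclei_radius_factor named per-class multiplier on the nuclear
#'   radius, emulating malignant nuclear enlargement; together with the
#'   density contrast this gives the classes a morphological signature that
#'   survives histogram normalization.
#' @param nuclei_scale_per_mag named vector mapping magnification to the
#'   object radius multiplier (40X smallest objects).
#' @param stroma_range interval of eosin stromal concentrations; the upper
#'   end emulates densely eosinophilic regions (collagen bundles, red cells)
#'   whose optical density clears the Macenko background threshold in all
#'   three channels; `c(0, 0)` disables stroma.
#' @param background_intensity white transmitted-light level I0.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `fixture_config`.
#' @export
fixture_config <- function(images_per_class_per_mag = 5,
                           magnifications = c(40, 100, 200, 400),
                           image_size = 224,
                           stain_basis_true = default_stain_basis(),
                           stain_jitter_deg = 0,
                           illumination_gain_range = c(1, 1),
                           contrast_jitter_range = c(1, 1),
                           nuclei_density = c(benign = 60, malignant = 120),
                           nuclei_radius_factor = c(benign = 1, malignant = 1.6),
                           nuclei_scale_per_mag = c("40" = 1, "100" = 1.5,
                                                    "200" = 2.2, "400" = 3.2),
                           stroma_range = c(0.15, 1.8),
                           background_intensity = 240,
                           seed = 1L) {
  stopifnot(images_per_class_per_mag >= 1,
            all(magnifications %in% c(40, 100, 200, 400)),
            length(illumination_gain_range) == 2,
            all(illumination_gain_range > 0),
            all(illumination_gain_range <= 2),
            stain_jitter_deg >= 0,
            all(c("benign", "malignant") %in% names(nuclei_density)))
  if (image_size < 32)
    stop_gwovit("image_size < 32 is too small to place objects", "image_too_small")
  if (!isTRUE(all.equal(colSums(stain_basis_true^2), c(1, 1),
                        check.attributes = FALSE)) ||
      any(stain_basis_true < 0))
    stop_gwovit("stain_basis_true must have unit-norm nonnegative columns",
                "invalid_basis")
  structure(list(images_per_class_per_mag = as.integer(images_per_class_per_mag),
                 magnifications = as.integer(magnifications),
                 image_size = as.integer(image_size),
                 stain_basis_true = unname(stain_basis_true),
                 stain_jitter_deg = stain_jitter_deg,
                 illumination_gain_range = illumination_gain_range,
                 contrast_jitter_range = contrast_jitter_range,
                 nuclei_density = nuclei_density,
                 nuclei_radius_factor = nuclei_radius_factor,
                 nuclei_scale_per_mag = nuclei_scale_per_mag,
                 stroma_range = stroma_range,
                 background_intensity = background_intensity,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# Rotate a unit column by an angle <= jitter_deg towards a random nonnegative
# direction; retries keep the perturbed column inside the nonnegative orthant
# so the recorded basis stays a valid stain basis.
jitter_column <- function(col, jitter_deg) {
  if (jitter_deg <= 0) return(col)
  theta <- runif(1, 0, jitter_deg) * pi / 180
  for (i in 1:25) {
    u <- rnorm(3)
    u <- u - sum(u * col) * col
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) next
    u <- u / nu
    cand <- cos(theta) * col + sin(theta) * u
    if (all(cand >= 0)) return(cand / sqrt(sum(cand^2)))
  }
  col
}

#' Render one synthetic histology image
#'
#' Deterministic for a fixed (config seed, class, magnification, index): the
#' per-image RNG stream is derived by hashing those four values, so any image
#' of a dataset can be regenerated independently.
#'
#' @param cfg a [fixture_config()].
#' @param class_label `"benign"` or `"malignant"`.
#' @param magnification one of `cfg$magnifications`.
#' @param index image index within its (class, magnification) cell.
#' @return list with `image` (H x W x 3 array in \[0,255\]) and `truth`
#'   (one-row data.frame of ground-truth parameters).
#' @export
render_image <- function(cfg, class_label, magnification, index = 1L) {
  stopifnot(inherits(cfg, "fixture_config"),
            class_label %in% c("benign", "malignant"))
  if (!magnification %in% cfg$magnifications)
    stop_gwovit("magnification not enabled in this fixture config",
                "invalid_magnification")
  s <- cfg$image_size
  I0 <- cfg$background_intensity
  # the basis jitter draws from its own substream so that renders with and
  # without jitter share identical concentration fields and gains
  B <- with_seed(stream_seed(cfg$seed, "jitter", class_label, magnification, index),
                 apply(cfg$stain_basis_true, 2, jitter_column,
                       jitter_deg = cfg$stain_jitter_deg))
  with_seed(stream_seed(cfg$seed, class_label, magnification, index), {
    mult <- cfg$nuclei_scale_per_mag[[as.character(magnification)]]
    lambda <- cfg$nuclei_density[[class_label]] / mult^2
    # the count has its own substream: configs differing only in density then
    # share stroma and nucleus-placement streams, giving matched image pairs
    n_nuclei <- if (lambda > 0) {
      with_seed(stream_seed(cfg$seed, "count", class_label, magnification, index),
                stats::rpois(1, lambda))
    } else 0L

    stroma_on <- diff(range(cfg$stroma_range)) > 0 || cfg$stroma_range[1] > 0
    # eosin-rich stroma: a smooth low-frequency random field over a faint
    # hematoxylin wash
    ch <- if (stroma_on) matrix(runif(s * s, 0, 0.02), s, s)
    else matrix(0, s, s)
    ce <- matrix(0, s, s)
    if (stroma_on) {
      coarse <- matrix(runif(64, cfg$stroma_range[1], cfg$stroma_range[2]), 8, 8)
      gx <- seq(1, 8, length.out = s)
      i0 <- pmin(floor(gx), 7); fx <- gx - i0
      up_rows <- coarse[i0, ] * (1 - fx) + coarse[i0 + 1, ] * fx
      ce <- up_rows[, i0] * rep(1 - fx, each = s) +
        up_rows[, i0 + 1] * rep(fx, each = s)
    }

    # hematoxylin-rich elliptical nuclei; eosin is suppressed inside so the
    # image contains near-pure pixels of both stains
    rf <- if (!is.null(cfg$nuclei_radius_factor))
      cfg$nuclei_radius_factor[[class_label]] else 1
    r_base <- max(2, s / 28) * mult * rf
    xs <- matrix(rep(seq_len(s), each = s), s, s)   # column coordinate
    ys <- matrix(rep(seq_len(s), times = s), s, s)  # row coordinate
    for (k in seq_len(n_nuclei)) {
      cx <- runif(1, 1, s); cy <- runif(1, 1, s)
      ra <- r_base * runif(1, 0.7, 1.3)
      rb <- r_base * runif(1, 0.6, 1.1)
      th <- runif(1, 0, pi)
      dx <- xs - cx; dy <- ys - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      inside <- (u / ra)^2 + (v / rb)^2 <= 1
      ch[inside] <- ch[inside] + runif(1, 0.9, 1.4)
      ce[inside] <- ce[inside] * 0.02
    }

    conc <- rbind(as.vector(ch), as.vector(ce))
    trans <- I0 * exp(-(B %*% conc))            # 3 x N transmitted light
    img <- array(t(trans), dim = c(s, s, 3))

    gains <- runif(3, cfg$illumination_gain_range[1], cfg$illumination_gain_range[2])
    contrast <- runif(1, cfg$contrast_jitter_range[1], cfg$contrast_jitter_range[2])
    img <- sweep(img, 3, gains, "*")
    img <- (img - 128) * contrast + 128
    img <- clip255(img)

    truth <- data.frame(class_label = class_label,
                        magnification = magnification,
                        index = index,
                        nuclei_count = n_nuclei,
                        t(c(basis = as.vector(B))),
                        t(c(gain = gains)),
                        contrast = contrast)
    list(image = img, truth = truth)
  })
}

#' Generate a BreakHis-style synthetic dataset on disk
#'
#' Writes PNG files under `out_dir/<class>/synthetic/sim/<mag>X/` together
#' with a `manifest.csv` (path, class, subtype, patient, magnification) and a
#' `ground_truth.csv` holding the per-image generation parameters.
#'
#' @param cfg a [fixture_config()].
#' @param out_dir output directory; must be empty unless `overwrite = TRUE`.
#' @param overwrite allow writing into a non-empty directory.
#' @return the dataset manifest (see [scan_manifest()]), invisibly gaining a
#'   `ground_truth` attribute.
#' @export
make_dataset <- function(cfg, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cfg, "fixture_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop_gwovit("out_dir is not empty; pass overwrite = TRUE to proceed",
                "refuse_overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truths <- list()
  for (cl in c("benign", "malignant")) {
    for (mag in cfg$magnifications) {
      for (i in seq_len(cfg$images_per_class_per_mag)) {
        r <- render_image(cfg, cl, mag, i)
        rel <- file.path(cl, "synthetic", "sim", paste0(mag, "X"),
                         sprintf("%s_%dX_%03d.png", cl, mag, i))
        write_image(r$image, file.path(out_dir, rel))
        rows[[length(rows) + 1L]] <-
          data.frame(path = rel, class_label = cl, subtype = "synthetic",
                     patient_id = "sim", magnification = mag)
        truths[[length(truths) + 1L]] <- cbind(path = rel, r$truth)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$origin <- "original"
  manifest$split <- "unassigned"
  truth <- do.call(rbind, truths)
  utils::write.csv(manifest[, c("path", "class_label", "subtype", "patient_id",
                                "magnification")],
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  attr(manifest, "root") <- normalizePath(out_dir)
  attr(manifest, "ground_truth") <- truth
  class(manifest) <- c("dataset_manifest", "data.frame")
  manifest
}
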