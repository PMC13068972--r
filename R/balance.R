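# Dataset manifest handling, per-magnification class balancing, seeded
# augmentation, and stratified train/val/test splitting for BreakHis-style
# directory trees: <class>/<subtype>/<patient>/<mag>X/<file>.

IMG_EXT <- c("png", "jpg", "jpeg", "tif", "tiff")
MAGS <- c(40L, 100L, 200L, 400L)

new_manifest <- function(df, root = NULL, rejects = NULL) {
  df$magnification <- as.integer(df$magnification)
  if (is.null(df$origin)) df$origin <- "original"
  if (is.null(df$split)) df$split <- "unassigned"
  if (is.null(df$parent)) df$parent <- NA_character_
  rownames(df) <- NULL
  structure(df, root = root, rejects = rejects,
            class = c("dataset_manifest", "data.frame"))
}

#' Scan a BreakHis-style directory tree into a manifest
#'
#' One row per image file; the magnification is parsed from the `<n>X` path
#' component. Files that do not fit the layout are collected in the
#' `"rejects"` attribute rather than silently dropped.
#'
#' @param root_dir dataset root.
#' @return a `dataset_manifest` data.frame with columns path, class_label,
#'   subtype, patient_id, magnification, origin, split.
#' @export
scan_manifest <- function(root_dir) {
  if (!dir.exists(root_dir)) stop_gwovit("root_dir does not exist", "no_root")
  files <- list.files(root_dir, recursive = TRUE, full.names = FALSE)
  files <- files[!grepl("\\.csv$", files)]
  rows <- list(); rejects <- character()
  for (f in files) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1]]
    ext <- tolower(tools::file_ext(f))
    mag_part <- if (length(parts) == 5L) sub("X$", "", parts[4]) else ""
    mag <- suppressWarnings(as.integer(mag_part))
    if (length(parts) != 5L || !ext %in% IMG_EXT || is.na(mag) ||
        !mag %in% MAGS || !parts[1] %in% c("benign", "malignant")) {
      rejects <- c(rejects, f)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      path = f, class_label = parts[1], subtype = parts[2],
      patient_id = parts[3], magnification = mag)
  }
  if (length(rows) == 0)
    stop_gwovit("no image files found under root_dir", "empty_tree")
  new_manifest(do.call(rbind, rows), root = normalizePath(root_dir),
               rejects = rejects)
}

#' Expand a published count table into a synthetic manifest
#'
#' Takes a table with columns class_label, subtype and one column per
#' magnification (`X40`, `X100`, `X200`, `X400`) and expands it into a
#' manifest with one placeholder row per counted image. Used to drive the
#' counting/balancing arithmetic from printed benchmark tables without the
#' image files.
#'
#' @param counts data.frame of per-subtype, per-magnification counts.
#' @return a `dataset_manifest`.
#' @export
expand_counts_manifest <- function(counts) {
  magcols <- grep("^X\\d+$", names(counts), value = TRUE)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (mc in magcols) {
      n <- counts[[mc]][i]
      if (n == 0) next
      mag <- as.integer(sub("^X", "", mc))
      rows[[length(rows) + 1L]] <- data.frame(
        path = sprintf("%s/%s/tab/%dX/img_%04d.png", counts$class_label[i],
                       counts$subtype[i], mag, seq_len(n)),
        class_label = counts$class_label[i], subtype = counts$subtype[i],
        patient_id = "tab", magnification = mag)
    }
  }
  new_manifest(do.call(rbind, rows))
}

#' Cross-tabulate image counts by class and magnification
#'
#' @param manifest a `dataset_manifest`.
#' @return object of class `class_count_table`: the 2 x n_mag count matrix
#'   with class totals, per-magnification totals, and the grand total.
#' @export
count_by_class_mag <- function(manifest) {
  stopifnot(nrow(manifest) > 0)
  tab <- table(factor(manifest$class_label, levels = c("benign", "malignant")),
               factor(manifest$magnification,
                      levels = sort(unique(manifest$magnification))))
  counts <- matrix(as.integer(tab), nrow = 2,
                   dimnames = list(rownames(tab), colnames(tab)))
  structure(list(counts = counts,
                 class_totals = rowSums(counts),
                 mag_totals = colSums(counts),
                 grand_total = sum(counts)),
            class = "class_count_table")
}

#' @export
print.class_count_table <- function(x, ...) {
  m <- cbind(x$counts, Total = x$class_totals)
  m <- rbind(m, Total = c(x$mag_totals, x$grand_total))
  print(m)
  invisible(x)
}

#' Plan per-magnification class balancing
#'
#' For every magnification, identifies the minority class and the number of
#' augmented images needed to equalize the two classes at the majority count.
#'
#' @param counts a [count_by_class_mag()] table.
#' @return object of class `balance_plan`: data.frame with one row per
#'   magnification (minority_class, n_to_generate, target_per_class).
#' @export
plan_balance <- function(counts) {
  stopifnot(inherits(counts, "class_count_table"))
  cm <- counts$counts
  if (any(cm == 0))
    stop_gwovit("a magnification has a class with zero images", "class_absent")
  plan <- data.frame(magnification = as.integer(colnames(cm)),
                     minority_class = rownames(cm)[apply(cm, 2, which.min)],
                     n_to_generate = abs(cm["malignant", ] - cm["benign", ]),
                     target_per_class = apply(cm, 2, max))
  rownames(plan) <- NULL
  structure(plan, class = c("balance_plan", "data.frame"))
}

# ---- augmentation ops -------------------------------------------------------

#' Rotate an image by multiples of 90 degrees
#' @param img H x W x 3 array.
#' @param k number of counter-clockwise quarter turns.
#' @return rotated image.
#' @export
rot90_image <- function(img, k = 1L) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  }
  img
}

flip_image <- function(img, horizontal = TRUE) {
  if (horizontal) img[, dim(img)[2]:1, , drop = FALSE]
  else img[dim(img)[1]:1, , , drop = FALSE]
}

# Inverse-mapped affine warp (shift, scale, rotate about the center) with
# bilinear sampling and edge replication.
affine_warp <- function(img, shift_frac = c(0, 0), scale = 1, degrees = 0) {
  H <- dim(img)[1]; W <- dim(img)[2]
  th <- degrees * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ys <- matrix(rep(seq_len(H), times = W), H, W) - cy
  xs <- matrix(rep(seq_len(W), each = H), H, W) - cx
  # inverse transform: undo shift, then rotation/scale
  xs2 <- xs - shift_frac[2] * W
  ys2 <- ys - shift_frac[1] * H
  xsrc <- (cos(-th) * xs2 - sin(-th) * ys2) / scale + cx
  ysrc <- (sin(-th) * xs2 + cos(-th) * ys2) / scale + cy
  x0 <- pmin(pmax(floor(xsrc), 1), W); x1 <- pmin(x0 + 1, W)
  y0 <- pmin(pmax(floor(ysrc), 1), H); y1 <- pmin(y0 + 1, H)
  fx <- pmin(pmax(xsrc - x0, 0), 1); fy <- pmin(pmax(ysrc - y0, 0), 1)
  out <- img
  for (k in 1:3) {
    ch <- img[, , k]
    out[, , k] <- (1 - fy) * (1 - fx) * ch[cbind(as.vector(y0), as.vector(x0))] +
      (1 - fy) * fx * ch[cbind(as.vector(y0), as.vector(x1))] +
      fy * (1 - fx) * ch[cbind(as.vector(y1), as.vector(x0))] +
      fy * fx * ch[cbind(as.vector(y1), as.vector(x1))]
  }
  out
}

gaussian_blur <- function(img, ksize = 3) {
  sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  r <- (ksize - 1) / 2
  kern <- exp(-((-r):r)^2 / (2 * sigma^2)); kern <- kern / sum(kern)
  pad_conv <- function(m) {
    # separable convolution with edge replication
    mp <- m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), ]
    m2 <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(ksize)) m2 <- m2 + kern[i] * mp[i:(i + nrow(m) - 1), ]
    mp <- m2[, c(rep(1, r), seq_len(ncol(m)), rep(ncol(m), r))]
    m3 <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(ksize)) m3 <- m3 + kern[i] * mp[, i:(i + ncol(m) - 1)]
    m3
  }
  for (k in 1:3) img[, , k] <- pad_conv(img[, , k])
  img
}

#' Augmentation specification
#'
#' Parameter ranges follow the common defaults of the named operations:
#' shift up to 6.25%, scale within ±10%, rotation within ±15° for
#' shift-scale-rotate; brightness/contrast deltas ±0.2; HSV shifts
#' (10°, 0.2, 0.1); blur kernels 3 or 5. Each op fires with its own
#' probability.
#'
#' @param horizontal_flip,vertical_flip,rot90,shift_scale_rotate,
#'   brightness_contrast,hue_saturation_value,gaussian_blur per-op
#'   application probabilities in \[0,1\].
#' @param shift_limit,scale_limit,rotate_limit shift-scale-rotate ranges.
#' @param brightness_limit,contrast_limit photometric delta ranges.
#' @param hue_shift,sat_shift,val_shift HSV shift magnitudes.
#' @param blur_kernels candidate odd kernel sizes.
#' @param seed RNG seed for the derived per-image streams.
#' @return object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(horizontal_flip = 0.5, vertical_flip = 0.5,
                              rot90 = 0.5, shift_scale_rotate = 0.5,
                              brightness_contrast = 0.5,
                              hue_saturation_value = 0.5, gaussian_blur = 0.5,
                              shift_limit = 0.0625, scale_limit = 0.1,
                              rotate_limit = 15, brightness_limit = 0.2,
                              contrast_limit = 0.2, hue_shift = 10,
                              sat_shift = 0.2, val_shift = 0.1,
                              blur_kernels = c(3, 5), seed = 42L) {
  p <- c(horizontal_flip, vertical_flip, rot90, shift_scale_rotate,
         brightness_contrast, hue_saturation_value, gaussian_blur)
  stopifnot(all(p >= 0 & p <= 1))
  structure(list(p = list(hflip = horizontal_flip, vflip = vertical_flip,
                          rot90 = rot90, ssr = shift_scale_rotate,
                          bc = brightness_contrast, hsv = hue_saturation_value,
                          blur = gaussian_blur),
                 shift_limit = shift_limit, scale_limit = scale_limit,
                 rotate_limit = rotate_limit,
                 brightness_limit = brightness_limit,
                 contrast_limit = contrast_limit, hue_shift = hue_shift,
                 sat_shift = sat_shift, val_shift = val_shift,
                 blur_kernels = blur_kernels, seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Apply a seeded augmentation to one image
#'
#' Each enabled operation fires with its configured probability, using the
#' RNG stream derived from `(spec$seed, stream_key)`; the result is
#' deterministic per stream key and keeps the input dimensions. With
#' `ensure_geometric = TRUE`, a quarter-turn is forced when no geometric op
#' fired, so an augmented copy never duplicates its parent.
#'
#' @param img H x W x 3 array in \[0,255\].
#' @param spec an [augmentation_spec()].
#' @param stream_key any value identifying this draw (e.g. output filename).
#' @param ensure_geometric force at least one geometric op.
#' @return augmented image.
#' @export
augment_image <- function(img, spec, stream_key, ensure_geometric = FALSE) {
  assert_image(img)
  with_seed(stream_seed(spec$seed, "augment", stream_key), {
    geometric <- FALSE
    if (runif(1) < spec$p$hflip) { img <- flip_image(img, TRUE); geometric <- TRUE }
    if (runif(1) < spec$p$vflip) { img <- flip_image(img, FALSE); geometric <- TRUE }
    if (runif(1) < spec$p$rot90) {
      k <- sample(1:3, 1)
      img <- rot90_image(img, k); geometric <- TRUE
    }
    if (runif(1) < spec$p$ssr) {
      img <- affine_warp(img,
                         shift_frac = runif(2, -spec$shift_limit, spec$shift_limit),
                         scale = 1 + runif(1, -spec$scale_limit, spec$scale_limit),
                         degrees = runif(1, -spec$rotate_limit, spec$rotate_limit))
      geometric <- TRUE
    }
    if (runif(1) < spec$p$bc) {
      b <- runif(1, -spec$brightness_limit, spec$brightness_limit) * 255
      ct <- 1 + runif(1, -spec$contrast_limit, spec$contrast_limit)
      img <- clip255((img - 127.5) * ct + 127.5 + b)
    }
    if (runif(1) < spec$p$hsv) {
      hsv <- rgb_to_hsv_mat(img)
      hsv[, 1] <- hsv[, 1] + runif(1, -spec$hue_shift, spec$hue_shift)
      hsv[, 2] <- hsv[, 2] + runif(1, -spec$sat_shift, spec$sat_shift)
      hsv[, 3] <- hsv[, 3] + runif(1, -spec$val_shift, spec$val_shift)
      img <- hsv_to_rgb_img(hsv, dim(img))
    }
    if (runif(1) < spec$p$blur) {
      img <- gaussian_blur(img, sample(spec$blur_kernels, 1))
    }
    if (ensure_geometric && !geometric) img <- rot90_image(img, sample(1:3, 1))
    img
  })
}

#' Execute a balancing plan
#'
#' Generates exactly `n_to_generate` augmented minority-class images per
#' magnification, sampling parent originals uniformly with replacement,
#' writing them under `out_dir` with an `_aug<i>` suffix, and returning the
#' merged manifest. Original rows are never modified.
#'
#' @param manifest the scanned `dataset_manifest` (images readable under its
#'   root attribute or `in_dir`).
#' @param plan a [plan_balance()] result computed from the same manifest.
#' @param spec an [augmentation_spec()].
#' @param out_dir directory for augmented images.
#' @param in_dir image root (defaults to the manifest's root attribute).
#' @return merged `dataset_manifest` with origin = "augmented" rows appended.
#' @export
execute_plan <- function(manifest, plan, spec, out_dir,
                         in_dir = attr(manifest, "root")) {
  stopifnot(inherits(plan, "balance_plan"))
  orig <- manifest[manifest$origin == "original", , drop = FALSE]
  new_rows <- list()
  for (r in seq_len(nrow(plan))) {
    n <- plan$n_to_generate[r]
    if (n == 0) next
    mag <- plan$magnification[r]
    minority <- plan$minority_class[r]
    pool <- orig[orig$magnification == mag & orig$class_label == minority, ,
                 drop = FALSE]
    parents <- with_seed(stream_seed(spec$seed, "parents", mag),
                         sample(nrow(pool), n, replace = TRUE))
    for (i in seq_len(n)) {
      prow <- pool[parents[i], ]
      rel <- sub("\\.([A-Za-z]+)$", sprintf("_aug%04d.\\1", i), prow$path)
      img <- read_image(file.path(in_dir, prow$path))
      aug <- augment_image(img, spec, rel, ensure_geometric = TRUE)
      write_image(aug, file.path(out_dir, rel))
      nr <- prow
      nr$path <- rel; nr$origin <- "augmented"; nr$parent <- prow$path
      new_rows[[length(new_rows) + 1L]] <- nr
    }
  }
  merged <- rbind(as.data.frame(manifest),
                  if (length(new_rows)) do.call(rbind, new_rows))
  new_manifest(merged, root = attr(manifest, "root"))
}

# ---- stratified splitting ---------------------------------------------------

#' Split specification
#'
#' @param ratios train/val/test proportions; must sum to 1.
#' @param seed RNG seed.
#' @param unit `"image"` (default; matches published counts) or `"patient"`
#'   (whole patients per split, avoiding patient leakage).
#' @return object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(0.70, 0.15, 0.15), seed = 42L,
                       unit = c("image", "patient")) {
  stopifnot(length(ratios) == 3, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-9)
  structure(list(ratios = ratios, seed = as.integer(seed),
                 unit = match.arg(unit)),
            class = "split_spec")
}

largest_remainder <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties broken by split order (train, val, test)
    ord <- order(-(raw - base), seq_along(ratios))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Stratified train/val/test split
#'
#' Within each (magnification, class) stratum, rows are partitioned into
#' train/val/test at the requested ratios with largest-remainder rounding;
#' the assignment is deterministic under the spec seed. In patient-unit mode
#' whole patients are assigned greedily to the emptiest split.
#'
#' @param manifest a `dataset_manifest`.
#' @param spec a [split_spec()].
#' @return the manifest with the `split` column filled in.
#' @export
stratified_split <- function(manifest, spec = split_spec()) {
  splits <- c("train", "val", "test")
  out <- manifest
  strata <- unique(manifest[, c("magnification", "class_label")])
  strata <- strata[order(strata$magnification, strata$class_label), ]
  for (s in seq_len(nrow(strata))) {
    idx <- which(manifest$magnification == strata$magnification[s] &
                   manifest$class_label == strata$class_label[s])
    idx <- idx[order(manifest$path[idx])]
    if (spec$unit == "image") {
      if (length(idx) < 3)
        stop_gwovit("stratum too small for an image-level split", "small_stratum")
      perm <- with_seed(stream_seed(spec$seed, "split",
                                    strata$magnification[s],
                                    strata$class_label[s]),
                        sample(length(idx)))
      sizes <- largest_remainder(length(idx), spec$ratios)
      lab <- rep(splits, times = sizes)
      out$split[idx[perm]] <- lab
    } else {
      pats <- unique(manifest$patient_id[idx])
      perm <- with_seed(stream_seed(spec$seed, "psplit",
                                    strata$magnification[s],
                                    strata$class_label[s]),
                        sample(pats))
      filled <- c(train = 0, val = 0, test = 0)
      target <- spec$ratios * length(idx)
      for (p in perm) {
        pick <- which.max(target - filled) # emptiest relative to target
        pid <- idx[manifest$patient_id[idx] == p]
        out$split[pid] <- splits[pick]
        filled[pick] <- filled[pick] + length(pid)
      }
    }
  }
  out
}
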