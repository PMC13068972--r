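# Shared helpers: tiny configurations and oracles used across test files.

angle_deg <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi

quantize <- function(img) round(pmin(pmax(img, 0), 255))

# A small clean fixture world: one magnification, no corruption.
clean_fixture_cfg <- function(n = 2, size = 48, seed = 5, ...) {
  fixture_config(images_per_class_per_mag = n, magnifications = 40,
                 image_size = size,
                 nuclei_density = c(benign = 10, malignant = 20),
                 seed = seed, ...)
}

tiny_vit_cfg <- function(image_size = 16, ...) {
  vit_config(image_size = image_size, patch_size = 8, projection_dim = 8,
             num_heads = 2, key_dim = 4, depth = 2, mlp_ratio = 2,
             head_hidden = 6, attention_dropout = 0, mlp_dropout = 0,
             head_dropout = 0, ...)
}

random_image <- function(size = 24, seed = 1) {
  gwovit:::with_seed(seed,
    array(runif(size * size * 3, 0, 255), dim = c(size, size, 3)))
}

# Synthetic manifest rows without any files on disk.
fake_manifest <- function(n_benign, n_malignant, mag = 40) {
  df <- data.frame(
    path = c(sprintf("benign/s/p/%dX/b%04d.png", mag, seq_len(n_benign)),
             sprintf("malignant/s/p/%dX/m%04d.png", mag, seq_len(n_malignant))),
    class_label = rep(c("benign", "malignant"), c(n_benign, n_malignant)),
    subtype = "s", patient_id = "p", magnification = mag)
  gwovit:::new_manifest(df)
}

# ReferenceStats carrying only intensity CDFs (enough for match_histogram).
build_reference_stats_cdf_only <- function(img) {
  structure(list(rgb_cdfs = sapply(1:3, function(k)
    gwovit:::channel_cdf(img[, , k]))), class = "reference_stats")
}
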