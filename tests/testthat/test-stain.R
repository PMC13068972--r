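# Histogram matching, Shades-of-Gray, optical density and Macenko stages.

test_that("histogram matching maps the worked 4-level example by hand", {
  # source channel {0, 0, 128, 255}; reference {64, 64, 191, 191}
  src <- array(rep(c(0, 0, 128, 255), 3), dim = c(2, 2, 3))
  ref <- array(rep(c(64, 64, 191, 191), 3), dim = c(2, 2, 3))
  stats <- build_reference_stats_cdf_only(ref)
  out <- match_histogram(src, stats)
  expect_setequal(as.vector(out[, , 1]), c(64, 64, 191, 191))
  expect_setequal(as.vector(out[, , 2]), c(64, 64, 191, 191))
})

test_that("matching an image to itself is the identity on the 8-bit grid", {
  img <- quantize(random_image(32, seed = 11))
  out <- match_histogram(img, build_reference_stats_cdf_only(img))
  expect_equal(out, img)
})

test_that("matching to a constant reference collapses to that constant", {
  img <- random_image(16, seed = 12)
  ref <- array(77, dim = c(16, 16, 3))
  out <- match_histogram(img, build_reference_stats_cdf_only(ref))
  expect_true(all(out == 77))
})

test_that("histogram matching never increases the CDF objective", {
  ref <- random_image(32, seed = 20)
  stats <- build_reference_stats_cdf_only(ref)
  objective <- function(img, k)
    sum((gwovit:::channel_cdf(img[, , k]) - stats$rgb_cdfs[, k])^2)
  for (s in 1:5) {
    img <- random_image(32, seed = 100 + s)
    out <- match_histogram(img, stats)
    for (k in 1:3) expect_lte(objective(out, k), objective(img, k) + 1e-12)
  }
})

test_that("illuminant estimation matches closed forms", {
  g <- array(90, dim = c(8, 8, 3))
  expect_equal(estimate_illuminant(g, 6), rep(90, 3), tolerance = 1e-9)

  img <- random_image(16, seed = 13)
  expect_equal(estimate_illuminant(img, 1),
               c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3])),
               tolerance = 1e-9)

  two <- array(0, dim = c(1, 2, 3)); two[1, 2, ] <- 255
  expect_equal(estimate_illuminant(two, 6), rep((255^6 / 2)^(1 / 6), 3),
               tolerance = 1e-6)
})

test_that("shades of gray equalizes channel illuminants and undoes a cast", {
  img <- random_image(32, seed = 14) * 0.55   # headroom against clipping
  # force equal channel 6-norms: a gray-world "ideal" image
  e <- estimate_illuminant(img, 6)
  ideal <- sweep(img, 3, mean(e) / e, "*")
  out_id <- shades_of_gray(ideal, 6)
  expect_lt(max(abs(out_id - ideal)), 1.0)

  cast <- ideal; cast[, , 1] <- cast[, , 1] * 1.5
  corrected <- shades_of_gray(cast, 6)
  # correction restores the ideal up to one global brightness factor
  scale <- mean(corrected) / mean(ideal)
  expect_lt(max(abs(corrected / scale - ideal)), 1.0)
  e_out <- estimate_illuminant(corrected, 6)
  expect_lt(max(e_out) / min(e_out), 1.01)
  expect_lte(max(e_out) / min(e_out),
             max(estimate_illuminant(cast, 6)) / min(estimate_illuminant(cast, 6)))
})

test_that("shades of gray is idempotent and rejects empty channels", {
  img <- random_image(24, seed = 15) * 0.7
  once <- shades_of_gray(img, 6)
  twice <- shades_of_gray(once, 6)
  expect_lt(max(abs(twice - once)), 1.0)

  dead <- img; dead[, , 2] <- 0
  expect_error(shades_of_gray(dead, 6), class = "zero_illuminant")
})

test_that("optical density follows -log((I+eps)/I0) with clamping", {
  cfg <- preprocess_config()
  img <- array(cfg$I0, dim = c(2, 2, 3))
  od <- compute_od(img, cfg)
  expect_lt(max(od$values), 1e-5)

  img0 <- array(0, dim = c(2, 2, 3))
  od0 <- compute_od(img0, cfg)
  expect_equal(max(od0$values), -log(cfg$epsilon * 255 / cfg$I0),
               tolerance = 1e-9)

  # strictly decreasing in intensity
  ladder <- array(rep(seq(0, 239, length.out = 12), 3), dim = c(3, 4, 3))
  odl <- compute_od(ladder, cfg)
  expect_true(all(diff(odl$values[order(as.vector(ladder[, , 1])), 1]) < 0))
})

test_that("stain basis estimation recovers fixture ground truth", {
  cfg <- clean_fixture_cfg(n = 3, seed = 5)
  pc <- preprocess_config()
  for (i in 1:3) {
    r <- render_image(cfg, "malignant", 40, i)
    truth <- matrix(unlist(r$truth[paste0("basis", 1:6)]), 3, 2)
    B <- estimate_stain_basis(compute_od(quantize(r$image), pc), pc)
    expect_lt(angle_deg(B[, 1], truth[, 1]), 2)
    expect_lt(angle_deg(B[, 2], truth[, 2]), 2)

    # literal (raw SVD) mode can only promise the spanned plane
    Bl <- estimate_stain_basis(compute_od(quantize(r$image), pc),
                               preprocess_config(basis_mode = "literal"))
    # principal angle between the two 2-D subspaces
    qa <- qr.Q(qr(truth)); qb <- qr.Q(qr(unclass(Bl)))
    sv <- svd(crossprod(qa, qb))$d
    # 8-bit quantization and OD clamping tilt the fitted plane slightly
    expect_lt(acos(min(1, min(sv))) * 180 / pi, 3)
  }
})

test_that("degenerate images are rejected with named errors", {
  pc <- preprocess_config()
  white <- array(250, dim = c(16, 16, 3))
  expect_error(estimate_stain_basis(compute_od(white, pc), pc),
               class = "background_only")

  # single-stain image: rank-1 optical density by construction
  B <- default_stain_basis()
  conc <- matrix(runif(256, 0.4, 1.2), 1)
  trans <- 240 * exp(-(B[, 1, drop = FALSE] %*% conc))
  img <- array(t(trans), dim = c(16, 16, 3))
  expect_error(estimate_stain_basis(compute_od(img, pc), pc),
               class = "rank_deficient")
})

test_that("macenko reconstruction sends background to white and couples to references", {
  cfg <- clean_fixture_cfg(n = 1, seed = 6)
  img <- quantize(render_image(cfg, "malignant", 40, 1)$image)
  pc <- preprocess_config()

  lit <- macenko_normalize(img, pc)
  expect_true(all(lit >= 0 & lit <= 255))
  # background pixels (at/above I0) reconstruct to ~I0
  bg <- img[, , 1] >= pc$I0 - 1 & img[, , 2] >= pc$I0 - 1 & img[, , 3] >= pc$I0 - 1
  if (any(bg)) {
    for (k in 1:3) expect_lt(max(abs(lit[, , k][bg] - pc$I0)), 3)
  }

  # reference-coupled self-normalization reproduces the input
  pr <- preprocess_config(mode = "reference")
  ref <- build_reference_stats(img, pr)
  self <- macenko_normalize(img, pr, ref)
  expect_lt(mean(abs(self - img)), 2)

  # and equals the literal output when the reference maxima are ones
  ref1 <- ref; ref1$robust_max_ref <- c(1, 1)
  ref1$stain_basis_ref <- estimate_stain_basis(compute_od(img, pc), pc)
  expect_lt(max(abs(macenko_normalize(img, pr, ref1) - lit)), 1e-8)

  expect_error(macenko_normalize(img, pr, ref = NULL), class = "missing_reference")
})

test_that("matched concentration fields under different basis jitters normalize together", {
  # two renders sharing (seed, class, mag, index) streams except for jitter:
  # reference-coupling to one common ref must pull them together
  base <- clean_fixture_cfg(n = 1, seed = 40)
  jit <- clean_fixture_cfg(n = 1, seed = 40, stain_jitter_deg = 4)
  a <- quantize(render_image(base, "malignant", 40, 1)$image)
  b <- quantize(render_image(jit, "malignant", 40, 1)$image)
  pr <- preprocess_config(mode = "reference")
  ref <- build_reference_stats(a, pr)
  na <- macenko_normalize(a, pr, ref)
  nb <- macenko_normalize(b, pr, ref)
  expect_lt(mean(abs(na - nb)), 5)
})
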