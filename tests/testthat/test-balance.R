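# Manifest scanning, published-count arithmetic, balancing and splitting.

test_that("scan_manifest parses the layout and reports rejects", {
  root <- withr::local_tempdir()
  img <- array(128, dim = c(8, 8, 3))
  write_image(img, file.path(root, "benign/adenosis/p1/40X/a.png"))
  write_image(img, file.path(root, "malignant/ductal/p2/400X/b.png"))
  dir.create(file.path(root, "benign/odd"), recursive = TRUE)
  writeLines("junk", file.path(root, "benign/odd/readme.txt"))

  man <- scan_manifest(root)
  expect_equal(nrow(man), 2)
  row <- man[man$path == "benign/adenosis/p1/40X/a.png", ]
  expect_equal(row$class_label, "benign")
  expect_equal(row$subtype, "adenosis")
  expect_equal(row$patient_id, "p1")
  expect_equal(row$magnification, 40L)
  expect_true("benign/odd/readme.txt" %in% attr(man, "rejects"))

  expect_error(scan_manifest(file.path(root, "nope")), class = "no_root")
})

test_that("published count table reproduces the benchmark totals", {
  man <- expand_counts_manifest(breakhis_counts())
  ct <- count_by_class_mag(man)
  expect_equal(ct$counts["malignant", "40"], 1370L)
  expect_equal(ct$counts["benign", "40"], 625L)   # 114+253+109+149
  expect_equal(unname(ct$class_totals), c(2480L, 5429L))
  expect_equal(ct$grand_total, 7909L)
})

test_that("balance plan equalizes to the majority class", {
  ct <- count_by_class_mag(expand_counts_manifest(breakhis_counts()))
  plan <- plan_balance(ct)
  expect_equal(plan$n_to_generate[plan$magnification == 40], 745)  # 1370 - 625
  expect_equal(plan$minority_class, rep("benign", 4))
  expect_equal(sum(plan$target_per_class), 5429)
  # executing the plan leaves both classes at the malignant totals
  post <- ct$counts
  post["benign", ] <- post["benign", ] + plan$n_to_generate
  expect_equal(unname(rowSums(post)), c(5429, 5429))

  bal <- fake_manifest(10, 10)
  plan0 <- plan_balance(count_by_class_mag(bal))
  expect_true(all(plan0$n_to_generate == 0))

  lonely <- fake_manifest(5, 0)
  expect_error(plan_balance(count_by_class_mag(lonely)), class = "class_absent")
})

test_that("augmentation ops satisfy their algebraic identities", {
  img <- random_image(24, seed = 7)
  expect_identical(rot90_image(img, 4), img)
  expect_identical(rot90_image(rot90_image(img, 1), 3), img)

  only_hflip <- augmentation_spec(horizontal_flip = 1, vertical_flip = 0,
                                  rot90 = 0, shift_scale_rotate = 0,
                                  brightness_contrast = 0,
                                  hue_saturation_value = 0, gaussian_blur = 0)
  once <- augment_image(img, only_hflip, "k1")
  expect_false(identical(once, img))
  expect_identical(augment_image(once, only_hflip, "k2"), img)

  spec <- augmentation_spec(seed = 9)
  a <- augment_image(img, spec, "key")
  b <- augment_image(img, spec, "key")
  expect_identical(a, b)
  expect_false(identical(a, augment_image(img, spec, "other")))
  expect_equal(dim(a), dim(img))
})

test_that("execute_plan fills the deficit and conserves originals", {
  root <- withr::local_tempdir()
  cfg <- fixture_config(images_per_class_per_mag = 6, magnifications = 40,
                        image_size = 32,
                        nuclei_density = c(benign = 6, malignant = 12), seed = 13)
  man <- make_dataset(cfg, root, overwrite = TRUE)
  # drop 4 benign originals -> 2 benign vs 6 malignant
  drop <- which(man$class_label == "benign")[1:4]
  man2 <- gwovit:::new_manifest(as.data.frame(man)[-drop, ],
                                root = attr(man, "root"))
  plan <- plan_balance(count_by_class_mag(man2))
  expect_equal(plan$n_to_generate, 4)

  outdir <- withr::local_tempdir()
  merged <- execute_plan(man2, plan, augmentation_spec(seed = 5), outdir)
  ct <- count_by_class_mag(merged)
  expect_equal(ct$counts["benign", "40"], ct$counts["malignant", "40"])
  expect_identical(as.data.frame(merged[merged$origin == "original", 1:5]),
                   as.data.frame(man2[, 1:5]))
  aug <- merged[merged$origin == "augmented", ]
  expect_equal(nrow(aug), 4)
  expect_false(any(aug$path %in% man2$path))
  expect_true(all(file.exists(file.path(outdir, aug$path))))
  expect_true(all(aug$parent %in% man2$path))

  # plan idempotence: no deficit remains
  expect_true(all(plan_balance(count_by_class_mag(merged))$n_to_generate == 0))
})

test_that("stratified split hits exact ratios and partitions the manifest", {
  man <- fake_manifest(100, 100)
  sp <- stratified_split(man, split_spec(seed = 42))
  tab <- table(sp$split, sp$class_label)
  expect_equal(unname(tab[c("train", "val", "test"), "benign"]), c(70, 15, 15))
  expect_equal(unname(tab[c("train", "val", "test"), "malignant"]), c(70, 15, 15))

  sp2 <- stratified_split(man, split_spec(seed = 42))
  expect_identical(sp$split, sp2$split)
  expect_false(identical(sp$split,
                         stratified_split(man, split_spec(seed = 1))$split))

  # partition: union = manifest, no row in two splits (split is a column,
  # so check all rows assigned)
  expect_true(all(sp$split %in% c("train", "val", "test")))
  expect_equal(nrow(sp), nrow(man))

  # largest remainder on an awkward size: 10 -> 7/2/1 (val wins the tie)
  small <- fake_manifest(10, 10)
  sps <- stratified_split(small, split_spec(seed = 1))
  expect_equal(as.integer(table(sps$split[sps$class_label == "benign"])[c("train", "val", "test")]),
               c(7L, 2L, 1L))

  expect_error(stratified_split(fake_manifest(2, 5), split_spec()),
               class = "small_stratum")
})

test_that("patient-unit splits keep whole patients together", {
  df <- data.frame(
    path = sprintf("benign/s/p%d/40X/i%03d.png", rep(1:10, each = 6), 1:60),
    class_label = "benign", subtype = "s",
    patient_id = rep(sprintf("p%d", 1:10), each = 6), magnification = 40)
  df2 <- df
  df2$path <- sub("benign", "malignant", df2$path)
  df2$class_label <- "malignant"
  man <- gwovit:::new_manifest(rbind(df, df2))
  sp <- stratified_split(man, split_spec(seed = 3, unit = "patient"))
  per_pat <- tapply(sp$split, paste(sp$class_label, sp$patient_id),
                    function(x) length(unique(x)))
  expect_true(all(per_pat == 1))
  expect_true(all(c("train", "val", "test") %in% sp$split))
})
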