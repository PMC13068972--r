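test_that("patch arithmetic follows the published geometry", {
  expect_equal(num_patches(224, 16), 196L)
  expect_equal(num_patches(16, 16), 1L)
  expect_equal(num_patches(224, 14), 256L)  # (224/14)^2
  expect_error(num_patches(224, 15), class = "indivisible")

  expect_equal(patch_flatten_dim(16, 3), 768L)
  expect_equal(patch_flatten_dim(1, 1), 1L)
  expect_equal(patch_flatten_dim(8, 3), 192L)
})

test_that("config validation names each violated invariant", {
  expect_s3_class(vit_config(), "vit_config")  # compact default is valid
  expect_error(vit_config(projection_dim = 100, num_heads = 8),
               class = "head_divisibility")
  expect_error(vit_config(head_dropout = 1.2), class = "dropout_range")
  expect_error(vit_config(depth = 0), class = "depth_range")
  expect_error(vit_config(head_hidden = integer(0)), class = "head_hidden_empty")
})

test_that("forward pass yields probability rows and is deterministic in eval mode", {
  cfg <- tiny_vit_cfg()
  model <- build_model(cfg, seed = 1)
  imgs <- lapply(1:4, function(i) random_image(16, seed = i))
  p1 <- predict_vit(model, imgs)
  expect_equal(dim(p1), c(4L, 2L))
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-5)
  expect_identical(p1, predict_vit(model, imgs))
})

test_that("token counts include the class token only in cls mode", {
  expect_equal(gwovit:::vit_tokens(vit_config(aggregation = "gap")), 196L)
  expect_equal(gwovit:::vit_tokens(vit_config(aggregation = "cls_token")), 197L)
})

test_that("closed-form parameter count matches the built model and is ordered", {
  for (agg in c("gap", "cls_token")) {
    cfg <- vit_config(image_size = 32, patch_size = 8, projection_dim = 16,
                      num_heads = 4, key_dim = 4, depth = 3, head_hidden = c(12, 8),
                      aggregation = agg)
    model <- build_model(cfg, seed = 2)
    expect_equal(count_parameters(cfg),
                 sum(vapply(model$params, length, integer(1))))
  }
  deeper <- vit_config(depth = 7)
  expect_gt(count_parameters(deeper), count_parameters(vit_config(depth = 6)))
  small <- vit_config(depth = 4, num_heads = 4, projection_dim = 64, key_dim = 16)
  large <- vit_config(depth = 8, num_heads = 12, projection_dim = 252,
                      key_dim = 21)
  expect_gt(count_parameters(large), count_parameters(small))
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_vit_cfg()
  model <- build_model(cfg, seed = 3)
  imgs <- lapply(1:3, function(i) random_image(16, seed = 10 + i))
  ds <- vit_dataset(imgs, c(1, 2, 1), cfg)
  Xb <- do.call(rbind, ds$x)
  fw <- gwovit:::vit_pass(model$params, cfg, Xb, 3, train = TRUE)
  gr <- gwovit:::vit_backward(model$params, cfg, fw, ds$y)
  lossfn <- function(p)
    gwovit:::cross_entropy(gwovit:::vit_pass(p, cfg, Xb, 3)$probs, ds$y)
  set.seed(4)
  for (nm in c("emb_W", "pos", "l1_q_W", "l1_k_W", "l1_v_W", "l1_o_W",
               "l2_m1_W", "l2_ln2_g", "lnf_b", "head1_W", "out_W")) {
    for (j in sample(length(model$params[[nm]]), 2)) {
      eps <- 1e-5
      up <- model$params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- model$params; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      expect_equal(gr[[nm]][j], num, tolerance = 1e-4)
    }
  }
})

test_that("patch-order invariance holds exactly when positions are off and gap pools", {
  cfg <- tiny_vit_cfg(image_size = 32)  # 16 tokens
  model <- build_model(cfg, seed = 5)
  img <- random_image(32, seed = 6)
  patches <- extract_patches(img, cfg$patch_size)
  perm <- gwovit:::with_seed(7, sample(nrow(patches)))

  with_pos <- predict_vit(model, list(patches))
  with_pos_perm <- predict_vit(model, list(patches[perm, ]))
  expect_false(isTRUE(all.equal(with_pos, with_pos_perm, tolerance = 1e-10)))

  model$params$pos[] <- 0
  p0 <- predict_vit(model, list(patches))
  p0_perm <- predict_vit(model, list(patches[perm, ]))
  expect_equal(p0, p0_perm, tolerance = 1e-10)
})

test_that("one small AdamW step decreases the batch loss", {
  cfg <- tiny_vit_cfg()
  model <- build_model(cfg, seed = 8)
  imgs <- lapply(1:4, function(i) random_image(16, seed = 20 + i))
  ds <- vit_dataset(imgs, c(1, 2, 2, 1), cfg)
  Xb <- do.call(rbind, ds$x)
  fw <- gwovit:::vit_pass(model$params, cfg, Xb, 4, train = TRUE)
  loss0 <- gwovit:::cross_entropy(fw$probs, ds$y)
  gr <- gwovit:::vit_backward(model$params, cfg, fw, ds$y)
  st <- gwovit:::adamw_step(model$params, gr, list(t = 0L, m = list(), v = list()),
                            lr = 1e-3, wd = 0)
  loss1 <- gwovit:::cross_entropy(
    gwovit:::vit_pass(st$params, cfg, Xb, 4)$probs, ds$y)
  expect_lt(loss1, loss0)
})

test_that("training history and callbacks honor their contracts", {
  cfg <- tiny_vit_cfg()
  imgs <- lapply(1:12, function(i) random_image(16, seed = 30 + i))
  y <- rep(c("benign", "malignant"), 6)
  tr <- vit_dataset(imgs[1:8], y[1:8], cfg)
  va <- vit_dataset(imgs[9:12], y[9:12], cfg)

  one <- train_vit(build_model(cfg, 9), tr, va,
                   train_config(epochs = 1, batch_size = 4, seed = 1))
  expect_equal(nrow(one$history), 1L)
  expect_named(one$history,
               c("epoch", "train_loss", "train_acc", "val_loss", "val_acc", "lr"))

  # zero learning rate: no improvement after the first epoch -> early stop
  frozen <- train_vit(build_model(cfg, 9), tr, va,
                      train_config(learning_rate = 1e-30, epochs = 20,
                                   early_stopping_patience = 3,
                                   plateau_patience = 2, min_lr = 0,
                                   batch_size = 4, seed = 1))
  expect_true(frozen$stopped_early)
  expect_lt(nrow(frozen$history), 20)
  expect_lte(frozen$best_epoch, nrow(frozen$history))
  # plateau reduction was recorded in the lr column
  expect_lt(min(frozen$history$lr), 1e-30)

  expect_error(train_vit(build_model(cfg, 9), tr,
                         structure(list(x = list(), y = integer(), n = 0L),
                                   class = "vit_dataset"),
                         train_config(epochs = 1)),
               class = "empty_split")

  # seeded runs are reproducible
  r1 <- train_vit(build_model(cfg, 9), tr, va,
                  train_config(epochs = 2, batch_size = 4, seed = 2))
  r2 <- train_vit(build_model(cfg, 9), tr, va,
                  train_config(epochs = 2, batch_size = 4, seed = 2))
  expect_identical(r1$history, r2$history)
})
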