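# Compact Vision Transformer, implemented directly in base R.
#
# There is no deep-learning framework in the dependency stack, and the model
# itself is the scientific core of the package, so the forward pass, the
# backward pass and the AdamW optimizer are written out explicitly. The
# architecture is the standard pre-norm ViT encoder: a strided patch
# projection (equivalent to a Conv2D whose kernel and stride equal the patch
# size), learnable 1-D positional embeddings, `depth` blocks of
# LayerNorm -> multi-head self-attention -> residual -> LayerNorm -> GELU MLP
# -> residual, a final LayerNorm, global average pooling (or a class token),
# and a GELU MLP classification head with softmax output.
#
# Internally a batch is one (B*T) x D matrix whose rows are image-major token
# blocks; attention operates on each image's T x T block.

#' Number of patch tokens
#'
#' For an H x W image with p x p patches, `N = H * W / p^2`.
#'
#' @param image_size square image side.
#' @param patch_size patch side; must divide `image_size`.
#' @return integer patch count.
#' @examples
#' num_patches(224, 16) # 196
#' @export
num_patches <- function(image_size, patch_size) {
  if (image_size %% patch_size != 0)
    stop_gwovit("image_size must be divisible by patch_size", "indivisible")
  as.integer((image_size / patch_size)^2)
}

#' Flattened patch vector length
#'
#' @param patch_size patch side.
#' @param channels number of image channels.
#' @return `patch_size^2 * channels`.
#' @examples
#' patch_flatten_dim(16, 3) # 768
#' @export
patch_flatten_dim <- function(patch_size, channels = 3) {
  stopifnot(patch_size >= 1, channels >= 1)
  as.integer(patch_size^2 * channels)
}

#' Vision Transformer configuration
#'
#' Defaults are the compact experimental configuration (128-dim embeddings,
#' 8 heads of key dimension 16, 6 encoder layers, GAP aggregation, head
#' \[256, 128\]); the ViT-Base geometry (12 x 768, cls token) is reachable by
#' overriding fields. The transformer MLP hidden width defaults to
#' `mlp_ratio * projection_dim`.
#'
#' @param image_size,patch_size input geometry; size must divide evenly.
#' @param channels image channels.
#' @param projection_dim token embedding width; divisible by `num_heads`.
#' @param num_heads attention heads.
#' @param key_dim per-head query/key/value width.
#' @param depth encoder layers (>= 1).
#' @param mlp_ratio transformer MLP expansion ratio.
#' @param head_hidden classifier hidden layer sizes (nonempty).
#' @param attention_dropout,mlp_dropout,head_dropout dropout rates in \[0,1).
#' @param aggregation `"gap"` or `"cls_token"`.
#' @param num_classes output classes.
#' @return validated object of class `vit_config`.
#' @export
vit_config <- function(image_size = 224, patch_size = 16, channels = 3,
                       projection_dim = 128, num_heads = 8, key_dim = 16,
                       depth = 6, mlp_ratio = 2, head_hidden = c(256, 128),
                       attention_dropout = 0.10, mlp_dropout = 0.10,
                       head_dropout = 0.50,
                       aggregation = c("gap", "cls_token"), num_classes = 2) {
  cfg <- structure(list(image_size = as.integer(image_size),
                        patch_size = as.integer(patch_size),
                        channels = as.integer(channels),
                        projection_dim = as.integer(projection_dim),
                        num_heads = as.integer(num_heads),
                        key_dim = as.integer(key_dim),
                        depth = as.integer(depth), mlp_ratio = mlp_ratio,
                        head_hidden = as.integer(head_hidden),
                        attention_dropout = attention_dropout,
                        mlp_dropout = mlp_dropout, head_dropout = head_dropout,
                        aggregation = match.arg(aggregation),
                        num_classes = as.integer(num_classes)),
                   class = "vit_config")
  validate_config(cfg)
}

#' Validate a ViT configuration
#'
#' Returns the configuration unchanged when every invariant holds; otherwise
#' raises a named error for the first violated invariant.
#'
#' @param cfg a `vit_config`.
#' @return `cfg`.
#' @export
validate_config <- function(cfg) {
  if (cfg$image_size %% cfg$patch_size != 0)
    stop_gwovit("image_size not divisible by patch_size", "indivisible")
  if (cfg$projection_dim %% cfg$num_heads != 0)
    stop_gwovit("projection_dim not divisible by num_heads", "head_divisibility")
  for (d in c(cfg$attention_dropout, cfg$mlp_dropout, cfg$head_dropout))
    if (d < 0 || d >= 1) stop_gwovit("dropout must be in [0, 1)", "dropout_range")
  if (cfg$depth < 1) stop_gwovit("depth must be >= 1", "depth_range")
  if (length(cfg$head_hidden) < 1)
    stop_gwovit("head_hidden must be nonempty", "head_hidden_empty")
  cfg
}

vit_tokens <- function(cfg) {
  num_patches(cfg$image_size, cfg$patch_size) +
    (cfg$aggregation == "cls_token")
}

attn_width <- function(cfg) cfg$num_heads * cfg$key_dim

mlp_width <- function(cfg) as.integer(round(cfg$mlp_ratio * cfg$projection_dim))

#' Closed-form trainable parameter count
#'
#' Matches the constructed model's actual parameter count exactly.
#'
#' @param cfg a `vit_config`.
#' @return integer count.
#' @export
count_parameters <- function(cfg) {
  validate_config(cfg)
  D <- cfg$projection_dim; A <- attn_width(cfg); M <- mlp_width(cfg)
  pd <- patch_flatten_dim(cfg$patch_size, cfg$channels)
  Tn <- vit_tokens(cfg)
  n <- pd * D + D                       # patch embedding
  n <- n + Tn * D                       # positional embeddings
  if (cfg$aggregation == "cls_token") n <- n + D
  per_layer <- 2 * D +                  # ln1
    3 * (D * A + A) +                   # q, k, v
    (A * D + D) +                       # output projection
    2 * D +                             # ln2
    (D * M + M) + (M * D + D)           # mlp
  n <- n + cfg$depth * per_layer + 2 * D  # final layernorm
  dims <- c(D, cfg$head_hidden, cfg$num_classes)
  n + sum(dims[-length(dims)] * dims[-1] + dims[-1])
}

# ---- initialization ---------------------------------------------------------

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build (initialize) a ViT model
#'
#' Xavier/Glorot-initialized weights; deterministic for a fixed seed.
#'
#' @param cfg a `vit_config`.
#' @param seed initialization seed.
#' @return object of class `vit_model` holding `cfg` and the parameter list.
#' @export
build_model <- function(cfg, seed = 42L) {
  validate_config(cfg)
  D <- cfg$projection_dim; A <- attn_width(cfg); M <- mlp_width(cfg)
  pd <- patch_flatten_dim(cfg$patch_size, cfg$channels)
  Tn <- vit_tokens(cfg)
  params <- with_seed(seed, {
    p <- list(emb_W = glorot(pd, D), emb_b = numeric(D),
              pos = matrix(stats::rnorm(Tn * D, 0, 0.02), Tn, D))
    if (cfg$aggregation == "cls_token") p$cls <- numeric(D)
    for (l in seq_len(cfg$depth)) {
      p[[sprintf("l%d_ln1_g", l)]] <- rep(1, D)
      p[[sprintf("l%d_ln1_b", l)]] <- numeric(D)
      p[[sprintf("l%d_q_W", l)]] <- glorot(D, A)
      p[[sprintf("l%d_q_b", l)]] <- numeric(A)
      p[[sprintf("l%d_k_W", l)]] <- glorot(D, A)
      p[[sprintf("l%d_k_b", l)]] <- numeric(A)
      p[[sprintf("l%d_v_W", l)]] <- glorot(D, A)
      p[[sprintf("l%d_v_b", l)]] <- numeric(A)
      p[[sprintf("l%d_o_W", l)]] <- glorot(A, D)
      p[[sprintf("l%d_o_b", l)]] <- numeric(D)
      p[[sprintf("l%d_ln2_g", l)]] <- rep(1, D)
      p[[sprintf("l%d_ln2_b", l)]] <- numeric(D)
      p[[sprintf("l%d_m1_W", l)]] <- glorot(D, M)
      p[[sprintf("l%d_m1_b", l)]] <- numeric(M)
      p[[sprintf("l%d_m2_W", l)]] <- glorot(M, D)
      p[[sprintf("l%d_m2_b", l)]] <- numeric(D)
    }
    p$lnf_g <- rep(1, D); p$lnf_b <- numeric(D)
    dims <- c(D, cfg$head_hidden)
    for (i in seq_along(cfg$head_hidden)) {
      p[[sprintf("head%d_W", i)]] <- glorot(dims[i], dims[i + 1])
      p[[sprintf("head%d_b", i)]] <- numeric(dims[i + 1])
    }
    p$out_W <- glorot(dims[length(dims)], cfg$num_classes)
    p$out_b <- numeric(cfg$num_classes)
    p
  })
  structure(list(cfg = cfg, params = params), class = "vit_model")
}

# ---- primitive layers -------------------------------------------------------

addbias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

rowscale <- function(M, g) M * matrix(g, nrow(M), length(g), byrow = TRUE)

softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1, max))
  e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

ln_forward <- function(X, g, b, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = addbias(rowscale(xhat, g), b), xhat = xhat, inv = inv)
}

ln_backward <- function(dy, g, cache) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat); db <- colSums(dy)
  dxh <- rowscale(dy, g)
  m1 <- rowMeans(dxh); m2 <- rowMeans(dxh * xhat)
  list(dx = (dxh - m1 - xhat * m2) * cache$inv, dg = dg, db = db)
}

drop_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  (stats::runif(n) >= p) / (1 - p)
}

#' Extract flattened patch tokens from an image
#'
#' Row-major non-overlapping p x p patches, each flattened to length
#' `p^2 * channels` and standardized by the fixed affine map
#' `(I/255 - 0.7) / 0.25` (0.7 is the typical bright-field H&E tissue
#' brightness); the centering uses no dataset statistics, so there is no
#' train/test leakage. Equivalent to the strided Conv2D patch
#' projection once multiplied by the embedding matrix.
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param patch_size patch side.
#' @return N x (p^2*3) matrix.
#' @export
extract_patches <- function(img, patch_size) {
  H <- dim(img)[1]; p <- patch_size
  n_side <- H / p
  stopifnot(n_side == round(n_side))
  out <- matrix(0, n_side * n_side, p * p * 3)
  k <- 1L
  for (r in seq_len(n_side)) {
    for (cc in seq_len(n_side)) {
      patch <- img[((r - 1) * p + 1):(r * p), ((cc - 1) * p + 1):(cc * p), ]
      out[k, ] <- (as.vector(patch) / 255 - 0.7) / 0.25
      k <- k + 1L
    }
  }
  out
}

#' Bundle images and labels into a ViT dataset
#'
#' Precomputes the patch matrices once so epochs only shuffle and stack.
#'
#' @param images list of H x W x 3 arrays.
#' @param labels character vector (`"benign"`/`"malignant"`) or integer 1/2.
#' @param cfg a `vit_config` (geometry source).
#' @return object of class `vit_dataset`.
#' @export
vit_dataset <- function(images, labels, cfg) {
  classes <- c("benign", "malignant")
  y <- if (is.character(labels) || is.factor(labels))
    match(as.character(labels), classes) else as.integer(labels)
  stopifnot(!anyNA(y), all(y %in% seq_len(cfg$num_classes)))
  x <- lapply(images, extract_patches, patch_size = cfg$patch_size)
  structure(list(x = x, y = y, classes = classes, n = length(y)),
            class = "vit_dataset")
}

# ---- forward / backward -----------------------------------------------------

# Core pass. Xb: (B*N) x pd patch matrix, image-major blocks. If `train`,
# dropout is sampled from the current RNG and caches for backward are kept.
vit_pass <- function(params, cfg, Xb, B, train = FALSE) {
  D <- cfg$projection_dim; hN <- cfg$num_heads; dk <- cfg$key_dim
  N <- nrow(Xb) / B; Tn <- vit_tokens(cfg)
  cls_mode <- cfg$aggregation == "cls_token"

  E <- addbias(Xb %*% params$emb_W, params$emb_b)
  if (cls_mode) {
    M0 <- matrix(0, Tn * B, D)
    cls_rows <- (seq_len(B) - 1L) * Tn + 1L
    patch_rows <- rep((seq_len(B) - 1L) * Tn, each = N) + 1L + seq_len(N)
    M0[cls_rows, ] <- matrix(params$cls, B, D, byrow = TRUE)
    M0[patch_rows, ] <- E
  } else {
    M0 <- E
  }
  tok_idx <- rep(seq_len(Tn), B)
  X <- M0 + params$pos[tok_idx, , drop = FALSE]

  caches <- vector("list", cfg$depth)
  scale <- 1 / sqrt(dk)
  for (l in seq_len(cfg$depth)) {
    pfx <- function(nm) params[[sprintf("l%d_%s", l, nm)]]
    ln1 <- ln_forward(X, pfx("ln1_g"), pfx("ln1_b"))
    Y1 <- ln1$out
    Q <- addbias(Y1 %*% pfx("q_W"), pfx("q_b"))
    K <- addbias(Y1 %*% pfx("k_W"), pfx("k_b"))
    V <- addbias(Y1 %*% pfx("v_W"), pfx("v_b"))
    O <- matrix(0, nrow(Q), ncol(Q))
    attn <- if (train) vector("list", B * hN) else NULL
    amask <- if (train && cfg$attention_dropout > 0) vector("list", B * hN) else NULL
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (h in seq_len(hN)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- softmax_rows(Q[rows, cols, drop = FALSE] %*%
                            t(K[rows, cols, drop = FALSE]) * scale)
        Ad <- A
        if (train && cfg$attention_dropout > 0) {
          mk <- matrix(drop_mask(length(A), cfg$attention_dropout), Tn, Tn)
          Ad <- A * mk
          amask[[(b - 1L) * hN + h]] <- mk
        }
        O[rows, cols] <- Ad %*% V[rows, cols, drop = FALSE]
        if (train) attn[[(b - 1L) * hN + h]] <- A
      }
    }
    AttnOut <- addbias(O %*% pfx("o_W"), pfx("o_b"))
    X2 <- X + AttnOut
    ln2 <- ln_forward(X2, pfx("ln2_g"), pfx("ln2_b"))
    Y2 <- ln2$out
    H1p <- addbias(Y2 %*% pfx("m1_W"), pfx("m1_b"))
    H1 <- gelu(H1p)
    m1k <- if (train && cfg$mlp_dropout > 0)
      matrix(drop_mask(length(H1), cfg$mlp_dropout), nrow(H1), ncol(H1)) else NULL
    H1d <- if (is.null(m1k)) H1 else H1 * m1k
    H2 <- addbias(H1d %*% pfx("m2_W"), pfx("m2_b"))
    m2k <- if (train && cfg$mlp_dropout > 0)
      matrix(drop_mask(length(H2), cfg$mlp_dropout), nrow(H2), ncol(H2)) else NULL
    H2d <- if (is.null(m2k)) H2 else H2 * m2k
    Xn <- X2 + H2d
    if (train)
      caches[[l]] <- list(ln1 = ln1, Y1 = Y1, Q = Q, K = K, V = V, O = O,
                          attn = attn, amask = amask, X2 = X2, ln2 = ln2,
                          Y2 = Y2, H1p = H1p, H1d = H1d, m1k = m1k, m2k = m2k)
    X <- Xn
  }

  lnf <- ln_forward(X, params$lnf_g, params$lnf_b)
  Mf <- lnf$out
  if (cls_mode) {
    G <- Mf[(seq_len(B) - 1L) * Tn + 1L, , drop = FALSE]
  } else {
    G <- rowsum(Mf, group = rep(seq_len(B), each = Tn)) / Tn
  }

  head_caches <- list(); Z <- G
  for (i in seq_along(cfg$head_hidden)) {
    Zp <- addbias(Z %*% params[[sprintf("head%d_W", i)]],
                  params[[sprintf("head%d_b", i)]])
    Za <- gelu(Zp)
    hk <- if (train && cfg$head_dropout > 0)
      matrix(drop_mask(length(Za), cfg$head_dropout), nrow(Za), ncol(Za)) else NULL
    Zd <- if (is.null(hk)) Za else Za * hk
    head_caches[[i]] <- list(Zin = Z, Zp = Zp, hk = hk)
    Z <- Zd
  }
  logits <- addbias(Z %*% params$out_W, params$out_b)
  probs <- softmax_rows(logits)

  list(probs = probs, Xb = Xb, B = B, Tn = Tn, N = N, tok_idx = tok_idx,
       caches = caches, lnf = lnf, Mf = Mf, G = G, Z = Z,
       head_caches = head_caches, cls_mode = cls_mode)
}

vit_backward <- function(params, cfg, fw, y) {
  B <- fw$B; Tn <- fw$Tn; N <- fw$N
  D <- cfg$projection_dim; hN <- cfg$num_heads; dk <- cfg$key_dim
  scale <- 1 / sqrt(dk)
  g <- list()

  Y1hot <- matrix(0, B, cfg$num_classes); Y1hot[cbind(seq_len(B), y)] <- 1
  dlogits <- (fw$probs - Y1hot) / B
  g$out_W <- t(fw$Z) %*% dlogits; g$out_b <- colSums(dlogits)
  dZ <- dlogits %*% t(params$out_W)
  for (i in rev(seq_along(cfg$head_hidden))) {
    hc <- fw$head_caches[[i]]
    dZa <- if (is.null(hc$hk)) dZ else dZ * hc$hk
    dZp <- dZa * gelu_grad(hc$Zp)
    g[[sprintf("head%d_W", i)]] <- t(hc$Zin) %*% dZp
    g[[sprintf("head%d_b", i)]] <- colSums(dZp)
    dZ <- dZp %*% t(params[[sprintf("head%d_W", i)]])
  }
  dG <- dZ

  dMf <- matrix(0, Tn * B, D)
  if (fw$cls_mode) {
    dMf[(seq_len(B) - 1L) * Tn + 1L, ] <- dG
  } else {
    dMf <- dG[rep(seq_len(B), each = Tn), , drop = FALSE] / Tn
  }
  lb <- ln_backward(dMf, params$lnf_g, fw$lnf)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dx

  for (l in rev(seq_len(cfg$depth))) {
    pfx <- function(nm) params[[sprintf("l%d_%s", l, nm)]]
    cc <- fw$caches[[l]]
    dH2d <- dX
    dH2 <- if (is.null(cc$m2k)) dH2d else dH2d * cc$m2k
    g[[sprintf("l%d_m2_W", l)]] <- t(cc$H1d) %*% dH2
    g[[sprintf("l%d_m2_b", l)]] <- colSums(dH2)
    dH1d <- dH2 %*% t(pfx("m2_W"))
    dH1 <- if (is.null(cc$m1k)) dH1d else dH1d * cc$m1k
    dH1p <- dH1 * gelu_grad(cc$H1p)
    g[[sprintf("l%d_m1_W", l)]] <- t(cc$Y2) %*% dH1p
    g[[sprintf("l%d_m1_b", l)]] <- colSums(dH1p)
    dY2 <- dH1p %*% t(pfx("m1_W"))
    lb2 <- ln_backward(dY2, pfx("ln2_g"), cc$ln2)
    g[[sprintf("l%d_ln2_g", l)]] <- lb2$dg
    g[[sprintf("l%d_ln2_b", l)]] <- lb2$db
    dX2 <- dX + lb2$dx

    dAttnOut <- dX2
    g[[sprintf("l%d_o_W", l)]] <- t(cc$O) %*% dAttnOut
    g[[sprintf("l%d_o_b", l)]] <- colSums(dAttnOut)
    dO <- dAttnOut %*% t(pfx("o_W"))
    dQ <- matrix(0, Tn * B, hN * dk)
    dK <- matrix(0, Tn * B, hN * dk)
    dV <- matrix(0, Tn * B, hN * dk)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (h in seq_len(hN)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- cc$attn[[(b - 1L) * hN + h]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- cc$V[rows, cols, drop = FALSE]
        Ad_grad <- dOh %*% t(Vh)
        mk <- if (!is.null(cc$amask)) cc$amask[[(b - 1L) * hN + h]] else NULL
        Amask <- if (is.null(mk)) A else A * mk
        dV[rows, cols] <- t(Amask) %*% dOh
        dA <- if (is.null(mk)) Ad_grad else Ad_grad * mk
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dS %*% cc$K[rows, cols, drop = FALSE] * scale
        dK[rows, cols] <- t(dS) %*% cc$Q[rows, cols, drop = FALSE] * scale
      }
    }
    g[[sprintf("l%d_q_W", l)]] <- t(cc$Y1) %*% dQ
    g[[sprintf("l%d_q_b", l)]] <- colSums(dQ)
    g[[sprintf("l%d_k_W", l)]] <- t(cc$Y1) %*% dK
    g[[sprintf("l%d_k_b", l)]] <- colSums(dK)
    g[[sprintf("l%d_v_W", l)]] <- t(cc$Y1) %*% dV
    g[[sprintf("l%d_v_b", l)]] <- colSums(dV)
    dY1 <- dQ %*% t(pfx("q_W")) + dK %*% t(pfx("k_W")) + dV %*% t(pfx("v_W"))
    lb1 <- ln_backward(dY1, pfx("ln1_g"), cc$ln1)
    g[[sprintf("l%d_ln1_g", l)]] <- lb1$dg
    g[[sprintf("l%d_ln1_b", l)]] <- lb1$db
    dX <- dX2 + lb1$dx
  }

  g$pos <- rowsum(dX, group = fw$tok_idx)
  if (fw$cls_mode) {
    cls_rows <- (seq_len(B) - 1L) * Tn + 1L
    patch_rows <- rep((seq_len(B) - 1L) * Tn, each = N) + 1L + seq_len(N)
    g$cls <- colSums(dX[cls_rows, , drop = FALSE])
    dE <- dX[patch_rows, , drop = FALSE]
  } else {
    dE <- dX
  }
  g$emb_W <- t(fw$Xb) %*% dE
  g$emb_b <- colSums(dE)
  g
}

#' Forward pass to class probabilities
#'
#' Evaluation-mode (no dropout) forward pass; rows of the result sum to 1.
#'
#' @param model a [build_model()] result.
#' @param x a `vit_dataset`, a list of patch matrices, or a list of images.
#' @param batch_size forward batch size.
#' @return n x num_classes probability matrix.
#' @export
predict_vit <- function(model, x, batch_size = 64L) {
  cfg <- model$cfg
  patches <- if (inherits(x, "vit_dataset")) x$x
  else lapply(x, function(el)
    if (is.matrix(el)) el else extract_patches(el, cfg$patch_size))
  n <- length(patches)
  out <- matrix(0, n, cfg$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    Xb <- do.call(rbind, patches[i:j])
    out[i:j, ] <- vit_pass(model$params, cfg, Xb, B = j - i + 1L)$probs
    i <- j + 1L
  }
  out
}

cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

# ---- training ---------------------------------------------------------------

#' Training configuration
#'
#' AdamW with decoupled weight decay, categorical cross-entropy on one-hot
#' labels, and the three stability callbacks: early stopping, learning-rate
#' reduction on plateau, and best-weights checkpointing (all keyed on
#' validation loss).
#'
#' @param learning_rate,weight_decay AdamW settings.
#' @param batch_size,epochs loop geometry.
#' @param early_stopping_patience epochs without val-loss improvement before
#'   stopping (0 disables).
#' @param plateau_factor,plateau_patience,min_lr ReduceLROnPlateau settings.
#' @param checkpoint_best restore best-validation-loss weights at the end.
#' @param seed seed for shuffling, dropout and initialization of the run.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         batch_size = 32L, epochs = 50L,
                         early_stopping_patience = 8L, plateau_factor = 0.5,
                         plateau_patience = 4L, min_lr = 1e-6,
                         checkpoint_best = TRUE, seed = 42L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr, checkpoint_best = isTRUE(checkpoint_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  decay_ok <- grepl("_W$", names(params))
  for (nm in names(grads)) {
    gv <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gv * 0; state$v[[nm]] <- gv * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gv
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gv^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (decay_ok[match(nm, names(params))]) upd <- upd + wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

#' Train a ViT model
#'
#' @param model a [build_model()] result.
#' @param train_ds,val_ds `vit_dataset` objects (both nonempty).
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list of class `vit_training` with the trained `model` and a
#'   `history` data.frame (per-epoch losses/accuracies, learning rate), plus
#'   `best_epoch` and `stopped_early`.
#' @export
train_vit <- function(model, train_ds, val_ds, tcfg = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(train_ds, "vit_dataset"), inherits(val_ds, "vit_dataset"))
  if (train_ds$n == 0 || val_ds$n == 0)
    stop_gwovit("empty split", "empty_split")
  cfg <- model$cfg
  params <- model$params
  state <- list(t = 0L, m = list(), v = list())
  lr <- tcfg$learning_rate
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric(), lr = numeric())
  best_loss <- Inf; best_params <- params; best_epoch <- 0L
  bad_stop <- 0L; bad_plateau <- 0L; stopped_early <- FALSE

  with_seed(tcfg$seed, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample(train_ds$n)
      tl <- 0; tn <- 0; tcorrect <- 0
      i <- 1L
      while (i <= train_ds$n) {
        j <- min(i + tcfg$batch_size - 1L, train_ds$n)
        idx <- ord[i:j]
        Xb <- do.call(rbind, train_ds$x[idx])
        y <- train_ds$y[idx]
        fw <- vit_pass(params, cfg, Xb, B = length(idx), train = TRUE)
        loss <- cross_entropy(fw$probs, y)
        if (!is.finite(loss))
          stop_gwovit(sprintf("NaN/Inf loss at epoch %d batch starting %d", ep, i),
                      "nan_loss")
        grads <- vit_backward(params, cfg, fw, y)
        st <- adamw_step(params, grads, state, lr, tcfg$weight_decay)
        params <- st$params; state <- st$state
        tl <- tl + loss * length(idx); tn <- tn + length(idx)
        tcorrect <- tcorrect + sum(max.col(fw$probs) == y)
        i <- j + 1L
      }
      vp <- predict_vit(list(cfg = cfg, params = params), val_ds)
      vl <- cross_entropy(vp, val_ds$y)
      va <- mean(max.col(vp) == val_ds$y)
      hist[nrow(hist) + 1L, ] <- list(ep, tl / tn, tcorrect / tn, vl, va, lr)
      if (verbose)
        message(sprintf("epoch %d: train %.4f/%.3f val %.4f/%.3f lr %.2g",
                        ep, tl / tn, tcorrect / tn, vl, va, lr))
      if (vl < best_loss - 1e-8) {
        best_loss <- vl; best_epoch <- ep
        if (tcfg$checkpoint_best) best_params <- params
        bad_stop <- 0L; bad_plateau <- 0L
      } else {
        bad_stop <- bad_stop + 1L; bad_plateau <- bad_plateau + 1L
        if (tcfg$plateau_patience > 0 && bad_plateau >= tcfg$plateau_patience) {
          lr <- max(lr * tcfg$plateau_factor, tcfg$min_lr)
          bad_plateau <- 0L
        }
        if (tcfg$early_stopping_patience > 0 &&
            bad_stop >= tcfg$early_stopping_patience) {
          stopped_early <- TRUE
          break
        }
      }
    }
  })
  model$params <- if (tcfg$checkpoint_best && best_epoch > 0) best_params else params
  structure(list(model = model, history = hist,
                 best_epoch = if (best_epoch > 0) best_epoch else nrow(hist),
                 stopped_early = stopped_early),
            class = "vit_training")
}
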