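# Grey Wolf Optimizer over the 5-dimensional ViT hyperparameter space.
#
# The pack encircles the three best solutions seen so far (alpha, beta,
# delta); every wolf moves to the average of its three leader-guided
# candidate positions, with the exploration coefficient `a` shrinking
# linearly from 2 to 0. Integer dimensions are optimized in continuous space
# and only rounded when a position is decoded into a model configuration.

#' Hyperparameter search space
#'
#' Defaults are the published bounds of the five tuned hyperparameters:
#' learning rate 1e-5..1e-3 (log10 scale), projection dimension 64..256,
#' attention heads 4..12, transformer layers 4..12, dropout 0.05..0.3.
#'
#' @param dimensions data.frame with columns name, kind
#'   (`continuous`/`integer`/`log10`), lower, upper.
#' @return object of class `search_space`.
#' @export
search_space <- function(dimensions = NULL) {
  if (is.null(dimensions)) {
    dimensions <- data.frame(
      name = c("learning_rate", "projection_dim", "num_heads", "depth", "dropout"),
      kind = c("log10", "integer", "integer", "integer", "continuous"),
      lower = c(-5, 64, 4, 4, 0.05),
      upper = c(-3, 256, 12, 12, 0.30))
  }
  stopifnot(all(dimensions$lower < dimensions$upper),
            !anyDuplicated(dimensions$name),
            all(dimensions$kind %in% c("continuous", "integer", "log10")))
  structure(dimensions, class = c("search_space", "data.frame"))
}

#' Linearly shrinking exploration coefficient
#'
#' `a(t) = 2 * (1 - t / T)`: 2 at the first iteration, 0 at the last.
#'
#' @param t current iteration (0-based).
#' @param T_max total iterations.
#' @return scalar in \[0, 2\].
#' @export
coefficient_a <- function(t, T_max) {
  stopifnot(T_max >= 1, t >= 0, t <= T_max)
  2 * (1 - t / T_max)
}

#' Prey-encircling position update
#'
#' Component-wise `D = |C * X_p - X|`, `X_next = X_p - A * D`.
#'
#' @param X wolf position.
#' @param X_p prey (leader) position.
#' @param A,C coefficient vectors of the same length.
#' @return updated position vector.
#' @export
encircle <- function(X, X_p, A, C) {
  stopifnot(length(X) == length(X_p))
  D <- abs(C * X_p - X)
  X_p - A * D
}

#' Sample the A and C coefficient vectors
#'
#' `A = 2a*r1 - a` (uniform in \[-a, a\]) and `C = 2*r2` (uniform in \[0, 2\]).
#'
#' @param a current exploration coefficient in \[0, 2\].
#' @param d dimensionality.
#' @return list with vectors `A` and `C`.
#' @export
sample_coefficients <- function(a, d) {
  stopifnot(a >= 0, a <= 2)
  list(A = 2 * a * stats::runif(d) - a, C = 2 * stats::runif(d))
}

clip_position <- function(x, space) pmin(pmax(x, space$lower), space$upper)

#' Decode a continuous position into hyperparameters
#'
#' log10 dimensions are exponentiated, integer dimensions rounded, and the
#' projection dimension snapped to the nearest multiple of the decoded head
#' count inside its bounds, so every decoded configuration is valid.
#'
#' @param position numeric vector in the space's continuous representation.
#' @param space a [search_space()].
#' @return named list of decoded values.
#' @export
decode_position <- function(position, space) {
  out <- list()
  for (i in seq_len(nrow(space))) {
    v <- unname(position[i])
    out[[space$name[i]]] <- switch(space$kind[i],
                                   log10 = 10^v,
                                   integer = as.integer(round(v)),
                                   continuous = v)
  }
  if (!is.null(out$projection_dim) && !is.null(out$num_heads)) {
    h <- out$num_heads
    i <- match("projection_dim", space$name)
    cand <- h * round(out$projection_dim / h)
    cand <- min(max(cand, h * ceiling(space$lower[i] / h)),
                h * floor(space$upper[i] / h))
    out$projection_dim <- as.integer(cand)
  }
  out
}

#' Encode hyperparameters into a position
#'
#' Inverse of [decode_position()] for in-bounds values.
#'
#' @param values named list (or vector) of hyperparameter values.
#' @param space a [search_space()].
#' @return numeric position vector.
#' @export
encode_position <- function(values, space) {
  vapply(seq_len(nrow(space)), function(i) {
    v <- values[[space$name[i]]]
    if (space$kind[i] == "log10") log10(v) else as.numeric(v)
  }, numeric(1))
}

config_key <- function(decoded) {
  paste(vapply(decoded, function(v) format(v, digits = 12), character(1)),
        collapse = "|")
}

init_pack <- function(space, pop_size) {
  d <- nrow(space)
  pos <- sapply(seq_len(d), function(i)
    stats::runif(pop_size, space$lower[i], space$upper[i]))
  matrix(pos, pop_size, d, dimnames = list(NULL, space$name))
}

#' One synchronized GWO pack step
#'
#' Every wolf computes three candidate positions by encircling alpha, beta
#' and delta with independently sampled coefficients, moves to their average,
#' is clipped to bounds, and re-evaluated (through the fitness cache);
#' leaders are then updated. A failed fitness evaluation leaves that wolf at
#' its previous position.
#'
#' @param pack pack state (as produced by [gwo_optimize()] internals).
#' @param space a [search_space()].
#' @param fitness function taking a decoded configuration and returning a
#'   scalar score (higher is better).
#' @return updated pack.
#' @export
pack_step <- function(pack, space, fitness) {
  a <- coefficient_a(pack$t, pack$T_max)
  d <- nrow(space)
  leaders <- pack$leaders
  evalfun <- if (!is.null(pack$evaluate)) pack$evaluate
  else function(p) fitness(decode_position(p, space))
  for (w in seq_len(nrow(pack$positions))) {
    X <- pack$positions[w, ]
    cand <- vapply(1:3, function(k) {
      co <- sample_coefficients(a, d)
      encircle(X, leaders$positions[k, ], co$A, co$C)
    }, numeric(d))
    cand <- matrix(cand, nrow = d)
    newX <- clip_position(rowMeans(cand), space)
    f <- tryCatch(evalfun(newX),
                  error = function(e) {
                    pack$failures <<- c(pack$failures, conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) {
      pack$positions[w, ] <- newX
      pack$fitness[w] <- f
    }
  }
  # leaders are the best three positions seen so far (stable on ties)
  for (w in seq_len(nrow(pack$positions))) {
    f <- pack$fitness[w]
    wpos <- pack$positions[w, , drop = FALSE]
    if (f > leaders$fitness[1]) {
      leaders$fitness <- c(f, leaders$fitness[1:2])
      leaders$positions <- rbind(wpos, leaders$positions[1:2, , drop = FALSE])
    } else if (f > leaders$fitness[2]) {
      leaders$fitness <- c(leaders$fitness[1], f, leaders$fitness[2])
      leaders$positions <- rbind(leaders$positions[1, , drop = FALSE], wpos,
                                 leaders$positions[2, , drop = FALSE])
    } else if (f > leaders$fitness[3]) {
      leaders$fitness[3] <- f
      leaders$positions[3, ] <- pack$positions[w, ]
    }
  }
  pack$leaders <- leaders
  pack$t <- pack$t + 1L
  pack$a <- coefficient_a(min(pack$t, pack$T_max), pack$T_max)
  pack
}

#' Run the Grey Wolf Optimizer
#'
#' Initializes `pop_size` wolves uniformly within bounds (log-uniformly on
#' log10 dimensions), runs `T_max` pack steps, and returns the best decoded
#' configuration with the full convergence trace. Fitness evaluations are
#' cached by decoded-configuration key, so wolves that round to the same
#' architecture cost one training run.
#'
#' @param space a [search_space()].
#' @param fitness function mapping a decoded configuration (named list) to a
#'   scalar score; higher is better. Pass the negative for minimization.
#' @param pop_size wolves (>= 3).
#' @param T_max iterations.
#' @param seed RNG seed.
#' @return list with `best_config`, `best_fitness`, `trace` (data.frame:
#'   iteration, best, mean, a), `pack`, `n_evaluations`, `cache_hits`.
#' @export
gwo_optimize <- function(space, fitness, pop_size = 10L, T_max = 25L,
                         seed = 42L) {
  if (pop_size < 3)
    stop_gwovit("pop_size must be >= 3 (alpha/beta/delta must exist)",
                "pop_too_small")
  with_seed(seed, {
    cache <- new.env(parent = emptyenv())
    stats_env <- new.env(parent = emptyenv())
    stats_env$evals <- 0L; stats_env$hits <- 0L
    evaluate <- function(position) {
      dec <- decode_position(position, space)
      key <- config_key(dec)
      if (!is.null(cache[[key]])) {
        stats_env$hits <- stats_env$hits + 1L
        return(cache[[key]])
      }
      stats_env$evals <- stats_env$evals + 1L
      val <- fitness(dec)
      cache[[key]] <- val
      val
    }

    positions <- init_pack(space, pop_size)
    fit <- apply(positions, 1, evaluate)
    ord <- order(-fit)
    leaders <- list(positions = positions[ord[1:3], , drop = FALSE],
                    fitness = fit[ord[1:3]])
    pack <- list(positions = positions, fitness = fit, leaders = leaders,
                 t = 0L, T_max = as.integer(T_max), a = 2,
                 evaluate = evaluate, failures = character())
    trace <- data.frame(iteration = 0L, best = leaders$fitness[1],
                        mean = mean(fit), a = 2)
    for (it in seq_len(T_max)) {
      pack <- pack_step(pack, space, fitness = NULL)
      trace[nrow(trace) + 1L, ] <- list(it, pack$leaders$fitness[1],
                                        mean(pack$fitness), pack$a)
    }
    list(best_config = decode_position(pack$leaders$positions[1, ], space),
         best_fitness = pack$leaders$fitness[1],
         trace = trace, pack = pack,
         n_evaluations = stats_env$evals, cache_hits = stats_env$hits)
  })
}

#' Budgeted proxy fitness for ViT hyperparameter search
#'
#' Returns a fitness closure that builds a ViT from a decoded GWO
#' configuration, trains it for a small number of proxy epochs, and scores
#' it by validation accuracy (negate `sign` for validation-loss
#' minimization). Deterministic for the fixed evaluation seed.
#'
#' @param train_ds,val_ds `vit_dataset` objects.
#' @param base_cfg template `vit_config`; the decoded learning rate,
#'   projection dimension, heads, depth and dropout override it.
#' @param proxy_epochs training budget per evaluation.
#' @param eval_seed seed shared by all evaluations.
#' @param sign `"accuracy"` maximizes val accuracy, `"loss"` maximizes
#'   negative val loss.
#' @return function(decoded) -> scalar fitness.
#' @export
vit_proxy_fitness <- function(train_ds, val_ds, base_cfg, proxy_epochs = 2L,
                              eval_seed = 7L, sign = c("accuracy", "loss")) {
  sign <- match.arg(sign)
  function(decoded) {
    cfg <- vit_config(image_size = base_cfg$image_size,
                      patch_size = base_cfg$patch_size,
                      projection_dim = decoded$projection_dim,
                      num_heads = decoded$num_heads,
                      key_dim = decoded$projection_dim %/% decoded$num_heads,
                      depth = decoded$depth,
                      mlp_ratio = base_cfg$mlp_ratio,
                      head_hidden = base_cfg$head_hidden,
                      attention_dropout = decoded$dropout,
                      mlp_dropout = decoded$dropout,
                      head_dropout = base_cfg$head_dropout,
                      aggregation = base_cfg$aggregation)
    model <- build_model(cfg, seed = eval_seed)
    tr <- train_vit(model, train_ds, val_ds,
                    train_config(learning_rate = decoded$learning_rate,
                                 epochs = proxy_epochs,
                                 early_stopping_patience = 0L,
                                 seed = eval_seed))
    last <- tr$history[nrow(tr$history), ]
    if (sign == "accuracy") last$val_acc else -last$val_loss
  }
}
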