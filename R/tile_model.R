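# Tile classifier: backbone contract, default feature+MLP backbone,
# augmentation, and the fully-supervised learning-rate schedule.
#
# The backbone contract is small: predict_tiles() maps a batch of RGB tiles
# to carcinoma probabilities in [0, 1] (deterministic in inference mode),
# and train_step() performs one optimiser update on a labelled batch at a
# given learning rate, returning the batch loss. The default desk-scale
# backbone summarises each tile into 8 colour/texture features (per-channel
# mean and sd, luminance gradient energy, mean saturation) and feeds a
# one-hidden-layer MLP with a sigmoid head, trained by Adam on binary
# cross-entropy. Any object honouring the contract can stand in (see
# manual_classifier()).

.n_tile_features <- 8L

#' Summarise a tile into colour/texture features
#'
#' @param tile RGB array `[s, s, 3]`.
#' @return numeric vector of length 8: per-channel means (3), per-channel
#'   sds (3), mean absolute luminance gradient, mean saturation.
#' @export
tile_features <- function(tile) {
  n <- dim(tile)[1]
  np <- n * n
  r <- tile[, , 1]; g <- tile[, , 2]; b <- tile[, , 3]
  sr <- sum(r); sg <- sum(g); sb <- sum(b)
  mr <- sr / np; mg <- sg / np; mb <- sb / np
  # population sd via sum of squares (cheaper than stats::sd at this size)
  sdr <- sqrt(max(0, sum(r * r) / np - mr^2))
  sdg <- sqrt(max(0, sum(g * g) / np - mg^2))
  sdb <- sqrt(max(0, sum(b * b) / np - mb^2))
  lum <- 0.299 * r + 0.587 * g + 0.114 * b
  grad <- (sum(abs(lum[, -1] - lum[, -n])) + sum(abs(lum[-n, ] - lum[-1, ]))) /
    (2 * n * (n - 1))
  mx <- pmax(r, g); mx <- pmax(mx, b)
  mn <- pmin(r, g); mn <- pmin(mn, b)
  sat <- sum((mx - mn) / pmax(mx, 1e-12)) / np
  c(mr, mg, mb, sdr, sdg, sdb, grad, sat)
}

# Feature matrix (n x 8) from a list of tiles.
tile_feature_matrix <- function(tiles) {
  if (length(tiles) == 0L) {
    return(matrix(numeric(0), ncol = .n_tile_features))
  }
  t(vapply(tiles, tile_features, numeric(.n_tile_features)))
}

# Fast batch path: features of every tile of a grid data frame, slicing the
# pixel array directly (avoids per-tile data-frame row overhead).
grid_features <- function(slide, grid) {
  feats <- matrix(0, nrow(grid), .n_tile_features)
  px <- slide$pixels
  xs <- grid$x; ys <- grid$y; ss <- grid$size
  for (i in seq_len(nrow(grid))) {
    feats[i, ] <- tile_features(
      px[(ys[i] + 1L):(ys[i] + ss[i]), (xs[i] + 1L):(xs[i] + ss[i]), ,
         drop = FALSE])
  }
  feats
}

#' Create the default tile classifier backbone
#'
#' A sigmoid-output network over the 8 tile features with Adam optimiser
#' state held inside the object (reference semantics via an environment).
#' `hidden = 0` gives a linear (logistic-regression) scorer — the desk
#' default: its score is a bounded-slope monotone ramp in feature space,
#' mirroring how a large CNN on heterogeneous real tiles generalises
#' instead of memorising every labelled mixture. `hidden > 0` inserts one
#' tanh hidden layer.
#'
#' @param hidden hidden layer width; 0 for the linear scorer.
#' @param seed seed for weight initialisation.
#' @param beta1,beta2 Adam moment decay rates.
#' @return object of classes `"mlp_classifier"`, `"tile_classifier"`.
#' @export
new_tile_classifier <- function(hidden = 0L, seed = 1L,
                                beta1 = 0.9, beta2 = 0.999) {
  stopifnot(beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, hidden >= 0)
  d <- .n_tile_features
  e <- new.env(parent = emptyenv())
  if (hidden > 0L) {
    with_seed(seed, {
      e$W1 <- matrix(stats::rnorm(d * hidden, sd = sqrt(1 / d)), d, hidden)
      e$b1 <- rep(0, hidden)
      e$W2 <- matrix(stats::rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1)
      e$b2 <- 0
    })
    e$adam_m <- lapply(list(e$W1, e$b1, e$W2, e$b2), function(p) p * 0)
  } else {
    with_seed(seed, {
      e$W2 <- matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1)
      e$b2 <- 0
    })
    e$adam_m <- lapply(list(e$W2, e$b2), function(p) p * 0)
  }
  e$adam_v <- e$adam_m
  e$adam_t <- 0L
  e$beta1 <- beta1
  e$beta2 <- beta2
  e$hidden <- as.integer(hidden)
  structure(list(env = e, hidden = as.integer(hidden),
                 backbone = "feature-mlp", input_features = d),
            class = c("mlp_classifier", "tile_classifier"))
}

.mlp_forward <- function(e, X) {
  if (e$hidden > 0L) {
    H <- tanh(sweep(X %*% e$W1, 2, e$b1, `+`))
    z <- as.numeric(H %*% e$W2) + e$b2
    list(H = H, p = 1 / (1 + exp(-z)))
  } else {
    z <- as.numeric(X %*% e$W2) + e$b2
    list(H = NULL, p = 1 / (1 + exp(-z)))
  }
}

#' Predict carcinoma probabilities for a batch of tiles
#'
#' Order-preserving, deterministic for fixed parameters (inference mode).
#'
#' @param model a tile classifier.
#' @param tiles list of RGB tile arrays, or a precomputed feature matrix.
#' @return numeric vector of probabilities in `[0, 1]`, one per tile.
#' @export
predict_tiles <- function(model, tiles) UseMethod("predict_tiles")

#' @export
predict_tiles.mlp_classifier <- function(model, tiles) {
  X <- if (is.matrix(tiles)) tiles else tile_feature_matrix(tiles)
  if (nrow(X) == 0L) return(numeric(0))
  .mlp_forward(model$env, X)$p
}

#' One optimiser step on a labelled batch
#'
#' @param model a tile classifier.
#' @param tiles list of RGB tile arrays or feature matrix.
#' @param labels numeric 0/1 vector (1 = carcinoma).
#' @param lr learning rate.
#' @return mean binary cross-entropy of the batch before the update.
#' @export
train_step <- function(model, tiles, labels, lr) UseMethod("train_step")

#' @export
train_step.mlp_classifier <- function(model, tiles, labels, lr) {
  e <- model$env
  X <- if (is.matrix(tiles)) tiles else tile_feature_matrix(tiles)
  n <- nrow(X)
  stopifnot(n == length(labels), n > 0L)
  fwd <- .mlp_forward(e, X)
  p <- pmin(pmax(fwd$p, 1e-15), 1 - 1e-15)
  loss <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  dz <- (fwd$p - labels) / n                       # d loss / d logit
  if (e$hidden > 0L) {
    gW2 <- t(fwd$H) %*% dz
    gb2 <- sum(dz)
    dH <- (matrix(dz, ncol = 1L) %*% t(e$W2)) * (1 - fwd$H^2)
    gW1 <- t(X) %*% dH
    gb1 <- colSums(dH)
    grads <- list(gW1, gb1, gW2, gb2)
    params <- list("W1", "b1", "W2", "b2")
  } else {
    grads <- list(t(X) %*% dz, sum(dz))
    params <- list("W2", "b2")
  }
  e$adam_t <- e$adam_t + 1L
  b1 <- e$beta1; b2 <- e$beta2; t <- e$adam_t
  for (i in seq_along(params)) {
    e$adam_m[[i]] <- b1 * e$adam_m[[i]] + (1 - b1) * grads[[i]]
    e$adam_v[[i]] <- b2 * e$adam_v[[i]] + (1 - b2) * grads[[i]]^2
    mhat <- e$adam_m[[i]] / (1 - b1^t)
    vhat <- e$adam_v[[i]] / (1 - b2^t)
    nm <- params[[i]]
    assign(nm, get(nm, envir = e) - lr * mhat / (sqrt(vhat) + 1e-8), envir = e)
  }
  loss
}

#' Snapshot / restore classifier parameters
#'
#' Used by the trainers to keep the best-validation-loss state.
#'
#' @param model a tile classifier.
#' @return for `get_params`, an opaque parameter list.
#' @export
get_params <- function(model) UseMethod("get_params")

#' @export
get_params.mlp_classifier <- function(model) {
  nms <- if (model$hidden > 0L) c("W1", "b1", "W2", "b2") else c("W2", "b2")
  as.list(model$env)[nms]
}

#' @rdname get_params
#' @param params parameter list from [get_params()].
#' @export
set_params <- function(model, params) UseMethod("set_params")

#' @export
set_params.mlp_classifier <- function(model, params) {
  for (nm in names(params)) assign(nm, params[[nm]], envir = model$env)
  invisible(model)
}

#' Wrap prediction/training functions as a tile classifier
#'
#' An extension and testing hook: any pair of functions honouring the
#' backbone contract becomes a classifier usable by the trainers and the
#' scorer (e.g. a frozen scorer for instrumented MIL epochs).
#'
#' @param predict_fn `function(tiles) -> probabilities`.
#' @param train_fn optional `function(tiles, labels, lr) -> loss`; default
#'   is a no-op returning `NA`.
#' @param state optional environment carried on the object.
#' @return object of classes `"manual_classifier"`, `"tile_classifier"`.
#' @export
manual_classifier <- function(predict_fn, train_fn = NULL, state = NULL) {
  structure(list(predict_fn = predict_fn,
                 train_fn = train_fn,
                 state = if (is.null(state)) new.env(parent = emptyenv())
                         else state),
            class = c("manual_classifier", "tile_classifier"))
}

#' @export
predict_tiles.manual_classifier <- function(model, tiles) {
  model$predict_fn(tiles)
}

#' @export
train_step.manual_classifier <- function(model, tiles, labels, lr) {
  if (is.null(model$train_fn)) return(NA_real_)
  model$train_fn(tiles, labels, lr)
}

#' @export
get_params.manual_classifier <- function(model) {
  as.list(model$state)
}

#' @export
set_params.manual_classifier <- function(model, params) {
  rm(list = ls(model$state), envir = model$state)
  for (nm in names(params)) assign(nm, params[[nm]], envir = model$state)
  invisible(model)
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint carries the backbone name, architecture fields and
#' parameter values.
#'
#' @param model an `mlp_classifier`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored classifier (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mlp_classifier"))
  saveRDS(list(backbone = model$backbone, hidden = model$hidden,
               input_features = model$input_features,
               params = get_params(model)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$backbone, "feature-mlp")) {
    stop("unknown backbone in checkpoint: ", ck$backbone)
  }
  model <- new_tile_classifier(hidden = ck$hidden)
  set_params(model, ck$params)
  model
}

#' Augmentation configuration
#'
#' @param flip_horizontal,flip_vertical allow the respective flips.
#' @param max_translation maximum absolute shift in pixels (must be smaller
#'   than the tile size).
#' @param colour_shift_range half-width of the per-channel additive colour
#'   offset, as a fraction of dynamic range (default 0.04).
#' @return object of class `"augmentation_config"`.
#' @export
augmentation_config <- function(flip_horizontal = TRUE, flip_vertical = TRUE,
                                max_translation = 4L,
                                colour_shift_range = 0.04) {
  stopifnot(max_translation >= 0, colour_shift_range >= 0)
  structure(list(flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical,
                 max_translation = as.integer(max_translation),
                 colour_shift_range = colour_shift_range),
            class = "augmentation_config")
}

#' Augment a tile (flips, translation, colour shift)
#'
#' Draws from the current RNG stream; wrap in [with_seed()] for
#' reproducibility. Translation shifts the content and replicates edge
#' pixels; colour shifts are independent per-channel additive offsets;
#' output values are clipped to `[0, 1]`.
#'
#' @param tile square RGB array.
#' @param cfg an [augmentation_config()].
#' @return augmented RGB array of the same shape.
#' @export
augment <- function(tile, cfg) {
  s <- dim(tile)[1]
  stopifnot(dim(tile)[2] == s, cfg$max_translation < s)
  if (cfg$flip_horizontal && stats::runif(1) < 0.5) {
    tile <- tile[, s:1, , drop = FALSE]
  }
  if (cfg$flip_vertical && stats::runif(1) < 0.5) {
    tile <- tile[s:1, , , drop = FALSE]
  }
  if (cfg$max_translation > 0L) {
    dx <- sample.int(2L * cfg$max_translation + 1L, 1L) - cfg$max_translation - 1L
    dy <- sample.int(2L * cfg$max_translation + 1L, 1L) - cfg$max_translation - 1L
    idx <- function(d) pmin(pmax(seq_len(s) + d, 1L), s)
    tile <- tile[idx(dy), idx(dx), , drop = FALSE]
  }
  if (cfg$colour_shift_range > 0) {
    shift <- stats::runif(3, -cfg$colour_shift_range, cfg$colour_shift_range)
    tile <- tile + rep(shift, each = s * s)
  }
  pmin(pmax(tile, 0), 1)
}

#' Fully-supervised learning-rate schedule
#'
#' Epoch 1 ramps linearly from `base_lr` to `max_lr` across its iterations
#' (warm start); epoch `e >= 2` is constant at `max_lr * decay^(e - 1)`,
#' i.e. the first decay is applied when epoch 1 ends, so epoch 2 runs at
#' `0.05 * 0.9 = 0.045` with the defaults.
#'
#' @param epoch epoch index, 1-based.
#' @param iteration iteration within the epoch, 0-based.
#' @param iterations_per_epoch iterations in one epoch.
#' @param base_lr warm-start initial rate (default 0.001).
#' @param max_lr peak rate reached at the end of epoch 1 (default 0.05).
#' @param decay per-epoch decay factor (default 0.9).
#' @return learning rate.
#' @export
#' @examples
#' fs_lr_schedule(1, 0, 100)    # 0.001
#' fs_lr_schedule(1, 99, 100)   # 0.05
#' fs_lr_schedule(2, 0, 100)    # 0.045
fs_lr_schedule <- function(epoch, iteration, iterations_per_epoch,
                           base_lr = 0.001, max_lr = 0.05, decay = 0.9) {
  if (epoch < 1) stop("epoch must be >= 1")
  stopifnot(iteration >= 0, iterations_per_epoch >= 1,
            iteration < iterations_per_epoch)
  if (epoch == 1) {
    if (iterations_per_epoch == 1L) return(max_lr)
    base_lr + (max_lr - base_lr) * iteration / (iterations_per_epoch - 1)
  } else {
    max_lr * decay^(epoch - 1)
  }
}
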