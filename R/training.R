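# The two training regimes.
#
# Fully supervised (FS): train on region-labelled grid tiles with the
# warm-start/decay learning-rate schedule, early stopping on validation
# loss, keeping the minimum-validation-loss state.
#
# Weakly supervised (WS/MIL): a warm phase on randomly sampled annotated
# tiles (k = 32 per slide, 2 epochs), then MIL epochs that visit slides in
# random order, score all tissue tiles in inference mode, select the top-k
# by carcinoma probability (k decaying linearly 5 -> 1), label them with
# the slide label, and flush an accumulation buffer of 512 tiles through
# the optimiser in batches of 64. Validation is slide-level
# (max-aggregation log loss), since tile labels need not exist in WS mode.

#' Fully-supervised training configuration
#'
#' Defaults follow the reference protocol: Adam (0.9, 0.999), batch 64,
#' warm start 0.001 -> 0.05 in epoch 1 then 0.9 decay per epoch, at most
#' 22 epochs with early-stopping patience 10.
#'
#' @param max_epochs maximum epochs (default 22).
#' @param patience early-stopping patience in epochs (default 10).
#' @param batch_size optimiser batch size (default 64).
#' @param base_lr,max_lr,lr_decay see [fs_lr_schedule()].
#' @param beta1,beta2 Adam moment decay rates.
#' @param augmentation an [augmentation_config()].
#' @param tile_size tile edge (default 512; 64 at desk scale).
#' @param stride training grid stride (default `tile_size`).
#' @param min_overlap region-coverage threshold for tile labels.
#' @param tissue_threshold minimum tissue fraction per tile.
#' @param val_stride stride used when scoring validation slides (default
#'   `tile_size`).
#' @param hidden backbone hidden width.
#' @param seed master seed for this run.
#' @return object of class `"fs_config"`.
#' @export
fs_config <- function(max_epochs = 22L, patience = 10L, batch_size = 64L,
                      base_lr = 0.001, max_lr = 0.05, lr_decay = 0.9,
                      beta1 = 0.9, beta2 = 0.999,
                      augmentation = augmentation_config(),
                      tile_size = 512L, stride = tile_size,
                      min_overlap = 0.5, tissue_threshold = 0.1,
                      val_stride = tile_size, hidden = 0L, seed = 1L) {
  if (patience > max_epochs) stop("patience must be <= max_epochs")
  stopifnot(beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1, batch_size >= 1)
  structure(as.list(environment()), class = "fs_config")
}

#' Weakly-supervised (MIL) training configuration
#'
#' Defaults follow the reference protocol: warm phase of 32 random
#' annotated tiles per slide for 2 epochs; then MIL with top-k decaying
#' linearly from 5 to 1, an accumulation buffer of 512 tiles trained in
#' Adam batches of 64, learning rate starting at 0.001 and decaying 0.9
#' per MIL epoch.
#'
#' @param warm_k tiles sampled per slide in the warm phase (default 32).
#' @param warm_epochs warm-phase epochs (default 2).
#' @param k_start,k_end top-k decay endpoints (defaults 5 and 1).
#' @param mil_epochs MIL epochs; the default 5 makes the k sequence
#'   5, 4, 3, 2, 1.
#' @param buffer_n accumulation buffer size (default 512; must be a
#'   multiple of `batch_size`).
#' @param batch_size optimiser batch size (default 64).
#' @param initial_lr MIL learning rate at epoch 1 (default 0.001).
#' @param lr_decay_per_epoch multiplicative decay per MIL epoch (default
#'   0.9).
#' @param beta1,beta2 Adam moment decay rates.
#' @param augmentation an [augmentation_config()].
#' @param tile_size tile edge (default 512; 64 at desk scale).
#' @param stride scoring stride inside MIL epochs (default `tile_size`).
#' @param min_overlap warm-phase region-coverage threshold.
#' @param tissue_threshold minimum tissue fraction per tile.
#' @param val_stride stride for validation scoring (default `tile_size`).
#' @param hidden backbone hidden width.
#' @param seed master seed for this run.
#' @return object of class `"mil_config"`.
#' @export
mil_config <- function(warm_k = 32L, warm_epochs = 2L,
                       k_start = 5L, k_end = 1L, mil_epochs = 5L,
                       buffer_n = 512L, batch_size = 64L,
                       initial_lr = 0.001, lr_decay_per_epoch = 0.9,
                       beta1 = 0.9, beta2 = 0.999,
                       augmentation = augmentation_config(),
                       tile_size = 512L, stride = tile_size,
                       min_overlap = 0.5, tissue_threshold = 0.1,
                       val_stride = tile_size, hidden = 0L, seed = 1L) {
  if (k_end > k_start) stop("k_end must be <= k_start")
  if (buffer_n %% batch_size != 0) {
    stop("buffer_n must be a multiple of batch_size")
  }
  stopifnot(warm_k >= 1, warm_epochs >= 0, mil_epochs >= 0,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  structure(as.list(environment()), class = "mil_config")
}

#' Top-k schedule of the MIL phase
#'
#' Linear interpolation from `k_start` to `k_end` over the MIL epochs,
#' rounded half up; a single-epoch horizon uses `k_start`.
#'
#' @param mil_epoch MIL epoch index in `1..mil_epochs`.
#' @param cfg a [mil_config()].
#' @return integer k.
#' @export
#' @examples
#' vapply(1:5, k_schedule, integer(1), cfg = mil_config())  # 5 4 3 2 1
k_schedule <- function(mil_epoch, cfg) {
  if (mil_epoch < 1 || mil_epoch > cfg$mil_epochs) {
    stop("mil_epoch must be in 1..", cfg$mil_epochs)
  }
  if (cfg$mil_epochs == 1L) return(as.integer(cfg$k_start))
  k <- cfg$k_start + (cfg$k_end - cfg$k_start) *
    (mil_epoch - 1) / (cfg$mil_epochs - 1)
  as.integer(floor(k + 0.5))
}

#' Indices of the k largest probabilities
#'
#' Descending by probability, ties broken toward the smaller index; if
#' `k` exceeds the list length all indices are returned.
#'
#' @param probabilities numeric vector.
#' @param k number of tiles to select (>= 1).
#' @return integer vector of 1-based indices.
#' @export
#' @examples
#' select_top_k(c(0.2, 0.9, 0.5, 0.9), 2)  # 2 4
select_top_k <- function(probabilities, k) {
  stopifnot(k >= 1)
  n <- length(probabilities)
  if (n == 0L) return(integer(0))
  order(-probabilities, seq_len(n))[seq_len(min(k, n))]
}

# Tiles of a slide that pass the tissue filter; returns the grid data frame.
tissue_tiles <- function(record, tile_size, stride, tissue_threshold) {
  grid <- tile_grid(record$slide$width, record$slide$height, tile_size, stride)
  if (nrow(grid) == 0L) return(grid)
  mask <- tissue_mask(record$slide)
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    tissue_fraction(mask, grid[i, ]) >= tissue_threshold
  }, logical(1))
  grid[keep, , drop = FALSE]
}

# Per-slide inference cache: tissue-passing grid plus its (un-augmented)
# feature matrix. Features are model-independent, so MIL scoring passes,
# per-epoch validation and final prediction can share one cache.
slide_inference_cache <- function(record, tile_size, stride,
                                  tissue_threshold) {
  grid <- tissue_tiles(record, tile_size, stride, tissue_threshold)
  list(grid = grid, feats = grid_features(record$slide, grid))
}

.build_cache <- function(records, tile_size, stride, tissue_threshold) {
  out <- lapply(records, slide_inference_cache, tile_size = tile_size,
                stride = stride, tissue_threshold = tissue_threshold)
  names(out) <- vapply(records, `[[`, character(1), "slide_id")
  out
}

# Train on accumulated feature rows in shuffled batches; returns mean loss.
.train_batches <- function(model, feats, labels, lr, batch_size, shuffle_seed) {
  n <- nrow(feats)
  ord <- with_seed(shuffle_seed, sample.int(n))
  losses <- c()
  for (start in seq(1L, n, by = batch_size)) {
    idx <- ord[start:min(start + batch_size - 1L, n)]
    losses <- c(losses,
                train_step(model, feats[idx, , drop = FALSE], labels[idx], lr))
  }
  mean(losses)
}

# Extract + augment tiles listed in a grid data frame, returning features.
.augmented_features <- function(record, grid, aug_cfg) {
  feats <- matrix(0, nrow(grid), .n_tile_features)
  px <- record$slide$pixels
  xs <- grid$x; ys <- grid$y; ss <- grid$size
  for (i in seq_len(nrow(grid))) {
    tile <- px[(ys[i] + 1L):(ys[i] + ss[i]),
               (xs[i] + 1L):(xs[i] + ss[i]), , drop = FALSE]
    feats[i, ] <- tile_features(augment(tile, aug_cfg))
  }
  feats
}

#' Warm phase of MIL training
#'
#' For each of `warm_epochs` passes, samples `warm_k` annotated tiles per
#' slide (from tiles whose region coverage yields a label), labels them by
#' [assign_tile_label()], and trains in batches of `batch_size` at
#' `initial_lr`. Slides without a single labelable tile are skipped with a
#' warning.
#'
#' @param records list of `slide_record` objects with annotations.
#' @param cfg a [mil_config()].
#' @param model a tile classifier (modified in place and returned).
#' @param seed substream seed; defaults to the config seed.
#' @return the model, with attribute `"n_draws"` (total tile draws).
#' @export
warm_phase <- function(records, cfg, model, seed = cfg$seed) {
  n_draws <- 0L
  warned <- character(0)
  for (epoch in seq_len(cfg$warm_epochs)) {
    feats <- list(); labels <- c()
    for (ri in seq_along(records)) {
      rec <- records[[ri]]
      grid <- tissue_tiles(rec, cfg$tile_size, cfg$stride, cfg$tissue_threshold)
      tl <- if (nrow(grid) > 0L) {
        vapply(seq_len(nrow(grid)), function(i) {
          assign_tile_label(grid[i, ], rec$regions, cfg$min_overlap)
        }, character(1))
      } else character(0)
      grid <- grid[tl != "unlabelled", , drop = FALSE]
      tl <- tl[tl != "unlabelled"]
      if (nrow(grid) == 0L) {
        if (!rec$slide_id %in% warned) {
          warning("warm phase: slide ", rec$slide_id,
                  " has no labelable tiles; skipped")
          warned <- c(warned, rec$slide_id)
        }
        next
      }
      pick_seed <- substream_seed(seed, "warm-sample",
                                  epoch * 100003L + ri)
      pick <- with_seed(pick_seed,
                        sample.int(nrow(grid), min(cfg$warm_k, nrow(grid))))
      sub <- grid[pick, , drop = FALSE]
      aug_seed <- substream_seed(seed, "warm-augment", epoch * 100003L + ri)
      f <- with_seed(aug_seed,
                     .augmented_features(rec, sub, cfg$augmentation))
      feats[[length(feats) + 1L]] <- f
      labels <- c(labels, as.numeric(tl[pick] == "carcinoma"))
      n_draws <- n_draws + nrow(sub)
    }
    if (length(feats) > 0L) {
      .train_batches(model, do.call(rbind, feats), labels, cfg$initial_lr,
                     cfg$batch_size,
                     substream_seed(seed, "warm-shuffle", epoch))
    }
  }
  attr(model, "n_draws") <- n_draws
  model
}

# Accumulation buffer: environment holding feature rows + labels.
new_tile_buffer <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$feats <- matrix(numeric(0), ncol = .n_tile_features)
  e$labels <- numeric(0)
  e$capacity <- capacity
  e
}

#' One MIL epoch
#'
#' Visits slides in a seeded random permutation; scores all tissue tiles of
#' each slide in inference mode; appends the top-k tiles (by carcinoma
#' probability) to the accumulation buffer labelled with the *slide* label;
#' each time the buffer reaches `buffer_n`, runs `buffer_n / batch_size`
#' optimiser steps on a seeded shuffle of the buffer (with augmentation)
#' and empties it. The buffer persists across epochs via the `buffer`
#' argument.
#'
#' @param records list of `slide_record` objects (slide labels required).
#' @param model a tile classifier.
#' @param k tiles selected per slide.
#' @param cfg a [mil_config()].
#' @param lr learning rate for flushes during this epoch.
#' @param buffer buffer environment from a previous epoch, or `NULL`.
#' @param seed substream seed for visit order / shuffles.
#' @param cache optional named list of per-slide inference caches (grid +
#'   feature matrix); computed on the fly when `NULL`.
#' @return list of epoch statistics: `n_selected`, `n_flushes`, `n_steps`,
#'   `buffer_remainder`, `mean_flush_loss`, plus the `buffer` for the next
#'   epoch.
#' @export
mil_epoch <- function(records, model, k, cfg, lr = cfg$initial_lr,
                      buffer = NULL, seed = cfg$seed, cache = NULL) {
  if (is.null(buffer)) buffer <- new_tile_buffer(cfg$buffer_n)
  visit <- with_seed(substream_seed(seed, "visit-order"),
                     sample.int(length(records)))
  n_selected <- 0L; n_flushes <- 0L; n_steps <- 0L
  flush_losses <- c()
  for (ri in visit) {
    rec <- records[[ri]]
    entry <- if (!is.null(cache)) cache[[rec$slide_id]] else
      slide_inference_cache(rec, cfg$tile_size, cfg$stride,
                            cfg$tissue_threshold)
    grid <- entry$grid
    if (nrow(grid) == 0L) {
      warning("MIL epoch: slide ", rec$slide_id, " has no tissue tiles; skipped")
      next
    }
    probs <- predict_tiles(model, entry$feats)
    sel <- select_top_k(probs, k)
    y <- as.numeric(rec$slide_label == "carcinoma")
    # augment the selected tiles as they enter the buffer
    aug_seed <- substream_seed(seed, "mil-augment", ri)
    sel_feats <- with_seed(aug_seed,
                           .augmented_features(rec, grid[sel, , drop = FALSE],
                                               cfg$augmentation))
    for (j in seq_along(sel)) {
      buffer$feats <- rbind(buffer$feats, sel_feats[j, ])
      buffer$labels <- c(buffer$labels, y)
      n_selected <- n_selected + 1L
      if (nrow(buffer$feats) == buffer$capacity) {
        n_flushes <- n_flushes + 1L
        loss <- .train_batches(model, buffer$feats, buffer$labels, lr,
                               cfg$batch_size,
                               substream_seed(seed, "buffer-shuffle",
                                              n_flushes))
        flush_losses <- c(flush_losses, loss)
        n_steps <- n_steps + buffer$capacity %/% cfg$batch_size
        buffer$feats <- matrix(numeric(0), ncol = .n_tile_features)
        buffer$labels <- numeric(0)
      }
    }
  }
  list(n_selected = n_selected, n_flushes = n_flushes, n_steps = n_steps,
       buffer_remainder = nrow(buffer$feats),
       mean_flush_loss = if (length(flush_losses)) mean(flush_losses)
                         else NA_real_,
       buffer = buffer)
}

# Slide-level validation: max-aggregated probabilities vs slide labels.
.validate_slides <- function(model, records, tile_size, stride,
                             tissue_threshold, cache = NULL) {
  probs <- vapply(seq_along(records), function(i) {
    rec <- records[[i]]
    entry <- if (!is.null(cache)) cache[[rec$slide_id]] else
      slide_inference_cache(rec, tile_size, stride, tissue_threshold)
    if (nrow(entry$grid) == 0L) {
      stop("slide ", rec$slide_id, " has zero scorable tiles")
    }
    max(predict_tiles(model, entry$feats))
  }, numeric(1))
  y <- as.numeric(vapply(records, `[[`, character(1), "slide_label") ==
                    "carcinoma")
  auc <- if (length(unique(y)) == 2L) roc_auc(y, probs) else NA_real_
  list(loss = log_loss(y, probs), auc = auc)
}

.new_history <- function() {
  data.frame(epoch = integer(0), phase = character(0),
             train_loss = numeric(0), val_loss = numeric(0),
             val_auc = numeric(0), lr = numeric(0), k = integer(0))
}

# Shared best-state tracker for both trainers.
.track_best <- function(best, model, val_loss, epoch) {
  if (!is.na(val_loss) && val_loss < best$loss) {
    list(loss = val_loss, params = get_params(model), epoch = epoch)
  } else {
    best
  }
}

#' Train the fully-supervised baseline
#'
#' Trains on region-labelled tiles with the warm-start/decay schedule,
#' validates each epoch on the *tile-level* loss of the validation slides'
#' region-labelled tiles (the labels available to a fully-supervised
#' protocol — including their noise), stops early after `patience` epochs
#' without validation improvement, and returns the minimum-validation-loss
#' state. Slide-level validation AUC is recorded in the history for
#' monitoring but plays no role in stopping.
#'
#' @param dataset labelled-tile data frame from
#'   [build_supervised_dataset()].
#' @param slides list of `slide_record` objects indexed by the dataset's
#'   `slide_id` (pixel source for the tiles).
#' @param val list of `slide_record` objects for validation.
#' @param cfg an [fs_config()].
#' @param model optional classifier to continue training; default fresh.
#' @return object of class `c("fs_model", "wsi_model")`.
#' @export
fs_train <- function(dataset, slides, val, cfg = fs_config(), model = NULL) {
  if (length(unique(dataset$label)) < 2L) {
    stop("fully-supervised training requires both classes in the dataset")
  }
  slide_index <- stats::setNames(seq_along(slides),
                                 vapply(slides, `[[`, character(1), "slide_id"))
  if (anyNA(slide_index[unique(dataset$slide_id)])) {
    stop("dataset references slides not present in `slides`")
  }
  if (is.null(model)) {
    model <- new_tile_classifier(hidden = cfg$hidden,
                                 seed = substream_seed(cfg$seed, "init"),
                                 beta1 = cfg$beta1, beta2 = cfg$beta2)
  }
  n <- nrow(dataset)
  iters <- ceiling(n / cfg$batch_size)
  y_all <- as.numeric(dataset$label == "carcinoma")
  val_cache <- .build_cache(val, cfg$tile_size, cfg$val_stride,
                            cfg$tissue_threshold)
  # tile-level validation set: the labels an FS protocol actually has
  val_tiles <- suppressWarnings(
    build_supervised_dataset(val, cfg$tile_size, cfg$val_stride,
                             cfg$min_overlap, cfg$tissue_threshold))
  if (nrow(val_tiles) == 0L) {
    stop("validation slides yield no labelled tiles")
  }
  val_index <- stats::setNames(seq_along(val),
                               vapply(val, `[[`, character(1), "slide_id"))
  val_feats <- do.call(rbind, lapply(seq_len(nrow(val_tiles)), function(i) {
    rec <- val[[val_index[[val_tiles$slide_id[i]]]]]
    tile_features(extract_tile(rec$slide, val_tiles[i, ]))
  }))
  val_y <- as.numeric(val_tiles$label == "carcinoma")
  history <- .new_history()
  best <- list(loss = Inf, params = get_params(model), epoch = 0L)
  since_best <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(substream_seed(cfg$seed, "fs-shuffle", epoch),
                     sample.int(n))
    epoch_losses <- numeric(iters)
    lr <- NA_real_
    for (it in seq_len(iters)) {
      idx <- ord[((it - 1L) * cfg$batch_size + 1L):min(it * cfg$batch_size, n)]
      rows <- dataset[idx, , drop = FALSE]
      feats <- matrix(0, length(idx), .n_tile_features)
      aseed <- substream_seed(cfg$seed, "fs-augment", epoch * 1000003L + it)
      with_seed(aseed, {
        for (j in seq_along(idx)) {
          rec <- slides[[slide_index[[rows$slide_id[j]]]]]
          px <- rec$slide$pixels
          tile <- px[(rows$y[j] + 1L):(rows$y[j] + rows$size[j]),
                     (rows$x[j] + 1L):(rows$x[j] + rows$size[j]), ,
                     drop = FALSE]
          feats[j, ] <- tile_features(augment(tile, cfg$augmentation))
        }
      })
      lr <- fs_lr_schedule(epoch, it - 1L, iters,
                           cfg$base_lr, cfg$max_lr, cfg$lr_decay)
      epoch_losses[it] <- train_step(model, feats, y_all[idx], lr)
    }
    tile_val_loss <- log_loss(val_y, predict_tiles(model, val_feats))
    v <- .validate_slides(model, val, cfg$tile_size, cfg$val_stride,
                          cfg$tissue_threshold, cache = val_cache)
    history <- rbind(history, data.frame(
      epoch = epoch, phase = "fs", train_loss = mean(epoch_losses),
      val_loss = tile_val_loss, val_auc = v$auc, lr = lr, k = NA_integer_))
    prev_best <- best$loss
    best <- .track_best(best, model, tile_val_loss, epoch)
    if (!is.na(tile_val_loss) && tile_val_loss < prev_best) since_best <- 0L
    else since_best <- since_best + 1L
    if (since_best >= cfg$patience) break
  }
  set_params(model, best$params)
  new_wsi_model("fs_model", model, history, cfg, best$epoch)
}

#' Train the weakly-supervised (MIL) model
#'
#' Runs the warm phase, then `mil_epochs` MIL epochs with k from
#' [k_schedule()] and learning rate `initial_lr * decay^(epoch - 1)`.
#' Validation is slide-level log loss after every epoch (warm and MIL);
#' the returned state is the one with minimum validation loss. The
#' accumulation buffer persists across MIL epochs; a partial buffer left at
#' the end of training is discarded.
#'
#' @param records training `slide_record` list (annotations are only needed
#'   for the warm phase; the MIL phase uses slide labels alone).
#' @param val validation `slide_record` list.
#' @param cfg a [mil_config()].
#' @param model optional pre-initialised classifier.
#' @return object of class `c("mil_model", "wsi_model")`.
#' @export
mil_train <- function(records, val, cfg = mil_config(), model = NULL) {
  if (is.null(model)) {
    model <- new_tile_classifier(hidden = cfg$hidden,
                                 seed = substream_seed(cfg$seed, "init"),
                                 beta1 = cfg$beta1, beta2 = cfg$beta2)
  }
  history <- .new_history()
  best <- list(loss = Inf, params = get_params(model), epoch = 0L)
  epoch_no <- 0L
  train_cache <- .build_cache(records, cfg$tile_size, cfg$stride,
                              cfg$tissue_threshold)
  val_cache <- .build_cache(val, cfg$tile_size, cfg$val_stride,
                            cfg$tissue_threshold)
  for (we in seq_len(cfg$warm_epochs)) {
    single <- cfg
    single$warm_epochs <- 1L
    model <- warm_phase(records, single, model,
                        seed = substream_seed(cfg$seed, "warm-epoch", we))
    epoch_no <- epoch_no + 1L
    v <- .validate_slides(model, val, cfg$tile_size, cfg$val_stride,
                          cfg$tissue_threshold, cache = val_cache)
    history <- rbind(history, data.frame(
      epoch = epoch_no, phase = "warm", train_loss = NA_real_,
      val_loss = v$loss, val_auc = v$auc, lr = cfg$initial_lr,
      k = NA_integer_))
    best <- .track_best(best, model, v$loss, epoch_no)
  }
  buffer <- NULL
  for (me in seq_len(cfg$mil_epochs)) {
    k <- k_schedule(me, cfg)
    lr <- cfg$initial_lr * cfg$lr_decay_per_epoch^(me - 1)
    stats <- mil_epoch(records, model, k, cfg, lr = lr, buffer = buffer,
                       seed = substream_seed(cfg$seed, "mil-epoch", me),
                       cache = train_cache)
    buffer <- stats$buffer
    epoch_no <- epoch_no + 1L
    v <- .validate_slides(model, val, cfg$tile_size, cfg$val_stride,
                          cfg$tissue_threshold, cache = val_cache)
    history <- rbind(history, data.frame(
      epoch = epoch_no, phase = "mil", train_loss = stats$mean_flush_loss,
      val_loss = v$loss, val_auc = v$auc, lr = lr, k = k))
    best <- .track_best(best, model, v$loss, epoch_no)
  }
  set_params(model, best$params)  # end-of-training partial buffer discarded
  new_wsi_model("mil_model", model, history, cfg, best$epoch)
}

# ---- wsi_model S3 class ----------------------------------------------------

new_wsi_model <- function(subclass, classifier, history, config, best_epoch) {
  structure(list(classifier = classifier, history = history,
                 config = config, best_epoch = best_epoch),
            class = c(subclass, "wsi_model"))
}

#' @export
print.wsi_model <- function(x, ...) {
  regime <- if (inherits(x, "mil_model")) "weakly-supervised (MIL)"
            else "fully-supervised"
  cat("Whole-slide tile classifier --", regime, "\n")
  cat("  backbone:", x$classifier$backbone,
      "| hidden units:", x$classifier$hidden, "\n")
  cat("  epochs trained:", nrow(x$history),
      "| best epoch:", x$best_epoch, "\n")
  if (nrow(x$history) > 0L) {
    i <- which(x$history$epoch == x$best_epoch)
    if (length(i) == 1L) {
      cat(sprintf("  best validation loss: %.4f (AUC %.3f)\n",
                  x$history$val_loss[i], x$history$val_auc[i]))
    }
  }
  invisible(x)
}

#' @export
summary.wsi_model <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.wsi_model <- function(object, ...) {
  get_params(object$classifier)
}

#' Predict slide-level carcinoma probabilities
#'
#' Scores each slide in sliding-window fashion and aggregates by maximum
#' tile probability.
#'
#' @param object a fitted `wsi_model`.
#' @param records list of `slide_record` objects (or a single record).
#' @param stride inference stride; the reference protocol uses half the
#'   tile size (512/256); default `tile_size / 2`.
#' @param threshold classification threshold on the probability.
#' @param ... unused.
#' @return data frame with `slide_id`, `probability`, `predicted_label`,
#'   `n_tiles`.
#' @export
predict.wsi_model <- function(object, records,
                              stride = object$config$tile_size %/% 2L,
                              threshold = 0.5, ...) {
  if (inherits(records, "slide_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    map <- score_slide(object$classifier, rec$slide, object$config$tile_size,
                       stride, object$config$tissue_threshold)
    pred <- aggregate_slide(map, threshold = threshold)
    data.frame(slide_id = pred$slide_id,
               probability = pred$probability,
               predicted_label = pred$predicted_label,
               n_tiles = pred$n_tiles_scored,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
plot.wsi_model <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) {
    warning("empty training history; nothing to plot")
    return(invisible(x))
  }
  graphics::plot(h$epoch, h$val_loss, type = "b", pch = 19,
                 xlab = "epoch", ylab = "validation loss (slide level)",
                 main = "Training history", ...)
  if (any(!is.na(h$train_loss))) {
    graphics::lines(h$epoch, h$train_loss, type = "b", lty = 2, pch = 1)
    graphics::legend("topright", legend = c("validation", "training"),
                     lty = c(1, 2), pch = c(19, 1), bty = "n")
  }
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
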