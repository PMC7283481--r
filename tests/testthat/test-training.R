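test_that("k_schedule interpolates linearly and validates its range", {
  cfg <- mil_config(k_start = 5L, k_end = 1L, mil_epochs = 5L)
  expect_equal(vapply(1:5, k_schedule, integer(1), cfg = cfg), 5:1)
  const <- mil_config(k_start = 3L, k_end = 3L, mil_epochs = 4L)
  expect_equal(vapply(1:4, k_schedule, integer(1), cfg = const),
               rep(3L, 4))
  one <- mil_config(mil_epochs = 1L)
  expect_equal(k_schedule(1, one), 5L)
  expect_error(k_schedule(6, cfg), "1\\.\\.5")
  expect_error(k_schedule(0, cfg), "1\\.\\.5")
})

test_that("select_top_k matches the full-sort oracle incl. ties and clamping", {
  expect_equal(select_top_k(c(0.2, 0.9, 0.5, 0.9), 2), c(2L, 4L))
  expect_equal(select_top_k(c(0.3, 0.8, 0.1), 1), 2L)
  expect_equal(select_top_k(c(0.3, 0.8, 0.1), 10), c(2L, 1L, 3L))
  expect_equal(select_top_k(numeric(0), 3), integer(0))
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    p <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties frequent
    k <- sample(1:12, 1)
    expect_identical(select_top_k(p, k), top_k_oracle(p, k))
  }
})

test_that("mil_config enforces its invariants", {
  expect_error(mil_config(k_start = 2L, k_end = 5L), "k_end")
  expect_error(mil_config(buffer_n = 100L, batch_size = 64L), "multiple")
  expect_error(fs_config(max_epochs = 5L, patience = 10L), "patience")
})

test_that("warm phase draws the documented number of tiles, deterministically", {
  specs <- desk_spec(6, seed = 31, size = 256L)
  records <- generate_cohort_records(specs)
  cfg <- mil_config(tile_size = 64L, warm_k = 8L, warm_epochs = 2L,
                    batch_size = 8L, seed = 31)

  draws <- counting_stub()
  m <- warm_phase(records, cfg, draws, seed = 5)
  # 6 slides x 8 tiles x 2 epochs, fewer only for tile-poor slides
  expect_lte(attr(m, "n_draws"), 6L * 8L * 2L)
  expect_gt(attr(m, "n_draws"), 0L)
  # every trained batch respects the batch size
  expect_true(all(draws$state$batch_sizes <= 8L))

  # warm_epochs = 0 leaves parameters untouched
  mlp <- new_tile_classifier(seed = 2)
  before <- get_params(mlp)
  cfg0 <- mil_config(tile_size = 64L, warm_epochs = 0L, seed = 31)
  warm_phase(records, cfg0, mlp, seed = 5)
  expect_identical(get_params(mlp), before)

  # same seed, same sampled tiles: identical resulting parameters
  m1 <- new_tile_classifier(seed = 7)
  m2 <- new_tile_classifier(seed = 7)
  warm_phase(records, cfg, m1, seed = 9)
  warm_phase(records, cfg, m2, seed = 9)
  expect_identical(get_params(m1), get_params(m2))
})

test_that("mil_epoch selects slide-labelled top tiles and flushes by arithmetic", {
  # 20 uniform-tissue slides of 9 tiles each, frozen scorer, k = 3:
  # 60 selected tiles, buffer 16 -> 3 flushes (2 steps each), remainder 12
  records <- lapply(1:20, function(i) {
    rect_region_record(192, 192, if (i %% 2) "carcinoma" else "non_neoplastic",
                       slide_id = sprintf("s%02d", i))
  })
  cfg <- mil_config(tile_size = 64L, buffer_n = 16L, batch_size = 8L,
                    k_start = 3L, seed = 1,
                    augmentation = augmentation_config(FALSE, FALSE, 0L, 0))
  stub <- counting_stub()
  stats <- mil_epoch(records, stub, k = 3L, cfg, lr = 0.1, seed = 42)
  expect_equal(stats$n_selected, 60L)
  expect_equal(stats$n_flushes, 3L)
  expect_equal(stats$n_steps, 6L)
  expect_equal(stats$buffer_remainder, 60L - 3L * 16L)
  expect_equal(stub$state$steps, 6L)
  expect_true(all(stub$state$batch_sizes == 8L))

  # label provenance: buffered labels equal the slide labels
  label_log <- new.env(parent = emptyenv()); label_log$y <- numeric(0)
  logger <- manual_classifier(
    predict_fn = function(tiles) {
      n <- if (is.matrix(tiles)) nrow(tiles) else length(tiles)
      seq_len(n) / (n + 1)
    },
    train_fn = function(tiles, labels, lr) {
      label_log$y <- c(label_log$y, labels)
      0
    })
  cfg2 <- mil_config(tile_size = 64L, buffer_n = 8L, batch_size = 8L,
                     seed = 1,
                     augmentation = augmentation_config(FALSE, FALSE, 0L, 0))
  mil_epoch(records, logger, k = 2L, cfg2, lr = 0.1, seed = 7)
  # slides alternate carcinoma / non_neoplastic with k tiles each; all
  # flushed labels must be 0 or 1 and average 0.5 over the full epoch
  expect_true(all(label_log$y %in% c(0, 1)))
  expect_equal(mean(label_log$y), 0.5)

  # tie-break: on a constant map the lowest-index tiles are selected
  expect_equal(select_top_k(rep(0, 9), 1), 1L)

  # determinism: frozen model, fixed seed -> identical statistics
  s1 <- mil_epoch(records, frozen_stub(), 3L, cfg, lr = 0, seed = 5)
  s2 <- mil_epoch(records, frozen_stub(), 3L, cfg, lr = 0, seed = 5)
  expect_equal(s1[c("n_selected", "n_flushes", "buffer_remainder")],
               s2[c("n_selected", "n_flushes", "buffer_remainder")])
})

test_that("hard negatives are the maximal-scoring tiles of negative slides", {
  spec <- desk_spec(4, seed = 77, size = 256L)
  records <- Filter(function(r) r$slide_label == "non_neoplastic",
                    generate_cohort_records(spec))
  stub <- frozen_stub()
  cfg <- mil_config(tile_size = 64L, seed = 1)
  for (rec in records) {
    cache <- milwsi:::slide_inference_cache(rec, 64L, 64L, 0.1)
    probs <- predict_tiles(stub, cache$feats)
    sel <- select_top_k(probs, 2L)
    expect_equal(sort(probs[sel], decreasing = TRUE),
                 sort(probs, decreasing = TRUE)[1:2])
  }
})

test_that("fs_train implements min-validation-loss early stopping", {
  # scripted validation losses ~ [0.9, 0.5, 0.6, 0.7, ...] via a stub whose
  # constant prediction depends on the number of completed training steps
  qs <- exp(-c(0.9, 0.5, 0.6, 0.7, 0.8, 0.8))
  records <- list(rect_region_record(128, 128, "carcinoma", "pos"),
                  rect_region_record(128, 128, "non_neoplastic", "neg"))
  val <- list(rect_region_record(128, 128, "carcinoma", "vpos"))
  ds <- build_supervised_dataset(records, 64L, 64L)
  steps_per_epoch <- ceiling(nrow(ds) / 4)

  state <- new.env(parent = emptyenv())
  state$count <- 0L
  stub <- manual_classifier(
    predict_fn = function(tiles) {
      n <- if (is.matrix(tiles)) nrow(tiles) else length(tiles)
      epoch <- min(max(1L, state$count %/% steps_per_epoch),
                   length(qs))
      rep(qs[epoch], n)
    },
    train_fn = function(tiles, labels, lr) {
      state$count <- state$count + 1L
      state$epoch_at_step <- c(state$epoch_at_step, state$count)
      0.1
    },
    state = state)

  cfg <- fs_config(max_epochs = 6L, patience = 2L, batch_size = 4L,
                   tile_size = 64L, seed = 1,
                   augmentation = augmentation_config(FALSE, FALSE, 0L, 0))
  fit <- fs_train(ds, records, val, cfg, model = stub)
  # stops after epoch 4 (epochs 3 and 4 fail to beat epoch 2)
  expect_equal(nrow(fit$history), 4L)
  expect_equal(fit$best_epoch, 2L)
  expect_equal(fit$history$val_loss[1:4], c(0.9, 0.5, 0.6, 0.7),
               tolerance = 1e-9)
})

test_that("fs_train refuses single-class datasets and runs out its epochs otherwise", {
  rec <- rect_region_record(128, 128, "carcinoma")
  ds <- build_supervised_dataset(list(rec), 64L, 64L)
  cfg <- fs_config(max_epochs = 3L, patience = 3L, tile_size = 64L)
  expect_error(fs_train(ds, list(rec), list(rec), cfg), "both classes")
})

test_that("mil_train bookkeeping: history rows and degenerate horizons", {
  spec <- desk_spec(8, seed = 19, size = 256L)
  records <- generate_cohort_records(spec)
  train <- records[1:6]; val <- records[7:8]
  cfg <- mil_config(tile_size = 64L, warm_epochs = 1L, mil_epochs = 2L,
                    warm_k = 4L, buffer_n = 8L, batch_size = 8L,
                    initial_lr = 0.02, seed = 3)
  fit <- mil_train(train, val, cfg)
  expect_s3_class(fit, "mil_model")
  expect_equal(nrow(fit$history), 1L + 2L)
  expect_equal(fit$history$phase, c("warm", "mil", "mil"))
  expect_false(any(is.na(fit$history$val_loss)))

  # mil_epochs = 0 returns the warm-phase model
  cfg0 <- mil_config(tile_size = 64L, warm_epochs = 1L, mil_epochs = 0L,
                     warm_k = 4L, seed = 3)
  fit0 <- mil_train(train, val, cfg0)
  expect_equal(nrow(fit0$history), 1L)
  expect_equal(fit0$history$phase, "warm")
})
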