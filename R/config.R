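# Pipeline configuration and the stage runner.
#
# One YAML file configures all stages; defaults are the reference
# protocol's constants (tile 512, inference stride 256, x10, Adam
# (0.9, 0.999) batch 64, FS warm start 0.001 -> 0.05 with 0.9 decay / 22
# epochs / patience 10, warm phase k = 32 x 2 epochs, top-k 5 -> 1 over 5
# MIL epochs, buffer 512, MIL lr 0.001, bootstrap 1000).

default_config <- function() {
  list(
    seed = 1L,
    working_magnification = 10,
    tile_size = 512L,
    inference_stride = 256L,
    tissue_threshold = 0.1,
    paths = list(
      out_dir = ".",
      manifest = NULL,
      checkpoint = NULL,
      predictions = NULL,
      report = NULL,
      heatmap_dir = NULL
    ),
    synthesize = list(
      n_slides = 20L,
      carcinoma_fraction = 0.5,
      slide_width = 512L,
      slide_height = 512L,
      necrosis_in_carcinoma = 0.3,
      necrosis_in_negative = 0.5,
      texture_noise_sd = 0.05
    ),
    train_fs = list(
      max_epochs = 22L,
      patience = 10L,
      batch_size = 64L,
      base_lr = 0.001,
      max_lr = 0.05,
      lr_decay = 0.9,
      beta1 = 0.9,
      beta2 = 0.999,
      min_overlap = 0.5,
      hidden = 0L
    ),
    train_ws = list(
      warm_k = 32L,
      warm_epochs = 2L,
      k_start = 5L,
      k_end = 1L,
      mil_epochs = 5L,
      buffer_n = 512L,
      batch_size = 64L,
      initial_lr = 0.001,
      lr_decay_per_epoch = 0.9,
      beta1 = 0.9,
      beta2 = 0.999,
      min_overlap = 0.5,
      hidden = 0L
    ),
    evaluate = list(
      bootstrap_iterations = 1000L
    )
  )
}

# Merge user values over defaults, rejecting unknown keys (with a nearest
# -key suggestion) and recursing into nested blocks.
.merge_config <- function(defaults, user, prefix = "") {
  errors <- character(0)
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults)) {
      near <- agrep(key, names(defaults), max.distance = 2, value = TRUE)
      hint <- if (length(near) > 0L) {
        paste0(" (did you mean \"", near[1], "\"?)")
      } else ""
      errors <- c(errors, paste0("unknown key \"", full, "\"", hint))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      sub <- .merge_config(defaults[[key]], user[[key]],
                           paste0(full, "."))
      defaults[[key]] <- sub$config
      errors <- c(errors, sub$errors)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  list(config = defaults, errors = errors)
}

.validate_config <- function(cfg) {
  errors <- character(0)
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  chk(cfg$tile_size > 0, "tile_size must be positive")
  chk(cfg$inference_stride > 0, "inference_stride must be positive")
  chk(cfg$tissue_threshold >= 0 && cfg$tissue_threshold <= 1,
      "tissue_threshold must be in [0, 1]")
  ws <- cfg$train_ws
  chk(ws$k_end <= ws$k_start, "train_ws: k_end must be <= k_start")
  chk(ws$buffer_n %% ws$batch_size == 0,
      "train_ws: buffer_n must be a multiple of batch_size")
  chk(ws$beta1 > 0 && ws$beta1 < 1 && ws$beta2 > 0 && ws$beta2 < 1,
      "train_ws: Adam betas must lie in (0, 1)")
  fs <- cfg$train_fs
  chk(fs$patience <= fs$max_epochs, "train_fs: patience must be <= max_epochs")
  chk(fs$beta1 > 0 && fs$beta1 < 1 && fs$beta2 > 0 && fs$beta2 < 1,
      "train_fs: Adam betas must lie in (0, 1)")
  sy <- cfg$synthesize
  for (p in c("carcinoma_fraction", "necrosis_in_carcinoma",
              "necrosis_in_negative")) {
    chk(sy[[p]] >= 0 && sy[[p]] <= 1,
        paste0("synthesize: ", p, " must be in [0, 1]"))
  }
  chk(min(sy$slide_width, sy$slide_height) >= cfg$tile_size,
      "synthesize: slide size must be >= tile_size")
  errors
}

#' Load and validate a pipeline configuration
#'
#' Reads YAML, fills defaults (the reference protocol's constants), rejects
#' unknown keys with a nearest-key suggestion, and validates every block's
#' invariants, reporting all problems at once.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated configuration list of class `"run_config"`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  errors <- character(0)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      merged <- .merge_config(cfg, user)
      cfg <- merged$config
      errors <- merged$errors
    }
  }
  errors <- c(errors, .validate_config(cfg))
  if (length(errors) > 0L) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.write_provenance <- function(cfg, stage, out_dir) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  prov <- list(stage = stage,
               config_md5 = unname(tools::md5sum(tmp)),
               config = unclass(cfg),
               seed = cfg$seed,
               package_version = as.character(utils::packageVersion("milwsi")))
  unlink(tmp)
  jsonlite::write_json(prov,
                       file.path(out_dir, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

.fs_config_from_run <- function(cfg) {
  fs <- cfg$train_fs
  fs_config(max_epochs = fs$max_epochs, patience = fs$patience,
            batch_size = fs$batch_size, base_lr = fs$base_lr,
            max_lr = fs$max_lr, lr_decay = fs$lr_decay,
            beta1 = fs$beta1, beta2 = fs$beta2,
            tile_size = cfg$tile_size, min_overlap = fs$min_overlap,
            tissue_threshold = cfg$tissue_threshold,
            hidden = fs$hidden, seed = cfg$seed)
}

.mil_config_from_run <- function(cfg) {
  ws <- cfg$train_ws
  mil_config(warm_k = ws$warm_k, warm_epochs = ws$warm_epochs,
             k_start = ws$k_start, k_end = ws$k_end,
             mil_epochs = ws$mil_epochs, buffer_n = ws$buffer_n,
             batch_size = ws$batch_size, initial_lr = ws$initial_lr,
             lr_decay_per_epoch = ws$lr_decay_per_epoch,
             beta1 = ws$beta1, beta2 = ws$beta2,
             tile_size = cfg$tile_size, min_overlap = ws$min_overlap,
             tissue_threshold = cfg$tissue_threshold,
             hidden = ws$hidden, seed = cfg$seed)
}

# Split records into train/validation (last ~20% of slides validate).
.train_val_split <- function(records) {
  n <- length(records)
  n_val <- max(2L, floor(n / 5))
  if (n <= n_val) stop("too few slides to split off a validation set")
  list(train = records[seq_len(n - n_val)],
       val = records[(n - n_val + 1L):n])
}

#' Run pipeline stages
#'
#' Stages (in dependency order): `"synthesize"` writes a synthetic cohort
#' and its manifest; `"train-fs"` / `"train-ws"` fit the two regimes and
#' save a checkpoint; `"predict"` scores every manifest slide with the
#' checkpoint (stride `inference_stride`) and writes a predictions TSV plus
#' optional heatmaps; `"evaluate"` writes a JSON report and a ROC plot.
#' Missing dependencies (e.g. `"evaluate"` without predictions) fail before
#' any work; every completed stage writes a provenance file into the
#' output directory.
#'
#' @param config a `run_config` from [load_config()], or a path to one.
#' @param stages ordered character subset of the stage names above.
#' @return invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("synthesize", "train-ws", "predict",
                                    "evaluate")) {
  if (is.character(config)) config <- load_config(config)
  known <- c("synthesize", "train-fs", "train-ws", "predict", "evaluate")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stages: ", paste(bad, collapse = ", "))
  out_dir <- config$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- if (!is.null(config$paths$manifest)) config$paths$manifest
                   else file.path(out_dir, "manifest.tsv")
  checkpoint <- if (!is.null(config$paths$checkpoint)) config$paths$checkpoint
                else file.path(out_dir, "checkpoint.rds")
  pred_path <- if (!is.null(config$paths$predictions)) config$paths$predictions
               else file.path(out_dir, "predictions.tsv")
  report_path <- if (!is.null(config$paths$report)) config$paths$report
                 else file.path(out_dir, "report.json")

  # dependency check before any work
  for (i in seq_along(stages)) {
    st <- stages[i]
    before <- stages[seq_len(i - 1L)]
    if (st %in% c("train-fs", "train-ws", "predict") &&
        !"synthesize" %in% before && !file.exists(manifest_path)) {
      stop("stage ", st, " needs a manifest (", manifest_path,
           "); run synthesize first or point paths$manifest at one")
    }
    if (st == "predict" && !any(c("train-fs", "train-ws") %in% before) &&
        !file.exists(checkpoint)) {
      stop("stage predict needs a checkpoint (", checkpoint,
           "); run a training stage first")
    }
    if (st == "evaluate" && !"predict" %in% before &&
        !file.exists(pred_path)) {
      stop("stage evaluate needs predictions (", pred_path,
           "); run predict first")
    }
  }

  results <- list()
  for (st in stages) {
    if (st == "synthesize") {
      sy <- config$synthesize
      spec <- cohort_spec(n_slides = sy$n_slides,
                          carcinoma_fraction = sy$carcinoma_fraction,
                          slide_size = c(sy$slide_width, sy$slide_height),
                          tile_size = config$tile_size,
                          necrosis_in_carcinoma = sy$necrosis_in_carcinoma,
                          necrosis_in_negative = sy$necrosis_in_negative,
                          texture_noise_sd = sy$texture_noise_sd,
                          seed = substream_seed(config$seed, "synthesize"))
      manifest <- generate_cohort(spec, out_dir)
      .log_stage(st, "wrote ", nrow(manifest), " slides to ", out_dir)
      results$synthesize <- manifest
    } else if (st %in% c("train-fs", "train-ws")) {
      records <- load_slide_records(manifest_path,
                                    config$working_magnification)
      split <- .train_val_split(records)
      if (st == "train-fs") {
        cfg <- .fs_config_from_run(config)
        dataset <- build_supervised_dataset(
          split$train, cfg$tile_size, cfg$stride, cfg$min_overlap,
          cfg$tissue_threshold)
        fit <- fs_train(dataset, split$train, split$val, cfg)
      } else {
        fit <- mil_train(split$train, split$val, .mil_config_from_run(config))
      }
      save_checkpoint(fit$classifier, checkpoint)
      utils::write.table(fit$history, file.path(out_dir, "history.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      .log_stage(st, "best epoch ", fit$best_epoch, "; checkpoint at ",
                 checkpoint)
      results[[st]] <- fit
    } else if (st == "predict") {
      records <- load_slide_records(manifest_path,
                                    config$working_magnification)
      model <- load_checkpoint(checkpoint)
      rows <- lapply(records, function(rec) {
        map <- score_slide(model, rec$slide, config$tile_size,
                           config$inference_stride, config$tissue_threshold)
        if (!is.null(config$paths$heatmap_dir)) {
          hd <- config$paths$heatmap_dir
          if (!dir.exists(hd)) dir.create(hd, recursive = TRUE)
          hm <- render_heatmap(map, rec$slide$pixels)
          png::writePNG(hm, file.path(hd, paste0(rec$slide_id, "_heatmap.png")))
        }
        pred <- aggregate_slide(map)
        .log_stage(st, rec$slide_id, ": ", pred$n_tiles_scored,
                   " tiles scored, p = ", sprintf("%.4f", pred$probability))
        data.frame(slide_id = pred$slide_id, probability = pred$probability,
                   predicted_label = pred$predicted_label,
                   n_tiles = pred$n_tiles_scored, stringsAsFactors = FALSE)
      })
      preds <- do.call(rbind, rows)
      write_predictions(preds, pred_path)
      results$predict <- preds
    } else if (st == "evaluate") {
      res <- evaluate_predictions(
        pred_path, manifest_path,
        n_iterations = config$evaluate$bootstrap_iterations,
        seed = substream_seed(config$seed, "bootstrap"),
        report_path = report_path,
        roc_plot_path = file.path(out_dir, "roc.png"))
      .log_stage(st, sprintf("AUC %.4f (%.4f-%.4f), log loss %.4f",
                             res$auc, res$ci_low, res$ci_high, res$log_loss))
      results$evaluate <- res
    }
    .write_provenance(config, st, out_dir)
  }
  invisible(results)
}
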