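# Desk-scale study protocol.
#
# The reference protocol operates on gigapixel slides (512-px tiles at x10,
# thousands of slides, ~1M optimiser iterations). The desk-scale protocol
# reproduces its *structure* at laptop size: 512x512-px synthetic slides,
# 64-px tiles, 120 slides per cohort (64 train / 16 validation / 40 held
# out). The optimiser settings are rescaled for the small feature-MLP
# backbone and the ~10^2-iteration regime: the FS schedule keeps the
# reference warm-start/decay shape over 10 epochs; the MIL phase keeps
# k = 32 warm sampling and the linear top-k decay but spreads it over 15
# epochs with a 64-tile buffer and a 0.05 starting rate, so the
# hard-negative stream performs a comparable number of parameter updates
# relative to model size. See the methods vignette for the reasoning.

#' Desk-scale cohort specification
#'
#' The frozen study conditions used by the package's worked examples: 120
#' slides of 512 x 512 pixels, 64-px tiles, half carcinoma; the confounded
#' variant renders 30% of each carcinoma polygon with the shared
#' necrosis/inflammation texture and puts confounder patches on half the
#' non-neoplastic slides.
#'
#' @param seed cohort seed.
#' @param confounded logical; `FALSE` gives the noise-free control cohort.
#' @return a [cohort_spec()].
#' @export
desk_cohort_spec <- function(seed, confounded = TRUE) {
  cohort_spec(n_slides = 120L, carcinoma_fraction = 0.5,
              slide_size = c(512L, 512L), tile_size = 64L,
              necrosis_in_carcinoma = if (confounded) 0.3 else 0,
              necrosis_in_negative = if (confounded) 0.5 else 0,
              texture_noise_sd = 0.05, seed = seed)
}

#' Desk-scale training configurations
#'
#' @param seed run seed.
#' @return an [fs_config()] / [mil_config()] with desk-scale sizes.
#' @export
desk_fs_config <- function(seed) {
  fs_config(max_epochs = 10L, patience = 10L, tile_size = 64L, seed = seed)
}

#' @rdname desk_fs_config
#' @export
desk_mil_config <- function(seed) {
  mil_config(tile_size = 64L, initial_lr = 0.05, lr_decay_per_epoch = 0.95,
             buffer_n = 64L, mil_epochs = 15L, seed = seed)
}

#' Run the desk-scale two-regime comparison on one cohort
#'
#' Generates (in memory) the 120-slide cohort, trains the fully-supervised
#' baseline and the weakly-supervised MIL model on the same 64/16 split,
#' and scores the 40 held-out slides at stride 32 (half the tile size).
#'
#' @param seed cohort + training seed.
#' @param confounded whether to use the confounded cohort.
#' @return list with `auc_fs`, `auc_ws`, `log_loss_fs`, `log_loss_ws`,
#'   `labels`, `prob_fs`, `prob_ws`, `n_test`.
#' @export
desk_compare_regimes <- function(seed, confounded = TRUE) {
  records <- generate_cohort_records(desk_cohort_spec(seed, confounded))
  train <- records[1:64]
  val <- records[65:80]
  test <- records[81:120]
  ds <- build_supervised_dataset(train, 64L, 64L)
  fs <- fs_train(ds, train, val, desk_fs_config(seed))
  ws <- mil_train(train, val, desk_mil_config(seed))
  y <- as.numeric(vapply(test, `[[`, character(1), "slide_label") ==
                    "carcinoma")
  p_fs <- predict(fs, test)$probability
  p_ws <- predict(ws, test)$probability
  list(auc_fs = roc_auc(y, p_fs), auc_ws = roc_auc(y, p_ws),
       log_loss_fs = log_loss(y, p_fs), log_loss_ws = log_loss(y, p_ws),
       labels = y, prob_fs = p_fs, prob_ws = p_ws, n_test = length(y))
}
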