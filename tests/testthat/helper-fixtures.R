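# Shared fixtures and independent oracles, built in code.

# Constant-colour slide image (tissue-coloured by default so the tissue
# mask keeps it).
flat_slide <- function(width, height, colour = c(0.6, 0.4, 0.6),
                       slide_id = "flat") {
  px <- array(rep(colour, each = height * width),
              dim = c(height, width, 3L))
  new_slide_image(slide_id, px)
}

# Slide record fully covered by one rectangular region.
rect_region_record <- function(width, height, label,
                               slide_id = paste0("rect_", label),
                               colour = c(0.6, 0.4, 0.6)) {
  poly <- cbind(c(0, width, width, 0), c(0, 0, height, height))
  new_slide_record(slide_id, flat_slide(width, height, colour, slide_id),
                   list(region_annotation(poly, label)), label)
}

# Brute-force tile-grid enumeration: scan all origins, keep multiples of
# the stride whose window fits.
tile_grid_oracle <- function(width, height, tile_size, stride) {
  count <- 0L
  for (y in seq(0L, max(0L, height - tile_size), by = stride)) {
    for (x in seq(0L, max(0L, width - tile_size), by = stride)) {
      count <- count + 1L
    }
  }
  if (width < tile_size || height < tile_size) 0L else count
}

# Rasterised pixel-count oracle for tile/region coverage.
coverage_oracle <- function(tile, regions, resolution = 1L) {
  s <- tile$size * resolution
  xs <- tile$x + (seq_len(s) - 0.5) / resolution
  ys <- tile$y + (seq_len(s) - 0.5) / resolution
  px <- rep(xs, times = s)
  py <- rep(ys, each = s)
  cov <- c(carcinoma = 0, non_neoplastic = 0)
  for (cls in names(cov)) {
    inside <- rep(FALSE, length(px))
    for (r in regions) {
      if (r$label == cls) {
        inside <- inside | point_in_polygon(px, py, r$polygon)
      }
    }
    cov[cls] <- mean(inside)
  }
  cov
}

# Full-sort oracle for top-k selection with stable tie-break.
top_k_oracle <- function(p, k) {
  ord <- order(-p, seq_along(p))
  ord[seq_len(min(k, length(p)))]
}

# Brute-force pairwise ROC AUC (ties count 1/2).
roc_auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Stub classifier whose probabilities are a fixed deterministic function of
# tile features (mean of the red channel), for instrumented MIL epochs.
frozen_stub <- function() {
  manual_classifier(function(tiles) {
    X <- if (is.matrix(tiles)) tiles else t(vapply(tiles, tile_features,
                                                  numeric(8)))
    p <- X[, 1]
    pmin(pmax(p, 0), 1)
  })
}

# Stub that counts train_step calls.
counting_stub <- function(prob_fn = NULL) {
  state <- new.env(parent = emptyenv())
  state$steps <- 0L
  state$batch_sizes <- integer(0)
  mc <- manual_classifier(
    predict_fn = if (is.null(prob_fn)) {
      function(tiles) {
        X <- if (is.matrix(tiles)) tiles else t(vapply(tiles, tile_features,
                                                       numeric(8)))
        X[, 1]
      }
    } else prob_fn,
    train_fn = function(tiles, labels, lr) {
      n <- if (is.matrix(tiles)) nrow(tiles) else length(tiles)
      state$steps <- state$steps + 1L
      state$batch_sizes <- c(state$batch_sizes, n)
      0
    },
    state = state)
  mc
}

# Small desk-scale cohort specs shared across tests.
desk_spec <- function(n_slides, seed, confounded = TRUE, size = 256L) {
  cohort_spec(n_slides = n_slides, carcinoma_fraction = 0.5,
              slide_size = c(size, size), tile_size = 64L,
              necrosis_in_carcinoma = if (confounded) 0.3 else 0,
              necrosis_in_negative = if (confounded) 0.5 else 0,
              seed = seed)
}
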