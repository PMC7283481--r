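# Sliding-window slide scoring, max-probability aggregation, heatmaps.

#' Score a slide on the inference grid
#'
#' Applies the classifier in sliding-window fashion (reference protocol:
#' 512-pixel tiles, stride 256, at x10) to every grid cell passing the
#' tissue filter. Filtered (background) cells are missing (`NA`).
#'
#' @param model a tile classifier.
#' @param slide a `slide_image` at working magnification.
#' @param tile_size tile edge in pixels.
#' @param stride grid stride in pixels.
#' @param tissue_threshold minimum tissue fraction for a cell to be scored.
#' @return object of class `"probability_map"`: `slide_id`, `rows`, `cols`,
#'   `stride`, `tile_size`, and `values` (a `rows x cols` matrix in
#'   `[0, 1]` with `NA` for unscored cells).
#' @export
score_slide <- function(model, slide, tile_size, stride,
                        tissue_threshold = 0.1) {
  grid <- tile_grid(slide$width, slide$height, tile_size, stride)
  if (nrow(grid) == 0L) {
    stop("slide ", slide$slide_id, " (", slide$width, "x", slide$height,
         ") is smaller than the tile size ", tile_size)
  }
  mask <- tissue_mask(slide)
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    tissue_fraction(mask, grid[i, ]) >= tissue_threshold
  }, logical(1))
  if (!any(keep)) {
    stop("slide ", slide$slide_id, " has zero scorable tiles ",
         "(all cells below the tissue threshold)")
  }
  nrows <- max(grid$row) + 1L
  ncols <- max(grid$col) + 1L
  values <- matrix(NA_real_, nrows, ncols)
  scored <- grid[keep, , drop = FALSE]
  probs <- predict_tiles(model, grid_features(slide, scored))
  values[cbind(scored$row + 1L, scored$col + 1L)] <- probs
  structure(list(slide_id = slide$slide_id, rows = nrows, cols = ncols,
                 stride = as.integer(stride),
                 tile_size = as.integer(tile_size), values = values),
            class = "probability_map")
}

#' Aggregate a probability map into a slide prediction
#'
#' The slide probability is the maximum over non-missing cells (background
#' cells neither dilute nor dominate the slide score).
#'
#' @param map a `probability_map`.
#' @param threshold label threshold (default 0.5); the predicted label is
#'   carcinoma iff probability >= threshold.
#' @return object of class `"slide_prediction"`: `slide_id`, `probability`,
#'   `predicted_label`, `n_tiles_scored`.
#' @export
aggregate_slide <- function(map, threshold = 0.5) {
  v <- map$values[!is.na(map$values)]
  if (length(v) == 0L) {
    stop("probability map of slide ", map$slide_id, " has no scored cells")
  }
  p <- max(v)
  structure(list(slide_id = map$slide_id, probability = p,
                 predicted_label = if (p >= threshold) "carcinoma"
                                   else "non_neoplastic",
                 n_tiles_scored = length(v)),
            class = "slide_prediction")
}

#' Render a probability heatmap over a slide thumbnail
#'
#' Each scored cell's tile footprint is tinted with a fixed monotone colour
#' ramp of its probability, alpha-blended over the thumbnail; missing cells
#' leave the thumbnail untouched.
#'
#' @param map a `probability_map`.
#' @param thumbnail RGB array whose dimensions are proportional to the
#'   slide's (any integer or fractional scale).
#' @param alpha overlay opacity in `[0, 1]`.
#' @return RGB array with the thumbnail's dimensions.
#' @export
render_heatmap <- function(map, thumbnail, alpha = .heatmap_alpha) {
  th <- dim(thumbnail)[1]; tw <- dim(thumbnail)[2]
  slide_w <- (map$cols - 1L) * map$stride + map$tile_size
  slide_h <- (map$rows - 1L) * map$stride + map$tile_size
  sx <- tw / slide_w; sy <- th / slide_h
  if (abs(sx / sy - 1) > 0.2) {
    stop("thumbnail aspect ratio does not match the probability map's slide")
  }
  ramp <- grDevices::colorRamp(.heatmap_colours)
  out <- thumbnail
  for (r in seq_len(map$rows)) {
    for (cc in seq_len(map$cols)) {
      p <- map$values[r, cc]
      if (is.na(p)) next
      col <- ramp(p)[1, ] / 255
      x0 <- max(1L, floor((cc - 1L) * map$stride * sx) + 1L)
      y0 <- max(1L, floor((r - 1L) * map$stride * sy) + 1L)
      x1 <- min(tw, ceiling(((cc - 1L) * map$stride + map$tile_size) * sx))
      y1 <- min(th, ceiling(((r - 1L) * map$stride + map$tile_size) * sy))
      for (ch in 1:3) {
        out[y0:y1, x0:x1, ch] <-
          (1 - alpha) * out[y0:y1, x0:x1, ch] + alpha * col[ch]
      }
    }
  }
  out
}

#' Heatmap ramp colour for a probability
#'
#' Exposes the fixed colour ramp used by [render_heatmap()].
#'
#' @param p probability in `[0, 1]` (vectorised).
#' @return matrix of RGB values in `[0, 1]`, one row per probability.
#' @export
heatmap_colour <- function(p) {
  grDevices::colorRamp(.heatmap_colours)(p) / 255
}

#' Write / read a predictions table
#'
#' TSV with columns `slide_id`, `probability` (6 decimal places),
#' `predicted_label`, `n_tiles`.
#'
#' @param predictions data frame as produced by [predict.wsi_model()].
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  out$probability <- sprintf("%.6f", out$probability)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a probability map as TSV
#'
#' Four comment header lines (`slide_id`, `dims`, `stride`, `tile_size`)
#' followed by the `rows x cols` value grid (`NA` for missing cells).
#'
#' @param map a `probability_map`.
#' @param path file path.
#' @return `path` (write) or the restored `probability_map` (read).
#' @export
write_probability_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# slide_id\t", map$slide_id),
               paste0("# dims\t", map$rows, "\t", map$cols),
               paste0("# stride\t", map$stride),
               paste0("# tile_size\t", map$tile_size)), con)
  utils::write.table(map$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  hdr <- readLines(path, n = 4L)
  fields <- strsplit(hdr, "\t")
  vals <- as.matrix(utils::read.table(path, skip = 4L, sep = "\t"))
  dimnames(vals) <- NULL
  structure(list(slide_id = fields[[1]][2],
                 rows = as.integer(fields[[2]][2]),
                 cols = as.integer(fields[[2]][3]),
                 stride = as.integer(fields[[3]][2]),
                 tile_size = as.integer(fields[[4]][2]),
                 values = vals),
            class = "probability_map")
}
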