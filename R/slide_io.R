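# Slide reading, magnification handling, grid tiling, tissue masking.
#
# Coordinate convention (used everywhere in the package): 0-based pixels at
# the working magnification, x = column, y = row, half-open windows
# [x, x + size) x [y, y + size).

#' Construct a slide image object
#'
#' @param slide_id identifier string.
#' @param pixels RGB array `[height, width, 3]` with values in `[0, 1]`.
#' @param base_magnification objective power of the stored raster.
#' @param working_magnification objective power after downsampling.
#' @return object of class `"slide_image"` with fields `slide_id`, `pixels`,
#'   `width`, `height`, `base_magnification`, `working_magnification`.
#' @export
new_slide_image <- function(slide_id, pixels, base_magnification = 10,
                            working_magnification = base_magnification) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            working_magnification <= base_magnification,
            working_magnification > 0)
  structure(list(slide_id = slide_id,
                 pixels = pixels,
                 width = dim(pixels)[2],
                 height = dim(pixels)[1],
                 base_magnification = base_magnification,
                 working_magnification = working_magnification),
            class = "slide_image")
}

#' Construct a slide record
#'
#' @param slide_id identifier.
#' @param slide a `slide_image`.
#' @param regions list of region annotations (may be empty).
#' @param slide_label `"carcinoma"` or `"non_neoplastic"`; when regions are
#'   present it must agree with [derive_slide_label()].
#' @param truth_mask optional integer class-code matrix (synthetic slides).
#' @return object of class `"slide_record"`.
#' @export
new_slide_record <- function(slide_id, slide, regions, slide_label,
                             truth_mask = NULL) {
  slide_label <- match.arg(slide_label, c("carcinoma", "non_neoplastic"))
  if (length(regions) > 0L) {
    derived <- derive_slide_label(regions)
    if (!identical(derived, slide_label)) {
      stop("slide_label '", slide_label, "' inconsistent with annotations ('",
           derived, "') for slide ", slide_id)
    }
  }
  structure(list(slide_id = slide_id, slide = slide, regions = regions,
                 slide_label = slide_label, truth_mask = truth_mask),
            class = "slide_record")
}

# Block (area) mean downsampling of a matrix by an integer factor.
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  h2 <- nrow(m) %/% f; w2 <- ncol(m) %/% f
  m <- m[seq_len(h2 * f), seq_len(w2 * f), drop = FALSE]
  m <- matrix(colMeans(matrix(m, nrow = f)), nrow = h2)       # rows
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w2))      # cols
}

#' Load a slide image, downsampling to a working magnification
#'
#' Reads a plain raster slide (PNG or single-level TIFF) and downsamples by
#' area averaging from `base_magnification` to `target_magnification`. Only
#' integer downsample factors are supported (the standard use is x20 to
#' x10, factor 2). When no base magnification is supplied the file is
#' treated as already at the target.
#'
#' @param image_path path to a PNG or TIFF file.
#' @param target_magnification working objective power (default 10).
#' @param base_magnification objective power of the file; `NULL` means
#'   "already at target".
#' @param slide_id identifier; defaults to the file stem.
#' @return a `slide_image` at the working magnification; dimensions are the
#'   base dimensions divided by the factor (floored).
#' @export
load_slide <- function(image_path, target_magnification = 10,
                       base_magnification = NULL, slide_id = NULL) {
  if (!file.exists(image_path)) stop("cannot read slide image: ", image_path)
  if (is.null(base_magnification)) base_magnification <- target_magnification
  if (target_magnification > base_magnification) {
    stop("target magnification (x", target_magnification,
         ") exceeds base magnification (x", base_magnification,
         "): upsampling is not supported")
  }
  ext <- tolower(tools::file_ext(image_path))
  px <- switch(ext,
    png = png::readPNG(image_path),
    tif = ,
    tiff = tiff::readTIFF(image_path),
    stop("unsupported slide format '.", ext, "' (PNG or TIFF expected): ",
         image_path))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  f <- base_magnification / target_magnification
  if (abs(f - round(f)) > 1e-9) {
    stop("downsample factor ", f, " is not an integer; only integer ",
         "base/working magnification ratios are supported")
  }
  f <- as.integer(round(f))
  if (f > 1L) {
    px <- {
      ch <- lapply(1:3, function(k) block_mean(px[, , k], f))
      array(c(ch[[1]], ch[[2]], ch[[3]]),
            dim = c(dim(ch[[1]]), 3L))
    }
  }
  if (is.null(slide_id)) {
    slide_id <- tools::file_path_sans_ext(basename(image_path))
  }
  new_slide_image(slide_id, px,
                  base_magnification = base_magnification,
                  working_magnification = target_magnification)
}

#' Enumerate the tile grid of a slide
#'
#' Tiles are square, fully inside the slide (right/bottom margins not
#' covered by a full tile are dropped), and enumerated row-major (row
#' varies slowest).
#'
#' @param width,height slide dimensions in pixels at working magnification.
#' @param tile_size tile edge in pixels.
#' @param stride step between tile origins in pixels.
#' @return data frame of tile specs with columns `row`, `col` (0-based grid
#'   indices), `x`, `y` (0-based top-left corner, `x = col * stride`,
#'   `y = row * stride`) and `size`; `(floor((W-T)/S)+1) *
#'   (floor((H-T)/S)+1)` rows when both dimensions fit a tile, else 0 rows.
#' @export
#' @examples
#' nrow(tile_grid(1024, 1024, 512, 256))  # 9
tile_grid <- function(width, height, tile_size, stride) {
  if (tile_size <= 0 || stride <= 0) {
    stop("tile_size and stride must be positive")
  }
  empty <- data.frame(row = integer(0), col = integer(0), x = integer(0),
                      y = integer(0), size = integer(0))
  if (width < tile_size || height < tile_size) return(empty)
  nx <- (width - tile_size) %/% stride + 1L
  ny <- (height - tile_size) %/% stride + 1L
  g <- expand.grid(col = seq_len(nx) - 1L, row = seq_len(ny) - 1L)
  data.frame(row = g$row, col = g$col,
             x = as.integer(g$col * stride), y = as.integer(g$row * stride),
             size = as.integer(tile_size))
}

#' Compute the tissue mask of a slide
#'
#' Background is near-white, low-saturation pixels (value > 0.90 and
#' saturation < 0.12 in HSV terms); everything else is tissue. Deterministic.
#'
#' @param slide a `slide_image`.
#' @return logical `[height, width]` matrix, `TRUE` on tissue.
#' @export
tissue_mask <- function(slide) {
  stopifnot(inherits(slide, "slide_image"))
  px <- slide$pixels
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  !(mx > 0.90 & sat < 0.12)
}

#' Tissue fraction of a tile window
#'
#' @param mask logical matrix from [tissue_mask()].
#' @param tile one-row tile spec (list or data.frame row with `x`, `y`,
#'   `size`).
#' @return proportion in `[0, 1]`: the mean of the mask over the half-open
#'   tile window.
#' @export
tissue_fraction <- function(mask, tile) {
  mean(mask[tile$y + seq_len(tile$size), tile$x + seq_len(tile$size)])
}

#' Extract a tile's pixel block
#'
#' @param slide a `slide_image`.
#' @param tile tile spec with `x`, `y`, `size`.
#' @return RGB array `[size, size, 3]`.
#' @export
extract_tile <- function(slide, tile) {
  x <- tile$x; y <- tile$y; s <- tile$size
  if (x < 0 || y < 0 || x + s > slide$width || y + s > slide$height) {
    stop("tile (", x, ",", y, ") size ", s, " is out of bounds for slide ",
         slide$slide_id, " (", slide$width, "x", slide$height, ")")
  }
  slide$pixels[y + seq_len(s), x + seq_len(s), , drop = FALSE]
}
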