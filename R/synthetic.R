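# Synthetic slide cohorts.
#
# Each slide is a convex "tissue" blob on a near-white background,
# partitioned into convex lobes (Voronoi cells of seeded random points).
# On carcinoma slides a subset of lobes is annotated carcinoma and rendered
# with the carcinoma texture; a proportion `necrosis_in_carcinoma` of each
# carcinoma lobe's area is rendered with the shared confounder
# (necrosis/inflammation) texture while keeping the carcinoma annotation --
# the tile-label noise the weak-supervision comparison depends on.
# Non-neoplastic slides carry the *same* confounder texture as patches with
# per-slide probability `necrosis_in_negative`.

#' Specify a synthetic slide cohort
#'
#' @param n_slides number of slides.
#' @param carcinoma_fraction proportion of carcinoma slides in `[0, 1]`;
#'   the carcinoma slide count is `floor(n_slides * carcinoma_fraction + 0.5)`
#'   (round half up) and the carcinoma indices are the first ones of a
#'   seeded shuffle.
#' @param slide_size integer `c(width, height)` in pixels.
#' @param tile_size tile edge in pixels (64 at desk scale; 512 mirrors
#'   clinical practice).
#' @param necrosis_in_carcinoma proportion of each carcinoma polygon's area
#'   rendered with the confounder texture.
#' @param necrosis_in_negative proportion of non-neoplastic slides that
#'   contain confounder patches.
#' @param texture_noise_sd master pixel-intensity noise scale (fraction of
#'   dynamic range).
#' @param seed integer RNG seed; same spec + same seed reproduce the cohort
#'   byte for byte.
#' @return an object of class `"cohort_spec"`.
#' @export
#' @examples
#' spec <- cohort_spec(n_slides = 4, slide_size = c(128, 128), tile_size = 32)
#' slide <- generate_slide(spec, 1)
#' slide$slide_label
cohort_spec <- function(n_slides,
                        carcinoma_fraction = 0.5,
                        slide_size = c(512L, 512L),
                        tile_size = 64L,
                        necrosis_in_carcinoma = 0.3,
                        necrosis_in_negative = 0.5,
                        texture_noise_sd = 0.05,
                        seed = 1L) {
  stopifnot(length(n_slides) == 1L, n_slides >= 0,
            length(slide_size) == 2L, length(tile_size) == 1L)
  props <- c(carcinoma_fraction = carcinoma_fraction,
             necrosis_in_carcinoma = necrosis_in_carcinoma,
             necrosis_in_negative = necrosis_in_negative)
  bad <- props < 0 | props > 1
  if (any(bad)) {
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[bad], collapse = ", "))
  }
  if (any(slide_size < tile_size)) {
    stop("invalid spec: slide_size (", paste(slide_size, collapse = "x"),
         ") must be >= tile_size (", tile_size, ") in both dimensions")
  }
  if (texture_noise_sd < 0) stop("texture_noise_sd must be >= 0")
  structure(list(
    n_slides = as.integer(n_slides),
    carcinoma_fraction = carcinoma_fraction,
    slide_size = as.integer(slide_size),
    tile_size = as.integer(tile_size),
    necrosis_in_carcinoma = necrosis_in_carcinoma,
    necrosis_in_negative = necrosis_in_negative,
    texture_noise_sd = texture_noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Per-slide diagnosis labels of a cohort
#'
#' Deterministic given the spec: `floor(n * fraction + 0.5)` carcinoma
#' slides, assigned to the first indices of a seeded shuffle.
#'
#' @param spec a [cohort_spec()].
#' @return character vector of length `n_slides`, values
#'   `"carcinoma"` / `"non_neoplastic"`.
#' @export
cohort_slide_labels <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_slides
  if (n == 0L) return(character(0))
  m <- floor(n * spec$carcinoma_fraction + 0.5)
  labels <- rep("non_neoplastic", n)
  idx <- with_seed(substream_seed(spec$seed, "carcinoma-assignment"),
                   sample.int(n))
  labels[idx[seq_len(m)]] <- "carcinoma"
  labels
}

#' Generate one synthetic slide
#'
#' @param spec a [cohort_spec()].
#' @param slide_index slide index in `1..n_slides`.
#' @return an object of class `"slide_record"`: fields `slide_id`, `slide`
#'   (a `slide_image`), `regions` (list of region annotations),
#'   `slide_label`, and `truth_mask` (integer matrix coded
#'   0 = background, 1 = normal tissue, 2 = carcinoma tissue,
#'   3 = confounder tissue).
#' @export
generate_slide <- function(spec, slide_index) {
  stopifnot(inherits(spec, "cohort_spec"),
            slide_index >= 1L, slide_index <= spec$n_slides)
  label <- cohort_slide_labels(spec)[slide_index]
  with_seed(substream_seed(spec$seed, "slide", slide_index),
            .generate_slide_impl(spec, slide_index, label))
}

.generate_slide_impl <- function(spec, slide_index, slide_label) {
  w <- spec$slide_size[1]; h <- spec$slide_size[2]

  # tissue blob and its lobular (Voronoi) partition
  tissue <- random_convex_polygon(w / 2 + stats::runif(1, -0.04, 0.04) * w,
                                  h / 2 + stats::runif(1, -0.04, 0.04) * h,
                                  0.40 * min(w, h), 0.48 * min(w, h),
                                  n_points = 14L)
  n_lobes <- 5L
  seeds <- matrix(numeric(0), ncol = 2L)
  while (nrow(seeds) < n_lobes) {
    cand <- cbind(stats::runif(4L * n_lobes, 0, w), stats::runif(4L * n_lobes, 0, h))
    keep <- point_in_polygon(cand[, 1], cand[, 2], tissue)
    seeds <- rbind(seeds, cand[keep, , drop = FALSE])
  }
  seeds <- seeds[seq_len(n_lobes), , drop = FALSE]
  cells <- voronoi_cells(seeds, tissue)
  cells <- cells[vapply(cells, polygon_area, numeric(1)) > 1]

  # carcinoma lobes: accumulate shuffled cells until the target slide-area
  # fraction is reached
  carcinoma_idx <- integer(0)
  if (identical(slide_label, "carcinoma")) {
    target <- stats::runif(1, 0.12, 0.35) * w * h
    ord <- sample.int(length(cells))
    acc <- 0
    for (i in ord) {
      carcinoma_idx <- c(carcinoma_idx, i)
      acc <- acc + polygon_area(cells[[i]])
      if (acc >= target) break
    }
  }

  # truth mask: 0 background, 1 normal, 2 carcinoma, 3 confounder
  mask <- matrix(0L, nrow = h, ncol = w)
  tissue_r <- rasterize_polygon(tissue, w, h)
  mask[tissue_r] <- 1L
  cell_rasters <- lapply(cells, rasterize_polygon, width = w, height = h)

  # Tumor cellularity: carcinoma polygons are parenchyma blobs over a
  # stromal background, covering a per-slide fraction of each polygon.
  # Real carcinoma annotations enclose stroma and inflammation alongside
  # tumor cells, and slides with sparse parenchyma are the hard positives.
  # Parenchyma blobs are kept below tile scale so that low-cellularity
  # slides expose only tumor/stroma mixture tiles (the hard positives).
  cellularity <- stats::runif(1, 0.15, 0.9)
  for (i in carcinoma_idx) {
    cell_r <- cell_rasters[[i]]
    cell_px <- sum(cell_r)
    if (cell_px == 0L) next
    r_blob <- min(16, max(6, sqrt(cell_px * 0.015 / pi)))
    bbox <- cells[[i]]
    tries <- 0L
    tumor_px <- 0L
    while (tumor_px / cell_px < cellularity && tries < 400L) {
      tries <- tries + 1L
      cx <- stats::runif(1, min(bbox[, 1]), max(bbox[, 1]))
      cy <- stats::runif(1, min(bbox[, 2]), max(bbox[, 2]))
      if (!point_in_polygon(cx, cy, cells[[i]])) next
      blob <- random_convex_polygon(cx, cy, 0.85 * r_blob, 1.15 * r_blob)
      newly <- rasterize_polygon(blob, w, h) & cell_r & mask != 2L
      tumor_px <- tumor_px + sum(newly)
      mask[newly] <- 2L
    }
  }

  # confounder inside carcinoma lobes, up to necrosis_in_carcinoma of each
  if (length(carcinoma_idx) > 0L && spec$necrosis_in_carcinoma > 0) {
    for (i in carcinoma_idx) {
      cell_r <- cell_rasters[[i]]
      cell_px <- sum(cell_r)
      if (cell_px == 0L) next
      r_blob <- min(22, max(6, sqrt(cell_px * 0.035 / pi)))
      bbox <- cells[[i]]
      tries <- 0L
      conf_px <- 0L
      while (conf_px / cell_px < spec$necrosis_in_carcinoma && tries < 400L) {
        tries <- tries + 1L
        cx <- stats::runif(1, min(bbox[, 1]), max(bbox[, 1]))
        cy <- stats::runif(1, min(bbox[, 2]), max(bbox[, 2]))
        if (!point_in_polygon(cx, cy, cells[[i]])) next
        blob <- random_convex_polygon(cx, cy, 0.85 * r_blob, 1.15 * r_blob)
        newly <- rasterize_polygon(blob, w, h) & cell_r & mask != 3L
        conf_px <- conf_px + sum(newly)
        mask[newly] <- 3L
      }
    }
  }

  # confounder patches on non-neoplastic slides (same texture process)
  if (identical(slide_label, "non_neoplastic") &&
      stats::runif(1) < spec$necrosis_in_negative) {
    n_patch <- sample(1:2, 1L)
    placed <- 0L; tries <- 0L
    while (placed < n_patch && tries < 100L) {
      tries <- tries + 1L
      cx <- stats::runif(1, min(tissue[, 1]), max(tissue[, 1]))
      cy <- stats::runif(1, min(tissue[, 2]), max(tissue[, 2]))
      if (!point_in_polygon(cx, cy, tissue)) next
      r_patch <- stats::runif(1, 34, 46)
      blob <- random_convex_polygon(cx, cy, 0.85 * r_patch, 1.15 * r_patch)
      patch_r <- rasterize_polygon(blob, w, h) & tissue_r
      if (sum(patch_r) < 0.3 * pi * r_patch^2) next  # mostly fell off-tissue
      mask[patch_r] <- 3L
      placed <- placed + 1L
    }
  }

  image <- .render_texture_image(mask, spec$texture_noise_sd)

  regions <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    regions[[i]] <- region_annotation(
      cells[[i]],
      if (i %in% carcinoma_idx) "carcinoma" else "non_neoplastic")
  }

  slide_id <- sprintf("slide_%03d", slide_index)
  new_slide_record(
    slide_id = slide_id,
    slide = new_slide_image(slide_id, image,
                            base_magnification = 10,
                            working_magnification = 10),
    regions = regions,
    slide_label = slide_label,
    truth_mask = mask)
}

# Render the class-coded mask as an RGB image: per-class mean colour plus
# fine and coarse Gaussian fields shared across classes (see R/textures.R).
.render_texture_image <- function(mask, noise_sd) {
  h <- nrow(mask); w <- ncol(mask)
  cls <- mask + 1L  # 1..4 -> background, normal, carcinoma, confounder
  par_order <- c("background", "normal", "carcinoma", "confounder")
  means <- vapply(.texture_params[par_order], function(p) p$mean, numeric(3))
  fine_gain <- vapply(.texture_params[par_order], function(p) p$fine, numeric(1))
  coarse_gain <- vapply(.texture_params[par_order], function(p) p$coarse, numeric(1))
  img <- array(0, dim = c(h, w, 3L))
  fg <- fine_gain[cls]; cg <- coarse_gain[cls]
  for (ch in 1:3) {
    fine <- matrix(stats::rnorm(h * w), nrow = h)  # fine-grain speckle
    coarse <- coarse_field(h, w)
    stain <- stats::rnorm(1)  # slide-level staining offset (tissue only)
    v <- means[ch, cls] + noise_sd * fg * fine +
      .texture_coarse_gain * noise_sd * cg * coarse +
      .texture_stain_gain * noise_sd * cg * stain
    img[, , ch] <- pmin(1, pmax(0, matrix(v, nrow = h)))
  }
  img
}

#' Generate a whole cohort in memory
#'
#' @param spec a [cohort_spec()].
#' @return list of `slide_record` objects of length `n_slides`.
#' @export
generate_cohort_records <- function(spec) {
  lapply(seq_len(spec$n_slides), function(i) generate_slide(spec, i))
}

#' Generate a cohort on disk
#'
#' Writes, per slide, an RGB PNG, a GeoJSON FeatureCollection of region
#' annotations, and a single-channel PNG truth mask (test scaffolding named
#' `*_truthmask.png`; pixel value = class code / 255), plus a TSV manifest.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest data frame, invisibly; columns `slide_id`,
#'   `image_path`, `annotation_path`, `slide_label`.
#' @export
generate_cohort <- function(spec, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  rows <- vector("list", spec$n_slides)
  for (i in seq_len(spec$n_slides)) {
    rec <- generate_slide(spec, i)
    img_path <- file.path(out_dir, paste0(rec$slide_id, ".png"))
    ann_path <- file.path(out_dir, paste0(rec$slide_id, ".geojson"))
    mask_path <- file.path(out_dir, paste0(rec$slide_id, "_truthmask.png"))
    ok <- tryCatch({
      png::writePNG(rec$slide$pixels, img_path)
      write_annotations(rec$regions, ann_path)
      png::writePNG(rec$truth_mask / 255, mask_path)
      TRUE
    }, error = function(e) {
      stop("I/O failure writing slide artifacts under ", out_dir, ": ",
           conditionMessage(e))
    })
    rows[[i]] <- data.frame(slide_id = rec$slide_id,
                            image_path = img_path,
                            annotation_path = ann_path,
                            slide_label = rec$slide_label,
                            stringsAsFactors = FALSE)
  }
  manifest <- if (spec$n_slides == 0L) {
    data.frame(slide_id = character(0), image_path = character(0),
               annotation_path = character(0), slide_label = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
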