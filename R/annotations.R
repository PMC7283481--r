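# Region annotations: GeoJSON I/O, tile label assignment, slide label rule.

.region_labels <- c("carcinoma", "non_neoplastic")

#' Construct a region annotation
#'
#' @param polygon n x 2 vertex matrix (>= 3 vertices, open form, pixel
#'   coordinates at working magnification).
#' @param label `"carcinoma"` or `"non_neoplastic"`.
#' @return object of class `"region_annotation"`.
#' @export
region_annotation <- function(polygon, label) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    stop("polygon must have >= 3 vertices in two columns")
  }
  if (polygon_area(polygon) <= 0) stop("polygon must have positive area")
  if (!label %in% .region_labels) {
    stop("unknown region label '", label, "'; expected one of: ",
         paste(.region_labels, collapse = ", "))
  }
  structure(list(polygon = polygon, label = label),
            class = "region_annotation")
}

#' Read region annotations from a GeoJSON FeatureCollection
#'
#' Each Feature must carry a Polygon geometry (outer ring only) and a
#' property `label` in `{"carcinoma", "non_neoplastic"}`. Coordinates in the
#' file are at base magnification and are rescaled by `scale` (working /
#' base) on load.
#'
#' @param path GeoJSON file path.
#' @param scale coordinate scale factor applied on load (default 1).
#' @return list of `region_annotation` objects.
#' @export
read_annotations <- function(path, scale = 1) {
  gj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) {
                   stop("malformed GeoJSON in ", path, ": ",
                        conditionMessage(e))
                 })
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  feats <- gj$features
  out <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    ft <- feats[[i]]
    geom <- ft$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      stop("feature ", i, " in ", path, ": geometry must be a Polygon")
    }
    ring <- geom$coordinates[[1]]
    if (is.null(ring) || length(ring) < 4L) {
      stop("feature ", i, " in ", path,
           ": polygon ring needs >= 3 distinct vertices")
    }
    xy <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    if (isTRUE(all.equal(xy[1, ], xy[nrow(xy), ]))) {
      xy <- xy[-nrow(xy), , drop = FALSE]  # drop closing vertex
    }
    label <- ft$properties$label
    if (is.null(label) || !label %in% .region_labels) {
      stop("feature ", i, " in ", path, ": unknown label '",
           if (is.null(label)) "<missing>" else label,
           "'; expected one of: ", paste(.region_labels, collapse = ", "))
    }
    out[[i]] <- region_annotation(xy * scale, label)
  }
  out
}

#' Write region annotations as GeoJSON
#'
#' @param regions list of `region_annotation` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(regions, path) {
  features <- lapply(regions, function(r) {
    ring <- rbind(r$polygon, r$polygon[1, ])  # closed ring
    list(type = "Feature",
         properties = list(label = r$label),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) as.numeric(ring[i, ])))))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assign a class label to a tile from region annotations
#'
#' The label is that of the class whose regions cover the largest fraction
#' of the tile window, provided that fraction is at least `min_overlap`;
#' ties break toward carcinoma; otherwise `"unlabelled"`. Coverage is the
#' polygon-rectangle intersection area summed over each class's regions
#' (capped at the tile area), divided by the tile area. Regions of the same
#' class are assumed not to overlap each other (annotation tools do not
#' doubly annotate one area with one label); overlapping same-class regions
#' would double-count.
#'
#' @param tile tile spec with `x`, `y`, `size`.
#' @param regions list of `region_annotation` objects.
#' @param min_overlap minimum covered fraction in `(0, 1]` (default 0.5).
#' @return `"carcinoma"`, `"non_neoplastic"`, or `"unlabelled"`.
#' @export
assign_tile_label <- function(tile, regions, min_overlap = 0.5) {
  stopifnot(min_overlap > 0, min_overlap <= 1)
  cov <- tile_class_coverage(tile, regions)
  best <- if (cov["carcinoma"] >= cov["non_neoplastic"]) "carcinoma"
          else "non_neoplastic"
  if (cov[best] >= min_overlap) best else "unlabelled"
}

#' Per-class coverage fractions of a tile
#'
#' @inheritParams assign_tile_label
#' @return named numeric vector `c(carcinoma = , non_neoplastic = )` of
#'   covered fractions in `[0, 1]`.
#' @export
tile_class_coverage <- function(tile, regions) {
  area <- as.numeric(tile$size)^2
  x0 <- tile$x; y0 <- tile$y; x1 <- tile$x + tile$size; y1 <- tile$y + tile$size
  cov <- c(carcinoma = 0, non_neoplastic = 0)
  for (r in regions) {
    cov[r$label] <- cov[r$label] + polygon_rect_area(r$polygon, x0, y0, x1, y1)
  }
  pmin(cov / area, 1)
}

#' Derive the slide-level label from region annotations
#'
#' Carcinoma takes priority: a slide with any carcinoma region is carcinoma,
#' otherwise non-neoplastic.
#'
#' @param regions non-empty list of `region_annotation` objects.
#' @return `"carcinoma"` or `"non_neoplastic"`.
#' @export
derive_slide_label <- function(regions) {
  if (length(regions) == 0L) {
    stop("cannot derive a slide label from zero regions; ",
         "use the manifest label instead")
  }
  labels <- vapply(regions, function(r) r$label, character(1))
  if (any(labels == "carcinoma")) "carcinoma" else "non_neoplastic"
}

#' Build the fully-supervised tile dataset
#'
#' Enumerates the tile grid of every slide, keeps tiles passing the tissue
#' filter, labels them from the region annotations, and drops unlabelled
#' tiles. Order is deterministic: slides in input order, tiles row-major.
#'
#' @param records list of `slide_record` objects with annotations.
#' @param tile_size tile edge (pixels).
#' @param stride grid stride (pixels); defaults to `tile_size`
#'   (non-overlapping training grid).
#' @param min_overlap minimum region coverage for a label (default 0.5).
#' @param tissue_threshold minimum tissue fraction for a tile to enter the
#'   dataset (default 0.1).
#' @return data frame of labelled tiles: `slide_id`, `x`, `y`, `size`,
#'   `label`. Slides contributing zero usable tiles are skipped with a
#'   warning.
#' @export
build_supervised_dataset <- function(records, tile_size, stride = tile_size,
                                     min_overlap = 0.5,
                                     tissue_threshold = 0.1) {
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    grid <- tile_grid(rec$slide$width, rec$slide$height, tile_size, stride)
    rows <- NULL
    if (nrow(grid) > 0L) {
      mask <- tissue_mask(rec$slide)
      keep <- vapply(seq_len(nrow(grid)), function(t) {
        tissue_fraction(mask, grid[t, ]) >= tissue_threshold
      }, logical(1))
      grid <- grid[keep, , drop = FALSE]
      if (nrow(grid) > 0L) {
        labels <- vapply(seq_len(nrow(grid)), function(t) {
          assign_tile_label(grid[t, ], rec$regions, min_overlap)
        }, character(1))
        grid <- grid[labels != "unlabelled", , drop = FALSE]
        labels <- labels[labels != "unlabelled"]
        if (nrow(grid) > 0L) {
          rows <- data.frame(slide_id = rec$slide_id,
                             x = grid$x, y = grid$y, size = grid$size,
                             label = labels, stringsAsFactors = FALSE)
        }
      }
    }
    if (is.null(rows)) {
      warning("slide ", rec$slide_id,
              " contributed no usable labelled tiles; skipped")
    }
    out[[i]] <- rows
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(slide_id = character(0), x = integer(0), y = integer(0),
                      size = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a slide manifest TSV
#'
#' Columns: `slide_id`, `image_path`, `annotation_path`, `slide_label`,
#' optionally `base_magnification`.
#'
#' @param path manifest path.
#' @return data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "image_path", "annotation_path", "slide_label")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0L) {
    stop("manifest ", path, " lacks columns: ", paste(miss, collapse = ", "))
  }
  bad <- !m$slide_label %in% .region_labels
  if (any(bad)) {
    stop("manifest ", path, " has unknown slide labels: ",
         paste(unique(m$slide_label[bad]), collapse = ", "))
  }
  m
}

#' Write a slide manifest TSV
#'
#' @param manifest data frame with the manifest columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load slide records listed in a manifest
#'
#' @param manifest data frame from [read_manifest()] or a path to one.
#' @param target_magnification working magnification (default 10).
#' @return list of `slide_record` objects.
#' @export
load_slide_records <- function(manifest, target_magnification = 10) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    base <- if ("base_magnification" %in% names(row) &&
                !is.na(row$base_magnification)) row$base_magnification else NULL
    slide <- load_slide(row$image_path, target_magnification, base,
                        slide_id = row$slide_id)
    scale <- slide$working_magnification /
      (if (is.null(base)) slide$working_magnification else base)
    regions <- if (!is.na(row$annotation_path) &&
                   nzchar(row$annotation_path) &&
                   file.exists(row$annotation_path)) {
      read_annotations(row$annotation_path, scale = scale)
    } else {
      list()
    }
    new_slide_record(row$slide_id, slide, regions, row$slide_label)
  })
}
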