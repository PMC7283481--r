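test_that("cohort_spec validates proportions and slide/tile geometry", {
  expect_error(cohort_spec(4, carcinoma_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_spec(4, necrosis_in_carcinoma = -0.1), "\\[0, 1\\]")
  expect_error(cohort_spec(4, slide_size = c(48L, 256L), tile_size = 64L),
               "invalid spec")
})

test_that("carcinoma slide counts follow round-half-up assignment", {
  expect_equal(sum(cohort_slide_labels(
    cohort_spec(10, 0.5, seed = 1)) == "carcinoma"), 5L)
  expect_equal(sum(cohort_slide_labels(
    cohort_spec(3, 0.5, seed = 1)) == "carcinoma"), 2L)  # round half up
  expect_equal(sum(cohort_slide_labels(
    cohort_spec(7, 0, seed = 1)) == "carcinoma"), 0L)
  expect_length(cohort_slide_labels(cohort_spec(0, 0.5)), 0L)
})

test_that("generation is deterministic and respects carcinoma_fraction = 0", {
  spec <- cohort_spec(3, carcinoma_fraction = 0,
                      slide_size = c(192L, 192L), tile_size = 64L, seed = 4)
  rec <- generate_slide(spec, 2)
  expect_equal(rec$slide_label, "non_neoplastic")
  expect_equal(sum(vapply(rec$regions, function(r)
    r$label == "carcinoma", logical(1))), 0L)
  expect_false(any(rec$truth_mask == 2L))

  again <- generate_slide(spec, 2)
  expect_identical(again$slide$pixels, rec$slide$pixels)
  expect_identical(again$regions, rec$regions)
  expect_identical(again$truth_mask, rec$truth_mask)
})

test_that("confounder area inside carcinoma polygons tracks the spec proportion", {
  spec <- desk_spec(4, seed = 11, size = 512L)
  labels <- cohort_slide_labels(spec)
  idx <- which(labels == "carcinoma")[1]
  rec <- generate_slide(spec, idx)
  carc_polys <- Filter(function(r) r$label == "carcinoma", rec$regions)
  expect_gte(length(carc_polys), 1L)
  inside <- Reduce(`|`, lapply(carc_polys, function(r)
    rasterize_polygon(r$polygon, 512L, 512L)))
  frac <- sum(rec$truth_mask == 3L & inside) / sum(inside)
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.35)
})

test_that("every carcinoma truth pixel lies inside a carcinoma polygon", {
  spec <- desk_spec(4, seed = 23, size = 256L)
  for (i in seq_len(spec$n_slides)) {
    rec <- generate_slide(spec, i)
    carc <- which(rec$truth_mask == 2L, arr.ind = TRUE)
    if (nrow(carc) == 0L) next
    take <- carc[seq(1L, nrow(carc), length.out = min(500L, nrow(carc))), ,
                 drop = FALSE]
    px <- take[, 2] - 0.5; py <- take[, 1] - 0.5
    inside <- rep(FALSE, length(px))
    for (r in rec$regions) {
      if (r$label == "carcinoma") {
        inside <- inside | point_in_polygon(px, py, r$polygon)
      }
    }
    expect_true(all(inside))
  }
})

test_that("slide labels are consistent with the annotation priority rule", {
  spec <- desk_spec(6, seed = 9, size = 192L)
  for (i in seq_len(spec$n_slides)) {
    rec <- generate_slide(spec, i)
    expect_equal(rec$slide_label, derive_slide_label(rec$regions))
  }
})

test_that("the confounder texture is distributed identically in both contexts", {
  # Slide-level staining offsets make pixels within one slide correlated, so
  # the comparison samples a few pixels from each of many slides; both
  # contexts must then be draws from one process.
  spec <- cohort_spec(150, carcinoma_fraction = 0.5,
                      slide_size = c(192L, 192L), tile_size = 64L,
                      necrosis_in_carcinoma = 0.3,
                      necrosis_in_negative = 0.6, seed = 42)
  recs <- generate_cohort_records(spec)
  labels <- vapply(recs, `[[`, character(1), "slide_label")
  pick <- function(rs, m) {
    unlist(lapply(rs, function(r) {
      keep <- r$truth_mask == 3L
      if (!any(keep)) return(NULL)
      unlist(lapply(1:2, function(ch) {
        v <- r$slide$pixels[, , ch][keep]
        sample(v, min(m, length(v)))
      }))
    }))
  }
  set.seed(1)
  in_carc <- pick(recs[labels == "carcinoma"], 75)
  in_neg <- pick(recs[labels == "non_neoplastic"], 125)
  expect_gte(length(in_carc), 10000L)
  expect_gte(length(in_neg), 10000L)
  ks <- suppressWarnings(stats::ks.test(in_carc, in_neg))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("a trivially separable cohort is nearly perfectly classifiable by nearest centroid", {
  spec <- cohort_spec(10, carcinoma_fraction = 0.5,
                      slide_size = c(256L, 256L), tile_size = 64L,
                      necrosis_in_carcinoma = 0, necrosis_in_negative = 0,
                      texture_noise_sd = 0.01, seed = 8)
  recs <- generate_cohort_records(spec)
  feats <- list(); y <- c()
  for (rec in recs) {
    g <- tile_grid(256, 256, 64, 32)
    for (i in seq_len(nrow(g))) {
      sub <- rec$truth_mask[g$y[i] + 1:64, g$x[i] + 1:64]
      purity <- max(mean(sub == 1L), mean(sub == 2L))
      if (purity < 0.9) next  # mixed or background-heavy tiles skipped
      feats[[length(feats) + 1L]] <-
        tile_features(extract_tile(rec$slide, g[i, ]))
      y <- c(y, as.numeric(mean(sub == 2L) >= 0.9))
    }
  }
  X <- do.call(rbind, feats)[, 1:3]
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  score <- -sqrt(rowSums((X - rep(mu1, each = nrow(X)))^2)) +
    sqrt(rowSums((X - rep(mu0, each = nrow(X)))^2))
  expect_gte(roc_auc(y, score), 0.99)
})

test_that("generate_cohort writes images, annotations, truth masks and a manifest", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(4, carcinoma_fraction = 0.5,
                      slide_size = c(128L, 128L), tile_size = 64L, seed = 2)
  manifest <- generate_cohort(spec, dir)
  expect_equal(nrow(manifest), 4L)
  expect_equal(sum(manifest$slide_label == "carcinoma"), 2L)
  expect_true(all(file.exists(manifest$image_path)))
  expect_true(all(file.exists(manifest$annotation_path)))
  expect_true(all(file.exists(file.path(dir, paste0(manifest$slide_id,
                                                    "_truthmask.png")))))
  disk <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(disk$slide_id, manifest$slide_id)

  # round-trip: records loaded from disk match the in-memory generation
  recs <- load_slide_records(file.path(dir, "manifest.tsv"))
  mem <- generate_slide(spec, 1)
  expect_equal(recs[[1]]$slide$pixels, mem$slide$pixels, tolerance = 1 / 254)
  expect_equal(recs[[1]]$slide_label, mem$slide_label)
  expect_equal(length(recs[[1]]$regions), length(mem$regions))

  # empty cohort: manifest only, no error
  dir2 <- withr::local_tempdir()
  m0 <- generate_cohort(cohort_spec(0, 0.5, c(128L, 128L), 64L), dir2)
  expect_equal(nrow(m0), 0L)
  expect_true(file.exists(file.path(dir2, "manifest.tsv")))
})
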