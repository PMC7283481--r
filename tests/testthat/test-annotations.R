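square <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                    c(y0, y0, y0 + s, y0 + s))

test_that("GeoJSON annotations round-trip and reject bad labels", {
  dir <- withr::local_tempdir()
  regions <- list(region_annotation(square(0, 0, 100), "carcinoma"),
                  region_annotation(square(50, 50, 80), "non_neoplastic"))
  path <- file.path(dir, "ann.geojson")
  write_annotations(regions, path)
  back <- read_annotations(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$label, "carcinoma")
  expect_equal(back[[1]]$polygon, regions[[1]]$polygon)
  expect_equal(back[[2]]$polygon, regions[[2]]$polygon)

  # scale applied on load (base -> working magnification)
  half <- read_annotations(path, scale = 0.5)
  expect_equal(half[[1]]$polygon, regions[[1]]$polygon * 0.5)

  # empty collection
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       file.path(dir, "empty.geojson"), auto_unbox = TRUE)
  expect_length(read_annotations(file.path(dir, "empty.geojson")), 0L)

  # unknown label rejected with the feature index
  bad <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(label = "adenocarcinoma"),
    geometry = list(type = "Polygon", coordinates = list(list(
      list(0, 0), list(10, 0), list(10, 10), list(0, 0)))))))
  jsonlite::write_json(bad, file.path(dir, "bad.geojson"),
                       auto_unbox = TRUE)
  expect_error(read_annotations(file.path(dir, "bad.geojson")),
               "feature 1.*adenocarcinoma")
})

test_that("region_annotation validates its polygon", {
  expect_error(region_annotation(cbind(0:1, 0:1), "carcinoma"), ">= 3")
  expect_error(region_annotation(square(0, 0, 10), "stroma"),
               "unknown region label")
})

test_that("assign_tile_label follows majority coverage with carcinoma ties", {
  tile <- list(x = 0L, y = 0L, size = 100L)
  carc <- region_annotation(square(-50, -50, 400), "carcinoma")
  expect_equal(assign_tile_label(tile, list(carc)), "carcinoma")
  expect_equal(assign_tile_label(tile, list()), "unlabelled")

  # 0.6 carcinoma / 0.4 non-neoplastic -> carcinoma at min_overlap 0.5
  left <- region_annotation(cbind(c(0, 60, 60, 0), c(0, 0, 100, 100)),
                            "carcinoma")
  right <- region_annotation(cbind(c(60, 100, 100, 60), c(0, 0, 100, 100)),
                             "non_neoplastic")
  expect_equal(assign_tile_label(tile, list(left, right)), "carcinoma")
  # the same configuration against the rasterised pixel-count oracle
  oc <- coverage_oracle(tile, list(left, right), resolution = 2L)
  expect_equal(unname(tile_class_coverage(tile, list(left, right))),
               unname(oc), tolerance = 0.02)

  # exact tie breaks toward carcinoma
  half_c <- region_annotation(cbind(c(0, 50, 50, 0), c(0, 0, 100, 100)),
                              "carcinoma")
  half_n <- region_annotation(cbind(c(50, 100, 100, 50), c(0, 0, 100, 100)),
                              "non_neoplastic")
  expect_equal(assign_tile_label(tile, list(half_c, half_n)), "carcinoma")

  # below min_overlap -> unlabelled
  small <- region_annotation(square(0, 0, 30), "carcinoma")
  expect_equal(assign_tile_label(tile, list(small), min_overlap = 0.5),
               "unlabelled")
})

test_that("geometric coverage agrees with the rasterised oracle on random polygons", {
  set.seed(99)
  mismatches <- 0L
  # disjoint candidate sites (regions of one class must not overlap)
  sites <- rbind(c(20, 20), c(80, 20), c(50, 80))
  for (i in 1:500) {
    tile <- list(x = sample(0:60, 1), y = sample(0:60, 1), size = 32L)
    which_sites <- sample(1:3, sample(1:3, 1))
    regions <- lapply(which_sites, function(j) {
      cx <- sites[j, 1]; cy <- sites[j, 2]
      r <- runif(1, 8, 28)
      ang <- sort(runif(sample(3:8, 1), 0, 2 * pi))
      poly <- cbind(cx + r * cos(ang), cy + r * sin(ang))
      poly <- poly[rev(grDevices::chull(poly)), , drop = FALSE]
      if (nrow(poly) < 3) return(NULL)
      region_annotation(poly, sample(c("carcinoma", "non_neoplastic"), 1))
    })
    regions <- Filter(Negate(is.null), regions)
    if (length(regions) == 0L) next
    geo <- tile_class_coverage(tile, regions)
    ora <- coverage_oracle(tile, regions, resolution = 4L)
    expect_lt(max(abs(geo - ora)), 0.02)
    # label decisions must agree away from the 2% boundary band
    away <- all(abs(ora - 0.5) > 0.02) &&
      abs(ora["carcinoma"] - ora["non_neoplastic"]) > 0.04
    if (away) {
      lbl_geo <- assign_tile_label(tile, regions)
      best <- if (ora["carcinoma"] >= ora["non_neoplastic"]) "carcinoma"
              else "non_neoplastic"
      lbl_ora <- if (ora[best] >= 0.5) best else "unlabelled"
      if (!identical(lbl_geo, lbl_ora)) mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("derive_slide_label applies carcinoma priority and is monotone", {
  carc <- region_annotation(square(0, 0, 10), "carcinoma")
  nn <- region_annotation(square(20, 20, 10), "non_neoplastic")
  expect_equal(derive_slide_label(list(carc, nn)), "carcinoma")
  expect_equal(derive_slide_label(list(nn, nn)), "non_neoplastic")
  expect_error(derive_slide_label(list()), "zero regions")
  # adding a carcinoma region never demotes a carcinoma slide
  set.seed(3)
  for (i in 1:20) {
    base <- sample(list(carc, nn), sample(1:4, 1), replace = TRUE)
    if (derive_slide_label(base) == "carcinoma") {
      expect_equal(derive_slide_label(c(base, list(carc))), "carcinoma")
    }
  }
})

test_that("build_supervised_dataset labels full-coverage slides and is deterministic", {
  rec <- rect_region_record(128, 128, "carcinoma")
  ds <- build_supervised_dataset(list(rec), tile_size = 64L, stride = 64L)
  expect_equal(nrow(ds), 4L)
  expect_true(all(ds$label == "carcinoma"))
  expect_equal(ds$x, c(0L, 64L, 0L, 64L))
  expect_identical(ds, build_supervised_dataset(list(rec), 64L, 64L))

  # a slide whose annotations cover nothing contributes zero tiles + warning
  bare <- new_slide_record("bare", flat_slide(128, 128),
                           list(region_annotation(square(500, 500, 50),
                                                  "non_neoplastic")),
                           "non_neoplastic")
  expect_warning(ds2 <- build_supervised_dataset(list(bare), 64L, 64L),
                 "no usable")
  expect_equal(nrow(ds2), 0L)
})

test_that("manifest round-trips and rejects unknown slide labels", {
  dir <- withr::local_tempdir()
  m <- data.frame(slide_id = c("a", "b"),
                  image_path = c("a.png", "b.png"),
                  annotation_path = c("a.geojson", "b.geojson"),
                  slide_label = c("carcinoma", "non_neoplastic"),
                  stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.tsv")
  write_manifest(m, path)
  expect_equal(read_manifest(path), m)
  m$slide_label[1] <- "benign"
  write_manifest(m, path)
  expect_error(read_manifest(path), "unknown slide labels")
})
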