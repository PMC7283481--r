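test_that("roc_auc matches hand-checked values and edge cases", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.2)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)  # all ties
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  expect_error(roc_auc(c(1, 0), c(0.2)), "equal length")
})

test_that("roc_auc equals the brute-force pairwise oracle, with ties", {
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    # coarse scores force frequent ties
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(roc_auc(y, s), roc_auc_oracle(y, s))
  }
})

test_that("roc_auc is invariant under strictly monotone transforms and complements", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- runif(n)  # continuous: ties almost surely absent
    a <- roc_auc(y, s)
    expect_equal(roc_auc(y, qlogis(s)), a)
    expect_equal(roc_auc(y, s^3), a)
    expect_equal(roc_auc(y, -s), 1 - a)
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:20) {
    y <- c(0, 1, sample(0:1, 48, replace = TRUE))
    s <- round(runif(50), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(y, s), ref)
  }
})

test_that("log_loss matches closed forms and is permutation-symmetric", {
  expect_equal(log_loss(c(1, 0), c(0.5, 0.5)), log(2))
  expect_lt(log_loss(1, 1 - 1e-12), 1e-11)
  expect_equal(log_loss(c(1, 1, 0), c(0.9, 0.8, 0.3)),
               -mean(log(c(0.9, 0.8, 0.7))))
  set.seed(2)
  y <- sample(0:1, 20, replace = TRUE)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(log_loss(y[perm], p[perm]), log_loss(y, p))
  expect_error(log_loss(c(1, 0), c(0.5)), "equal length")
  # clipping keeps confident-wrong predictions finite
  expect_true(is.finite(log_loss(1, 0)))
})

test_that("bootstrap_ci is deterministic, degenerate on separated data, and shrinks with n", {
  y <- rep(c(1, 0), each = 10)
  s <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  ci <- bootstrap_ci(y, s, n_iterations = 200, seed = 5)
  expect_equal(unname(ci), c(1, 1))

  set.seed(77)
  y2 <- rep(c(1, 0), each = 50)
  s2 <- c(rnorm(50, 1), rnorm(50, 0))
  expect_identical(bootstrap_ci(y2, s2, n_iterations = 300, seed = 9),
                   bootstrap_ci(y2, s2, n_iterations = 300, seed = 9))
  expect_error(bootstrap_ci(rep(1, 5), runif(5), seed = 1), "both classes")

  widths <- sapply(1:12, function(i) {
    w <- numeric(2)
    for (j in 1:2) {
      n <- c(100, 400)[j]
      set.seed(1000 * i + j)
      y <- rep(c(1, 0), each = n / 2)
      s <- c(rnorm(n / 2, 1.19), rnorm(n / 2, 0))
      ci <- bootstrap_ci(y, s, n_iterations = 200, seed = i)
      w[j] <- ci[2] - ci[1]
    }
    w
  })
  expect_lt(median(widths[2, ]), median(widths[1, ]))
})

test_that("evaluate_predictions joins on slide_id and reports closed-form cases", {
  dir <- withr::local_tempdir()
  manifest <- data.frame(slide_id = sprintf("s%02d", 1:20),
                         image_path = "x.png", annotation_path = "x.geojson",
                         slide_label = rep(c("carcinoma", "non_neoplastic"),
                                           10),
                         stringsAsFactors = FALSE)
  preds <- data.frame(slide_id = manifest$slide_id,
                      probability = ifelse(manifest$slide_label ==
                                             "carcinoma", 1, 0),
                      predicted_label = manifest$slide_label,
                      n_tiles = 9L, stringsAsFactors = FALSE)
  res <- evaluate_predictions(preds, manifest, n_iterations = 100, seed = 3)
  expect_equal(res$auc, 1.0)
  expect_lt(res$log_loss, 1e-10)
  expect_equal(res$n_pos, 10L)
  expect_equal(res$n_neg, 10L)

  flat <- preds
  flat$probability <- 0.5
  res2 <- evaluate_predictions(flat, manifest, n_iterations = 100, seed = 3)
  expect_equal(res2$auc, 0.5)
  expect_equal(res2$log_loss, log(2))

  # report + ROC plot files written
  rp <- file.path(dir, "report.json"); pp <- file.path(dir, "roc.png")
  evaluate_predictions(preds, manifest, n_iterations = 50, seed = 1,
                       report_path = rp, roc_plot_path = pp)
  expect_true(file.exists(rp))
  expect_true(file.exists(pp))
  report <- jsonlite::read_json(rp)
  expect_equal(report$auc, 1.0)

  expect_error(evaluate_predictions(preds[-1, ], manifest,
                                    n_iterations = 10, seed = 1),
               "missing from predictions")
  preds$slide_id[1] <- "ghost"
  expect_error(evaluate_predictions(preds, manifest, n_iterations = 10,
                                    seed = 1), "ghost")
})
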