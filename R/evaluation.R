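# Slide-level evaluation: ROC AUC, log loss, percentile bootstrap CIs.

#' ROC AUC (Mann-Whitney formulation)
#'
#' Equals the probability that a uniformly random positive outscores a
#' uniformly random negative, ties counting one half; computed from midrank
#' sums, which is exactly the pairwise count.
#'
#' @param labels binary vector (1/TRUE = positive).
#' @param scores numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.2))  # 0.75
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC AUC requires both classes to be present")
  }
  r <- rank(scores)  # midranks: ties count 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary log loss (mean negative log-likelihood)
#'
#' Probabilities are clipped to `[eps, 1 - eps]` before taking logs.
#'
#' @param labels binary vector (1 = positive).
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param eps clipping epsilon (default 1e-15).
#' @return mean of `-(y log p + (1 - y) log(1 - p))`.
#' @export
#' @examples
#' log_loss(c(1, 0), c(0.5, 0.5))  # log(2)
log_loss <- function(labels, probabilities, eps = 1e-15) {
  labels <- as.numeric(labels)
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities must have equal length")
  }
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Percentile bootstrap confidence interval for the ROC AUC
#'
#' Resamples slides with replacement `n_iterations` times (the reference
#' protocol uses 1000) and takes the percentile interval of the resampled
#' AUCs. Resamples missing a class are redrawn, with a global attempt cap
#' of `10 * n_iterations`.
#'
#' @param labels binary vector.
#' @param scores numeric scores.
#' @param n_iterations bootstrap iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return named numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(labels, scores, n_iterations = 1000L, level = 0.95,
                         seed = 1L) {
  labels <- as.numeric(labels)
  n <- length(labels)
  if (length(unique(labels)) < 2L) {
    stop("bootstrap CI requires both classes to be present")
  }
  aucs <- numeric(n_iterations)
  with_seed(seed, {
    attempts <- 0L
    cap <- 10L * n_iterations
    i <- 1L
    while (i <= n_iterations) {
      attempts <- attempts + 1L
      if (attempts > cap) {
        stop("could not obtain ", n_iterations,
             " two-class bootstrap resamples in ", cap, " attempts")
      }
      idx <- sample.int(n, n, replace = TRUE)
      s <- sum(labels[idx])
      if (s == 0 || s == n) next  # single-class resample: redraw
      aucs[i] <- roc_auc(labels[idx], scores[idx])
      i <- i + 1L
    }
  })
  q <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Evaluate slide predictions against a manifest
#'
#' Joins predictions to manifest labels on `slide_id` and computes ROC AUC
#' with a percentile bootstrap CI plus the log loss. Optionally writes a
#' JSON report and a ROC curve plot.
#'
#' @param predictions predictions data frame or path to a predictions TSV.
#' @param manifest manifest data frame or path.
#' @param n_iterations bootstrap iterations (default 1000).
#' @param seed bootstrap seed.
#' @param report_path optional path for a JSON report.
#' @param roc_plot_path optional path for a ROC curve PNG.
#' @return object of class `"eval_result"`: `auc`, `ci_low`, `ci_high`,
#'   `log_loss`, `n_pos`, `n_neg`, `n_bootstrap`, `seed`.
#' @export
evaluate_predictions <- function(predictions, manifest,
                                 n_iterations = 1000L, seed = 1L,
                                 report_path = NULL, roc_plot_path = NULL) {
  if (is.character(predictions)) predictions <- read_predictions(predictions)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  unmatched <- setdiff(predictions$slide_id, manifest$slide_id)
  if (length(unmatched) > 0L) {
    stop("prediction slide_ids missing from manifest: ",
         paste(unmatched, collapse = ", "))
  }
  unmatched <- setdiff(manifest$slide_id, predictions$slide_id)
  if (length(unmatched) > 0L) {
    stop("manifest slide_ids missing from predictions: ",
         paste(unmatched, collapse = ", "))
  }
  m <- merge(predictions, manifest[, c("slide_id", "slide_label")],
             by = "slide_id", sort = TRUE)
  y <- as.numeric(m$slide_label == "carcinoma")
  p <- m$probability
  ci <- bootstrap_ci(y, p, n_iterations = n_iterations, seed = seed)
  res <- structure(list(auc = roc_auc(y, p),
                        ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                        log_loss = log_loss(y, p),
                        n_pos = sum(y == 1), n_neg = sum(y == 0),
                        n_bootstrap = as.integer(n_iterations),
                        seed = as.integer(seed)),
                   class = "eval_result")
  if (!is.null(report_path)) {
    jsonlite::write_json(unclass(res), report_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(roc_plot_path)) {
    grDevices::png(roc_plot_path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    plot_roc(y, p, main = sprintf("ROC (AUC = %.3f)", res$auc))
  }
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("ROC AUC: %.4f (95%% CI %.4f-%.4f, %d bootstrap iterations)\n",
              x$auc, x$ci_low, x$ci_high, x$n_bootstrap))
  cat(sprintf("Log loss: %.4f\n", x$log_loss))
  cat(sprintf("Slides: %d carcinoma, %d non-neoplastic\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param labels binary vector.
#' @param scores numeric scores.
#' @param ... passed to [graphics::plot()].
#' @return the data frame of (fpr, tpr) points, invisibly.
#' @export
plot_roc <- function(labels, scores, ...) {
  labels <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(labels[ord] == 1) / sum(labels == 1))
  fpr <- c(0, cumsum(labels[ord] == 0) / sum(labels == 0))
  graphics::plot(fpr, tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(data.frame(fpr = fpr, tpr = tpr))
}
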