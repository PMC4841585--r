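#' Repeated balanced k-fold cross-validation
#'
#' Each repeat draws a fresh class-balanced subsample of the dataset
#' ([balanced_subsample()]), splits it into `k` stratified folds, and for
#' each fold trains on the remaining folds and scores the held-out one.
#' Anything fitted from data — the PSAAP propensity matrix — is fitted
#' inside the training folds only, so held-out windows never influence
#' their own encoding. The held-out scores of a repeat are pooled into one
#' ROC/AUC and one confusion matrix at the cutoff; metrics are then
#' averaged across repeats and reported as mean and standard deviation.
#'
#' @inheritParams soh_fit
#' @param k Number of folds (default 10). Must not exceed the per-class
#'   count of the balanced subsample.
#' @param repeats Number of independent balanced subsamples (default 20).
#' @return Object of class `soh_cv`: `metrics` (one row per repeat: `AUC`,
#'   `SN`, `SP`, `ACC`, `MCC`), `summary` (mean/sd per metric), `roc` (the
#'   pooled ROC of the first repeat, for plotting) and the configuration.
#' @seealso [summarize_metrics()], [plot.soh_cv()]
#' @export
soh_cv <- function(dataset, encoding = c("aaindex", "binary", "psaap"),
                   k = 10L, repeats = 20L, gamma = 0.005, cost = 1,
                   cutoff = 0.5, properties = NULL, seed = 1L) {
  encoding <- match.arg(encoding)
  stopifnot(k >= 2L, repeats >= 1L)
  if (encoding == "aaindex" && is.null(properties)) {
    properties <- aa_properties()
  }
  n_pos <- sum(dataset$label == 1L)
  if (k > n_pos) {
    stop("k = ", k, " exceeds the positive class size (", n_pos, ")",
         call. = FALSE)
  }
  roc1 <- NULL
  metrics <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    sub <- balanced_subsample(dataset, seed = seed + 1000L * r)
    folds <- with_seed(seed + 1000L * r + 1L,
                       stratified_folds(sub$label, k))
    prob <- numeric(nrow(sub))
    for (fold in seq_len(k)) {
      test <- folds == fold
      train <- sub[!test, , drop = FALSE]
      psaap <- if (encoding == "psaap") {
        fit_psaap(train[train$label == 1L, ])
      }
      x_tr <- encode_windows(train, encoding, psaap = psaap,
                             properties = properties)
      fit <- svm_train(x_tr, train$label, gamma = gamma, cost = cost)
      x_te <- encode_windows(sub[test, , drop = FALSE], encoding,
                             psaap = psaap, properties = properties)
      prob[test] <- svm_prob(fit, x_te)
    }
    ra <- roc_auc(prob, sub$label)
    if (r == 1L) roc1 <- ra$roc
    m <- compute_metrics(confusion_counts(sub$label == 1L, prob > cutoff))
    metrics[[r]] <- c(AUC = ra$auc, m)
  }
  metrics <- as.data.frame(do.call(rbind, metrics))
  structure(list(
    metrics = metrics, summary = summarize_metrics(metrics), roc = roc1,
    encoding = encoding, k = as.integer(k), repeats = as.integer(repeats),
    gamma = gamma, cost = cost, cutoff = cutoff, seed = seed,
    n_balanced = 2L * n_pos, call = match.call()
  ), class = "soh_cv")
}

# Stratified fold assignment: within each class, shuffle and deal folds
# round-robin, so every fold holds both classes whenever k <= class size.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' @export
print.soh_cv <- function(x, digits = 4, ...) {
  cat(sprintf("Repeated balanced cross-validation: %d-fold x %d repeats\n",
              x$k, x$repeats))
  cat(sprintf("  encoding: %s; gamma = %g, cost = %g, cutoff = %g; balanced n = %d\n",
              x$encoding, x$gamma, x$cost, x$cutoff, x$n_balanced))
  s <- x$summary
  fmt <- function(metric, pct) {
    row <- s[s$metric == metric, ]
    if (pct) sprintf("%.2f +/- %.2f", 100 * row$mean, 100 * row$sd)
    else sprintf("%.4f +/- %.4f", row$mean, row$sd)
  }
  cat(sprintf("  AUC %s | SN(%%) %s | SP(%%) %s | ACC(%%) %s | MCC %s\n",
              fmt("AUC", FALSE), fmt("SN", TRUE), fmt("SP", TRUE),
              fmt("ACC", TRUE), fmt("MCC", FALSE)))
  invisible(x)
}

#' @export
summary.soh_cv <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' Plot the cross-validated ROC curve
#'
#' Draws the pooled held-out ROC of the first repeat with the chance
#' diagonal, annotated with the mean cross-validated AUC.
#'
#' @param x A `soh_cv` object.
#' @param ... Further arguments passed to [plot()].
#' @export
plot.soh_cv <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2,
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (%s encoding)", x$encoding), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  auc <- x$summary$mean[x$summary$metric == "AUC"]
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("mean AUC = %.4f", auc))
  invisible(x)
}
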