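#' Confusion counts from truth and calls
#'
#' @param truth,call Binary vectors (logical, or 0/1) of equal length;
#'   1/`TRUE` is the modified (positive) class.
#' @return Named integer vector with elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, call) {
  truth <- as.logical(truth)
  call <- as.logical(call)
  stopifnot(length(truth) == length(call), !anyNA(truth), !anyNA(call))
  c(TP = sum(truth & call), FP = sum(!truth & call),
    TN = sum(!truth & !call), FN = sum(truth & !call))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, accuracy
#' `ACC = (TP+TN)/n` and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' When any factor of the MCC denominator is zero the coefficient is
#' undefined; 0 is returned with a warning, the usual convention.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN` (e.g. from
#'   [confusion_counts()]).
#' @return Named numeric vector `SN`, `SP`, `ACC`, `MCC` (fractions; MCC in
#'   \[-1, 1\]).
#' @export
compute_metrics <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  stopifnot(!anyNA(counts), all(counts >= 0))
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  n <- tp + fp + tn + fn
  if (n == 0) stop("no evaluated examples", call. = FALSE)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    warning("MCC denominator is zero; returning 0 by convention",
            call. = FALSE)
    mcc <- 0
  } else {
    mcc <- (tp * tn - fp * fn) / sqrt(denom)
  }
  c(SN = sn, SP = sp, ACC = acc, MCC = mcc)
}

#' ROC curve and area under it
#'
#' Threshold sweep over the unique scores, grouping tied scores into a
#' single step, with trapezoidal integration. The resulting AUC equals the
#' probability that a random positive outscores a random negative (ties
#' counting one half).
#'
#' @param scores Numeric prediction scores (higher means more likely
#'   positive).
#' @param labels Binary labels parallel to `scores`.
#' @return List with `roc`, a data frame of (`fpr`, `tpr`) points from
#'   (0,0) to (1,1), and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse ties: one step per unique score
  last_of_group <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(l)[last_of_group]
  fp <- cumsum(!l)[last_of_group]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Aggregate per-repeat metrics as mean and standard deviation
#'
#' @param reports Data frame (or list of named vectors) of per-repeat
#'   scalar metrics, e.g. the `metrics` element of a [soh_cv()] result.
#' @return Data frame with one row per metric and columns `metric`,
#'   `mean`, `sd` (sample standard deviation; 0 for a single report).
#' @export
summarize_metrics <- function(reports) {
  if (!is.data.frame(reports)) {
    reports <- as.data.frame(do.call(rbind, reports))
  }
  num <- reports[, vapply(reports, is.numeric, logical(1)), drop = FALSE]
  num <- num[, setdiff(names(num), "repeat."), drop = FALSE]
  stopifnot(nrow(num) >= 1L)
  data.frame(
    metric = names(num),
    mean = vapply(num, mean, numeric(1)),
    sd = if (nrow(num) > 1L) vapply(num, stats::sd, numeric(1))
         else rep(0, ncol(num)),
    row.names = NULL
  )
}
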