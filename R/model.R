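# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw a class-balanced subsample of a labelled dataset
#'
#' Keeps every positive window and draws, uniformly without replacement, a
#' matching number of negatives. Balancing the classes this way before
#' training avoids the high false-negative rate an SVM incurs on the raw
#' benchmark, where unmodified cysteines outnumber modified ones roughly
#' seven to one; repeating the draw and averaging integrates out the
#' sampling variability.
#'
#' @param dataset A `soh_dataset` (columns `window`, `label`).
#' @param seed Integer seed making the draw reproducible; `NULL` uses the
#'   current RNG state.
#' @return The balanced subset, positives first, as a `soh_dataset`.
#' @export
balanced_subsample <- function(dataset, seed = NULL) {
  stopifnot(is.data.frame(dataset), !is.null(dataset$label))
  pos <- which(dataset$label == 1L)
  neg <- which(dataset$label == 0L)
  if (length(neg) < length(pos)) {
    stop("fewer negatives (", length(neg), ") than positives (", length(pos),
         "); cannot balance by subsampling negatives", call. = FALSE)
  }
  take <- with_seed(seed, sample(neg, length(pos)))
  dataset[c(pos, sort(take)), , drop = FALSE]
}

# Deterministic RBF-SVM with Platt-sigmoid probability calibration.
# libsvm's decision values are deterministic; the sigmoid
# P(modified | f) = 1 / (1 + exp(a*f + b)) is fitted by logistic regression
# of the training labels on the training decision values.
svm_train <- function(x, y, gamma = 0.005, cost = 1) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  yf <- factor(y, levels = c(0L, 1L))
  fit <- e1071::svm(x, yf, kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  f <- decision_values(fit, x)
  platt <- suppressWarnings(
    stats::glm(y ~ f, family = stats::binomial())$coefficients
  )
  structure(list(svm = fit, platt = platt, dim = ncol(x)),
            class = "soh_svm")
}

decision_values <- function(fit, x) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  f <- as.numeric(dv)
  # libsvm orients the decision boundary by class order of appearance;
  # flip so larger values always mean the modified ('1') class.
  if (colnames(dv)[1L] == "0/1") -f else f
}

svm_prob <- function(model, x) {
  stopifnot(inherits(model, "soh_svm"))
  if (ncol(x) != model$dim) {
    stop("feature dimension (", ncol(x), ") does not match training (",
         model$dim, ")", call. = FALSE)
  }
  f <- decision_values(model$svm, x)
  as.numeric(stats::plogis(model$platt[1L] + model$platt[2L] * f))
}

#' Fit an S-sulfenylation site classifier
#'
#' Trains an ensemble of `n_models` RBF-kernel support vector machines,
#' each on a fresh class-balanced subsample of the training windows
#' ([balanced_subsample()]), and averages their calibrated probabilities at
#' prediction time. Encoder artifacts that depend on data — the PSAAP
#' propensity matrix — are fitted on the training positives only.
#'
#' @param dataset A labelled `soh_dataset` from [build_dataset()] (after
#'   any [redundancy_filter()] pass).
#' @param encoding Feature scheme: `"aaindex"` (default), `"binary"` or
#'   `"psaap"`.
#' @param gamma RBF kernel width parameter (default 0.005).
#' @param cost SVM margin penalty C (default 1).
#' @param cutoff Probability above which a cysteine is called modified
#'   (strictly greater; default 0.5).
#' @param n_models Number of balanced subsamples / ensemble members
#'   (default 20).
#' @param properties Optional property table for `encoding = "aaindex"`.
#' @param seed Integer seed controlling the negative subsampling.
#' @return An object of class `soh_model` with `print`, `summary` and
#'   `predict` methods.
#' @seealso [predict.soh_model()], [soh_cv()], [save_model()]
#' @export
soh_fit <- function(dataset, encoding = c("aaindex", "binary", "psaap"),
                    gamma = 0.005, cost = 1, cutoff = 0.5, n_models = 20L,
                    properties = NULL, seed = 1L) {
  encoding <- match.arg(encoding)
  stopifnot(is.data.frame(dataset), !is.null(dataset$label),
            gamma > 0, cost > 0, cutoff > 0, cutoff < 1, n_models >= 1L)
  n_pos <- sum(dataset$label == 1L)
  n_neg <- sum(dataset$label == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("training data contain a single class", call. = FALSE)
  }
  if (encoding == "aaindex" && is.null(properties)) {
    properties <- aa_properties()
  }
  psaap <- if (encoding == "psaap") {
    fit_psaap(dataset[dataset$label == 1L, ])
  }
  members <- lapply(seq_len(n_models), function(b) {
    sub <- balanced_subsample(dataset, seed = seed + b - 1L)
    x <- encode_windows(sub, encoding, psaap = psaap, properties = properties)
    svm_train(x, sub$label, gamma = gamma, cost = cost)
  })
  structure(list(
    members = members, encoding = encoding, psaap = psaap,
    properties = properties, gamma = gamma, cost = cost, cutoff = cutoff,
    n_models = as.integer(n_models), seed = seed,
    n_pos = n_pos, n_neg = n_neg, call = match.call()
  ), class = "soh_model")
}

#' Predict S-sulfenylation for cysteine windows
#'
#' Probabilities are the ensemble mean of the members' calibrated outputs;
#' a window is called modified when its probability strictly exceeds the
#' cutoff (so a probability exactly at the cutoff is a negative call).
#'
#' @param object A fitted `soh_model`.
#' @param newdata Windows to score: a character vector of 21-residue
#'   windows or a data frame with a `window` column (provenance columns
#'   `accession`/`position` are carried through).
#' @param cutoff Call threshold; defaults to the model's training cutoff.
#' @param ... Unused.
#' @return Data frame with the windows, their `probability` and the binary
#'   `call` (1 = modified).
#' @export
predict.soh_model <- function(object, newdata, cutoff = object$cutoff, ...) {
  windows <- as_windows(newdata)
  x <- encode_windows(windows, object$encoding, psaap = object$psaap,
                      properties = object$properties)
  probs <- rowMeans(vapply(object$members, svm_prob, numeric(nrow(x)), x = x))
  out <- if (is.data.frame(newdata)) {
    cols <- intersect(c("accession", "position", "window"), names(newdata))
    newdata[, cols, drop = FALSE]
  } else {
    data.frame(window = windows, stringsAsFactors = FALSE)
  }
  out$probability <- probs
  out$call <- as.integer(probs > cutoff)
  rownames(out) <- NULL
  out
}

#' Scan proteins for S-sulfenylation sites
#'
#' Extracts every cysteine-centered window from the proteins and scores it
#' with the model: the per-cysteine table a user wants from a FASTA file.
#'
#' @param model A fitted `soh_model`.
#' @param proteins Named character vector of protein sequences (e.g. from
#'   [read_fasta()]).
#' @param cutoff Call threshold; defaults to the model's.
#' @return Data frame with `accession`, `position`, `window`,
#'   `probability`, `call`; zero rows when the proteins contain no
#'   cysteine.
#' @export
predict_sites <- function(model, proteins, cutoff = model$cutoff) {
  windows <- extract_windows(proteins)
  if (nrow(windows) == 0L) {
    return(data.frame(accession = character(), position = integer(),
                      window = character(), probability = numeric(),
                      call = integer(), stringsAsFactors = FALSE))
  }
  predict(model, windows, cutoff = cutoff)
}

#' @export
print.soh_model <- function(x, ...) {
  cat("S-sulfenylation site classifier (RBF-SVM ensemble)\n")
  cat(sprintf("  encoding: %s (%d features)\n", x$encoding,
              x$members[[1L]]$dim))
  cat(sprintf("  ensemble: %d balanced subsamples; gamma = %g, cost = %g, cutoff = %g\n",
              x$n_models, x$gamma, x$cost, x$cutoff))
  cat(sprintf("  training windows: %d modified, %d unmodified\n",
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
summary.soh_model <- function(object, ...) {
  print(object)
  sv <- vapply(object$members, function(m) m$svm$tot.nSV, integer(1))
  cat(sprintf("  support vectors per member: median %d (range %d-%d)\n",
              as.integer(stats::median(sv)), min(sv), max(sv)))
  invisible(object)
}
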