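#' Position-specific residue composition of a window set
#'
#' Frequency of each residue at each of the 20 flanking positions (the
#' central cysteine is constant and omitted). Padding characters `'X'` are
#' excluded from the denominator, so short flanks do not dilute the
#' composition of the residues that are actually present; the `'X'` row is
#' therefore all zeros and each column with at least one real residue sums
#' to 1. The table is written in the orientation sequence-logo tools
#' consume.
#'
#' @param windows Windows (character vector or data frame with a `window`
#'   column).
#' @return 21 x 20 numeric matrix: rows residues `A..Y`, `X`; columns the
#'   flanking positions `-10..-1, +1..+10`.
#' @export
composition_matrix <- function(windows) {
  fl <- flank_matrix(windows)
  pos <- flank_positions(ncol(fl) %/% 2L, ncol(fl) - ncol(fl) %/% 2L)
  out <- apply(fl, 2L, function(col) {
    counts <- tabulate(match(col, ALPHABET), nbins = length(ALPHABET))
    counts[length(ALPHABET)] <- 0L           # drop padding
    n <- sum(counts)
    if (n > 0L) counts / n else counts
  })
  dimnames(out) <- list(ALPHABET, as.character(pos))
  out
}

#' Two-sample positional residue enrichment
#'
#' Contrasts, per (flanking position, residue) pair, the residue frequency
#' in a positive window set against a negative one — the numerical analogue
#' of a two-sample sequence logo. Each pair is tested with a two-proportion
#' z-test (chi-squared without continuity correction); when any expected
#' cell count falls below 5 the exact Fisher test is used instead. No
#' multiple-testing correction is applied: results are reported at the
#' fixed significance level `alpha`, the convention of two-sample logo
#' displays.
#'
#' @param pos_windows,neg_windows The two window sets.
#' @param alpha Significance level below which a pair is reported
#'   (default 0.01).
#' @return Data frame with columns `position`, `residue`, `direction`
#'   (`"enriched"` if the residue is more frequent in `pos_windows`, else
#'   `"depleted"`), `p_value`, `positive_freq`, `negative_freq`; only rows
#'   with `p_value < alpha`, ordered by position then p-value.
#' @export
two_sample_enrichment <- function(pos_windows, neg_windows, alpha = 0.01) {
  stopifnot(alpha > 0, alpha <= 1)
  fp <- flank_matrix(pos_windows)
  fn <- flank_matrix(neg_windows)
  if (ncol(fp) != ncol(fn)) {
    stop("window sets have different flank counts", call. = FALSE)
  }
  pos_labels <- flank_positions(ncol(fp) %/% 2L, ncol(fp) - ncol(fp) %/% 2L)
  rows <- list()
  for (j in seq_len(ncol(fp))) {
    colp <- fp[, j][fp[, j] != "X"]
    coln <- fn[, j][fn[, j] != "X"]
    n1 <- length(colp); n2 <- length(coln)
    if (n1 == 0L || n2 == 0L) next
    for (res in AA20) {
      k1 <- sum(colp == res); k2 <- sum(coln == res)
      if (k1 + k2 == 0L) next
      p <- two_proportion_p(k1, n1, k2, n2)
      if (p < alpha) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = pos_labels[j], residue = res,
          direction = if (k1 / n1 > k2 / n2) "enriched" else "depleted",
          p_value = p, positive_freq = k1 / n1, negative_freq = k2 / n2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(), residue = character(),
                      direction = character(), p_value = numeric(),
                      positive_freq = numeric(), negative_freq = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Two-sided p-value for H0: equal proportions, k1/n1 vs k2/n2.
# z-test via chi-squared without continuity correction; Fisher's exact
# test when any expected count is below 5.
two_proportion_p <- function(k1, n1, k2, n2) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(
      stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$p.value
    )
  }
}
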