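#' Load the bundled amino-acid physicochemical property table
#'
#' Fourteen AAindex scales — hydrophobicity, solvent accessibility,
#' polarity, polarizability, accessible surface area, pK-N, pK-C, melting
#' point, molecular weight, optical rotation, net charge of side chains,
#' entropy of formation, heat capacity and absolute entropy — for the 20
#' standard amino acids. The dummy padding residue `'X'` has value 0 on
#' every scale. The bundled file records the AAindex accession of each
#' scale; supply `path` to substitute your own table with the same layout.
#'
#' @param normalize If `TRUE` (default) each scale is min-max rescaled to
#'   \[0, 1\] over the 20 amino acids via [normalize_properties()], so that
#'   scales with large raw ranges (molecular weight, melting point) do not
#'   dominate the RBF kernel.
#' @param path Optional path to an alternative TSV with columns `property`,
#'   `accession`, then one column per residue `A..Y` and `X`.
#' @return Numeric matrix, 14 properties (rows) by 21 residues (columns).
#' @export
aa_properties <- function(normalize = TRUE, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "sohsite",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(ALPHABET %in% names(tab))) {
    stop("property table must have one column per residue A..Y plus X",
         call. = FALSE)
  }
  m <- as.matrix(tab[, ALPHABET])
  storage.mode(m) <- "double"
  rownames(m) <- tab$property
  if (nrow(m) != 14L) {
    stop("expected 14 property rows, found ", nrow(m), call. = FALSE)
  }
  if (normalize) m <- normalize_properties(m)
  m
}

#' Min-max normalize a property table
#'
#' Each property row is linearly rescaled so its minimum over the 20 amino
#' acids is 0 and its maximum 1; the `'X'` column stays 0 (padding carries
#' no physicochemical signal). Idempotent.
#'
#' @param table Numeric property matrix as returned by [aa_properties()].
#' @return The rescaled matrix.
#' @export
normalize_properties <- function(table) {
  stopifnot(is.matrix(table), all(ALPHABET %in% colnames(table)))
  aa <- table[, AA20, drop = FALSE]
  rng <- apply(aa, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  if (any(span == 0)) {
    stop("constant property row(s): ",
         paste(rownames(table)[span == 0], collapse = ", "), call. = FALSE)
  }
  out <- (aa - rng[1L, ]) / span
  out <- cbind(out, X = 0)
  out[, colnames(table), drop = FALSE]
}

# Flank residues of each window as an n x (xi+eta) character matrix, the
# central cysteine removed; validates alphabet and centering.
flank_matrix <- function(windows) {
  m <- window_char_matrix(windows)
  if (ncol(m) %% 2L == 0L) {
    stop("windows must have odd length (a single central residue)",
         call. = FALSE)
  }
  check_window_matrix(m)
  center <- (ncol(m) + 1L) %/% 2L
  m[, -center, drop = FALSE]
}

#' One-hot (binary) window encoding
#'
#' Each of the 20 flanking positions contributes a 21-length indicator
#' block (residues in order `A..Y` then `X`), concatenated upstream-to-
#' downstream for a 420-dimensional vector per window. The central
#' cysteine, being constant, is omitted.
#'
#' @param windows Character vector of 21-residue windows (or a data frame
#'   with a `window` column).
#' @return Numeric matrix, one row per window, 420 columns.
#' @export
encode_binary <- function(windows) {
  fl <- flank_matrix(windows)
  n <- nrow(fl)
  k <- ncol(fl)
  a <- length(ALPHABET)
  idx <- match(fl, ALPHABET)                      # column-major over fl
  out <- matrix(0, n, k * a)
  pos <- rep(seq_len(k), each = n)                # flank position of each cell
  out[cbind(rep(seq_len(n), k), (pos - 1L) * a + idx)] <- 1
  colnames(out) <- paste0("p", rep(flank_positions(k %/% 2L, k - k %/% 2L),
                                   each = a), ".", ALPHABET)
  out
}

#' Decode a one-hot encoded matrix back to windows
#'
#' Inverse of [encode_binary()]; reinserts the constant central cysteine.
#'
#' @param x Matrix produced by [encode_binary()].
#' @return Character vector of windows.
#' @export
decode_binary <- function(x) {
  a <- length(ALPHABET)
  stopifnot(ncol(x) %% a == 0L)
  k <- ncol(x) %/% a
  apply(x, 1L, function(row) {
    blocks <- matrix(row, nrow = a)
    res <- ALPHABET[apply(blocks, 2L, which.max)]
    paste(c(res[seq_len(k %/% 2L)], "C", res[(k %/% 2L + 1L):k]),
          collapse = "")
  })
}

#' Fit a position-specific amino-acid propensity (PSAAP) matrix
#'
#' Entry (r, p) is the frequency of residue r at flanking position p among
#' the supplied windows — by convention the modified (positive) training
#' peptides, so the matrix captures the positional residue propensity of
#' the modified class. Every column sums to 1.
#'
#' @param windows Positive training windows (character vector or data frame
#'   with a `window` column).
#' @return 21 x 20 numeric matrix; rows are residues `A..Y`, `X`, columns
#'   the flanking positions `-10..-1, +1..+10`.
#' @export
fit_psaap <- function(windows) {
  fl <- flank_matrix(windows)
  pos <- flank_positions(ncol(fl) %/% 2L, ncol(fl) - ncol(fl) %/% 2L)
  counts <- apply(fl, 2L, function(col) {
    tabulate(match(col, ALPHABET), nbins = length(ALPHABET))
  })
  freq <- counts / nrow(fl)
  dimnames(freq) <- list(ALPHABET, as.character(pos))
  freq
}

#' PSAAP window encoding
#'
#' Position j of the output is the fitted propensity of the window's
#' residue at flanking position j: a 20-dimensional vector of positional
#' frequencies looked up in `matrix`.
#'
#' @param windows Windows to encode.
#' @param matrix A propensity matrix from [fit_psaap()].
#' @return Numeric matrix, one row per window, 20 columns.
#' @export
encode_psaap <- function(windows, matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(ALPHABET))
  fl <- flank_matrix(windows)
  if (ncol(fl) != ncol(matrix)) {
    stop("window flank count (", ncol(fl), ") does not match PSAAP matrix (",
         ncol(matrix), " positions)", call. = FALSE)
  }
  out <- vapply(seq_len(ncol(fl)), function(j) {
    matrix[cbind(match(fl[, j], ALPHABET), j)]
  }, numeric(nrow(fl)))
  out <- matrix(out, nrow = nrow(fl))
  colnames(out) <- colnames(matrix)
  out
}

#' AAindex physicochemical window encoding
#'
#' Each flanking position contributes the 14 property values of its
#' residue, concatenated upstream-to-downstream: a 280-dimensional vector
#' per window. Padding residues (`'X'`) contribute 14 zeros.
#'
#' @param windows Windows to encode.
#' @param table Property matrix from [aa_properties()]; the normalized
#'   bundled table by default.
#' @return Numeric matrix, one row per window, 280 columns.
#' @export
encode_aaindex <- function(windows, table = aa_properties()) {
  stopifnot(is.matrix(table), all(ALPHABET %in% colnames(table)))
  fl <- flank_matrix(windows)
  n <- nrow(fl)
  k <- ncol(fl)
  p <- nrow(table)
  vals <- table[, fl, drop = FALSE]     # p x (n*k), fl read column-major
  out <- matrix(0, n, k * p)
  for (j in seq_len(k)) {
    block <- t(vals[, ((j - 1L) * n + 1L):(j * n), drop = FALSE])
    out[, ((j - 1L) * p + 1L):(j * p)] <- block
  }
  pos <- flank_positions(k %/% 2L, k - k %/% 2L)
  colnames(out) <- paste0("p", rep(pos, each = p), ".", rownames(table))
  out
}

#' Encode windows under a named scheme
#'
#' Dispatcher over the three encodings. For `"psaap"` a fitted propensity
#' matrix must be supplied (it is fitted on training positives only — never
#' on the windows being encoded — to avoid information leakage).
#'
#' @param windows Windows to encode.
#' @param scheme One of `"aaindex"`, `"binary"`, `"psaap"`.
#' @param psaap PSAAP matrix (required for `scheme = "psaap"`).
#' @param properties Property table (for `scheme = "aaindex"`; defaults to
#'   the bundled normalized table).
#' @return Numeric feature matrix, one row per window.
#' @export
encode_windows <- function(windows, scheme = c("aaindex", "binary", "psaap"),
                           psaap = NULL, properties = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    binary = encode_binary(windows),
    psaap = {
      if (is.null(psaap)) {
        stop("scheme 'psaap' requires a fitted propensity matrix", call. = FALSE)
      }
      encode_psaap(windows, psaap)
    },
    aaindex = encode_aaindex(windows,
                             if (is.null(properties)) aa_properties()
                             else properties)
  )
}
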