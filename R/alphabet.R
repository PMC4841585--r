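# Residue alphabet shared across the package.
#
# The 20 standard amino acids in alphabetical one-letter order, plus the
# dummy residue 'X' used to pad windows that run off a protein terminus.
# 'X' always sorts last, so one-hot blocks are A..Y then X.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ALPHABET <- c(AA20, "X")

# Flanking position labels for a window with xi upstream and eta downstream
# residues; the central cysteine (position 0) is never encoded.
flank_positions <- function(xi = 10L, eta = 10L) {
  c(seq.int(-xi, -1L), seq.int(1L, eta))
}

# Split windows (character vector of equal-length strings) into a matrix of
# single characters, one row per window.
window_char_matrix <- function(windows) {
  windows <- as_windows(windows)
  n <- length(windows)
  w <- nchar(windows[1L])
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = n, ncol = w, byrow = TRUE)
}

# Accept either a character vector of windows or a data frame with a
# `window` column (e.g. the labelled dataset) everywhere windows are consumed.
as_windows <- function(x) {
  if (is.data.frame(x)) {
    if (is.null(x$window)) {
      stop("data frame has no 'window' column", call. = FALSE)
    }
    x <- x$window
  }
  x <- as.character(x)
  if (length(x) == 0L) {
    stop("no windows supplied", call. = FALSE)
  }
  len <- unique(nchar(x))
  if (length(len) != 1L) {
    stop("windows have unequal lengths: ", paste(len, collapse = ", "),
         call. = FALSE)
  }
  x
}

# Validate that all characters of a window matrix are in the alphabet and
# that the central column is cysteine.
check_window_matrix <- function(m) {
  center <- (ncol(m) + 1L) %/% 2L
  if (!all(m[, center] == "C")) {
    bad <- which(m[, center] != "C")[1L]
    stop("window ", bad, " is not centered on a cysteine", call. = FALSE)
  }
  bad <- !(m %in% ALPHABET)
  if (any(bad)) {
    stop("window contains characters outside the 21-letter alphabet: ",
         paste(unique(m[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(m)
}
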