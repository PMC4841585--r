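#' Extract cysteine-centered peptide windows from protein sequences
#'
#' Every cysteine in every input protein yields one window of
#' `xi + eta + 1` residues: `xi` upstream residues, the central `C`, and
#' `eta` downstream residues. Where a cysteine sits closer than `xi`/`eta`
#' residues to a protein terminus, the missing flank is padded with the
#' dummy residue `"X"`, so padding only ever appears as a contiguous prefix
#' and/or suffix.
#'
#' Non-standard residue codes (`B`, `Z`, `J`, `U`, `O`, `*`, and anything
#' else outside the 20 standard amino acids) are mapped to `"X"` with a
#' warning, so real-world FASTA files remain usable.
#'
#' @param proteins Named character vector of protein sequences (names are
#'   accessions), or a single unnamed sequence.
#' @param xi,eta Number of upstream / downstream flank residues (default 10,
#'   giving 21-residue windows).
#' @return A data frame with columns `accession`, `position` (1-based
#'   position of the central cysteine in the protein) and `window`.
#' @examples
#' extract_windows(c(P1 = "MKCALCW"), xi = 3, eta = 3)
#' @export
extract_windows <- function(proteins, xi = 10L, eta = 10L) {
  stopifnot(xi >= 1L, eta >= 1L)
  proteins <- stats::setNames(as.character(proteins), names(proteins))
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    if (length(proteins) == 1L) {
      names(proteins) <- "protein"
    } else {
      stop("multiple sequences must be named with accessions", call. = FALSE)
    }
  }
  out <- lapply(names(proteins), function(acc) {
    seq <- clean_sequence(proteins[[acc]], acc)
    if (!nzchar(seq)) {
      stop("protein '", acc, "' has an empty sequence", call. = FALSE)
    }
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hits <- which(chars == "C")
    if (length(hits) == 0L) {
      return(data.frame(accession = character(), position = integer(),
                        window = character(), stringsAsFactors = FALSE))
    }
    padded <- c(rep("X", xi), chars, rep("X", eta))
    win <- vapply(hits, function(p) {
      paste(padded[p:(p + xi + eta)], collapse = "")
    }, character(1))
    data.frame(accession = acc, position = hits, window = win,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Uppercase and map residue codes outside the 20-letter amino-acid alphabet
# (ambiguity codes B/Z/J, selenocysteine U, pyrrolysine O, stop '*', gaps)
# to the dummy residue 'X', warning once per protein.
clean_sequence <- function(seq, accession = "protein") {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% AA20) & chars != "X"
  if (any(bad)) {
    warning("protein '", accession, "': ", sum(bad),
            " non-standard residue(s) (", paste(unique(chars[bad]), collapse = ","),
            ") mapped to 'X'", call. = FALSE)
    chars[bad] <- "X"
    seq <- paste(chars, collapse = "")
  }
  seq
}

#' Assemble a labelled cysteine window dataset
#'
#' Windows at experimentally annotated sites become positives; every other
#' cysteine window from the same proteins becomes a negative. This mirrors
#' the usual benchmark construction for cysteine modification predictors:
#' the negative class is all unannotated cysteines of the very proteins in
#' which positives were observed.
#'
#' @param proteins Named character vector of protein sequences.
#' @param positive_sites Data frame with columns `accession` and `position`
#'   (1-based) identifying the modified cysteines.
#' @param xi,eta Flank lengths passed to [extract_windows()].
#' @return A data frame of class `soh_dataset` with columns `accession`,
#'   `position`, `window`, `label` (1 = modified, 0 = unmodified).
#' @export
build_dataset <- function(proteins, positive_sites, xi = 10L, eta = 10L) {
  windows <- extract_windows(proteins, xi = xi, eta = eta)
  stopifnot(is.data.frame(positive_sites),
            all(c("accession", "position") %in% names(positive_sites)))
  key <- paste(windows$accession, windows$position)
  pos_key <- paste(positive_sites$accession, positive_sites$position)
  if (anyDuplicated(pos_key)) {
    stop("duplicate positive sites: ",
         paste(unique(pos_key[duplicated(pos_key)]), collapse = "; "),
         call. = FALSE)
  }
  missing <- !(positive_sites$accession %in% names(proteins))
  if (any(missing)) {
    stop("accession(s) not found among proteins: ",
         paste(unique(positive_sites$accession[missing]), collapse = ", "),
         call. = FALSE)
  }
  not_c <- !(pos_key %in% key)
  if (any(not_c)) {
    i <- which(not_c)[1L]
    stop("annotated site is not a cysteine: ", positive_sites$accession[i],
         " position ", positive_sites$position[i], call. = FALSE)
  }
  windows$label <- as.integer(key %in% pos_key)
  class(windows) <- c("soh_dataset", "data.frame")
  windows
}

#' Remove redundant windows by pairwise sequence identity
#'
#' Greedy representative-keeping scan in input order (as CD-HIT does):
#' a window is dropped if its identity to any previously kept window is at
#' least `threshold`. Identity between two equal-length windows is the
#' fraction of positions carrying the same character, with the fixed window
#' length (padding included, `'X'` matching `'X'` counted) as denominator.
#'
#' @param dataset A `soh_dataset` (or any data frame with a `window` column).
#' @param threshold Identity fraction at or above which the later window of
#'   a pair is removed (default 0.40).
#' @return The dataset restricted to the kept rows, original order preserved.
#' @export
redundancy_filter <- function(dataset, threshold = 0.40) {
  stopifnot(threshold > 0, threshold <= 1)
  m <- window_char_matrix(dataset)
  n <- nrow(m)
  w <- ncol(m)
  min_matches <- threshold * w
  keep <- logical(n)
  kept_rows <- matrix(character(), nrow = 0L, ncol = w)
  for (i in seq_len(n)) {
    if (nrow(kept_rows) == 0L) {
      redundant <- FALSE
    } else {
      matches <- colSums(t(kept_rows) == m[i, ])
      redundant <- any(matches >= min_matches)
    }
    if (!redundant) {
      keep[i] <- TRUE
      kept_rows <- rbind(kept_rows, m[i, , drop = FALSE])
    }
  }
  if (is.data.frame(dataset)) dataset[keep, , drop = FALSE] else dataset[keep]
}

#' Pairwise identity between two equal-length windows
#'
#' @param a,b Window strings of equal length.
#' @return Fraction of positions with identical characters.
#' @export
window_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}
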