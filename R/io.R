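#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [seqinr::read.fasta()] returning sequences as a named
#' uppercase character vector, the form consumed by [extract_windows()] and
#' [build_dataset()].
#'
#' @param path Path to a (possibly line-wrapped, multi-record) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no sequences in ", path, call. = FALSE)
  out <- toupper(vapply(recs, as.character, character(1)))
  names(out) <- vapply(recs, function(r) attr(r, "name"), character(1))
  if (anyDuplicated(names(out))) {
    stop("duplicate accessions in ", path, ": ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  seqinr::write.fasta(as.list(unname(proteins)), names = names(proteins),
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Read a site annotation table
#'
#' Tab-separated table with header columns `accession`, `position`
#' (1-based) and optionally `label` (1 = modified, 0 = unmodified).
#'
#' @param path Path to the TSV file.
#' @return Data frame with `accession` (character), `position` (integer) and,
#'   when present in the file, `label` (integer).
#' @export
read_sites <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position")
  if (!all(need %in% names(tab))) {
    stop("site table must have columns 'accession' and 'position': ", path,
         call. = FALSE)
  }
  tab$accession <- as.character(tab$accession)
  pos <- suppressWarnings(as.integer(tab$position))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop("invalid position at data row(s) ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  tab$position <- pos
  if ("label" %in% names(tab)) {
    lab <- suppressWarnings(as.integer(tab$label))
    if (any(is.na(lab) | !(lab %in% c(0L, 1L)))) {
      stop("labels must be 0 or 1: ", path, call. = FALSE)
    }
    tab$label <- lab
  }
  tab
}

#' Write a site table or labelled dataset as TSV
#'
#' @param x Data frame (e.g. a `soh_dataset`).
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled window dataset written by [write_tsv()]
#'
#' @param path Path to a TSV with columns `accession`, `position`, `window`,
#'   `label`.
#' @return A `soh_dataset` data frame.
#' @export
read_dataset <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "window", "label")
  if (!all(need %in% names(tab))) {
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$label <- as.integer(tab$label)
  check_window_matrix(window_char_matrix(tab$window))
  class(tab) <- c("soh_dataset", "data.frame")
  tab
}

#' Save a fitted model to disk
#'
#' The archive is a self-describing RDS container holding the classifier
#' ensemble, the encoding scheme and its fitted artifacts (PSAAP matrix,
#' property table) and the training configuration; [load_model()] restores
#' it bit-exactly.
#'
#' @param model A `soh_model` from [soh_fit()].
#' @param path Output path (conventionally `.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "soh_model"))
  saveRDS(list(format = "sohsite-model", version = 1L, model = model), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Path to the model archive.
#' @return The restored `soh_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "sohsite-model")) {
    stop("not a sohsite model archive: ", path, call. = FALSE)
  }
  obj$model
}
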