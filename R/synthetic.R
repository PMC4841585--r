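#' Default planted motif for the synthetic benchmark
#'
#' One enrichment rule per flanking position, emulating the positional
#' signature reported for S-sulfenylated peptides: lysine upstream at
#' -6, -5, -2 and downstream at +7, +8; arginine at -4; glutamate at -3
#' and downstream at +1, +3, +4, +5. Each rule fires with probability
#' 0.35 against an otherwise uniform background.
#'
#' @param probability Per-rule firing probability (default 0.35).
#' @return Data frame with columns `position`, `residue`, `probability`.
#' @export
soh_motif_rules <- function(probability = 0.35) {
  data.frame(
    position = c(-6L, -5L, -2L, 7L, 8L, -4L, -3L, 1L, 3L, 4L, 5L),
    residue = c("K", "K", "K", "K", "K", "R", "E", "E", "E", "E", "E"),
    probability = probability,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cysteine-site benchmark with a planted motif
#'
#' Emits one protein per labelled site: a single central cysteine with
#' flanks drawn residue-by-residue from a background distribution, plus the
#' site annotation table. Positive-site flanks are overridden by the
#' enrichment rules: at a rule's position the rule's residue is planted
#' with the stated probability (multiple rules may share a position if
#' their probabilities sum to at most 1), otherwise the background is
#' drawn. Flank lengths are sampled from rounded normals emulating the
#' short tryptic peptides of sulfenylome experiments (upstream mean 5.8,
#' sd 4.7; downstream mean 7.0, sd 4.5; truncated to \[0, xi\]/\[0, eta\]),
#' so terminal `'X'` padding paths are exercised; positive flanks are
#' additionally long enough to carry every planted position. The
#' background excludes cysteine, so each protein contains exactly one
#' labelled cysteine and class counts are exact.
#'
#' @param n_positive,n_negative Number of modified / unmodified sites.
#' @param rules Enrichment rules as in [soh_motif_rules()]; a zero-row
#'   data frame plants no signal.
#' @param background Named probability vector over residues for flank
#'   sampling; default uniform over the 19 non-cysteine amino acids.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param xi,eta Flank lengths of the extraction windows (default 10).
#' @return List with `proteins` (named character vector, FASTA-writable)
#'   and `sites` (data frame `accession`, `position`, `label`).
#' @export
generate_benchmark <- function(n_positive, n_negative,
                               rules = soh_motif_rules(), background = NULL,
                               seed = 1L, xi = 10L, eta = 10L) {
  stopifnot(n_positive >= 1L, n_negative >= 1L)
  if (is.null(background)) {
    bg_res <- setdiff(AA20, "C")
    background <- stats::setNames(rep(1 / length(bg_res), length(bg_res)),
                                  bg_res)
  }
  stopifnot(all(background >= 0), sum(background) > 0,
            all(names(background) %in% AA20))
  background <- background / sum(background)
  rules <- validate_rules(rules, xi, eta)
  max_up <- if (nrow(rules)) max(0L, -min(rules$position)) else 0L
  max_down <- if (nrow(rules)) max(0L, max(rules$position)) else 0L

  n <- n_positive + n_negative
  label <- rep(c(1L, 0L), c(n_positive, n_negative))
  with_seed(seed, {
    up_len <- clip_int(stats::rnorm(n, 5.8, 4.7), 0L, xi)
    down_len <- clip_int(stats::rnorm(n, 7.0, 4.5), 0L, eta)
    up_len[label == 1L] <- pmax(up_len[label == 1L], max_up)
    down_len[label == 1L] <- pmax(down_len[label == 1L], max_down)
    proteins <- character(n)
    for (i in seq_len(n)) {
      up <- draw_flank(up_len[i], -rev(seq_len(up_len[i])),
                       if (label[i] == 1L) rules else rules[0L, ],
                       background)
      down <- draw_flank(down_len[i], seq_len(down_len[i]),
                         if (label[i] == 1L) rules else rules[0L, ],
                         background)
      proteins[i] <- paste(c(up, "C", down), collapse = "")
    }
  })
  names(proteins) <- sprintf("SYN%05d", seq_len(n))
  sites <- data.frame(accession = names(proteins),
                      position = up_len + 1L,
                      label = label, stringsAsFactors = FALSE)
  list(proteins = proteins, sites = sites)
}

# Round-and-truncate a normal draw into [lo, hi].
clip_int <- function(x, lo, hi) {
  pmin(pmax(as.integer(round(x)), lo), hi)
}

validate_rules <- function(rules, xi, eta) {
  stopifnot(is.data.frame(rules),
            all(c("position", "residue", "probability") %in% names(rules)))
  if (nrow(rules) == 0L) return(rules)
  if (any(rules$probability < 0 | rules$probability > 1)) {
    stop("rule probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(rules$position == 0L | rules$position < -xi | rules$position > eta)) {
    stop("rule positions must lie in -xi..-1 or 1..eta", call. = FALSE)
  }
  if (!all(rules$residue %in% AA20)) {
    stop("rule residues must be standard amino acids", call. = FALSE)
  }
  mass <- tapply(rules$probability, rules$position, sum)
  if (any(mass > 1 + 1e-12)) {
    stop("rule probabilities at a single position must sum to at most 1",
         call. = FALSE)
  }
  rules
}

# Draw `len` flank residues at the given window positions: rules fire with
# their probabilities, otherwise the background distribution is used.
draw_flank <- function(len, positions, rules, background) {
  if (len == 0L) return(character(0))
  res <- sample(names(background), len, replace = TRUE, prob = background)
  for (j in seq_len(len)) {
    at <- rules[rules$position == positions[j], , drop = FALSE]
    if (nrow(at) == 0L) next
    u <- stats::runif(1)
    cum <- cumsum(at$probability)
    hit <- which(u < cum)
    if (length(hit)) res[j] <- at$residue[hit[1L]]
  }
  res
}

#' Generate a null benchmark (labels independent of sequence)
#'
#' All flanks are background draws and labels are assigned independently
#' of the sequence, so any classifier's true cross-validated AUC is 0.5:
#' the calibration control for the modelling pipeline.
#'
#' @param n Sites per class.
#' @param seed Integer seed.
#' @inheritParams generate_benchmark
#' @return As [generate_benchmark()].
#' @export
null_benchmark <- function(n, seed = 1L, xi = 10L, eta = 10L) {
  stopifnot(n >= 2L)
  generate_benchmark(n, n, rules = soh_motif_rules()[0L, ], seed = seed,
                     xi = xi, eta = eta)
}
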