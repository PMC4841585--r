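# Shared fixture builders: windows are built in code, nothing is read from
# disk except files the tests themselves write to tempdir().

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 21-residue window from explicit flanks (default arbitrary residues).
toy_window <- function(up = "ARNDKLMNPQ", down = "RSTVWYAEGH") {
  stopifnot(nchar(up) == 10L, nchar(down) == 10L)
  paste0(up, "C", down)
}

# n random valid windows over the 20 amino acids (no padding).
random_windows <- function(n, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(c(sample(aa, 10, TRUE), "C", sample(aa, 10, TRUE)), collapse = "")
  }, character(1)))
}

# A window sharing exactly `m` of 21 positions with toy 'AAAA...C...AAAA'
# (the central C always matches, so m - 1 flank positions are kept as 'A').
poly_a_window <- function() paste0(strrep("A", 10), "C", strrep("A", 10))

window_matching_polyA_at <- function(m) {
  stopifnot(m >= 1L, m <= 21L)
  flanks <- rep("K", 20L)
  flanks[seq_len(m - 1L)] <- "A"
  paste(c(flanks[1:10], "C", flanks[11:20]), collapse = "")
}

# Tiny labelled dataset straight from the generator.
small_benchmark_dataset <- function(n_pos, n_neg, seed = 1,
                                    rules = soh_motif_rules()) {
  b <- generate_benchmark(n_pos, n_neg, rules = rules, seed = seed)
  build_dataset(b$proteins,
                b$sites[b$sites$label == 1L, c("accession", "position")])
}

# Brute-force pairwise-concordance AUC: P(score_pos > score_neg) + 0.5 ties.
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
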