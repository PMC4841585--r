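test_that("one-hot encoding places a single 1 per 21-residue block, A first and X last", {
  all_a <- poly_a_window()
  v <- encode_binary(all_a)
  expect_equal(ncol(v), 420L)
  expect_equal(unname(which(v[1, ] == 1)), (0:19) * 21 + 1)   # offset 0 of each block

  all_x <- "XXXXXXXXXXCXXXXXXXXXX"
  v <- encode_binary(all_x)
  expect_equal(unname(which(v[1, ] == 1)), (0:19) * 21 + 21)  # offset 20 of each block

  for (w in random_windows(5, seed = 2)) {
    v <- encode_binary(w)
    expect_equal(sum(v == 1), 20)
    expect_equal(sum(v == 0), 400)
  }
  expect_error(encode_binary(paste0(strrep("A", 10), "C", "B", strrep("A", 9))),
               "alphabet")
})

test_that("one-hot encoding is invertible and equivariant under flank swaps", {
  ws <- random_windows(10, seed = 4)
  expect_equal(decode_binary(encode_binary(ws)), ws)

  # swapping two flank residues swaps their blocks and touches nothing else
  w <- toy_window(up = "ARNDKLMNPQ", down = "RSTVWYAEGH")
  swapped <- toy_window(up = "RANDKLMNPQ", down = "RSTVWYAEGH")  # swap flanks 1,2
  v1 <- matrix(encode_binary(w), nrow = 21)      # one column per flank position
  v2 <- matrix(encode_binary(swapped), nrow = 21)
  expect_equal(v2[, 1], v1[, 2])
  expect_equal(v2[, 2], v1[, 1])
  expect_equal(v2[, 3:20], v1[, 3:20])
})

test_that("PSAAP fitting gives positional frequencies with unit column sums", {
  # both training windows carry K at -1
  w <- c(toy_window(up = "ARNDKLMNPK"), toy_window(up = "GGGGGGGGGK"))
  m <- fit_psaap(w)
  expect_equal(dim(m), c(21L, 20L))
  expect_equal(m["K", "-1"], 1.0)

  # K,K,R,E at +1 across four windows
  w4 <- vapply(c("K", "K", "R", "E"), function(r) {
    toy_window(down = paste0(r, "STVWYAEGH"))
  }, character(1))
  m4 <- fit_psaap(w4)
  expect_equal(m4["K", "1"], 0.5)
  expect_equal(m4["R", "1"], 0.25)
  expect_equal(m4["E", "1"], 0.25)
  expect_equal(unname(colSums(m4)), rep(1, 20), tolerance = 1e-12)

  expect_error(fit_psaap(character(0)), "no windows")
})

test_that("PSAAP encoding looks up fitted frequencies and never alters the matrix", {
  train <- toy_window()
  m <- fit_psaap(train)
  expect_equal(as.numeric(encode_psaap(train, m)), rep(1, 20))

  # residues never seen at their position in training encode to zero,
  # even for a residue absent from training altogether (fold-unique probe)
  probe <- toy_window(up = "FFFFFFFFFF", down = "FFFFFFFFFF")
  before <- m
  enc <- encode_psaap(probe, m)
  expect_equal(as.numeric(enc), rep(0, 20))
  expect_identical(m, before)

  # hand lookup against the 4-window fit
  w4 <- vapply(c("K", "K", "R", "E"), function(r) {
    toy_window(down = paste0(r, "STVWYAEGH"))
  }, character(1))
  m4 <- fit_psaap(w4)
  v <- encode_psaap(toy_window(down = "KSTVWYAEGH"), m4)
  expect_equal(unname(v[1, "1"]), 0.5)        # K seen in 2 of 4 at +1
  expect_equal(unname(v[1, "2"]), 1.0)        # S in all four at +2
  expect_equal(unname(v[1, 1:10]), rep(1, 10))  # shared upstream flank
})

test_that("AAindex encoding emits 14 values per flank, zero for padding", {
  expect_equal(as.numeric(encode_aaindex("XXXXXXXXXXCXXXXXXXXXX")),
               rep(0, 280))
  v <- encode_aaindex(toy_window())
  expect_equal(ncol(v), 280L)
  # changing a single flank residue only touches that flank's 14 coordinates
  # (two residues may tie on an individual scale, e.g. equal net charge)
  v2 <- encode_aaindex(toy_window(up = "WRNDKLMNPQ"))
  diff <- which(v[1, ] != v2[1, ])
  expect_gt(length(diff), 0L)
  expect_true(all(diff %in% 1:14))
  expect_equal(v[1, -(1:14)], v2[1, -(1:14)])
})

test_that("property normalization is a [0,1] min-max over amino acids, X pinned at 0", {
  raw <- aa_properties(normalize = FALSE)
  expect_equal(dim(raw), c(14L, 21L))
  expect_equal(unname(raw[, "X"]), rep(0, 14))

  norm <- normalize_properties(raw)
  expect_equal(unname(apply(norm[, sohsite:::AA20], 1, min)), rep(0, 14))
  expect_equal(unname(apply(norm[, sohsite:::AA20], 1, max)), rep(1, 14))
  expect_equal(unname(norm[, "X"]), rep(0, 14))
  expect_equal(normalize_properties(norm), norm)   # idempotent

  # midpoint maps to 0.5
  fake <- raw
  fake[1, sohsite:::AA20] <- c(5, 10, rep(15, 18))
  expect_equal(unname(normalize_properties(fake)[1, "C"]), 0.5)

  fake[2, sohsite:::AA20] <- 7
  expect_error(normalize_properties(fake), "constant")
})

test_that("encoder dispatcher enforces the PSAAP matrix requirement", {
  w <- toy_window()
  expect_equal(ncol(encode_windows(w, "binary")), 420L)
  expect_error(encode_windows(w, "psaap"), "propensity")
  m <- fit_psaap(w)
  expect_equal(ncol(encode_windows(w, "psaap", psaap = m)), 20L)
})
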