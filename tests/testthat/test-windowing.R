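test_that("every cysteine yields one window, padded with X at termini", {
  w <- extract_windows(c(P = "C"))
  expect_equal(w$window, "XXXXXXXXXXCXXXXXXXXXX")
  expect_equal(w$position, 1L)

  w <- extract_windows(c(P1 = "ACDEFGHIKLMNPQRSTVWYC"))
  expect_equal(nrow(w), 2L)
  expect_equal(w$window[1], "XXXXXXXXXACDEFGHIKLMN")
  expect_equal(w$position[1], 2L)
  expect_equal(w$window[2], "MNPQRSTVWYCXXXXXXXXXX")
  expect_equal(w$position[2], 21L)

  # count conservation over a batch of random proteins
  withr::with_seed(11, {
    prots <- vapply(1:20, function(i) {
      paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
                   sample(5:60, 1), TRUE), collapse = "")
    }, character(1))
  })
  names(prots) <- paste0("P", seq_along(prots))
  w <- extract_windows(prots)
  expect_equal(nrow(w), sum(vapply(strsplit(prots, ""),
                                   function(x) sum(x == "C"), integer(1))))
  # padding only as contiguous prefix/suffix
  expect_true(all(grepl("^X*[^X].*[^X]X*$|^X*[^X]X*$", w$window)))
})

test_that("unpadded windows equal the protein substring around the site", {
  withr::with_seed(5, {
    seq <- paste(sample(strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]],
                        80, TRUE), collapse = "")
  })
  seq <- paste0(substr(seq, 1, 40), "C", substr(seq, 41, 80))
  w <- extract_windows(c(P = seq))
  full <- w[w$position > 10 & w$position <= nchar(seq) - 10, ]
  for (i in seq_len(nrow(full))) {
    expect_equal(full$window[i],
                 substr(seq, full$position[i] - 10, full$position[i] + 10))
  }
})

test_that("degenerate inputs are handled: empty, cysteine-free, non-standard", {
  expect_error(extract_windows(c(P = "")), "empty")
  expect_equal(nrow(extract_windows(c(P = "ARNDEF"))), 0L)
  expect_warning(w <- extract_windows(c(P = "BUCZO")), "mapped to 'X'")
  expect_equal(w$window, "XXXXXXXXXXCXXXXXXXXXX")
  expect_equal(w$position, 3L)
})

test_that("dataset assembly labels annotated sites positive, other cysteines negative", {
  prots <- c(P1 = "ACDEFCGHIKCLMN", P2 = "MKLV")
  sites <- data.frame(accession = "P1", position = 6L)
  ds <- build_dataset(prots, sites)
  expect_s3_class(ds, "soh_dataset")
  expect_equal(sum(ds$label == 1L), 1L)
  expect_equal(sum(ds$label == 0L), 2L)
  expect_equal(ds$label[ds$position == 6L], 1L)

  # zero annotated sites -> all negative
  ds0 <- build_dataset(prots, sites[0, ])
  expect_equal(sum(ds0$label), 0L)
  expect_equal(nrow(ds0), 3L)

  expect_error(build_dataset(prots, data.frame(accession = "P1", position = 3L)),
               "not a cysteine.*P1.*3")
  expect_error(build_dataset(prots, data.frame(accession = "P9", position = 1L)),
               "P9")
  expect_error(build_dataset(prots, data.frame(accession = c("P1", "P1"),
                                               position = c(6L, 6L))),
               "duplicate")
})

test_that("redundancy filter removes later windows at or above the identity threshold", {
  # identical pair: one survives
  ds <- data.frame(window = rep(poly_a_window(), 2), label = c(1L, 0L))
  expect_equal(nrow(redundancy_filter(ds, 0.40)), 1L)

  # 8 of 21 positions shared (38.1%) -> both survive
  w8 <- window_matching_polyA_at(8L)
  expect_equal(window_identity(poly_a_window(), w8), 8 / 21)
  both <- data.frame(window = c(poly_a_window(), w8), label = 1:0)
  expect_equal(nrow(redundancy_filter(both, 0.40)), 2L)

  # 9 of 21 positions shared (42.9%) -> the later one is removed
  w9 <- window_matching_polyA_at(9L)
  expect_equal(window_identity(poly_a_window(), w9), 9 / 21)
  pair <- data.frame(window = c(poly_a_window(), w9), label = 1:0)
  kept <- redundancy_filter(pair, 0.40)
  expect_equal(kept$window, poly_a_window())
})

test_that("redundancy filter is idempotent and keeps input order", {
  ds <- data.frame(window = random_windows(60, seed = 3),
                   label = rep_len(0:1, 60))
  once <- redundancy_filter(ds, 0.40)
  twice <- redundancy_filter(once, 0.40)
  expect_identical(once, twice)
  expect_true(all(diff(match(once$window, ds$window)) > 0))
  # no surviving pair at or above the threshold
  m <- vapply(once$window, function(a) {
    vapply(once$window, window_identity, numeric(1), a = a)
  }, numeric(nrow(once)))
  diag(m) <- 0
  expect_true(all(m < 0.40))
})
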